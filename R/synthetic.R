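#' Sample a synthetic alignment from a planted-coupling Potts model
#'
#' Gibbs-samples M sequences from P(s) proportional to
#' exp( sum_i h_i(s_i) + sum_(i,j) J delta(s_i, s_j) ), where the planted
#' pairs (i, j) carry a ferromagnetic ("matching-state") coupling of the
#' given strength. Each sequence is an independent chain burnt in for
#' `n_sweeps` full Gibbs sweeps from a uniform random start; all chains are
#' advanced in lockstep, so the whole sample is vectorised and fully
#' determined by `seed`. Optional near-duplicate rows (a parent row with 5%
#' of positions re-randomised) are appended to exercise sequence
#' reweighting.
#'
#' @param L alignment length.
#' @param q alphabet size (2-21; states use the first q symbols of the
#'   amino-acid alphabet, so q = 21 includes the gap).
#' @param M number of independent sequences.
#' @param planted_pairs data.frame with columns `i`, `j`, `coupling`;
#'   planted pairs must satisfy |i - j| >= 5 so they survive the
#'   minimum-separation filter.
#' @param fields optional L x q matrix of site biases (default 0).
#' @param n_sweeps Gibbs burn-in sweeps per sequence (default 50).
#' @param duplication_fraction fraction of near-duplicate rows appended
#'   (default 0).
#' @param seed integer seed; fully determines the output.
#' @return An [alignment][read_alignment] with ids `seq_*` (and `dup_*` for
#'   duplicates) and attribute `ground_truth` (list with `planted_pairs`).
#' @export
sample_potts_msa <- function(L, q, M, planted_pairs = NULL, fields = NULL,
                             n_sweeps = 50L, duplication_fraction = 0,
                             seed = NULL) {
  stopifnot(L >= 1L, q >= 2L, q <= 21L, M >= 1L)
  pp <- planted_pairs
  if (is.null(pp))
    pp <- data.frame(i = integer(), j = integer(), coupling = numeric())
  if (nrow(pp) > 0L) {
    stopifnot(all(pp$i >= 1L), all(pp$j <= L))
    if (any(abs(pp$i - pp$j) < 5L))
      stop("planted pairs must be separated by >= 5 positions")
  }
  if (is.null(fields)) fields <- matrix(0, L, q)
  stopifnot(all(dim(fields) == c(L, q)))
  ab <- aa_alphabet()[seq_len(q)]
  with_seed(seed, {
    S <- matrix(sample.int(q, M * L, replace = TRUE), nrow = M, ncol = L)
    partners <- lapply(seq_len(L), function(i) {
      a <- pp[pp$i == i, ]; b <- pp[pp$j == i, ]
      data.frame(site = c(a$j, b$i), coupling = c(a$coupling, b$coupling))
    })
    for (sweep in seq_len(n_sweeps)) {
      for (i in seq_len(L)) {
        logits <- matrix(fields[i, ], nrow = M, ncol = q, byrow = TRUE)
        pr <- partners[[i]]
        if (nrow(pr) > 0L) {
          for (r in seq_len(nrow(pr))) {
            sj <- S[, pr$site[r]]
            logits[cbind(seq_len(M), sj)] <-
              logits[cbind(seq_len(M), sj)] + pr$coupling[r]
          }
        }
        gumbel <- -log(-log(matrix(stats::runif(M * q), M, q)))
        S[, i] <- max.col(logits + gumbel, ties.method = "first")
      }
    }
    ids <- paste0("seq_", seq_len(M))
    n_dup <- round(duplication_fraction * M)
    if (n_dup > 0L) {
      parents <- sample.int(M, n_dup, replace = TRUE)
      D <- S[parents, , drop = FALSE]
      n_mut <- max(1L, round(0.05 * L))
      for (r in seq_len(n_dup)) {
        posn <- sample.int(L, n_mut)
        D[r, posn] <- sample.int(q, n_mut, replace = TRUE)
      }
      S <- rbind(S, D)
      ids <- c(ids, paste0("dup_", seq_len(n_dup)))
    }
    seqs <- matrix(ab[S], nrow = nrow(S))
    aln <- new_alignment(seqs, ids, alphabet = ab)
    attr(aln, "ground_truth") <- list(planted_pairs = pp, q = q, L = L,
                                      n_sweeps = n_sweeps, seed = seed)
    aln
  })
}

#' Deterministic toy C-alpha chains
#'
#' Idealised test structures with a paired random sequence:
#' `"extended"` is a straight chain at 3.8 A spacing; `"helix"` uses ideal
#' alpha-helix parameters (2.3 A radius, 1.5 A rise, 100 degrees per
#' residue); `"dimer"` is two mirror-image helical protomers of n/2
#' residues related by reflection through the plane y = 2.25 A (an exact
#' exchange symmetry, and non-planar so the elastic network has the full
#' six rigid-body modes).
#'
#' @param n number of residues (even for `"dimer"`).
#' @param geometry `"extended"`, `"helix"` or `"dimer"`.
#' @param seed seed for the random sequence (coordinates are deterministic).
#' @return List with `coords` (n x 3 matrix) and `sequence` (character
#'   vector of one-letter codes).
#' @export
make_toy_chain <- function(n, geometry = c("extended", "helix", "dimer"),
                           seed = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 2L)
  coords <- switch(geometry,
    extended = cbind(3.8 * (seq_len(n) - 1L), 0, 0),
    helix = {
      t <- (seq_len(n) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1L))
    },
    dimer = {
      if (n %% 2L != 0L) stop("dimer geometry needs an even n")
      half <- n %/% 2L
      t <- (seq_len(half) - 1L) * 100 * pi / 180
      one <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(half) - 1L))
      two <- one                       # mirror protomer: reflect y -> 4.5 - y
      two[, 2L] <- 4.5 - two[, 2L]
      rbind(one, two)
    })
  rownames(coords) <- seq_len(n)
  sequence <- with_seed(seed,
    sample(setdiff(aa_alphabet(), "-"), n, replace = TRUE))
  list(coords = coords, sequence = sequence)
}

#' Synthetic multi-predictor disorder score table
#'
#' Emulates a panel of per-residue disorder predictors: scores centre on
#' 0.7 inside the given disordered ranges and 0.15 outside, with a
#' per-predictor systematic offset (sd 0.04) and per-residue jitter
#' (sd 0.05), clipped to \[0, 1\].
#'
#' @param n number of residues.
#' @param disordered_ranges list of `c(start, end)` intervals (1-based,
#'   inclusive); overlapping ranges are merged with a warning.
#' @param n_predictors number of predictor columns (default 6, mirroring a
#'   typical consensus panel).
#' @param seed integer seed.
#' @return data.frame with `residue` and `predictor_1..n_predictors`.
#' @export
make_disorder_fixture <- function(n, disordered_ranges = list(),
                                  n_predictors = 6L, seed = NULL) {
  stopifnot(n >= 1L, n_predictors >= 1L)
  inside <- rep(FALSE, n)
  if (length(disordered_ranges) > 0L) {
    rng <- do.call(rbind, lapply(disordered_ranges, function(r) {
      stopifnot(length(r) == 2L, r[1L] >= 1L, r[2L] <= n, r[1L] <= r[2L])
      r
    }))
    cover <- integer(0)
    for (k in seq_len(nrow(rng))) {
      span <- rng[k, 1L]:rng[k, 2L]
      if (length(intersect(cover, span)) > 0L)
        warning("overlapping disordered ranges merged")
      cover <- union(cover, span)
    }
    inside[cover] <- TRUE
  }
  base <- ifelse(inside, 0.7, 0.15)
  with_seed(seed, {
    scores <- vapply(seq_len(n_predictors), function(p) {
      offset <- stats::rnorm(1, 0, 0.04)
      pmin(pmax(base + offset + stats::rnorm(n, 0, 0.05), 0), 1)
    }, numeric(n))
    out <- data.frame(residue = seq_len(n), scores)
    names(out) <- c("residue", paste0("predictor_", seq_len(n_predictors)))
    out
  })
}

#' Write a toy C-alpha chain as a PDB file
#'
#' @param chain output of [make_toy_chain()] (or any list with `coords` and
#'   `sequence`).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  n <- nrow(chain$coords)
  resid <- bio3d::aa123(chain$sequence)
  bio3d::write.pdb(file = path, xyz = as.vector(t(chain$coords)),
                   resno = seq_len(n), resid = resid,
                   elety = rep("CA", n), chain = rep("A", n))
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes everything the pipeline consumes: a Potts-model
#' alignment (FASTA), a toy structure (PDB), a multi-predictor disorder
#' table (TSV) and the generating ground truth (JSON), all determined by
#' one seed.
#'
#' @param dir output directory (created if needed).
#' @param L,q,M,planted_pairs,n_sweeps,duplication_fraction passed to
#'   [sample_potts_msa()].
#' @param seed integer seed for every stochastic component.
#' @return Named list of file paths, invisibly.
#' @export
simulate_fixture_bundle <- function(dir, L = 50L, q = 8L, M = 500L,
                                    planted_pairs = NULL, n_sweeps = 50L,
                                    duplication_fraction = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- sample_potts_msa(L, q, M, planted_pairs,
                          n_sweeps = n_sweeps,
                          duplication_fraction = duplication_fraction,
                          seed = seed)
  chain <- make_toy_chain(L, "helix", seed = seed + 1L)
  dis <- make_disorder_fixture(L, list(c(max(1L, L %/% 3L), L %/% 2L)),
                               seed = seed + 2L)
  paths <- list(msa = file.path(dir, "msa.fasta"),
                structure = file.path(dir, "structure.pdb"),
                disorder = file.path(dir, "disorder.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  write_alignment(aln, paths$msa, "fasta")
  write_chain_pdb(chain, paths$structure)
  utils::write.table(dis, paths$disorder, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(attr(aln, "ground_truth"), paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
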