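#' Sequence reweighting by pairwise identity
#'
#' Down-weights redundant alignment rows: sequence a receives weight
#' 1 / m^a, where m^a counts the sequences (including a itself) whose
#' fractional identity to a is at least `identity_threshold`. Identity is the
#' fraction of columns with matching symbols (gap-gap matches count). The sum
#' of weights is the effective sequence number M_eff.
#'
#' @param aln an [alignment][read_alignment] object.
#' @param identity_threshold fraction in (0, 1]; default 0.8, the usual
#'   direct-coupling-analysis convention.
#' @return An object of class `weight_set`: list with `weights`, `M_eff`,
#'   `identity_threshold`.
#' @export
compute_weights <- function(aln, identity_threshold = 0.8) {
  stopifnot(inherits(aln, "alignment"))
  if (!(identity_threshold > 0 && identity_threshold <= 1))
    stop("identity_threshold must be in (0, 1]")
  L <- ncol(aln$seq)
  A <- one_hot(aln$seq, aln$alphabet %||% aa_alphabet())
  sim <- as.matrix(Matrix::tcrossprod(A))    # pairwise matching-column counts
  m <- rowSums(sim >= identity_threshold * L - 1e-9)
  w <- 1 / m
  structure(list(weights = w, M_eff = sum(w),
                 identity_threshold = identity_threshold),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Sequence weights: M =", length(x$weights),
      " M_eff =", format(x$M_eff, digits = 6),
      " (identity threshold", x$identity_threshold, ")\n")
  invisible(x)
}

#' Reweighted, pseudocounted site frequencies
#'
#' Single-site and pairwise state frequencies from a weighted alignment with
#' a uniform pseudocount lambda spread over the q-state alphabet:
#' P_i(A) = (lambda/q + sum_a w_a d(A, A_i^a)) / (lambda + M_eff) and the
#' analogous pairwise form with lambda/q^2. Diagonal pair blocks are set to
#' P_ii(A,B) = d(A,B) P_i(A) so that marginal consistency holds everywhere.
#'
#' @param aln an [alignment][read_alignment] object.
#' @param w a [weight_set][compute_weights]; defaults to weights at 0.8.
#' @param lambda pseudocount weight (>= 0). Default `M_eff`, the mean-field
#'   DCA convention.
#' @return Object of class `frequency_model`: list with `f1` (L x q), `f2`
#'   (Lq x Lq, site-major blocks), `lambda`, `q`, `L`, `M_eff`.
#' @export
frequencies <- function(aln, w = compute_weights(aln), lambda = NULL) {
  stopifnot(inherits(aln, "alignment"), inherits(w, "weight_set"))
  ab <- aln$alphabet %||% aa_alphabet()
  q <- length(ab)
  L <- ncol(aln$seq)
  lambda <- lambda %||% w$M_eff
  if (lambda < 0) stop("lambda must be non-negative")
  A <- one_hot(aln$seq, ab)
  Aw <- A * w$weights
  denom <- lambda + w$M_eff
  f1 <- matrix((lambda / q + Matrix::colSums(Aw)) / denom, nrow = L,
               ncol = q, byrow = TRUE)
  f2 <- as.matrix(Matrix::crossprod(Aw, A))
  f2 <- (lambda / q^2 + f2) / denom
  for (i in seq_len(L)) {                 # exact diagonal blocks
    b <- .state_block(i, q)
    f2[b, b] <- diag(f1[i, ], nrow = q)
  }
  structure(list(f1 = f1, f2 = f2, lambda = lambda, q = q, L = L,
                 M_eff = w$M_eff),
            class = "frequency_model")
}

#' Mutual information between alignment columns
#'
#' MI_ij = sum_AB P_ij(A,B) log( P_ij(A,B) / (P_i(A) P_j(B)) ) in natural
#' log (nats); terms with P_ij = 0 contribute 0. Captures both direct and
#' transitively induced covariation between columns.
#'
#' @param fm a [frequency_model][frequencies].
#' @return Symmetric L x L matrix, zero diagonal.
#' @export
mutual_information <- function(fm) {
  stopifnot(inherits(fm, "frequency_model"))
  L <- fm$L; q <- fm$q
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    bi <- .state_block(i, q)
    for (j in (i + 1L):L) {
      P <- fm$f2[bi, .state_block(j, q)]
      ref <- outer(fm$f1[i, ], fm$f1[j, ])
      nz <- P > 0
      mi[i, j] <- mi[j, i] <- sum(P[nz] * log(P[nz] / ref[nz]))
    }
  }
  mi
}

#' Mean-field pair couplings (direct coupling analysis)
#'
#' Inverts the connected-correlation matrix C_ij(A,B) = P_ij(A,B) -
#' P_i(A) P_j(B), built over q-1 states per site (the last alphabet state —
#' the gap, for protein alignments — is removed as the reference, making C
#' invertible under a positive pseudocount), and returns the coupling
#' tensor e = -C^{-1} in the reference-state gauge.
#'
#' @param fm a [frequency_model][frequencies] computed with `lambda > 0`.
#' @return Object of class `mf_couplings`: list with `e` (L(q-1) x L(q-1)
#'   matrix; site-diagonal blocks zeroed), `q`, `L`.
#' @export
mean_field_couplings <- function(fm) {
  stopifnot(inherits(fm, "frequency_model"))
  if (fm$lambda <= 0)
    stop("mean-field inversion requires lambda > 0 (regularization)")
  L <- fm$L; q <- fm$q; qr <- q - 1L
  keep <- as.vector(vapply(seq_len(L),
                           function(i) .state_block(i, q)[seq_len(qr)],
                           integer(qr)))
  f1r <- as.vector(t(fm$f1[, seq_len(qr), drop = FALSE]))
  C <- fm$f2[keep, keep] - tcrossprod(f1r)
  e <- tryCatch(-solve(C), error = function(err)
    stop("connected-correlation matrix is singular; ",
         "increase the pseudocount lambda (", conditionMessage(err), ")"))
  for (i in seq_len(L)) {                 # couplings are defined for i != j
    b <- .state_block(i, qr)
    e[b, b] <- 0
  }
  structure(list(e = e, q = q, L = L), class = "mf_couplings")
}

# q x q coupling block for pair (i, j) in the reference gauge (last state 0)
coupling_block <- function(mf, i, j) {
  qr <- mf$q - 1L
  W <- matrix(0, mf$q, mf$q)
  W[seq_len(qr), seq_len(qr)] <- mf$e[.state_block(i, qr), .state_block(j, qr)]
  W
}

#' Direct information from mean-field couplings
#'
#' For each pair (i, j) a two-site direct distribution
#' P_dir(A,B) proportional to exp(e_ij(A,B) + h_i(A) + h_j(B)) is fitted by
#' alternating marginal-matching updates of the auxiliary fields until its
#' marginals equal P_i and P_j; the direct information is the
#' Kullback-Leibler divergence of P_dir from the product of marginals.
#'
#' @param fm a [frequency_model][frequencies].
#' @param mf [mean_field_couplings()] output for the same model.
#' @param tol convergence tolerance on the maximum marginal error
#'   (default 1e-6).
#' @param max_iter maximum fixed-point iterations per pair (default 500).
#' @return Symmetric non-negative L x L matrix, zero diagonal.
#' @export
direct_information <- function(fm, mf, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(fm, "frequency_model"), inherits(mf, "mf_couplings"))
  L <- fm$L
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      W <- exp(pmin(coupling_block(mf, i, j), 500))
      di[i, j] <- di[j, i] <-
        .pair_di(W, fm$f1[i, ], fm$f1[j, ], tol, max_iter, i, j)
    }
  }
  di[di < 0 & di > -1e-12] <- 0
  di
}

.pair_di <- function(W, Pi, Pj, tol, max_iter, i, j) {
  q <- length(Pi)
  mu1 <- rep(1 / q, q)
  mu2 <- rep(1 / q, q)
  for (it in seq_len(max_iter)) {
    new1 <- Pi / pmax(as.vector(W %*% mu2), 1e-300)
    new1 <- new1 / sum(new1)
    new2 <- Pj / pmax(as.vector(crossprod(W, new1)), 1e-300)
    new2 <- new2 / sum(new2)
    delta <- max(abs(new1 - mu1), abs(new2 - mu2))
    mu1 <- new1; mu2 <- new2
    if (delta < tol) break
  }
  Pdir <- W * outer(mu1, mu2)
  Pdir <- Pdir / sum(Pdir)
  resid <- max(abs(rowSums(Pdir) - Pi), abs(colSums(Pdir) - Pj))
  if (resid > 100 * tol)
    stop(sprintf(
      "direct-information fixed point did not converge for pair (%d, %d); residual %.3g",
      i, j, resid))
  ref <- outer(Pi, Pj)
  nz <- Pdir > 0
  sum(Pdir[nz] * log(Pdir[nz] / ref[nz]))
}

#' Fit coevolutionary couplings to a multiple sequence alignment
#'
#' The main sequence-space estimator: reweights sequences by pairwise
#' identity, forms pseudocounted 21-state frequencies, and scores every
#' column pair by mutual information (MI) and by mean-field direct
#' information (DI, direct coupling analysis). MI measures total statistical
#' dependence; DI isolates the directly coupled component by globally
#' inverting the correlation matrix of a Potts model.
#'
#' @param aln an [alignment][read_alignment] object (use [map_columns()]
#'   first to report pairs in reference residue numbering).
#' @param identity_threshold reweighting identity threshold (default 0.8).
#' @param lambda pseudocount; default `M_eff`.
#' @param di_tol,di_max_iter fixed-point controls for [direct_information()].
#' @return Object of class `dca`: list with symmetric `mi` and `di` matrices
#'   (dimnames = reference residue numbers where mapped), `weights`,
#'   `M_eff`, `params`, `positions`.
#' @examples
#' aln <- sample_potts_msa(L = 12, q = 4, M = 300,
#'                         planted_pairs = data.frame(i = 2, j = 9,
#'                                                    coupling = 2),
#'                         seed = 1)
#' fit <- dca(aln)
#' summary(fit)
#' @export
dca <- function(aln, identity_threshold = 0.8, lambda = NULL,
                di_tol = 1e-6, di_max_iter = 500L) {
  stopifnot(inherits(aln, "alignment"))
  if (nrow(aln$seq) < 2L)
    stop("coupling analysis needs >= 2 effective sequences")
  w <- compute_weights(aln, identity_threshold)
  if (w$M_eff < 2)
    stop("coupling analysis needs >= 2 effective sequences (M_eff = ",
         format(w$M_eff, digits = 4), ")")
  fm <- frequencies(aln, w, lambda)
  mi <- mutual_information(fm)
  mf <- mean_field_couplings(fm)
  di <- direct_information(fm, mf, tol = di_tol, max_iter = di_max_iter)
  pos <- aln$column_map %||% seq_len(fm$L)
  dn <- list(as.character(pos), as.character(pos))
  dimnames(mi) <- dn
  dimnames(di) <- dn
  structure(list(mi = mi, di = di, weights = w, M_eff = w$M_eff,
                 positions = pos,
                 params = list(identity_threshold = identity_threshold,
                               lambda = fm$lambda, q = fm$q, L = fm$L,
                               gap_policy = "gap is the 21st state")),
            class = "dca")
}

#' @export
print.dca <- function(x, ...) {
  cat("Coevolutionary coupling fit (mutual information + mean-field DCA)\n")
  cat("  alignment: L =", x$params$L, "columns, q =", x$params$q,
      "states, M_eff =", format(x$M_eff, digits = 6), "\n")
  cat("  pseudocount lambda =", format(x$params$lambda, digits = 6),
      "; identity threshold =", x$params$identity_threshold, "\n")
  invisible(x)
}

#' @export
summary.dca <- function(object, top_n = 5L, min_separation = 5L, ...) {
  top_mi <- select_top_pairs(object$mi, top_n = top_n,
                             min_separation = min_separation)
  top_di <- select_top_pairs(object$di, top_n = top_n,
                             min_separation = min_separation)
  out <- list(fit = object, top_mi = top_mi, top_di = top_di)
  class(out) <- "summary.dca"
  out
}

#' @export
print.summary.dca <- function(x, ...) {
  print(x$fit)
  cat("\nTop mutual-information pairs (separation >= ",
      attr(x$top_mi, "min_separation"), "):\n", sep = "")
  print(as.data.frame(x$top_mi), row.names = FALSE)
  cat("\nTop direct-information pairs:\n")
  print(as.data.frame(x$top_di), row.names = FALSE)
  invisible(x)
}

#' Coupling score matrix of a fit
#'
#' @param object a [dca] fit.
#' @param score `"di"` or `"mi"`.
#' @param ... ignored.
#' @return The symmetric score matrix.
#' @export
coef.dca <- function(object, score = c("di", "mi"), ...) {
  object[[match.arg(score)]]
}

#' Heatmaps of the MI and DI coupling maps
#'
#' @param x a [dca] fit.
#' @param which `"both"`, `"mi"` or `"di"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.dca <- function(x, which = c("both", "mi", "di"), ...) {
  which <- match.arg(which)
  draw <- function(m, lab) {
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    xlab = "column", ylab = "column", main = lab, ...)
  }
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
    draw(x$mi, "Mutual information"); draw(x$di, "Direct information")
  } else draw(x[[which]], toupper(which))
  invisible(x)
}

#' Write pair scores as TSV
#'
#' Writes one row per unordered column pair (i < j, reference numbering)
#' with the MI and DI scores of a fit.
#'
#' @param x a [dca] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(x, path) {
  stopifnot(inherits(x, "dca"))
  L <- x$params$L
  ut <- which(upper.tri(x$mi), arr.ind = TRUE)
  df <- data.frame(i = x$positions[ut[, 1L]], j = x$positions[ut[, 2L]],
                   mi = x$mi[ut], di = x$di[ut])
  df <- df[stats::complete.cases(df[, c("i", "j")]), ]
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
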