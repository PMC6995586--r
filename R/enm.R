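#' Parse point mutations in wild-type/position/mutant notation
#'
#' @param mutations character vector like `c("H63F", "G72S")`.
#' @return data.frame with columns `wt`, `pos`, `mut`.
#' @export
parse_mutations <- function(mutations) {
  if (length(mutations) == 0L)
    return(data.frame(wt = character(), pos = integer(), mut = character()))
  m <- regmatches(mutations, regexec("^([A-Z])([0-9]+)([A-Z])$", mutations))
  if (any(lengths(m) != 4L))
    stop("malformed mutation(s): ",
         paste(mutations[lengths(m) != 4L], collapse = ", "))
  data.frame(wt = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             mut = vapply(m, `[`, "", 4L))
}

#' Define a sequence variant
#'
#' @param name variant name.
#' @param mutations character vector in `"H63F"` notation (empty for the
#'   wild type).
#' @return Object of class `variant_spec`.
#' @export
variant_spec <- function(name, mutations = character()) {
  structure(list(name = name, mutations = parse_mutations(mutations)),
            class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  mut <- if (nrow(x$mutations) == 0L) "(wild type, no substitutions)"
  else paste(paste0(x$mutations$wt, x$mutations$pos, x$mutations$mut),
             collapse = ", ")
  cat("Variant ", x$name, ": ", mut, "\n", sep = "")
  invisible(x)
}

#' Apply a variant to a reference sequence
#'
#' Substitutes the variant's mutations into the sequence after checking that
#' each stated wild-type residue matches; the sequence length is unchanged.
#'
#' @param sequence a single string or character vector of one-letter codes.
#' @param spec a [variant_spec()].
#' @return The mutated sequence, in the same form as the input.
#' @export
apply_variant <- function(sequence, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  as_string <- is.character(sequence) && length(sequence) == 1L &&
    nchar(sequence) > 1L
  s <- if (as_string) strsplit(sequence, "")[[1L]] else sequence
  mt <- spec$mutations
  if (nrow(mt) > 0L) {
    if (any(mt$pos < 1L | mt$pos > length(s)))
      stop("mutation position out of range for variant ", spec$name)
    bad <- s[mt$pos] != mt$wt
    if (any(bad))
      stop("wild-type mismatch at position ", mt$pos[bad][1L],
           ": sequence has ", s[mt$pos[bad][1L]], ", variant ",
           spec$name, " expects ", mt$wt[bad][1L])
    s[mt$pos] <- mt$mut
  }
  if (as_string) paste(s, collapse = "") else s
}

#' C-alpha elastic network normal modes
#'
#' Fits an anisotropic elastic network to a C-alpha trace: every residue
#' pair within `cutoff` Angstrom is joined by a harmonic spring of stiffness
#' `k`, the 3n x 3n Hessian of the resulting pair potential is assembled and
#' diagonalised, and the six rigid-body modes (five for exactly collinear
#' chains) are identified by their near-zero eigenvalues. The low-frequency
#' internal modes approximate the collective motions of the protein.
#'
#' @param coords n x 3 matrix of C-alpha coordinates (Angstrom). Extra rows
#'   may represent pseudo-atoms, e.g. bound metal ions cross-linking loop
#'   residues.
#' @param cutoff spring cutoff in Angstrom (default 10, a standard C-alpha
#'   network choice).
#' @param k uniform spring constant (default 1; sets the energy scale only).
#' @return Object of class `enm`: list with `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns, coordinate-major:
#'   x1,y1,z1,x2,...), `n_zero_modes`, `cutoff`, `k`, `n`, `coords`.
#' @examples
#' ch <- make_toy_chain(8, "helix", seed = 1)
#' m <- enm(ch$coords)
#' m$n_zero_modes   # 6 rigid-body modes
#' @export
enm <- function(coords, cutoff = 10, k = 1.0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 2L)
    stop("coords must be an n x 3 matrix with n >= 2")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)
  connected <- nrow(pairs) > 0L
  if (connected) {
    cg <- igraph::graph_from_edgelist(cbind(pairs[, 1L], pairs[, 2L]),
                                      directed = FALSE)
    cg <- igraph::add_vertices(cg, max(0L, n - igraph::vcount(cg)))
    connected <- igraph::components(cg)$no == 1L
  }
  if (!connected)
    stop("structure is disconnected at cutoff ", cutoff,
         " A; increase the cutoff")
  H <- matrix(0, 3L * n, 3L * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    dv <- coords[j, ] - coords[i, ]
    blk <- -k * tcrossprod(dv) / sum(dv^2)
    bi <- (3L * i - 2L):(3L * i); bj <- (3L * j - 2L):(3L * j)
    H[bi, bj] <- H[bi, bj] + blk
    H[bj, bi] <- H[bj, bi] + blk
    H[bi, bi] <- H[bi, bi] - blk
    H[bj, bj] <- H[bj, bj] - blk
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(values))
  n_zero <- sum(abs(values) < tol)
  structure(list(values = values, vectors = vectors, n_zero_modes = n_zero,
                 cutoff = cutoff, k = k, n = n, coords = coords),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat("C-alpha elastic network model: ", x$n, " nodes, cutoff ", x$cutoff,
      " A, k = ", x$k, "\n  ", 3L * x$n, " modes (", x$n_zero_modes,
      " rigid-body); lowest internal frequency^2 = ",
      format(x$values[x$n_zero_modes + 1L], digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  print(object)
  flex <- fluctuations(object)
  cat("  mean-square fluctuation range: ",
      format(min(flex), digits = 4), " - ",
      format(max(flex), digits = 4), "\n", sep = "")
  invisible(object)
}

#' Per-residue mean-square fluctuations
#'
#' @param x an [enm] fit.
#' @return Numeric vector of <|dr_i|^2> over internal (non-rigid) modes.
#' @export
fluctuations <- function(x) {
  stopifnot(inherits(x, "enm"))
  diag(.enm_covariance(x))
}

# n x n covariance <dr_i . dr_j> from the pseudo-inverse over internal modes
.enm_covariance <- function(x) {
  keep <- seq.int(x$n_zero_modes + 1L, 3L * x$n)
  if (length(keep) == 0L) stop("all modes are rigid-body modes")
  cov <- matrix(0, x$n, x$n)
  for (kk in keep) {
    V <- matrix(x$vectors[, kk], nrow = 3L)   # 3 x n, column = residue
    cov <- cov + crossprod(V) / x$values[kk]
  }
  cov
}

#' Residue cross-correlation matrix from normal modes
#'
#' Normalised covariance of residue displacements over the internal modes,
#' weighted 1/lambda_k (equal-temperature weighting):
#' c_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>). Values near +1 mark
#' residues moving in phase, near -1 in anti-phase.
#'
#' @param x an [enm] fit.
#' @return Object of class `cross_correlation`: n x n matrix in \[-1, 1\]
#'   with unit diagonal.
#' @export
cross_correlation <- function(x) {
  stopifnot(inherits(x, "enm"))
  cov <- .enm_covariance(x)
  c <- cov / sqrt(tcrossprod(diag(cov)))
  dimnames(c) <- list(rownames(x$coords) %||% seq_len(x$n),
                      rownames(x$coords) %||% seq_len(x$n))
  structure(c, class = c("cross_correlation", "matrix"))
}

#' Plot a cross-correlation matrix
#'
#' @param x a [cross_correlation()] matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.cross_correlation <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), unclass(x), zlim = c(-1, 1),
                  xlab = "residue", ylab = "residue",
                  main = "Residue cross-correlation", ...)
  invisible(x)
}

#' Dynamic correlation network
#'
#' Joins residues that are simultaneously in structural contact and
#' dynamically correlated (|c_ij| at or above `correlation_cutoff`). Each
#' edge stores `weight` = |c_ij| (strength, used for modularity) and
#' `length` = -log|c_ij| (the information-style distance used for
#' betweenness: perfectly correlated residues are at distance 0).
#'
#' @param c a [cross_correlation()] matrix.
#' @param cmap a [contact_map()] over the same residues.
#' @param correlation_cutoff minimum |c_ij| (default 0.35, a common choice
#'   for dynamic networks).
#' @return An `igraph` graph over all residues.
#' @export
correlation_network <- function(c, cmap, correlation_cutoff = 0.35) {
  stopifnot(inherits(cmap, "contact_map"))
  cm <- cmap$contacts
  if (!all(dim(c) == dim(cm)))
    stop("cross-correlation and contact map dimensions disagree")
  keep <- cm & abs(unclass(c)) >= correlation_cutoff & upper.tri(cm)
  idx <- which(keep, arr.ind = TRUE)
  nodes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  w <- pmin(abs(c[idx]), 1)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = w, length = -log(w))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::set_graph_attr(g, "kind", "structure-correlation")
}

#' Community clustering of a correlation network
#'
#' Girvan-Newman decomposition of a residue network plus the coarse-grained
#' community graph (one node per community, edges = summed inter-community
#' weight).
#'
#' @param g an `igraph` residue graph.
#' @return List with `partition` ([community_partition][girvan_newman]) and
#'   `coarse` ([community_graph()]).
#' @export
community_clusters <- function(g) {
  part <- girvan_newman(g)
  list(partition = part, coarse = community_graph(g, part))
}

#' Betweenness centrality profile
#'
#' Node betweenness along shortest paths measured with the edge `length`
#' attribute (for correlation networks -log|c|, so strongly correlated
#' contacts are short), normalised by (n-1)(n-2)/2 to \[0, 1\]. Residues
#' bridging dynamic communities score high; rigidified stretches score low.
#'
#' @param g an `igraph` residue graph.
#' @return Object of class `centrality_profile`: named numeric vector.
#' @export
betweenness_profile <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  if (n < 3L) {
    b <- stats::setNames(rep(0, n), nm)
    return(structure(b, class = "centrality_profile"))
  }
  len <- igraph::E(g)$length %||% (1 / igraph::E(g)$weight)
  b <- igraph::betweenness(g, weights = pmax(len, 1e-12), normalized = FALSE)
  b <- b / ((n - 1) * (n - 2) / 2)
  structure(stats::setNames(as.numeric(b), nm), class = "centrality_profile")
}

#' Plot a centrality profile along the sequence
#'
#' @param x a [betweenness_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.centrality_profile <- function(x, ...) {
  pos <- suppressWarnings(as.numeric(names(x)))
  if (anyNA(pos)) pos <- seq_along(x)
  graphics::plot(pos, as.numeric(x), type = "h", xlab = "residue",
                 ylab = "normalised betweenness", ...)
  invisible(x)
}

#' Cross-link a structure with a metal-mimicking pseudo-atom
#'
#' Appends one extra network node at the centroid of the given residues,
#' operationalising a bound metal ion that tethers its coordinating loop
#' residues without atomic detail.
#'
#' @param coords n x 3 coordinate matrix.
#' @param residues indices of the coordinating residues.
#' @return (n+1) x 3 coordinate matrix; the pseudo-atom is the last row.
#' @export
add_crosslink_node <- function(coords, residues) {
  coords <- as.matrix(coords)
  stopifnot(all(residues >= 1L & residues <= nrow(coords)))
  out <- rbind(coords, colMeans(coords[residues, , drop = FALSE]))
  rownames(out) <- as.character(seq_len(nrow(out)))
  out
}
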