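# Independent brute-force oracles used across the test files. Each oracle
# recomputes a quantity by the most literal route available (explicit loops,
# exhaustive enumeration, finite differences) so it shares no code with the
# implementation it checks.

# uniform (no reweighting) weight set, for tests on tiny alignments where
# identity-based reweighting would collapse the empirical distribution
uniform_weights <- function(M) {
  structure(list(weights = rep(1, M), M_eff = M, identity_threshold = 1),
            class = "weight_set")
}

# O(M^2 L) pairwise-identity sequence weights
brute_force_weights <- function(seqs, threshold) {
  M <- nrow(seqs); L <- ncol(seqs)
  m <- integer(M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      ident <- sum(seqs[a, ] == seqs[b, ]) / L
      if (ident >= threshold - 1e-12) m[a] <- m[a] + 1L
    }
  }
  1 / m
}

# plug-in mutual information of two columns by direct weighted counting
brute_force_mi <- function(col_a, col_b, w = rep(1, length(col_a))) {
  ab <- coevnet:::aa_alphabet()
  W <- sum(w)
  mi <- 0
  for (A in ab) {
    for (B in ab) {
      pab <- sum(w[col_a == A & col_b == B]) / W
      if (pab > 0) {
        pa <- sum(w[col_a == A]) / W
        pb <- sum(w[col_b == B]) / W
        mi <- mi + pab * log(pab / (pa * pb))
      }
    }
  }
  mi
}

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) {
      out[[length(out) + 1L]] <<- s
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# maximal cliques by 2^n subset enumeration on an adjacency matrix
brute_force_cliques <- function(adj) {
  n <- nrow(adj)
  subsets <- lapply(seq_len(2^n - 1L), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0))
  complete <- Filter(function(s) {
    if (length(s) < 2L) return(length(s) == 1L && sum(adj[s, ]) == 0)
    all(adj[s, s][upper.tri(adj[s, s])])
  }, subsets)
  maximal <- Filter(function(s) {
    ext <- setdiff(seq_len(n), s)
    !any(vapply(ext, function(v) all(adj[v, s]), TRUE))
  }, complete)
  maximal[lengths(maximal) >= 2 | vapply(maximal, function(s)
    sum(adj[s, ]) == 0, TRUE)]
}

# exact node betweenness on a weighted graph: Floyd-Warshall distances plus
# shortest-path counting by dynamic programming
brute_force_betweenness <- function(len) {
  n <- nrow(len)
  d <- len
  d[is.na(d) | d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j]) d[i, j] <- alt
      }
    }
  }
  # count shortest paths by DP over nodes in order of distance from source
  cnt <- matrix(0, n, n)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    sigma <- numeric(n); sigma[s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(is.finite(len[, v]) & len[, v] > 0 &
                      abs(d[s, ] + len[, v] - d[s, v]) <= 1e-12)
      sigma[v] <- sum(sigma[pred])
    }
    cnt[s, ] <- sigma
  }
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
        through <- if (abs(d[s, v] + d[v, t] - d[s, t]) <= 1e-12)
          cnt[s, v] * cnt[v, t] else 0
        acc <- acc + through / cnt[s, t]
      }
    }
    btw[v] <- acc
  }
  btw
}

# finite-difference Hessian of the elastic pair potential
# E(x) = sum_{ij in contact} k/2 (|r_ij| - d0_ij)^2 at the equilibrium
fd_hessian <- function(coords, cutoff, k = 1, h = 1e-5) {
  n <- nrow(coords)
  d0 <- as.matrix(dist(coords))
  adj <- d0 <= cutoff & upper.tri(d0)
  energy <- function(xvec) {
    co <- matrix(xvec, ncol = 3L, byrow = TRUE)
    dd <- as.matrix(dist(co))
    sum(k / 2 * (dd[adj] - d0[adj])^2)
  }
  x0 <- as.vector(t(coords))
  m <- length(x0)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      xpp <- x0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm <- x0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp <- x0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm <- x0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- H[b, a] <-
        (energy(xpp) - energy(xpm) - energy(xmp) + energy(xmm)) / (4 * h^2)
    }
  }
  H
}

# direct information for one pair by independently fitting the auxiliary
# fields with a general-purpose optimiser and summing the q^2 outcomes
di_enumeration_oracle <- function(e_block, Pi, Pj) {
  q <- length(Pi)
  W <- exp(e_block)
  obj <- function(par) {
    m1 <- exp(c(par[seq_len(q - 1)], 0)); m1 <- m1 / sum(m1)
    m2 <- exp(c(par[q:(2 * q - 2)], 0)); m2 <- m2 / sum(m2)
    P <- W * outer(m1, m2); P <- P / sum(P)
    sum((rowSums(P) - Pi)^2) + sum((colSums(P) - Pj)^2)
  }
  fit <- optim(rep(0, 2 * q - 2), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
  par <- fit$par
  m1 <- exp(c(par[seq_len(q - 1)], 0)); m1 <- m1 / sum(m1)
  m2 <- exp(c(par[q:(2 * q - 2)], 0)); m2 <- m2 / sum(m2)
  P <- W * outer(m1, m2); P <- P / sum(P)
  di <- 0
  for (a in seq_len(q)) {
    for (b in seq_len(q)) {
      if (P[a, b] > 0) di <- di + P[a, b] * log(P[a, b] / (Pi[a] * Pj[b]))
    }
  }
  di
}

# project a q x q coupling block onto the zero-sum (Ising) gauge
zero_sum_gauge <- function(J) {
  J - outer(rowMeans(J), rep(1, ncol(J))) -
    outer(rep(1, nrow(J)), colMeans(J)) + mean(J)
}

# alignment sampled exactly from a two-site Potts joint distribution
sample_two_site <- function(Jmat, M, seed) {
  q <- nrow(Jmat)
  P <- exp(Jmat); P <- P / sum(P)
  set.seed(seed)
  counts <- as.vector(rmultinom(1, M, as.vector(P)))
  idx <- rep(seq_len(q * q), counts)
  a <- ((idx - 1L) %% q) + 1L
  b <- ((idx - 1L) %/% q) + 1L
  ab <- coevnet:::aa_alphabet()[seq_len(q)]
  as_alignment(cbind(ab[a], ab[b]), alphabet = ab)
}

# standard planted-coupling Potts benchmark conditions
standard_potts_spec <- function(seed) {
  list(L = 50L, q = 8L, M = 4000L, coupling = 1.5,
       pairs = data.frame(i = c(2L, 6L, 10L, 14L, 18L, 22L, 26L, 30L, 34L, 38L),
                          j = c(9L, 13L, 17L, 21L, 25L, 29L, 33L, 37L, 41L, 45L),
                          coupling = 1.5),
       seed = seed)
}
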