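test_that("identity reweighting handles full and zero redundancy", {
  aln <- as_alignment(rep("ACDEFGHIKL", 3))
  w <- compute_weights(aln, 0.8)
  expect_equal(w$weights, rep(1 / 3, 3))
  expect_equal(w$M_eff, 1)

  distinct <- as_alignment(c("AAAAAAAAAA", "CCCCCCCCCC",
                             "DDDDDDDDDD", "EEEEEEEEEE"))
  w2 <- compute_weights(distinct, 0.8)
  expect_equal(w2$weights, rep(1, 4))
  expect_equal(w2$M_eff, 4)
  expect_error(compute_weights(aln, 0), "identity_threshold")
})

test_that("weights match the O(M^2 L) pairwise-identity oracle", {
  set.seed(3)
  seqs <- matrix(sample(c("A", "C", "D", "-"), 6 * 20, replace = TRUE),
                 nrow = 6)
  seqs[2, ] <- seqs[1, ]                       # one duplicated pair
  seqs[4, 1:3] <- seqs[3, 1:3]
  aln <- as_alignment(seqs)
  for (thr in c(0.6, 0.8, 1.0)) {
    w <- compute_weights(aln, thr)
    expect_equal(w$weights, brute_force_weights(seqs, thr))
    expect_true(all(w$weights > 0 & w$weights <= 1))
    expect_true(w$M_eff >= 1 && w$M_eff <= 6)
  }
})

test_that("frequencies obey the pseudocount formula and its limits", {
  aln <- as_alignment("ACDE")
  fm <- frequencies(aln, uniform_weights(1), lambda = 0)
  ab <- coevnet:::aa_alphabet()
  expect_equal(fm$f1[1, ], as.numeric(ab == "A"))
  expect_equal(fm$f1[3, ], as.numeric(ab == "D"))

  # pseudocount-dominated limit is uniform
  aln2 <- as_alignment(c("ACDE", "ACDF", "GHIK"))
  fm2 <- frequencies(aln2, uniform_weights(3), lambda = 1e6 * 3)
  expect_lt(max(abs(fm2$f1 - 1 / 21)), 1e-4)
})

test_that("frequencies match brute-force weighted counting on a toy MSA", {
  seqs <- rbind(c("A", "C", "A", "-"), c("A", "D", "A", "E"),
                c("C", "C", "A", "E"), c("A", "C", "C", "E"))
  aln <- as_alignment(seqs)
  w <- structure(list(weights = c(1, 0.5, 0.5, 1), M_eff = 3,
                      identity_threshold = 0.8), class = "weight_set")
  lam <- 3
  fm <- frequencies(aln, w, lambda = lam)
  ab <- coevnet:::aa_alphabet()
  q <- 21
  for (i in 1:4) {
    for (A in c("A", "C", "D", "E", "-")) {
      hand <- (lam / q + sum(w$weights[seqs[, i] == A])) / (lam + 3)
      expect_equal(fm$f1[i, match(A, ab)], hand)
    }
  }
  hand_joint <- (lam / q^2 + sum(w$weights[seqs[, 1] == "A" &
                                             seqs[, 2] == "C"])) / (lam + 3)
  expect_equal(fm$f2[match("A", ab), q + match("C", ab)], hand_joint)
})

test_that("frequency model invariants hold", {
  aln <- sample_potts_msa(L = 8, q = 5, M = 60, seed = 4)
  fm <- frequencies(aln, compute_weights(aln), lambda = NULL)
  q <- fm$q
  expect_lt(max(abs(rowSums(fm$f1) - 1)), 1e-10)
  for (i in 1:8) {
    bi <- coevnet:::.state_block(i, q)
    for (j in 1:8) {
      blk <- fm$f2[bi, coevnet:::.state_block(j, q)]
      expect_lt(abs(sum(blk) - 1), 1e-10)
      expect_lt(max(abs(rowSums(blk) - fm$f1[i, ])), 1e-10)  # marginals
      if (i == j) expect_equal(blk, diag(fm$f1[i, ], nrow = q))
    }
  }
  # increasing lambda monotonically flattens toward uniform
  dev <- vapply(c(0, 1, 10, 100, 1000), function(l)
    max(abs(frequencies(aln, compute_weights(aln), l)$f1 - 1 / q)),
    numeric(1))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("mutual information recovers analytic and oracle values", {
  # statistically independent columns with exact product counts
  grid <- expand.grid(a = c("A", "C"), b = c("D", "E", "F"))
  aln <- as_alignment(cbind(as.character(grid$a), as.character(grid$b)))
  fm <- frequencies(aln, uniform_weights(6), lambda = 0)
  expect_lt(abs(mutual_information(fm)[1, 2]), 1e-12)

  # perfectly covarying 50/50 binary columns: MI = ln 2
  aln2 <- as_alignment(c("AC", "AC", "DE", "DE"))
  fm2 <- frequencies(aln2, uniform_weights(4), lambda = 0)
  expect_equal(mutual_information(fm2)[1, 2], log(2), tolerance = 1e-12)
})

test_that("MI equals the explicit double-sum oracle on a toy MSA", {
  set.seed(9)
  seqs <- matrix(sample(c("A", "C", "D", "-"), 6 * 4, replace = TRUE),
                 nrow = 6)
  aln <- as_alignment(seqs)
  w <- uniform_weights(6)
  fm <- frequencies(aln, w, lambda = 0)
  mi <- mutual_information(fm)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(mi[i, j], brute_force_mi(seqs[, i], seqs[, j]),
                   tolerance = 1e-12)
      expect_equal(mi[i, j], mi[j, i])
    }
  }
  expect_true(all(diag(mi) == 0))
})

test_that("MI and DI are invariant to row order", {
  aln <- sample_potts_msa(L = 8, q = 4, M = 150,
                          planted_pairs = data.frame(i = 2, j = 7,
                                                     coupling = 1.5),
                          seed = 5)
  fit <- dca(aln)
  perm <- sample(nrow(aln$seq))
  shuffled <- as_alignment(aln$seq[perm, ], ids = aln$ids[perm],
                           alphabet = aln$alphabet)
  fit2 <- dca(shuffled)
  expect_equal(fit2$mi, fit$mi, tolerance = 1e-10)
  expect_equal(fit2$di, fit$di, tolerance = 1e-10)
})

test_that("degenerate alignments are rejected", {
  expect_error(dca(as_alignment("ACDE")), ">= 2 effective sequences")
})
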