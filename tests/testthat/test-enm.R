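test_that("variant substitution honours wild-type checks", {
  wt <- sod1_sequence(as_vector = TRUE)
  vars <- sod1_variants()
  apo <- apply_variant(wt, vars$apo)
  expect_equal(apo[63], "F")
  expect_equal(sum(apo != wt), 1)

  l4 <- apply_variant(wt, vars$L4)
  expect_equal(l4[c(65, 67, 72, 76, 80)], c("S", "P", "S", "Y", "A"))
  expect_equal(length(l4), length(wt))

  expect_equal(apply_variant(wt, vars$WT), wt)
  expect_equal(apply_variant(sod1_sequence(), vars$apo),
               paste(apo, collapse = ""))  # string in, string out

  bad <- variant_spec("bad", "A63F")   # position 63 is His, not Ala
  expect_error(apply_variant(wt, bad), "position 63")
  expect_error(apply_variant(wt, variant_spec("oob", "H999F")),
               "out of range")
})

test_that("the table and text variant assignments are both available", {
  tab <- sod1_variants("table")
  txt <- sod1_variants("text")
  expect_equal(paste0(tab$Cu$mutations$wt, tab$Cu$mutations$pos,
                      tab$Cu$mutations$mut), "H120F")
  expect_equal(paste0(txt$Cu$mutations$wt, txt$Cu$mutations$pos,
                      txt$Cu$mutations$mut), "H71F")
})

test_that("connected structures have exactly six rigid-body modes", {
  for (geom in c("helix", "dimer")) {
    ch <- make_toy_chain(12, geom, seed = 1)
    m <- enm(ch$coords, cutoff = 10)
    expect_equal(m$n_zero_modes, 6)
    expect_equal(length(m$values), 36)
    expect_true(all(m$values > -1e-8))
    # eigenvector orthonormality
    expect_lt(max(abs(crossprod(m$vectors) - diag(36))), 1e-8)
  }
  expect_error(enm(rbind(c(0, 0, 0), c(100, 0, 0)), cutoff = 10),
               "disconnected")
})

test_that("two beads with one spring give eigenvalue 2k", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  for (k in c(1, 2.5)) {
    m <- enm(co, cutoff = 5, k = k)
    nonzero <- m$values[abs(m$values) > 1e-8]
    expect_equal(length(nonzero), 1)
    expect_equal(nonzero, 2 * k, tolerance = 1e-10)
  }
})

test_that("the Hessian matches the finite-difference oracle", {
  ch <- make_toy_chain(10, "helix", seed = 5)
  m <- enm(ch$coords, cutoff = 10, k = 1)
  H <- m$vectors %*% diag(m$values) %*% t(m$vectors)
  H_fd <- fd_hessian(ch$coords, cutoff = 10, k = 1)
  expect_lt(max(abs(H - H_fd)), 1e-4)
})

test_that("the mode spectrum matches an independent ANM implementation", {
  ch <- make_toy_chain(12, "helix", seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, f)
  invisible(capture.output(
    nm <- bio3d::nma(bio3d::read.pdb(f), ff = "anm", cutoff = 10,
                     mass = FALSE, temp = NULL)))
  ours <- enm(ch$coords, cutoff = 10)
  expect_equal(ours$values[ours$values > 1e-8],
               nm$L[nm$L > 1e-8], tolerance = 1e-4)
})

test_that("cross-correlation has unit diagonal and dimer exchange symmetry", {
  ch <- make_toy_chain(12, "dimer", seed = 2)
  cc <- cross_correlation(enm(ch$coords, cutoff = 10))
  expect_lt(max(abs(diag(cc) - 1)), 1e-10)
  expect_lt(max(abs(cc - t(cc))), 1e-10)
  expect_true(all(cc >= -1 - 1e-10 & cc <= 1 + 1e-10))
  swap <- c(7:12, 1:6)                  # protomer exchange
  expect_lt(max(abs(unclass(cc)[swap, swap] - unclass(cc))), 1e-8)
})

test_that("cross-correlation matches the explicit mode-sum oracle", {
  ch <- make_toy_chain(5, "extended", seed = 3)
  m <- enm(ch$coords, cutoff = 8)
  cc <- cross_correlation(m)
  # independent route: pseudo-inverse of the reassembled Hessian
  H <- m$vectors %*% diag(m$values) %*% t(m$vectors)
  Hinv <- MASS::ginv(H)
  n <- 5
  cov <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
      cov[i, j] <- sum(diag(Hinv[bi, bj]))
    }
  }
  oracle <- cov / sqrt(outer(diag(cov), diag(cov)))
  expect_lt(max(abs(unclass(cc) - oracle)), 1e-8)
})

test_that("cross-correlation is invariant under rotation and translation", {
  ch <- make_toy_chain(9, "helix", seed = 4)
  cc <- cross_correlation(enm(ch$coords))
  theta <- 0.7; phi <- 1.2
  Rz <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)),
              c(0, sin(phi), cos(phi)))
  moved <- ch$coords %*% t(Rz %*% Rx) + matrix(c(5, -3, 11), 9, 3,
                                               byrow = TRUE)
  cc2 <- cross_correlation(enm(moved))
  expect_lt(max(abs(unclass(cc) - unclass(cc2))), 1e-8)
})

test_that("correlation network applies the double threshold", {
  ch <- make_toy_chain(10, "helix", seed = 6)
  m <- enm(ch$coords)
  cc <- cross_correlation(m)
  cm <- contact_map(ch$coords, cutoff = 8)
  g <- correlation_network(cc, cm, correlation_cutoff = 0.35)
  el <- igraph::as_data_frame(g)
  # brute-force double-threshold oracle
  want <- 0L
  for (i in 1:9) {
    for (j in (i + 1):10) {
      if (cm$contacts[i, j] && abs(cc[i, j]) >= 0.35) {
        want <- want + 1L
        expect_lt(abs(-log(min(abs(cc[i, j]), 1)) -
                        el$length[el$from == i & el$to == j]), 1e-12)
      }
    }
  }
  expect_equal(nrow(el), want)
  expect_true(all(el$weight > 0))
  # below-cutoff correlations never make an edge, contact or not
  g99 <- correlation_network(cc, cm, correlation_cutoff = 0.999999)
  el99 <- igraph::as_data_frame(g99)
  expect_true(all(el99$weight >= 0.999999))
})

test_that("betweenness matches analytic values and the path oracle", {
  star <- igraph::graph_from_edgelist(cbind(1, 2:5), directed = FALSE)
  igraph::V(star)$name <- as.character(1:5)
  igraph::E(star)$weight <- 1
  igraph::E(star)$length <- 1
  b <- betweenness_profile(star)
  expect_equal(unname(b["1"]), 1)          # raw 6 / ((4*3)/2)
  expect_equal(unname(b[as.character(2:5)]), rep(0, 4))

  path <- igraph::graph_from_edgelist(cbind(1:4, 2:5), directed = FALSE)
  igraph::V(path)$name <- as.character(1:5)
  igraph::E(path)$length <- 1
  bp <- betweenness_profile(path)
  expect_equal(which.max(bp), c("3" = 3))

  set.seed(19)
  for (rep in 1:3) {
    n <- 12
    len <- matrix(0, n, n)
    el <- which(upper.tri(len), arr.ind = TRUE)
    keep <- el[runif(nrow(el)) < 0.35, , drop = FALSE]
    w <- runif(nrow(keep), 0.2, 2)
    len[keep] <- w; len <- len + t(len)
    g <- igraph::graph_from_edgelist(keep, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::V(g)$name <- as.character(1:n)
    igraph::E(g)$length <- w
    got <- betweenness_profile(g)[as.character(1:n)]
    want <- brute_force_betweenness(len) / ((n - 1) * (n - 2) / 2)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("tiny networks get an all-zero centrality profile", {
  g <- igraph::graph_from_edgelist(cbind(1, 2), directed = FALSE)
  igraph::V(g)$name <- c("1", "2")
  igraph::E(g)$weight <- 1
  expect_equal(unname(betweenness_profile(g)), c(0, 0))
})

test_that("metal-mimicking cross-links stiffen the tethered stretch", {
  ch <- make_toy_chain(30, "helix", seed = 7)
  plain_net <- correlation_network(
    cross_correlation(enm(ch$coords)),
    contact_map(ch$coords, 8))
  linked_coords <- add_crosslink_node(ch$coords, c(8, 12, 16, 20))
  linked_net <- correlation_network(
    cross_correlation(enm(linked_coords)),
    contact_map(linked_coords, 8))
  plain <- community_clusters(plain_net)
  linked <- community_clusters(linked_net)
  # the cross-linked variant partitions into at least as many communities
  expect_gte(linked$partition$n_communities,
             plain$partition$n_communities)
  # and betweenness drops across the tethered stretch
  b0 <- betweenness_profile(plain_net)
  b1 <- betweenness_profile(linked_net)
  stretch <- as.character(8:20)
  expect_lte(mean(b1[stretch]), mean(b0[stretch]))
})
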