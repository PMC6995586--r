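make_sel <- function(i, j, score) {
  structure(data.frame(i = i, j = j, score = score),
            class = c("pair_selection", "data.frame"))
}

test_that("residue graphs mirror the pair list", {
  g <- build_graph(make_sel(c(1, 5, 9), c(20, 30, 40), c(1, 2, 3)))
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 3)

  g2 <- build_graph(make_sel(c(1, 7), c(7, 13), c(1, 1)))
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::diameter(g2, weights = NA), 2)

  expect_warning(g3 <- build_graph(make_sel(c(1, 1), c(8, 8), c(1, 4))),
                 "duplicate")
  expect_equal(igraph::ecount(g3), 1)
  expect_equal(igraph::E(g3)$weight, 4)
})

test_that("the published DI pair table yields its residue graph", {
  tab <- sod1_top_di_pairs()
  g <- build_graph(data.frame(i = tab$i, j = tab$j, score = tab$score),
                   kind = "G_DI")
  expect_equal(igraph::ecount(g), 18)
  # residue 28 appears in two pairs, so 18 pairs span 35 distinct residues
  expect_equal(igraph::vcount(g), 35)
  expect_equal(length(unique(c(tab$i, tab$j))), 35)
})

test_that("Girvan-Newman splits two K4 blocks at the bridge", {
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- build_graph(make_sel(edges[, 1], edges[, 2], rep(1, nrow(edges))))
  part <- girvan_newman(g)
  expect_equal(part$n_communities, 2)
  memb <- part$membership[as.character(1:8)]
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  expect_true(memb[1] != memb[5])
  # the bridge is removed first
  expect_equal(sort(as.numeric(part$removal_history[1, c("from", "to")])),
               c(4, 5))

  # modularity equals the exhaustive maximum over all partitions of 8 nodes
  adj <- matrix(0, 8, 8)
  adj[edges] <- 1; adj <- adj + t(adj)
  gi <- igraph::graph_from_adjacency_matrix(adj, "undirected")
  best <- max(vapply(all_partitions(8), function(p)
    igraph::modularity(gi, p), numeric(1)))
  expect_equal(part$modularity, best, tolerance = 1e-10)
})

test_that("stored modularity matches recomputation from the assignment", {
  set.seed(23)
  for (rep in 1:3) {
    s <- matrix(runif(144), 12, 12); s <- (s + t(s)) / 2; diag(s) <- 0
    sel <- suppressWarnings(select_top_pairs(s, 20, min_separation = 1))
    g <- build_graph(sel)
    part <- girvan_newman(g)
    expect_equal(partition_modularity(g, part), part$modularity,
                 tolerance = 1e-10)
  }
})

test_that("edgeless graphs fall apart into singletons", {
  g <- igraph::make_empty_graph(n = 4, directed = FALSE)
  igraph::V(g)$name <- as.character(1:4)
  part <- girvan_newman(g)
  expect_equal(part$n_communities, 4)
  expect_equal(part$modularity, 0)
})

test_that("planted two-block graphs are recovered", {
  set.seed(41)
  n <- 16
  labels <- rep(1:2, each = 8)
  edges <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (labels[i] == labels[j]) 0.9 else 0.05
      if (runif(1) < p) edges <- rbind(edges, c(i, j))
    }
  }
  g <- build_graph(make_sel(edges[, 1], edges[, 2], rep(1, nrow(edges))))
  part <- girvan_newman(g)
  memb <- part$membership[as.character(1:n)]
  expect_equal(part$n_communities, 2)
  expect_true(all(memb[1:8] == memb[1]) && all(memb[9:16] == memb[9]))
  expect_true(memb[1] != memb[9])
})

test_that("maximal cliques are complete, non-extendable and complete lists", {
  k4 <- build_graph(make_sel(combn(1:4, 2)[1, ], combn(1:4, 2)[2, ],
                             rep(1, 6)))
  cs <- maximal_cliques(k4)
  expect_equal(cs$cliques, list(c(1, 2, 3, 4)))
  expect_equal(cs$maximum_size, 4)

  tri <- build_graph(make_sel(c(1, 2, 1, 3), c(2, 3, 3, 4), rep(1, 4)))
  cs2 <- maximal_cliques(tri)
  expect_equal(cs2$cliques, list(c(1, 2, 3), c(3, 4)))

  for (seed in 1:5) {
    set.seed(seed)
    adj <- matrix(0, 10, 10)
    adj[upper.tri(adj)] <- runif(45) < 0.4
    adj <- adj + t(adj)
    keep <- which(rowSums(adj) > 0)
    el <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    g <- build_graph(make_sel(el[, 1], el[, 2], rep(1, nrow(el))))
    got <- maximal_cliques(g)$cliques
    want <- brute_force_cliques(adj == 1)
    want <- Filter(function(s) length(s) >= 2, want)
    want <- lapply(want, as.numeric)
    key <- function(l) sort(vapply(l, function(s)
      paste(sort(s), collapse = ","), ""))
    expect_equal(key(got), key(want))
    # every reported clique is complete and non-extendable
    for (cl in got) {
      expect_true(all(adj[cl, cl][upper.tri(adj[cl, cl])] == 1))
      others <- setdiff(keep, cl)
      expect_false(any(vapply(others, function(v)
        all(adj[v, cl] == 1), TRUE)))
    }
  }
})

test_that("community graphs aggregate inter-community weight", {
  sel <- make_sel(c(1, 2, 3, 4, 1, 2), c(2, 3, 4, 5, 4, 5),
                  c(5, 5, 1, 5, 0.2, 0.2))
  g <- build_graph(sel)
  part <- girvan_newman(g)
  cg <- community_graph(g, part)
  expect_equal(igraph::vcount(cg), part$n_communities)
  expect_equal(sum(igraph::V(cg)$size), igraph::vcount(g))
  total_inter <- sum(igraph::E(cg)$weight)
  memb <- part$membership
  el <- igraph::as_data_frame(g)
  inter <- sum(el$weight[memb[el$from] != memb[el$to]])
  expect_equal(total_inter, inter)
})

test_that("graphs round-trip through GraphML and TSV writers", {
  g <- build_graph(make_sel(c(1, 5), c(9, 13), c(0.5, 0.7)))
  part <- girvan_newman(g)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, gml, part)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_setequal(igraph::E(back)$weight, c(0.5, 0.7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graph_file(g, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 2)
})
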