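#' Weighted residue graph from a pair selection
#'
#' Nodes are residues appearing in at least one selected pair; each pair
#' contributes one undirected edge. Every edge carries two attributes:
#' `weight`, the coupling strength (MI or DI score), used for modularity,
#' and `length` = 1/weight, the distance used for betweenness (stronger
#' coupling = shorter path).
#'
#' @param sel a [pair_selection][select_top_pairs], or a data.frame with
#'   columns `i`, `j` and a score column named `score` or `weight`.
#' @param kind label stored as a graph attribute (e.g. `"G_MI"`, `"G_DI"`).
#' @return An `igraph` object with numeric-named vertices.
#' @export
build_graph <- function(sel, kind = "coupling") {
  df <- as.data.frame(sel)
  score_col <- intersect(c("score", "weight"), names(df))[1L]
  if (is.na(score_col)) stop("no score/weight column in pair list")
  if (nrow(df) == 0L) stop("empty pair selection")
  if (any(df[[score_col]] <= 0)) stop("edge weights must be positive")
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j))
  if (anyDuplicated(key)) {
    warning("duplicate pairs collapsed to maximum weight")
    df <- do.call(rbind, lapply(split(df, key), function(d)
      d[which.max(d[[score_col]]), , drop = FALSE]))
  }
  nodes <- sort(unique(c(df$i, df$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(df$i), to = as.character(df$j),
               weight = df[[score_col]], length = 1 / df[[score_col]]),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  g <- igraph::set_graph_attr(g, "kind", kind)
  g
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the globally highest edge betweenness
#' (computed with edge lengths, i.e. `length` attribute or 1/weight, so that
#' strong couplings are short paths), tracking the weighted modularity Q of
#' the component partition on the original graph after each removal, and
#' returns the partition with maximal Q. Among equal-betweenness edges the
#' lexicographically smallest (i, j) is removed, making the decomposition
#' deterministic.
#'
#' @param g an `igraph` graph (from [build_graph()] or
#'   [correlation_network()]).
#' @return Object of class `community_partition`: list with `membership`
#'   (named integer vector), `modularity`, `n_communities`,
#'   `removal_history` (data.frame of removed edges).
#' @export
girvan_newman <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name %||% as.character(seq_len(n))
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(n); names(memb) <- vnames
    return(structure(list(membership = memb, modularity = 0,
                          n_communities = n,
                          removal_history = data.frame(from = character(),
                                                       to = character(),
                                                       betweenness = numeric())),
                     class = "community_partition"))
  }
  w_mod <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  lengths0 <- igraph::E(g)$length %||% (1 / w_mod)
  work <- g
  best_memb <- igraph::components(work)$membership
  best_q <- igraph::modularity(g, best_memb, weights = w_mod)
  hist <- list()
  while (igraph::ecount(work) > 0L) {
    len <- pmax(igraph::E(work)$length %||%
                  (1 / igraph::E(work)$weight), 1e-12)
    eb <- igraph::edge_betweenness(work, weights = len)
    top <- which(eb >= max(eb) - 1e-10)
    ends <- igraph::ends(work, igraph::E(work)[top])
    es <- t(apply(ends, 1L, function(p) {
      pn <- suppressWarnings(as.numeric(p))
      if (anyNA(pn)) sort(p) else p[order(pn)]
    }))
    k1 <- suppressWarnings(as.numeric(es[, 1L]))
    k2 <- suppressWarnings(as.numeric(es[, 2L]))
    if (anyNA(k1) || anyNA(k2)) { k1 <- es[, 1L]; k2 <- es[, 2L] }
    sel <- order(k1, k2)[1L]
    pick <- top[sel]
    hist[[length(hist) + 1L]] <-
      data.frame(from = es[sel, 1L], to = es[sel, 2L],
                 betweenness = eb[pick])
    work <- igraph::delete_edges(work, igraph::E(work)[pick])
    memb <- igraph::components(work)$membership
    q <- igraph::modularity(g, memb, weights = w_mod)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  memb <- as.integer(best_memb); names(memb) <- vnames
  structure(list(membership = memb, modularity = best_q,
                 n_communities = length(unique(memb)),
                 removal_history = do.call(rbind, hist)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition: ", x$n_communities, " communities, Q = ",
      format(x$modularity, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' @param g the graph the partition belongs to.
#' @param partition a [community_partition][girvan_newman] or membership
#'   vector named by vertex.
#' @return The modularity Q computed with raw edge weights.
#' @export
partition_modularity <- function(g, partition) {
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  memb <- memb[igraph::V(g)$name]
  igraph::modularity(g, memb,
                     weights = igraph::E(g)$weight %||%
                       rep(1, igraph::ecount(g)))
}

#' Enumerate maximal cliques
#'
#' All maximal cliques (complete subgraphs not extendable by any adjacent
#' vertex) via Bron-Kerbosch search, returned in a deterministic order:
#' decreasing size, then lexicographically by sorted members.
#'
#' @param g an `igraph` graph.
#' @param min_size smallest clique size to report (default 2).
#' @return Object of class `clique_set`: list with `cliques` (list of
#'   numeric residue vectors) and `maximum_size`.
#' @export
maximal_cliques <- function(g, min_size = 2L) {
  stopifnot(igraph::is_igraph(g))
  cl <- igraph::max_cliques(g, min = min_size)
  members <- lapply(cl, function(v) {
    nm <- igraph::V(g)$name[v]
    num <- suppressWarnings(as.numeric(nm))
    if (anyNA(num)) sort(nm) else sort(num)
  })
  key <- vapply(members, function(m) paste(m, collapse = ","), "")
  ord <- order(-lengths(members), key)
  members <- members[ord]
  structure(list(cliques = members,
                 maximum_size = if (length(members)) max(lengths(members))
                 else 0L),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Maximal cliques: ", length(x$cliques), " (maximum size ",
      x$maximum_size, ")\n", sep = "")
  for (cl in x$cliques[lengths(x$cliques) == x$maximum_size])
    cat("  {", paste(cl, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Coarse-grained community graph
#'
#' Contracts each community to one node; edges between communities carry the
#' summed inter-community edge weight.
#'
#' @param g the residue graph.
#' @param partition its [community_partition][girvan_newman].
#' @return An `igraph` with one vertex per community (attribute `size` =
#'   member count).
#' @export
community_graph <- function(g, partition) {
  memb <- partition$membership[igraph::V(g)$name]
  cg <- igraph::contract(g, memb, vertex.attr.comb = list(name = "ignore"))
  cg <- igraph::simplify(cg, edge.attr.comb = list(weight = "sum",
                                                   length = "ignore"))
  igraph::V(cg)$name <- as.character(seq_len(igraph::vcount(cg)))
  igraph::V(cg)$size <- as.integer(table(factor(memb,
                                                levels = seq_len(igraph::vcount(cg)))))
  cg
}

#' Export a graph and optional partition
#'
#' @param g an `igraph` graph.
#' @param path output path; `.graphml` writes GraphML, anything else an
#'   edge-list TSV.
#' @param partition optional [community_partition][girvan_newman] stored as
#'   a `community` vertex attribute.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, partition = NULL) {
  if (!is.null(partition))
    igraph::V(g)$community <-
      unname(partition$membership[igraph::V(g)$name])
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
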