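#' Assemble a run configuration
#'
#' Collects file paths and analysis parameters for the two pipeline tracks.
#' Defaults match the package-wide conventions: identity threshold 0.8,
#' pseudocount = M_eff, minimum separation 5, top 100 pairs, 8 A contact
#' cutoff, 10 A elastic-network cutoff, 0.35 correlation cutoff.
#'
#' @param msa path to the alignment (or an `alignment` object).
#' @param structure structure for contact checks: PDB path, `pdb` object or
#'   coordinate matrix.
#' @param structures named list of per-variant structures for the structure
#'   track (name `"WT"` is the comparison reference).
#' @param disorder path to a disorder score TSV (or a data.frame).
#' @param ref_id,offset reference row and numbering offset for
#'   [map_columns()].
#' @param identity_threshold,lambda,min_separation,top_n,contact_cutoff,enm_cutoff,correlation_cutoff
#'   analysis parameters (see the respective functions).
#' @param seed integer seed for stochastic components.
#' @param out_dir output directory; `NULL` suppresses file output.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(msa = NULL, structure = NULL, structures = NULL,
                       disorder = NULL, ref_id = NULL, offset = 1L,
                       identity_threshold = 0.8, lambda = NULL,
                       min_separation = 5L, top_n = 100L,
                       contact_cutoff = 8, enm_cutoff = 10,
                       correlation_cutoff = 0.35, seed = 1L,
                       out_dir = NULL) {
  structure(list(msa = msa, structure = structure, structures = structures,
                 disorder = disorder, ref_id = ref_id, offset = offset,
                 identity_threshold = identity_threshold, lambda = lambda,
                 min_separation = min_separation, top_n = top_n,
                 contact_cutoff = contact_cutoff, enm_cutoff = enm_cutoff,
                 correlation_cutoff = correlation_cutoff, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  vals <- vals[vapply(vals, function(v) is.atomic(v) && length(v) >= 1L, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

.load_alignment <- function(x) {
  if (inherits(x, "alignment")) x else read_alignment(x)
}

.load_structure <- function(x) {
  if (is.character(x)) bio3d::read.pdb(x) else x
}

.ca_coords <- function(x) {
  if (inherits(x, "pdb")) {
    sel <- bio3d::atom.select(x, elety = "CA", verbose = FALSE)
    co <- matrix(x$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
    rownames(co) <- x$atom$resno[sel$atom]
    co
  } else {
    co <- as.matrix(x)
    if (is.null(rownames(co))) rownames(co) <- seq_len(nrow(co))
    co
  }
}

.out_path <- function(cfg, name) {
  if (is.null(cfg$out_dir)) return(NULL)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$out_dir, name)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the sequence-space track
#'
#' End-to-end coevolution analysis: sequence reweighting, pseudocounted
#' frequencies, MI and DI scoring, separation-filtered top-pair selection,
#' optional contact flagging against a structure, MI/DI residue graphs with
#' Girvan-Newman communities and maximal cliques, and optional consensus
#' disorder annotation of the selected pairs. Artifacts are written to
#' `cfg$out_dir` when set.
#'
#' @param cfg a [run_config()] with at least `msa`.
#' @return A report list with the fitted objects and summary counts.
#' @export
run_sequence_track <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$msa)) stop("config needs an 'msa' entry")
  aln <- .stage("read_alignment", .load_alignment(cfg$msa))
  if (!is.null(cfg$ref_id))
    aln <- .stage("map_columns", map_columns(aln, cfg$ref_id, cfg$offset))
  fit <- .stage("dca", dca(aln, cfg$identity_threshold, cfg$lambda))
  sel <- lapply(list(mi = fit$mi, di = fit$di), function(m)
    .stage("select_top_pairs",
           suppressWarnings(select_top_pairs(m, cfg$top_n,
                                             cfg$min_separation))))
  cmap <- NULL
  if (!is.null(cfg$structure)) {
    cmap <- .stage("contact_map",
                   contact_map(.load_structure(cfg$structure),
                               cfg$contact_cutoff))
    sel <- lapply(sel, function(s)
      .stage("flag_contacts", suppressWarnings(flag_contacts(s, cmap))))
  }
  nets <- lapply(names(sel), function(k) {
    g <- .stage("build_graph", build_graph(sel[[k]], paste0("G_", toupper(k))))
    list(graph = g,
         communities = .stage("girvan_newman", girvan_newman(g)),
         cliques = .stage("maximal_cliques", maximal_cliques(g)))
  })
  names(nets) <- names(sel)
  dis <- NULL
  if (!is.null(cfg$disorder)) {
    tab <- if (is.character(cfg$disorder)) read_disorder_scores(cfg$disorder)
    else cfg$disorder
    prof <- .stage("consensus_profile", consensus_profile(tab))
    dis <- lapply(sel, function(s)
      .stage("annotate_pairs", suppressWarnings(annotate_pairs(s, prof))))
    dis$profile <- prof
  }
  report <- list(
    track = "sequence",
    params = list(identity_threshold = cfg$identity_threshold,
                  lambda = fit$params$lambda,
                  min_separation = cfg$min_separation, top_n = cfg$top_n,
                  contact_cutoff = cfg$contact_cutoff),
    M_eff = fit$M_eff,
    counts = list(
      n_pairs = vapply(sel, nrow, 0L),
      n_contact_pairs = vapply(sel, function(s)
        attr(s, "n_contact") %||% NA_integer_, 0L),
      n_distinct_residues = vapply(sel, function(s)
        length(unique(c(s$i, s$j))), 0L),
      n_communities = vapply(nets, function(n)
        n$communities$n_communities, 0L),
      modularity = vapply(nets, function(n) n$communities$modularity, 0),
      max_clique_size = vapply(nets, function(n) n$cliques$maximum_size, 0L),
      disorder = if (!is.null(dis)) lapply(dis[c("mi", "di")],
                                           function(d) d$summary)))
  out <- list(report = report, fit = fit, selection = sel, contact_map = cmap,
              networks = nets, disorder = dis)
  if (!is.null(cfg$out_dir)) {
    write_pair_scores(fit, .out_path(cfg, "pair_scores.tsv"))
    for (k in names(sel))
      write_pair_selection(sel[[k]],
                           .out_path(cfg, paste0("top_pairs_", k, ".tsv")))
    for (k in names(nets))
      write_graph_file(nets[[k]]$graph,
                       .out_path(cfg, paste0("network_", k, ".graphml")),
                       nets[[k]]$communities)
    if (!is.null(dis))
      write_disorder_profile(dis$profile,
                             .out_path(cfg, "disorder_profile.tsv"))
    jsonlite::write_json(report, .out_path(cfg, "sequence_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out
}

#' Locate a coupled pair within a community partition
#'
#' @param partition a [community_partition][girvan_newman].
#' @param coarse the matching [community_graph()].
#' @param i,j residue labels.
#' @return `"same_cluster"`, `"connected_clusters"`, `"separate_clusters"`,
#'   or `"uncovered"` when a residue is not in the partition.
#' @export
pair_cluster_location <- function(partition, coarse, i, j) {
  ci <- partition$membership[as.character(i)]
  cj <- partition$membership[as.character(j)]
  if (is.na(ci) || is.na(cj)) return("uncovered")
  if (ci == cj) return("same_cluster")
  vn <- igraph::V(coarse)$name
  if (!(as.character(ci) %in% vn) || !(as.character(cj) %in% vn))
    return("separate_clusters")
  connected <- igraph::are_adjacent(coarse, as.character(ci),
                                    as.character(cj))
  if (connected) "connected_clusters" else "separate_clusters"
}

#' Run the structure-space track
#'
#' For each variant structure: C-alpha elastic-network normal modes,
#' residue cross-correlation, the dynamic correlation network (contacts
#' with |c| above the cutoff), Girvan-Newman coarse-grained communities and
#' the betweenness centrality profile. Produces a cross-variant comparison
#' table (community counts, modularity, mean centrality, per-residue
#' centrality deltas vs the `"WT"` entry) and, when `pairs` is given,
#' reports whether each coupled pair falls in the same or in connected
#' communities.
#'
#' @param cfg a [run_config()] with `structures` (named list).
#' @param pairs optional data.frame of coupled pairs (`i`, `j`) to locate in
#'   each variant's community partition.
#' @return A report list: per-variant results, `comparison` data.frame,
#'   `pair_locations`.
#' @export
run_structure_track <- function(cfg, pairs = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$structures) || length(cfg$structures) == 0L)
    stop("config needs a non-empty 'structures' list")
  vnames <- names(cfg$structures) %||%
    paste0("variant_", seq_along(cfg$structures))
  variants <- lapply(seq_along(cfg$structures), function(k) {
    coords <- .stage(paste0("coords[", vnames[k], "]"),
                     .ca_coords(.load_structure(cfg$structures[[k]])))
    modes <- .stage("enm", enm(coords, cfg$enm_cutoff))
    cc <- .stage("cross_correlation", cross_correlation(modes))
    cmap <- .stage("contact_map", contact_map(coords, cfg$contact_cutoff))
    net <- .stage("correlation_network",
                  correlation_network(cc, cmap, cfg$correlation_cutoff))
    cl <- .stage("community_clusters", community_clusters(net))
    btw <- .stage("betweenness_profile", betweenness_profile(net))
    list(name = vnames[k], modes = modes, cross_correlation = cc,
         network = net, clusters = cl, betweenness = btw)
  })
  names(variants) <- vnames
  comparison <- data.frame(
    variant = vnames,
    n_residues = vapply(variants, function(v) v$modes$n, 0L),
    n_communities = vapply(variants, function(v)
      v$clusters$partition$n_communities, 0L),
    modularity = vapply(variants, function(v)
      v$clusters$partition$modularity, 0),
    mean_betweenness = vapply(variants, function(v)
      mean(v$betweenness), 0))
  ref <- if ("WT" %in% vnames) "WT" else vnames[1L]
  deltas <- lapply(variants, function(v) {
    shared <- intersect(names(v$betweenness),
                        names(variants[[ref]]$betweenness))
    v$betweenness[shared] - variants[[ref]]$betweenness[shared]
  })
  pair_locations <- NULL
  if (!is.null(pairs)) {
    pair_locations <- do.call(rbind, lapply(vnames, function(vn) {
      v <- variants[[vn]]
      data.frame(variant = vn, i = pairs$i, j = pairs$j,
                 location = vapply(seq_len(nrow(pairs)), function(r)
                   pair_cluster_location(v$clusters$partition,
                                         v$clusters$coarse,
                                         pairs$i[r], pairs$j[r]), ""))
    }))
  }
  report <- list(track = "structure",
                 params = list(enm_cutoff = cfg$enm_cutoff,
                               contact_cutoff = cfg$contact_cutoff,
                               correlation_cutoff = cfg$correlation_cutoff),
                 comparison = comparison,
                 reference_variant = ref)
  out <- list(report = report, variants = variants, comparison = comparison,
              centrality_deltas = deltas, pair_locations = pair_locations)
  if (!is.null(cfg$out_dir)) {
    utils::write.table(comparison,
                       .out_path(cfg, "variant_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (vn in vnames) {
      v <- variants[[vn]]
      utils::write.table(
        data.frame(residue = names(v$betweenness),
                   betweenness = as.numeric(v$betweenness)),
        .out_path(cfg, paste0("betweenness_", vn, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_graph_file(v$network,
                       .out_path(cfg, paste0("corrnet_", vn, ".graphml")),
                       v$clusters$partition)
    }
    if (!is.null(pair_locations))
      utils::write.table(pair_locations,
                         .out_path(cfg, "pair_locations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, .out_path(cfg, "structure_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out
}
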