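#' Read a per-residue disorder score table
#'
#' TSV with one row per residue: a `residue` column plus one column per
#' disorder predictor (header = predictor name), scores in \[0, 1\].
#'
#' @param path input TSV path.
#' @return data.frame with `residue` first.
#' @export
read_disorder_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"residue" %in% names(df))
    stop("disorder table must have a 'residue' column")
  df
}

#' Classify residues by mean predicted disorder score
#'
#' A residue is disordered when its mean predicted disorder score (PDS)
#' exceeds 0.5, flexible when the PDS lies in \[0.2, 0.5\] (both boundaries
#' inclusive), and ordered below 0.2.
#'
#' @param mean_pds numeric vector of scores in \[0, 1\].
#' @return Character vector of `"ordered"`, `"flexible"`, `"disordered"`.
#' @export
classify_disorder <- function(mean_pds) {
  if (any(is.na(mean_pds)) || any(mean_pds < 0 | mean_pds > 1))
    stop("mean PDS values must lie in [0, 1]")
  ifelse(mean_pds > 0.5, "disordered",
         ifelse(mean_pds >= 0.2, "flexible", "ordered"))
}

#' Consensus intrinsic-disorder profile
#'
#' Averages the per-residue outputs of several disorder predictors into a
#' mean predicted disorder score (PDS) with its standard deviation across
#' predictors, and classifies each residue with [classify_disorder()].
#' Averaging multiple predictors is the usual way to stabilise per-residue
#' disorder estimates.
#'
#' @param scores a data.frame as from [read_disorder_scores()] (`residue`
#'   column + one column per predictor), or a list of such tables which are
#'   merged on `residue`.
#' @return Object of class `disorder_profile`: data.frame with `residue`,
#'   `mean_pds`, `sd`, `class`; the per-predictor scores are kept in
#'   attribute `per_predictor`.
#' @export
consensus_profile <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- Reduce(function(a, b) merge(a, b, by = "residue", all = TRUE),
                     scores)
  }
  if (!"residue" %in% names(scores))
    stop("disorder table must have a 'residue' column")
  preds <- setdiff(names(scores), "residue")
  if (length(preds) == 0L) stop("no predictor columns")
  m <- as.matrix(scores[, preds, drop = FALSE])
  n_avail <- rowSums(!is.na(m))
  if (any(n_avail == 0L)) {
    warning(sum(n_avail == 0L),
            " residue(s) missing from all predictors dropped")
    keep <- n_avail > 0L
    scores <- scores[keep, , drop = FALSE]
    m <- m[keep, , drop = FALSE]
  }
  mean_pds <- rowMeans(m, na.rm = TRUE)
  sdev <- apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) 0 else stats::sd(r)
  })
  out <- data.frame(residue = scores$residue, mean_pds = mean_pds,
                    sd = sdev, class = classify_disorder(mean_pds))
  rownames(out) <- NULL
  structure(out, class = c("disorder_profile", "data.frame"),
            per_predictor = scores)
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("Consensus disorder profile: ", nrow(x), " residues over ",
      ncol(attr(x, "per_predictor")) - 1L, " predictor(s)\n", sep = "")
  cat("  disordered: ", sum(x$class == "disordered"),
      "  flexible: ", sum(x$class == "flexible"),
      "  ordered: ", sum(x$class == "ordered"), "\n", sep = "")
  invisible(x)
}

#' Annotate coupled pairs with disorder classes
#'
#' Attaches the consensus disorder class of both members to each selected
#' pair and summarises how disorder distributes over the coupled pairs.
#'
#' @param sel a [pair_selection][select_top_pairs] (or data.frame with `i`,
#'   `j`).
#' @param profile a [disorder_profile][consensus_profile].
#' @return Object of class `pair_disorder`: list with `pairs` (per-pair
#'   classes and mean scores) and `summary` (counts: `n_pairs` covered,
#'   `n_both_disordered`, `n_any_disordered`, `n_any_above_0.3`).
#' @export
annotate_pairs <- function(sel, profile) {
  stopifnot(inherits(profile, "disorder_profile"))
  df <- as.data.frame(sel)
  ii <- match(df$i, profile$residue)
  jj <- match(df$j, profile$residue)
  covered <- !is.na(ii) & !is.na(jj)
  if (any(!covered))
    warning(sum(!covered), " pair(s) not covered by the disorder profile")
  pairs <- data.frame(i = df$i, j = df$j,
                      pds_i = profile$mean_pds[ii],
                      pds_j = profile$mean_pds[jj],
                      class_i = profile$class[ii],
                      class_j = profile$class[jj])
  both_dis <- covered & pairs$class_i == "disordered" &
    pairs$class_j == "disordered"
  any_dis <- covered & (pairs$class_i == "disordered" |
                          pairs$class_j == "disordered")
  any_03 <- covered & (pairs$pds_i > 0.3 | pairs$pds_j > 0.3)
  structure(list(pairs = pairs,
                 summary = list(n_pairs = sum(covered),
                                n_both_disordered = sum(both_dis),
                                n_any_disordered = sum(any_dis),
                                n_any_above_0.3 = sum(any_03))),
            class = "pair_disorder")
}

#' @export
print.pair_disorder <- function(x, ...) {
  s <- x$summary
  cat("Disorder annotation of ", s$n_pairs, " coupled pairs:\n",
      "  both members disordered:    ", s$n_both_disordered, "\n",
      "  >= 1 member disordered:     ", s$n_any_disordered, "\n",
      "  >= 1 member mean PDS > 0.3: ", s$n_any_above_0.3, "\n", sep = "")
  invisible(x)
}

#' Write a disorder profile as TSV
#'
#' @param profile a [disorder_profile][consensus_profile].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disorder_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
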