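#' Residue-residue contact map from a structure
#'
#' Two residues are in contact when their side-chain proxy atoms lie within
#' `cutoff` Angstrom: C-beta for residues that have one, C-alpha for glycine
#' (the common evaluation convention in coupling analysis). A plain n x 3
#' coordinate matrix (e.g. a C-alpha trace from [make_toy_chain()]) is used
#' as-is.
#'
#' @param structure a `bio3d` `pdb` object or an n x 3 coordinate matrix.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @param chain optional chain identifier to restrict a PDB structure.
#' @return Object of class `contact_map`: list with logical `contacts`
#'   matrix (dimnames = residue numbers), `cutoff`, `definition`.
#' @export
contact_map <- function(structure, cutoff = 8, chain = NULL) {
  if (inherits(structure, "pdb")) {
    xyz <- .residue_coords(structure, chain)
    coords <- xyz$coords
    resno <- xyz$resno
    def <- "Cb-Cb (Ca for Gly)"
  } else {
    coords <- as.matrix(structure)
    if (ncol(coords) != 3L) stop("coordinate matrix must be n x 3")
    resno <- rownames(coords) %||% seq_len(nrow(coords))
    def <- "Ca-Ca"
  }
  if (nrow(coords) < 2L) stop("need >= 2 residues with coordinates")
  d <- as.matrix(stats::dist(coords))
  contacts <- d <= cutoff
  diag(contacts) <- FALSE
  dimnames(contacts) <- list(as.character(resno), as.character(resno))
  structure(list(contacts = contacts, cutoff = cutoff,
                 definition = list(atoms = def, cutoff = cutoff)),
            class = "contact_map")
}

# one representative atom per residue: CB, or CA where CB is absent
.residue_coords <- function(pdb, chain = NULL) {
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  at <- at[at$elety %in% c("CA", "CB"), ]
  key <- paste(at$chain, at$resno, sep = "_")
  reps <- do.call(rbind, lapply(split(at, factor(key, levels = unique(key))),
                                function(r) {
    r[order(match(r$elety, c("CB", "CA")))[1L], , drop = FALSE]
  }))
  miss <- is.na(reps$x) | is.na(reps$y) | is.na(reps$z)
  if (any(miss)) {
    warning(sum(miss), " residue(s) without coordinates excluded")
    reps <- reps[!miss, , drop = FALSE]
  }
  list(coords = as.matrix(reps[, c("x", "y", "z")]), resno = reps$resno)
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map: ", nrow(x$contacts), " residues, ",
      sum(x$contacts) / 2, " contacts (", x$definition$atoms, " <= ",
      x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Select top-scoring residue pairs under a separation filter
#'
#' Ranks unordered column pairs by score, discarding pairs closer than
#' `min_separation` positions along the sequence (near-diagonal pairs carry
#' trivially high coupling scores). Ties are broken by (i, j) lexicographic
#' order, so the ranking is deterministic.
#'
#' @param scores symmetric score matrix (MI or DI); dimnames, when numeric,
#'   give residue numbering.
#' @param top_n number of pairs to keep (default 100).
#' @param min_separation minimum |i - j| along the sequence (default 5).
#' @return Object of class `pair_selection`: a data.frame with columns
#'   `i`, `j`, `score` (i < j, scores non-increasing) and attributes
#'   `min_separation`, `top_n`.
#' @export
select_top_pairs <- function(scores, top_n = 100L, min_separation = 5L) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores), top_n >= 1L)
  if (max(abs(scores - t(scores))) > 1e-8)
    stop("score matrix must be symmetric")
  pos <- suppressWarnings(as.integer(rownames(scores) %||%
                                       seq_len(nrow(scores))))
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  i <- pos[ut[, 1L]]; j <- pos[ut[, 2L]]; s <- scores[ut]
  ok <- !is.na(i) & !is.na(j) & abs(i - j) >= min_separation
  df <- data.frame(i = pmin(i[ok], j[ok]), j = pmax(i[ok], j[ok]),
                   score = s[ok])
  df <- df[order(-df$score, df$i, df$j), ]
  if (nrow(df) < top_n) {
    warning("only ", nrow(df), " eligible pairs (requested ", top_n, ")")
  } else df <- df[seq_len(top_n), ]
  rownames(df) <- NULL
  structure(df, class = c("pair_selection", "data.frame"),
            min_separation = min_separation, top_n = top_n)
}

#' Flag selected pairs that impose structural contacts
#'
#' @param sel a [pair_selection][select_top_pairs].
#' @param cmap a [contact_map()].
#' @return `sel` with a logical `in_contact` column (NA when a pair falls
#'   outside the structure's residue coverage) and attribute `n_contact`,
#'   the count of contact-imposing pairs among covered pairs.
#' @export
flag_contacts <- function(sel, cmap) {
  stopifnot(inherits(sel, "pair_selection"), inherits(cmap, "contact_map"))
  res <- rownames(cmap$contacts)
  ii <- match(as.character(sel$i), res)
  jj <- match(as.character(sel$j), res)
  covered <- !is.na(ii) & !is.na(jj)
  if (any(!covered))
    warning(sum(!covered), " pair(s) outside structure coverage")
  flag <- rep(NA, nrow(sel))
  flag[covered] <- cmap$contacts[cbind(ii[covered], jj[covered])]
  sel$in_contact <- flag
  attr(sel, "n_contact") <- sum(flag, na.rm = TRUE)
  sel
}

#' Write selected pairs as TSV
#'
#' @param sel a [pair_selection][select_top_pairs].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_selection <- function(sel, path) {
  utils::write.table(as.data.frame(sel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
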