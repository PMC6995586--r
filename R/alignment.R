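#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into an `alignment` object over
#' the 21-state alphabet (20 canonical amino acids plus the gap `"-"`).
#' Lowercase letters are upper-cased; any other symbol (`X`, `B`, `Z`, `U`,
#' `O`, `.`, ...) is coerced to a gap. Coercions are counted and reported.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`; defaults to a guess from the
#'   file extension (`.sto`/`.stk` mean Stockholm).
#' @return An object of class `alignment`: a list with `seq` (M x L character
#'   matrix), `ids`, `n_coerced`, and optionally `ref_id`/`column_map` after
#'   [map_columns()].
#' @seealso [write_alignment()], [map_columns()]
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  if (format == "fasta") {
    .check_fasta_ragged(path)
    fa <- bio3d::read.fasta(path, rm.dup = FALSE)
    seqs <- unname(fa$ali)
    ids <- fa$id
  } else {
    st <- .read_stockholm(path)
    seqs <- st$seqs
    ids <- st$ids
  }
  if (length(ids) == 0L || is.null(dim(seqs)) || nrow(seqs) == 0L)
    stop("empty alignment: ", path)
  new_alignment(seqs, ids)
}

#' Build an alignment from sequences in memory
#'
#' @param seqs character matrix (rows = sequences) or character vector of
#'   equal-length strings.
#' @param ids row identifiers; defaults to `seq_1 ... seq_M`.
#' @param alphabet state alphabet for downstream frequency models; default
#'   the full 21-state protein alphabet. Synthetic alignments over a
#'   reduced q-state alphabet should pass it here so coupling inference
#'   works in the q-state model that generated them.
#' @return An [alignment][read_alignment] object (non-standard symbols
#'   coerced to gap, as for [read_alignment()]).
#' @export
as_alignment <- function(seqs, ids = NULL, alphabet = aa_alphabet()) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    len <- nchar(seqs)
    if (length(unique(len)) > 1L) stop("ragged alignment: unequal lengths")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  ids <- ids %||% paste0("seq_", seq_len(nrow(seqs)))
  new_alignment(as.matrix(seqs), ids, alphabet = alphabet)
}

# constructor shared by readers and the synthetic generator
new_alignment <- function(seqs, ids, coerce = TRUE,
                          alphabet = aa_alphabet()) {
  stopifnot(is.matrix(seqs), nrow(seqs) == length(ids))
  seqs <- toupper(seqs)
  bad <- !(seqs %in% aa_alphabet())
  n_coerced <- sum(bad)
  if (coerce && n_coerced > 0L) {
    seqs[bad] <- "-"
    message(n_coerced, " non-standard symbol(s) coerced to gap")
  } else if (!coerce && n_coerced > 0L) {
    stop("alignment contains non-standard symbols")
  }
  if (!all(seqs %in% alphabet))
    stop("alignment contains symbols outside its declared alphabet")
  dimnames(seqs) <- NULL
  structure(list(seq = seqs, ids = as.character(ids),
                 n_coerced = n_coerced, alphabet = alphabet,
                 ref_id = NULL, column_map = NULL),
            class = "alignment")
}

.check_fasta_ragged <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  len <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq.int(hdr[k] + 1L, ends[k])]
    sum(nchar(gsub("\\s", "", body)))
  }, integer(1))
  if (length(unique(len)) > 1L) {
    bad <- sub("^>\\s*", "", lines[hdr[which(len != len[1L])[1L]]])
    stop("ragged alignment: sequence '", sub("\\s.*", "", bad),
         "' has length ", len[len != len[1L]][1L],
         " but expected ", len[1L])
  }
  invisible(TRUE)
}

# Minimal Stockholm 1.0 reader (single or multi-block; '#' annotation and
# '//' terminator ignored). No installed package parses this format.
.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- lines[!grepl("^\\s*(#|//|$)", lines)]
  if (length(keep) == 0L) stop("empty Stockholm alignment: ", path)
  parts <- regmatches(keep, regexec("^(\\S+)\\s+(\\S+)\\s*$", keep))
  if (any(lengths(parts) != 3L)) stop("malformed Stockholm line in ", path)
  ids <- vapply(parts, `[`, "", 2L)
  seq <- vapply(parts, `[`, "", 3L)
  uid <- unique(ids)
  full <- vapply(uid, function(id) paste(seq[ids == id], collapse = ""), "")
  len <- nchar(full)
  if (length(unique(len)) > 1L) {
    bad <- uid[which(len != len[1L])[1L]]
    stop("ragged alignment: sequence '", bad, "' has length ",
         len[uid == bad], " but expected ", len[1L])
  }
  seqs <- do.call(rbind, strsplit(full, ""))
  list(seqs = seqs, ids = uid)
}

#' Write an alignment to FASTA or Stockholm
#'
#' @param aln an [alignment][read_alignment] object.
#' @param path output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "alignment"))
  if (format == "fasta") {
    bio3d::write.fasta(seqs = aln$seq, ids = aln$ids, file = path)
  } else {
    pad <- formatC(aln$ids, width = max(nchar(aln$ids)), flag = "-")
    writeLines(c("# STOCKHOLM 1.0",
                 paste(pad, apply(aln$seq, 1L, paste, collapse = "")),
                 "//"), path)
  }
  invisible(path)
}

#' Map alignment columns to reference residue numbering
#'
#' Assigns each alignment column the residue number it occupies in a chosen
#' reference row, so that coupled pairs can be reported in the numbering of a
#' protein of interest (e.g. human SOD1 positions such as H63 or H120).
#' Columns where the reference row has a gap get `NA`.
#'
#' @param aln an [alignment][read_alignment] object.
#' @param ref_id identifier of the reference row.
#' @param offset residue number of the first non-gap reference column
#'   (1-based; default 1).
#' @return `aln` with `ref_id` set and `column_map` an integer vector of
#'   length L (NA at reference-gap columns), strictly increasing elsewhere.
#' @export
map_columns <- function(aln, ref_id, offset = 1L) {
  stopifnot(inherits(aln, "alignment"))
  k <- match(ref_id, aln$ids)
  if (is.na(k)) stop("unknown reference id: ", ref_id)
  row <- aln$seq[k, ]
  nongap <- row != "-"
  cmap <- rep(NA_integer_, length(row))
  cmap[nongap] <- cumsum(nongap)[nongap] + as.integer(offset) - 1L
  if (!any(nongap)) warning("reference row '", ref_id, "' is all gaps")
  aln$ref_id <- ref_id
  aln$column_map <- cmap
  aln
}

#' @export
print.alignment <- function(x, ...) {
  cat("Multiple sequence alignment: ", nrow(x$seq), " sequences x ",
      ncol(x$seq), " columns\n", sep = "")
  if (x$n_coerced > 0L)
    cat("  (", x$n_coerced, " non-standard symbols coerced to gap)\n", sep = "")
  if (!is.null(x$ref_id))
    cat("  reference numbering: row '", x$ref_id, "', residues ",
        min(x$column_map, na.rm = TRUE), "-",
        max(x$column_map, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
dim.alignment <- function(x) dim(x$seq)
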