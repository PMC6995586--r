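# Reference data for the worked example: human Cu/Zn superoxide dismutase
# (SOD1), the canonical case of a metalloprotein whose metal-binding loops
# IV and VII switch between disorder (apo) and order (metallated).

#' Mature human SOD1 sequence
#'
#' The 153-residue mature chain of human cytosolic Cu/Zn superoxide
#' dismutase (UniProt P00441, initiator methionine removed), the numbering
#' in which metal-binding residues are H46, H48, H63, H71, H80, D83 and
#' H120.
#'
#' @param as_vector return a character vector of one-letter codes instead
#'   of a single string.
#' @return The sequence.
#' @export
sod1_sequence <- function(as_vector = FALSE) {
  s <- paste0(
    "ATKAVCVLKGDGPVQGIINFEQKESNGPVKVWGSIKGLTEGLHGFHVHEFGDNTAGCTSA",
    "GPHFNPLSRKHGGPKDEERHVGDLGNVTADKDGVADVSIEDSVISLSGDHCIIGRTLVVH",
    "EKADDLGKGGNEESTKTGNAGSRLACGVIGIAQ")
  if (as_vector) strsplit(s, "")[[1L]] else s
}

#' SOD1 variant definitions
#'
#' The wild type plus six mutationally defined variants used to probe metal
#' residence and loop restraint: the de-metallated apo form (H63F), the two
#' mono-metallated forms, and three ALS-linked stretch mutants in loop IV
#' (L4), loop VII (L7) and loop IV plus beta-strand (L4S).
#'
#' The two mono-metallated assignments are reported inconsistently in the
#' source analysis: its variant table assigns Cu-SOD1 = H120F and
#' Zn-SOD1 = H71F while its narrative swaps them (Zn-SOD1 = H120F,
#' Cu-SOD1 = H71F). `source = "table"` (default) follows the table;
#' `source = "text"` follows the narrative.
#'
#' @param source `"table"` or `"text"` (see Details).
#' @return Named list of [variant_spec()] objects.
#' @export
sod1_variants <- function(source = c("table", "text")) {
  source <- match.arg(source)
  cu <- if (source == "table") "H120F" else "H71F"
  zn <- if (source == "table") "H71F" else "H120F"
  list(
    WT   = variant_spec("WT"),
    apo  = variant_spec("apo-SOD1", "H63F"),
    Cu   = variant_spec("Cu-SOD1", cu),
    Zn   = variant_spec("Zn-SOD1", zn),
    L4   = variant_spec("L4_SOD1", c("N65S", "L67P", "G72S", "D76Y", "H80A")),
    L7   = variant_spec("L7_SOD1", c("D124G", "D125H", "L126S", "S134N",
                                     "N139K", "L144F")),
    L4S  = variant_spec("L4S_SOD1", c("G72S", "D76Y", "H80A", "L84F",
                                      "A89T", "D90A", "G93C", "A95G")))
}

#' Published top mutual-information pairs for the SOD family
#'
#' The ten top-ranking mutual-information coupled pairs from a reference
#' coevolution analysis of the SOD_Cu (PF00080) family, in human SOD1
#' numbering, with each residue's mean predicted disorder score (PDS) and
#' its spread over the predictor panel. `highlighted` marks the rows
#' emphasised (bold) in the reference table.
#'
#' @return data.frame with columns `i`, `pds_i`, `sd_i`, `j`, `pds_j`,
#'   `sd_j`, `score`, `highlighted`.
#' @export
sod1_top_mi_pairs <- function() {
  data.frame(
    i = c(29L, 42L, 44L, 46L, 58L, 62L, 67L, 70L, 99L, 118L),
    pds_i = c(0.25, 0.21, 0.26, 0.27, 0.38, 0.44, 0.56, 0.68, 0.42, 0.27),
    sd_i = c(0.16, 0.10, 0.13, 0.11, 0.18, 0.19, 0.14, 0.10, 0.10, 0.09),
    j = c(98L, 117L, 122L, 115L, 68L, 116L, 124L, 96L, 122L, 125L),
    pds_j = c(0.43, 0.24, 0.36, 0.23, 0.60, 0.26, 0.48, 0.47, 0.36, 0.52),
    sd_j = c(0.11, 0.09, 0.05, 0.09, 0.12, 0.10, 0.06, 0.11, 0.05, 0.07),
    score = c(0.64260, 0.703328, 0.593079, 0.577762, 0.615481, 0.583716,
              0.608395, 0.603931, 0.603343, 0.6989),
    highlighted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                    FALSE, FALSE))
}

#' Published top direct-information pairs for the SOD family
#'
#' The eighteen top-ranking direct-information coupled pairs from the same
#' reference analysis as [sod1_top_mi_pairs()], with per-residue mean
#' predicted disorder scores.
#'
#' @return data.frame with columns `i`, `pds_i`, `sd_i`, `j`, `pds_j`,
#'   `sd_j`, `score`, `highlighted`.
#' @export
sod1_top_di_pairs <- function() {
  data.frame(
    i = c(8L, 10L, 15L, 16L, 17L, 28L, 29L, 31L, 39L, 40L, 42L, 44L, 46L,
          59L, 60L, 69L, 118L, 122L),
    pds_i = c(0.33, 0.28, 0.24, 0.25, 0.27, 0.25, 0.25, 0.25, 0.21, 0.21,
              0.21, 0.26, 0.27, 0.38, 0.39, 0.65, 0.27, 0.36),
    sd_i = c(0.12, 0.09, 0.05, 0.05, 0.07, 0.16, 0.16, 0.16, 0.11, 0.11,
             0.10, 0.13, 0.11, 0.19, 0.19, 0.13, 0.09, 0.05),
    j = c(86L, 138L, 28L, 89L, 100L, 99L, 98L, 115L, 83L, 137L, 119L, 56L,
          116L, 67L, 113L, 127L, 125L, 128L),
    pds_j = c(0.59, 0.63, 0.25, 0.54, 0.41, 0.42, 0.43, 0.23, 0.67, 0.62,
              0.28, 0.34, 0.26, 0.56, 0.22, 0.58, 0.52, 0.58),
    sd_j = c(0.05, 0.09, 0.16, 0.04, 0.09, 0.10, 0.11, 0.09, 0.09, 0.12,
             0.07, 0.17, 0.10, 0.14, 0.08, 0.09, 0.07, 0.09),
    score = c(0.108738, 0.122847, 0.125331, 0.109716, 0.0900074, 0.131024,
              0.095733, 0.0851411, 0.0948818, 0.249519, 0.105276,
              0.0880899, 0.0962272, 0.107917, 0.156108, 0.126032,
              0.100409, 0.156898),
    highlighted = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
                    FALSE, TRUE))
}

#' Disorder profile from a published pair table
#'
#' Collapses the per-residue mean PDS values printed in
#' [sod1_top_mi_pairs()]/[sod1_top_di_pairs()] into a
#' [disorder_profile][consensus_profile] covering the residues they
#' mention, so published tables can be fed to [annotate_pairs()].
#'
#' @param tab a table in the format of [sod1_top_di_pairs()].
#' @return A `disorder_profile`.
#' @export
pair_table_profile <- function(tab) {
  df <- rbind(data.frame(residue = tab$i, mean_pds = tab$pds_i,
                         sd = tab$sd_i),
              data.frame(residue = tab$j, mean_pds = tab$pds_j,
                         sd = tab$sd_j))
  df <- df[!duplicated(df$residue), ]
  df <- df[order(df$residue), ]
  out <- data.frame(residue = df$residue, mean_pds = df$mean_pds,
                    sd = df$sd, class = classify_disorder(df$mean_pds))
  rownames(out) <- NULL
  structure(out, class = c("disorder_profile", "data.frame"),
            per_predictor = data.frame(residue = df$residue,
                                       published = df$mean_pds))
}
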