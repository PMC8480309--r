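#' Read an mRNA/protein decay-rate table
#'
#' TSV with header and columns `gene` plus any of `mrna_decay_rate`
#' (per hour), `mrna_half_life` (hours), `protein_decay_rate` (per day);
#' missing fields are allowed. Validates that rates are non-negative and
#' that half-life agrees with `ln 2 / rate` within 1% where both are given.
#'
#' @param path TSV path.
#' @return Decay tibble.
#' @export
read_decay_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(x)) abort("decay table needs a `gene` column")
  for (col in intersect(c("mrna_decay_rate", "protein_decay_rate"), names(x))) {
    if (any(x[[col]] < 0, na.rm = TRUE)) abort(paste0(col, " must be non-negative"))
  }
  if (all(c("mrna_decay_rate", "mrna_half_life") %in% names(x))) {
    both <- !is.na(x$mrna_decay_rate) & !is.na(x$mrna_half_life) & x$mrna_decay_rate > 0
    rel <- abs(x$mrna_half_life[both] - log(2) / x$mrna_decay_rate[both]) /
      (log(2) / x$mrna_decay_rate[both])
    if (any(rel > 0.01)) {
      abort("mrna_half_life inconsistent with ln2/mrna_decay_rate (> 1%)")
    }
  }
  as_tibble(x)
}

#' Read a gene annotation table
#'
#' TSV with header; `location` column gives the predicted subcellular
#' location, `term` rows give GO-style term membership (one gene-term pair
#' per row). Either column may be absent.
#'
#' @param path TSV path.
#' @return Annotation tibble.
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(x)) abort("annotation table needs a `gene` column")
  if ("term" %in% names(x) && any(!nzchar(x$term) | is.na(x$term))) {
    abort("empty term identifier in annotation table")
  }
  as_tibble(x)
}
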