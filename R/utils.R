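#' Significance stars for a p-value
#'
#' Bands follow the usual four-level convention used in the figure legends of
#' germination multi-omics studies: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
stars_for_p <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

# all(x %in% y) with a readable error
assert_subset <- function(x, y, what_x = "set", what_y = "background") {
  missing <- setdiff(x, y)
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s must be contained in %s; %d id(s) are not (first: %s)",
      what_x, what_y, length(missing), missing[[1L]]
    ))
  }
  invisible(TRUE)
}

assert_prob <- function(p, what = "p") {
  if (!is.numeric(p)) abort(sprintf("%s must be numeric", what))
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("%s values must lie in [0, 1]; offending value %g", what, p[bad][[1L]]))
  }
  invisible(TRUE)
}
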