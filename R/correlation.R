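#' Spearman correlation of two vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Pairs with a
#' missing entry are dropped first; fewer than three complete pairs or a
#' constant vector give `NA` with a warning rather than an error, since
#' per-gene correlations are summarised over thousands of genes.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    warn("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Per-gene lagged correlation between two layers
#'
#' For each gene, sample `(t_i, r)` of layer `a` is paired with sample
#' `(t_(i+lag), r)` of layer `b` (replicate-matched, `i = 1..T-lag`) and the
#' Spearman correlation is computed over the pairs where both measurements
#' are detected. With `lag = 1` this asks whether today's polysomal mRNA
#' predicts tomorrow's protein. Genes with fewer than three usable pairs are
#' reported `NA`.
#'
#' @param a,b Expression-set tibbles over the same genes, times, replicates.
#' @param lag Non-negative contrast shift applied to `b`.
#' @return Tibble `gene`, `rho`, `n_pairs` with attributes `layer_pair` and
#'   `lag`; mean/median rho available via [summarise_correlation()].
#' @export
per_gene_layer_correlation <- function(a, b, lag = 0L) {
  validate_expression_set(a)
  validate_expression_set(b)
  ma <- es_matrices(a)
  mb <- es_matrices(b)
  if (!identical(ma$times, mb$times) || !identical(ma$reps, mb$reps)) {
    abort("layers have mismatched time/replicate structure")
  }
  if (!setequal(ma$genes, mb$genes)) abort("layers cover different gene sets")
  lag <- as.integer(lag)
  t_n <- length(ma$times)
  if (lag < 0L || lag >= t_n) abort("lag must be in [0, T-1]")
  ord <- match(ma$genes, mb$genes)
  cols_a <- which(ma$time_of_col %in% ma$times[seq_len(t_n - lag)])
  cols_b <- which(mb$time_of_col %in% mb$times[seq_len(t_n - lag) + lag])
  va <- ma$values[, cols_a, drop = FALSE]
  vb <- mb$values[ord, cols_b, drop = FALSE]
  ok <- ma$detected[, cols_a, drop = FALSE] & mb$detected[ord, cols_b, drop = FALSE]
  va[!ok] <- NA
  vb[!ok] <- NA
  rho <- vapply(seq_along(ma$genes), function(g) {
    suppressWarnings(spearman_rho(va[g, ], vb[g, ]))
  }, 1.0)
  out <- tibble(
    gene = ma$genes, rho = rho, n_pairs = rowSums(ok)
  )
  attr(out, "layer_pair") <- paste0(a$layer[[1L]], "->", b$layer[[1L]])
  attr(out, "lag") <- lag
  out
}

#' Summarise a per-gene correlation table
#'
#' @param x Tibble from [per_gene_layer_correlation()].
#' @return One-row tibble with the layer pair, lag, number of genes with a
#'   defined correlation, number excluded as undefined, and mean/median rho.
#' @export
summarise_correlation <- function(x) {
  tibble(
    layer_pair = attr(x, "layer_pair") %||% NA_character_,
    lag = attr(x, "lag") %||% NA_integer_,
    n_genes = sum(!is.na(x$rho)),
    n_undefined = sum(is.na(x$rho)),
    mean_rho = mean(x$rho, na.rm = TRUE),
    median_rho = median(x$rho, na.rm = TRUE)
  )
}

#' Polysome occupancy
#'
#' Log-ratio of polysomal over total mRNA per gene and sample (values are
#' already log2, so an elementwise difference): the standard translational
#' efficiency proxy.
#'
#' @param total,poly Expression-set tibbles with matched genes and samples.
#' @return Expression-set tibble with layer `"polysome_occupancy"`; a cell
#'   is detected only where both inputs are.
#' @export
polysome_occupancy <- function(total, poly) {
  validate_expression_set(total)
  validate_expression_set(poly)
  joined <- inner_join(
    total |> select("gene", "time_hai", "replicate",
      value_t = "value", det_t = "detected"
    ),
    poly |> select("gene", "time_hai", "replicate",
      value_p = "value", det_p = "detected"
    ),
    by = c("gene", "time_hai", "replicate")
  )
  if (nrow(joined) != nrow(total) || nrow(joined) != nrow(poly)) {
    abort("total and polysomal sets do not share the same genes/samples")
  }
  expression_set(
    joined |>
      mutate(
        detected = .data$det_t & .data$det_p,
        value = if_else(.data$detected, .data$value_p - .data$value_t, NA_real_)
      ) |>
      select("gene", "time_hai", "replicate", "value", "detected"),
    layer = "polysome_occupancy"
  )
}

#' Wilcoxon rank-sum test
#'
#' Exact null enumeration when the pooled sample size is at most 12 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. `alternative` refers to the location of `a`
#' relative to `b`.
#'
#' @param a,b Numeric vectors (non-empty; `NA` dropped).
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return One-row tibble `statistic` (rank-sum W for `a`), `p_value`,
#'   `exact`.
#' @export
ranksum_test <- function(a, b, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(
    a, b,
    alternative = sub("two_sided", "two.sided", alternative),
    exact = exact, correct = TRUE
  ))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; exact enumeration of the 2^n sign
#' assignments for n <= 12 (no tied magnitudes), otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param diffs Paired differences (at least 3 nonzero).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (location of
#'   the differences relative to zero).
#' @return One-row tibble `statistic` (V), `p_value`, `exact`.
#' @export
signedrank_test <- function(diffs, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  diffs <- diffs[!is.na(diffs)]
  if (all(diffs == 0)) abort("all differences are zero")
  diffs <- diffs[diffs != 0]
  if (length(diffs) < 3L) abort("need at least 3 nonzero differences")
  ties <- anyDuplicated(abs(diffs)) > 0L
  exact <- length(diffs) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(
    diffs,
    alternative = sub("two_sided", "two.sided", alternative),
    exact = exact, correct = TRUE
  ))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Shapiro-Wilk normality test
#'
#' Used as a reported gate justifying the nonparametric tests elsewhere in
#' the pipeline (no branching happens on it).
#'
#' @param x Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return One-row tibble `W`, `p_value`.
#' @export
shapiro_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (sd(x) == 0) abort("constant vector")
  st <- shapiro.test(x)
  tibble(W = unname(st$statistic), p_value = st$p.value)
}
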