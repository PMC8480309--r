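#' One-tailed Fisher (hypergeometric) enrichment of a gene set
#'
#' 2x2 table of set membership against an annotation (e.g. "contains the
#' motif"), with the exact hypergeometric tail p-value
#' `Pr(X >= a)` for `alternative = "greater"` (`Pr(X <= a)` for
#' `"less"`). The odds ratio is the plain cross-product `ad/bc`, with a
#' Haldane 0.5 correction (flagged) when any cell is zero.
#'
#' @param set_genes Gene ids of the foreground set (subset of background).
#' @param background_genes Gene universe; the table uses `background \ set`
#'   as the comparison group.
#' @param annotated_genes Genes carrying the annotation (subset of
#'   background).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return One-row tibble `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `haldane_corrected`, `p_value`.
#' @export
fisher_enrichment <- function(set_genes, background_genes, annotated_genes,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  set_genes <- unique(set_genes)
  background_genes <- unique(background_genes)
  annotated_genes <- unique(annotated_genes)
  assert_subset(set_genes, background_genes, "set_genes", "background_genes")
  assert_subset(annotated_genes, background_genes, "annotated_genes", "background_genes")
  a <- length(intersect(set_genes, annotated_genes))
  b <- length(set_genes) - a
  cc <- length(annotated_genes) - a
  d <- length(background_genes) - length(set_genes) - cc
  m <- a + cc # annotated
  n <- b + d # unannotated
  k <- a + b # set size
  p <- if (alternative == "greater") {
    phyper(a - 1L, m, n, k, lower.tail = FALSE)
  } else {
    phyper(a, m, n, k, lower.tail = TRUE)
  }
  haldane <- any(c(a, b, cc, d) == 0L)
  h <- if (haldane) 0.5 else 0
  tibble(
    a = a, b = b, c = cc, d = d,
    odds_ratio = ((a + h) * (d + h)) / ((b + h) * (cc + h)),
    haldane_corrected = haldane,
    p_value = p
  )
}

#' GO-term enrichment against a custom background
#'
#' Flat over-representation analysis (no GO-graph propagation): for every
#' term with at least one set gene, the one-tailed hypergeometric p against
#' the supplied background (e.g. all genes identified in the proteomic
#' dataset), BH-adjusted over the tested terms; significant at adjusted
#' p < 0.05.
#'
#' @param set_genes Foreground gene ids (subset of background).
#' @param background_genes Gene universe.
#' @param ann Annotation tibble with columns `gene`, `term`.
#' @return Tibble `term`, `set_count`, `set_size`, `bg_count`, `bg_size`,
#'   `odds_ratio`, `p_value`, `p_adj`, `significant`, ordered by `p_adj`.
#' @export
go_enrichment <- function(set_genes, background_genes, ann) {
  if (nrow(ann) == 0L) abort("empty annotation table")
  set_genes <- unique(set_genes)
  background_genes <- unique(background_genes)
  assert_subset(set_genes, background_genes, "set_genes", "background_genes")
  ann <- ann |>
    filter(.data$gene %in% background_genes) |>
    distinct(.data$gene, .data$term)
  if (!all(nzchar(ann$term))) abort("empty term identifier in annotation")
  counts <- ann |>
    group_by(.data$term) |>
    summarise(
      set_count = sum(.data$gene %in% set_genes),
      bg_count = n(),
      .groups = "drop"
    ) |>
    filter(.data$set_count >= 1L)
  if (nrow(counts) == 0L) {
    return(tibble(
      term = character(), set_count = integer(), set_size = integer(),
      bg_count = integer(), bg_size = integer(), odds_ratio = numeric(),
      p_value = numeric(), p_adj = numeric(), significant = logical()
    ))
  }
  k <- length(set_genes)
  nn <- length(background_genes)
  counts |>
    mutate(
      set_size = k,
      bg_size = nn,
      p_value = phyper(.data$set_count - 1L, .data$bg_count,
        nn - .data$bg_count, k,
        lower.tail = FALSE
      ),
      odds_ratio = {
        a <- .data$set_count
        b <- k - a
        cc <- .data$bg_count - a
        d <- nn - k - cc
        h <- ifelse(a == 0 | b == 0 | cc == 0 | d == 0, 0.5, 0)
        ((a + h) * (d + h)) / ((b + h) * (cc + h))
      },
      p_adj = bh_adjust(.data$p_value),
      significant = .data$p_adj < 0.05
    ) |>
    arrange(.data$p_adj, .data$p_value) |>
    select(
      "term", "set_count", "set_size", "bg_count", "bg_size",
      "odds_ratio", "p_value", "p_adj", "significant"
    )
}
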