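#' Region lengths of a sequence set
#'
#' @param seqs Sequence tibble from [sequence_set()] / [read_fasta_regions()].
#' @return Tibble `gene`, `utr5_len`, `cds_len`, `utr3_len`,
#'   `transcript_len` (nucleotides; empty regions give 0 and are excluded
#'   from that region's comparisons downstream).
#' @export
region_lengths <- function(seqs) {
  if (nrow(seqs) == 0L) abort("empty sequence set")
  tibble(
    gene = seqs$gene,
    utr5_len = nchar(seqs$utr5),
    cds_len = nchar(seqs$cds),
    utr3_len = nchar(seqs$utr3),
    transcript_len = nchar(seqs$full_transcript)
  )
}

#' Compare a feature between a gene set and a background
#'
#' Median-based comparison of e.g. decay rates or region lengths of the
#' DUG/DDG sets against the detected-proteome background. The background
#' deliberately includes the set (it is the full detected gene universe).
#' The default test is the unpaired rank-sum test; `test = "signedrank"`
#' instead pairs the sorted set values with equally spaced quantiles of the
#' background distribution (deterministic rank matching) and applies the
#' signed-rank test to the differences.
#'
#' @param set_ids,background_ids Gene id vectors (`set_ids` a subset of
#'   `background_ids`).
#' @param values Tibble with columns `gene`, `value`; missing/zero-length
#'   entries should be removed by the caller (NA is dropped here).
#' @param feature Feature label carried into the output.
#' @param test `"ranksum"` or `"signedrank"`.
#' @return One-row tibble: `feature`, `n_set`, `n_background`,
#'   `median_set`, `median_background`, `statistic`, `p_value`, `stars`.
#' @export
compare_feature <- function(set_ids, background_ids, values,
                            feature = "feature",
                            test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  assert_subset(set_ids, background_ids, "set_ids", "background_ids")
  v <- values |> filter(!is.na(.data$value))
  vs <- v$value[v$gene %in% set_ids]
  vb <- v$value[v$gene %in% background_ids]
  if (length(vs) == 0L) abort(paste0("gene set has no values for feature ", feature))
  res <- if (test == "ranksum") {
    ranksum_test(vs, vb)
  } else {
    qb <- quantile(vb, probs = seq_along(sort(vs)) / (length(vs) + 1), names = FALSE)
    signedrank_test(sort(vs) - qb)
  }
  tibble(
    feature = feature,
    n_set = length(vs), n_background = length(vb),
    median_set = median(vs), median_background = median(vb),
    statistic = res$statistic, p_value = res$p_value,
    stars = stars_for_p(res$p_value)
  )
}

#' Feature table comparing a delayed gene set to the proteome background
#'
#' Runs [compare_feature()] for every sequence-length and decay feature
#' available, mirroring the study's feature figure: region lengths (zero
#' lengths excluded), mRNA decay rate and half-life, protein decay rate.
#'
#' @param set_ids,background_ids Gene id vectors.
#' @param lengths Optional [region_lengths()] tibble.
#' @param decay Optional decay tibble (`gene`, `mrna_decay_rate`,
#'   `mrna_half_life`, `protein_decay_rate`).
#' @param set_label Label for the gene set (e.g. `"DUG"`).
#' @param test Passed to [compare_feature()].
#' @return Tibble with one row per feature, plus a `gene_set` column.
#' @export
compare_features <- function(set_ids, background_ids, lengths = NULL,
                             decay = NULL, set_label = "set",
                             test = "ranksum") {
  rows <- list()
  if (!is.null(lengths)) {
    for (feat in c("utr5_len", "cds_len", "utr3_len", "transcript_len")) {
      vals <- tibble(gene = lengths$gene, value = lengths[[feat]]) |>
        filter(.data$value > 0)
      if (sum(vals$gene %in% set_ids) == 0L) next # e.g. all-empty UTRs
      rows[[feat]] <- compare_feature(set_ids, background_ids, vals, feat, test)
    }
  }
  if (!is.null(decay)) {
    for (feat in c("mrna_decay_rate", "mrna_half_life", "protein_decay_rate")) {
      vals <- tibble(gene = decay$gene, value = decay[[feat]])
      if (sum(!is.na(vals$value[vals$gene %in% set_ids])) == 0L) next
      rows[[feat]] <- compare_feature(set_ids, background_ids, vals, feat, test)
    }
  }
  list_rbind(rows) |> mutate(gene_set = set_label, .before = 1L)
}
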