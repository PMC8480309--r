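#' Build a tidy expression set
#'
#' The package's central container is an ordinary tibble with one row per
#' gene x sample measurement and the schema
#' `gene`, `layer`, `time_hai`, `replicate`, `value`, `detected`:
#' log2 abundances (microarray intensity for the mRNA layers, LFQ signal for
#' protein) on a time grid in hours after imbibition (HAI; dry seed = 0),
#' with a logical detection mask instead of imputed values.
#'
#' @param data Data frame with columns `gene`, `time_hai`, `replicate`,
#'   `value` and optionally `detected` (defaults to `!is.na(value)`) and
#'   `layer`.
#' @param layer Layer tag, one of `"total_mRNA"`, `"polysomal_mRNA"`,
#'   `"protein"` (or a derived tag such as `"polysome_occupancy"`). Ignored
#'   if `data` already has a `layer` column.
#' @return A validated tibble with the expression-set schema.
#' @export
#' @examples
#' df <- expand.grid(gene = c("g1", "g2"), time_hai = c(0, 6), replicate = 1:2)
#' df$value <- rnorm(nrow(df))
#' expression_set(df, layer = "total_mRNA")
expression_set <- function(data, layer = NULL) {
  x <- as_tibble(data)
  if (!"layer" %in% names(x)) {
    if (is.null(layer)) abort("supply `layer` or a `layer` column")
    x$layer <- layer
  }
  if (!"detected" %in% names(x)) x$detected <- !is.na(x$value)
  x <- x[, c("gene", "layer", "time_hai", "replicate", "value", "detected")]
  x$gene <- as.character(x$gene)
  x$replicate <- as.integer(x$replicate)
  validate_expression_set(x)
  x
}

#' Validate the expression-set schema
#'
#' Checks the invariants: one measurement per (gene, layer, time, replicate),
#' finite values wherever `detected`, at least two time points.
#'
#' @param x Expression-set tibble.
#' @return `x`, invisibly.
#' @export
validate_expression_set <- function(x) {
  need <- c("gene", "layer", "time_hai", "replicate", "value", "detected")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  key <- paste(x$gene, x$layer, x$time_hai, x$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (gene, layer, time, replicate) record: ", key[duplicated(key)][[1L]]))
  }
  if (length(unique(x$time_hai)) < 2L) abort("an expression set needs at least 2 time points")
  bad <- x$detected & !is.finite(x$value)
  if (any(bad)) abort("non-finite value flagged as detected")
  invisible(x)
}

# time grid (sorted) and replicate ids of a layer tibble
es_times <- function(x) sort(unique(x$time_hai))
es_reps <- function(x) sort(unique(x$replicate))

# genes x samples value / detection matrices, columns ordered time-major
es_matrices <- function(x) {
  times <- es_times(x)
  reps <- es_reps(x)
  genes <- unique(x$gene)
  sample_key <- paste(rep(times, each = length(reps)), rep(reps, length(times)), sep = "_")
  v <- matrix(NA_real_, length(genes), length(sample_key),
    dimnames = list(genes, sample_key)
  )
  d <- matrix(FALSE, length(genes), length(sample_key),
    dimnames = list(genes, sample_key)
  )
  i <- cbind(
    match(x$gene, genes),
    match(paste(x$time_hai, x$replicate, sep = "_"), sample_key)
  )
  v[i] <- x$value
  d[i] <- x$detected
  list(
    values = v, detected = d, genes = genes, times = times, reps = reps,
    time_of_col = rep(times, each = length(reps)),
    rep_of_col = rep(reps, length(times))
  )
}

#' Read a log2 expression matrix from TSV
#'
#' Expects one row per gene (first column the gene id) and one column per
#' sample named `<time>_<replicate>` (e.g. `"6_2"` = 6 HAI, replicate 2).
#' Empty cells are recorded as not detected; they are never imputed.
#'
#' @param path Path to a TSV file.
#' @param layer Layer tag stored with the data.
#' @return Expression-set tibble (see [expression_set()]).
#' @export
read_expression_tsv <- function(path, layer) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < 2L) abort("expression TSV needs a gene column plus at least one sample")
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id in ", path, ": ", genes[duplicated(genes)][[1L]]))
  }
  sample_names <- names(raw)[-1L]
  m <- regmatches(sample_names, regexec("^([0-9]+(?:\\.[0-9]+)?)_([0-9]+)$", sample_names))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("sample header not of the form <time>_<replicate>: ", sample_names[bad][[1L]]))
  }
  times <- vapply(m, function(z) as.numeric(z[[2L]]), 1.0)
  reps <- vapply(m, function(z) as.integer(z[[3L]]), 1L)
  long <- purrr::imap(sample_names, function(col, j) {
    cells <- raw[[col]]
    num <- suppressWarnings(as.numeric(cells))
    nonempty <- !is.na(cells) & cells != ""
    if (any(nonempty & is.na(num))) {
      abort(paste0(
        "non-numeric cell in column ", col, ": '",
        cells[nonempty & is.na(num)][[1L]], "'"
      ))
    }
    tibble(
      gene = genes, time_hai = times[[j]], replicate = reps[[j]],
      value = num, detected = nonempty
    )
  }) |> list_rbind()
  expression_set(long, layer = layer)
}

#' Write an expression set as TSV
#'
#' Inverse of [read_expression_tsv()]: wide matrix, sample columns named
#' `<time>_<replicate>`, undetected cells written empty.
#'
#' @param x Expression-set tibble (a single layer).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression_set(x)
  if (length(unique(x$layer)) != 1L) abort("write one layer per file")
  wide <- x |>
    mutate(
      sample = paste(.data$time_hai, .data$replicate, sep = "_"),
      cell = if_else(.data$detected, format(.data$value, digits = 15, trim = TRUE), "")
    ) |>
    select("gene", "sample", "cell") |>
    pivot_wider(names_from = "sample", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Proteome detection filter
#'
#' A protein counts as identified when it is present in all replicates in at
#' least one physiological stage; everything else is dropped before any
#' proteome-level statistics.
#'
#' @param prot Expression-set tibble with layer `"protein"`.
#' @return Character vector of retained gene ids, in input order.
#' @export
protein_detection_filter <- function(prot) {
  validate_expression_set(prot)
  if (!all(prot$layer == "protein")) {
    abort("detection filter applies to the protein layer only")
  }
  n_rep <- length(es_reps(prot))
  keep <- prot |>
    group_by(.data$gene, .data$time_hai) |>
    summarise(full = sum(.data$detected) == n_rep, .groups = "drop_last") |>
    summarise(keep = any(.data$full), .groups = "drop")
  retained <- keep$gene[keep$keep]
  unique(prot$gene)[unique(prot$gene) %in% retained]
}

#' Subcellular location composition of a gene set
#'
#' Fraction of genes per predicted subcellular location, with genes absent
#' from the annotation pooled into an `"unannotated"` category; fractions
#' sum to one.
#'
#' @param genes Character vector of gene ids (non-empty).
#' @param ann Annotation tibble with columns `gene`, `location`.
#' @return Tibble with columns `location`, `n`, `fraction`.
#' @export
subcellular_ratios <- function(genes, ann) {
  if (length(genes) == 0L) abort("empty gene list")
  loc <- ann$location[match(genes, ann$gene)]
  loc[is.na(loc)] <- "unannotated"
  tibble(location = loc) |>
    count(.data$location, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
}

#' Expression bias of a detected subset
#'
#' Compares, per layer, the per-gene mean log2 expression of a subset (for
#' example the genes with an identified protein) against the full expressed
#' set, with a two-sided rank-sum test. Used to show that proteomics
#' preferentially detects highly expressed genes.
#'
#' @param full_set Expression-set tibble; may contain several layers.
#' @param subset_ids Gene ids of the subset (must all occur in `full_set`).
#' @return Tibble with one row per layer: medians of the per-gene means for
#'   subset and full set, group sizes, and the rank-sum p-value.
#' @export
expression_bias_summary <- function(full_set, subset_ids) {
  validate_expression_set(full_set)
  if (length(subset_ids) == 0L) abort("empty subset")
  assert_subset(subset_ids, unique(full_set$gene), "subset_ids", "full_set genes")
  per_gene <- full_set |>
    filter(.data$detected) |>
    group_by(.data$layer, .data$gene) |>
    summarise(mean_expr = mean(.data$value), .groups = "drop")
  per_gene |>
    group_by(.data$layer) |>
    summarise(
      n_subset = sum(.data$gene %in% subset_ids),
      n_full = n(),
      median_subset = median(.data$mean_expr[.data$gene %in% subset_ids]),
      median_full = median(.data$mean_expr),
      p_value = ranksum_test(
        .data$mean_expr[.data$gene %in% subset_ids], .data$mean_expr
      )$p_value,
      .groups = "drop"
    )
}
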