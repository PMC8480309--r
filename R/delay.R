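#' First significant change of each gene in a set of DE calls
#'
#' The smallest contrast index whose call is not `notsig`; its direction is
#' that call. First event wins when a gene changes more than once; all
#' events are kept in the `events` audit column.
#'
#' @param calls Tibble from [call_de()] for one layer.
#' @return Tibble `gene`, `first_contrast` (`NA` if never significant),
#'   `first_direction`, `events` (list of all significant contrast indices).
#' @export
first_change <- function(calls) {
  calls |>
    as_tibble() |>
    arrange(.data$gene, .data$contrast) |>
    group_by(.data$gene) |>
    summarise(
      first_contrast = if (any(.data$call != "notsig")) {
        min(.data$contrast[.data$call != "notsig"])
      } else {
        NA_integer_
      },
      first_direction = if (any(.data$call != "notsig")) {
        .data$call[.data$contrast == min(.data$contrast[.data$call != "notsig"])]
      } else {
        NA_character_
      },
      events = list(.data$contrast[.data$call != "notsig"]),
      .groups = "drop"
    )
}

#' Classify delayed-response genes (DUG / DDG)
#'
#' Matches each detected gene's first polysomal-level change to its first
#' protein-level change. With both changes in the same direction the gene is
#' `DUG` (up) or `DDG` (down) if the protein change comes 1-3 contrasts
#' later (`shift` in `{+1,+2,+3}`), or `concordant` at shift 0. Changes in
#' opposite directions are `discordant`; a protein change without any
#' polysomal change is `protein_only`; everything else is `unchanged`.
#' Genes not in `detected_genes` (the proteome detection filter) are
#' excluded. `any_later_change = TRUE` relaxes the protein event to the
#' first same-direction change strictly after the polysomal change rather
#' than the gene's overall first protein change.
#'
#' @param poly_calls,prot_calls [call_de()] tibbles for the polysomal and
#'   protein layers (shared gene universe).
#' @param detected_genes Gene ids from [protein_detection_filter()].
#' @param max_shift Largest delay counted as DUG/DDG (3, forced by 4
#'   contrasts).
#' @param any_later_change See above.
#' @return Tibble `gene`, `poly_first_contrast`, `poly_direction`,
#'   `prot_first_contrast`, `prot_direction`, `shift`, `klass`.
#' @export
classify_delay <- function(poly_calls, prot_calls, detected_genes,
                           max_shift = 3L, any_later_change = FALSE) {
  if (length(detected_genes) == 0L) abort("empty detected gene set")
  poly <- first_change(poly_calls) |>
    rename(
      poly_first_contrast = "first_contrast",
      poly_direction = "first_direction", poly_events = "events"
    )
  prot_tbl <- prot_calls |> as_tibble() |> arrange(.data$gene, .data$contrast)
  prot <- first_change(prot_calls) |>
    rename(
      prot_first_contrast = "first_contrast",
      prot_direction = "first_direction", prot_events = "events"
    )
  rec <- tibble(gene = detected_genes) |>
    left_join(poly, by = "gene") |>
    left_join(prot, by = "gene")

  if (any_later_change) {
    # protein event = first significant protein contrast strictly after the
    # polysomal change, matching its direction
    later <- pmap(
      list(rec$gene, rec$poly_first_contrast, rec$poly_direction),
      function(g, pc, pd) {
        if (is.na(pc)) {
          return(list(NA_integer_, NA_character_))
        }
        cand <- prot_tbl |>
          filter(
            .data$gene == g, .data$contrast > pc,
            .data$call == pd
          )
        if (nrow(cand) == 0L) {
          return(list(NA_integer_, NA_character_))
        }
        list(cand$contrast[[1L]], cand$call[[1L]])
      }
    )
    has_poly <- !is.na(rec$poly_first_contrast)
    rec$prot_first_contrast[has_poly] <- map_int(later[has_poly], ~ .x[[1L]])
    rec$prot_direction[has_poly] <- map_chr(later[has_poly], ~ .x[[2L]])
  }

  rec |>
    mutate(
      shift = .data$prot_first_contrast - .data$poly_first_contrast,
      klass = dplyr::case_when(
        is.na(.data$poly_first_contrast) & is.na(.data$prot_first_contrast) ~ "unchanged",
        is.na(.data$poly_first_contrast) ~ "protein_only",
        is.na(.data$prot_first_contrast) ~ "unchanged",
        .data$poly_direction != .data$prot_direction ~ "discordant",
        .data$shift == 0 ~ "concordant",
        .data$shift >= 1 & .data$shift <= max_shift &
          .data$poly_direction == "up" ~ "DUG",
        .data$shift >= 1 & .data$shift <= max_shift &
          .data$poly_direction == "down" ~ "DDG",
        TRUE ~ "unchanged"
      )
    ) |>
    select(
      "gene", "poly_first_contrast", "poly_direction",
      "prot_first_contrast", "prot_direction", "shift", "klass"
    )
}

#' Fraction of the proteome with delayed protein-level changes
#'
#' `(#DUG + #DDG) / proteome_size`. With 425 DUGs and 93 DDGs over 1,469
#' identified proteins this evaluates to 0.353 — roughly a third of a
#' detected seed proteome showing delayed protein-level changes.
#'
#' @param records Delay tibble from [classify_delay()].
#' @param proteome_size Number of identified proteins (> 0, at least the
#'   number of delayed genes).
#' @return Fraction in `[0, 1]`.
#' @export
delayed_fraction <- function(records, proteome_size) {
  if (proteome_size <= 0) abort("proteome_size must be positive")
  n_delayed <- sum(records$klass %in% c("DUG", "DDG"))
  if (proteome_size < n_delayed) abort("proteome_size smaller than the delayed set")
  n_delayed / proteome_size
}

#' Aligned mean expression profiles per delay class and shift
#'
#' For every (class, shift) bucket of delayed genes, the mean polysomal and
#' protein profiles across the time grid, with the protein profile also
#' re-indexed (`aligned_contrast = contrast position - shift`) so that its
#' first change lines up with the polysomal one.
#'
#' @param records [classify_delay()] output.
#' @param poly,prot The expression sets the records were computed on.
#' @return Tibble `klass`, `shift`, `layer`, `time_hai`, `time_index`,
#'   `aligned_index`, `mean_value`, `sem`, `n_genes`. Empty buckets are
#'   omitted.
#' @export
shifted_profiles <- function(records, poly, prot) {
  delayed <- records |> filter(.data$klass %in% c("DUG", "DDG"))
  if (nrow(delayed) == 0L) {
    return(tibble(
      klass = character(), shift = integer(), layer = character(),
      time_hai = numeric(), time_index = integer(), aligned_index = numeric(),
      mean_value = numeric(), sem = numeric(), n_genes = integer()
    ))
  }
  profile_of <- function(x, layer_shift) {
    x |>
      filter(.data$detected) |>
      inner_join(delayed |> select("gene", "klass", "shift"), by = "gene") |>
      group_by(.data$gene, .data$klass, .data$shift, .data$time_hai) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      group_by(.data$klass, .data$shift, .data$time_hai) |>
      summarise(
        mean_value = mean(.data$value),
        sem = sd(.data$value) / sqrt(n()),
        n_genes = n(),
        .groups = "drop"
      ) |>
      group_by(.data$klass, .data$shift) |>
      mutate(
        time_index = match(.data$time_hai, sort(unique(.data$time_hai))),
        aligned_index = .data$time_index - if (layer_shift) .data$shift else 0L
      ) |>
      ungroup()
  }
  bind_rows(
    profile_of(poly, layer_shift = FALSE) |> mutate(layer = poly$layer[[1L]]),
    profile_of(prot, layer_shift = TRUE) |> mutate(layer = prot$layer[[1L]])
  ) |>
    select(
      "klass", "shift", "layer", "time_hai", "time_index",
      "aligned_index", "mean_value", "sem", "n_genes"
    )
}

#' Correlation enhancement under protein lags
#'
#' Computes the per-gene Spearman correlation of each mRNA layer with the
#' protein layer at each requested lag and tests every lag's rho
#' distribution against lag 0 with the rank-sum test. A positive mean
#' enhancement at lag 1 is the signature of delayed protein-level changes.
#'
#' @param total,poly,prot Aligned expression-set tibbles.
#' @param lags Integer lags (must include 0 for the comparisons).
#' @param genes Optional gene subset (e.g. the detected proteome).
#' @return List with `per_gene` (per gene x pair x lag rho) and `summary`
#'   (mean/median rho per pair x lag plus `p_vs_lag0`).
#' @export
delay_correlation_enhancement <- function(total, poly, prot, lags = 0:2,
                                          genes = NULL) {
  if (!0L %in% lags) abort("lags must include 0 as the reference")
  pairs <- list(
    total = list(a = total, label = "total_mRNA->protein"),
    poly = list(a = poly, label = "polysomal_mRNA->protein")
  )
  per_gene <- purrr::map(pairs, function(pr) {
    purrr::map(lags, function(l) {
      x <- per_gene_layer_correlation(pr$a, prot, lag = l)
      if (!is.null(genes)) x <- x |> filter(.data$gene %in% genes)
      x |> mutate(layer_pair = pr$label, lag = l)
    }) |> list_rbind()
  }) |> list_rbind()
  summary <- per_gene |>
    group_by(.data$layer_pair, .data$lag) |>
    summarise(
      n_genes = sum(!is.na(.data$rho)),
      mean_rho = mean(.data$rho, na.rm = TRUE),
      median_rho = median(.data$rho, na.rm = TRUE),
      .groups = "drop"
    )
  p_vs_lag0 <- purrr::map(split(per_gene, per_gene$layer_pair), function(d) {
    ref <- d$rho[d$lag == 0L & !is.na(d$rho)]
    other <- setdiff(unique(d$lag), 0L)
    tibble(
      layer_pair = d$layer_pair[[1L]],
      lag = other,
      p_vs_lag0 = map_dbl(other, function(l) {
        ranksum_test(d$rho[d$lag == l & !is.na(d$rho)], ref)$p_value
      })
    )
  }) |> list_rbind()
  summary <- summary |> left_join(p_vs_lag0, by = c("layer_pair", "lag"))
  list(per_gene = per_gene, summary = summary)
}

#' Score delay classification against planted truth
#'
#' Sensitivity is computed over observable planted delayed genes (those
#' whose lag fits inside the contrast grid); planted delayed genes that are
#' unobservable are excluded from both the sensitivity denominator and the
#' false-call numerator, since no classifier could recover them.
#'
#' @param records [classify_delay()] output.
#' @param truth Truth tibble from [generate_multiomics()].
#' @return One-row tibble with `n_called`, `n_true_observable`,
#'   `sensitivity`, `fdp`, and `modal_shift_match` (fraction of correctly
#'   called delayed genes whose recovered shift equals the planted lag).
#' @export
score_delay <- function(records, truth) {
  called <- records$gene[records$klass %in% c("DUG", "DDG")]
  truth_delayed <- truth |> filter(.data$klass %in% c("delayed_up", "delayed_down"))
  observable <- truth_delayed$gene[truth_delayed$observable]
  unobservable <- truth_delayed$gene[!truth_delayed$observable]
  hits <- intersect(called, observable)
  false_calls <- setdiff(called, truth_delayed$gene)
  scored_calls <- setdiff(called, unobservable)
  shift_of <- setNames(records$shift, records$gene)
  lag_of <- setNames(truth$lag, truth$gene)
  tibble(
    n_called = length(called),
    n_true_observable = length(observable),
    sensitivity = if (length(observable) > 0) length(hits) / length(observable) else NA_real_,
    fdp = if (length(scored_calls) > 0) length(false_calls) / length(scored_calls) else 0,
    modal_shift_match = if (length(hits) > 0) {
      mean(shift_of[hits] == lag_of[hits])
    } else {
      NA_real_
    }
  )
}
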