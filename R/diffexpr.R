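#' Fit consecutive-time-point contrasts per gene
#'
#' Per gene, a one-way group-means model over its detected time points:
#' the pooled within-time residual variance `s2` with residual df
#' `df_residual = (detected samples) - (time points with >= 1 detection)`,
#' and for each consecutive contrast (0->6, 6->26, 26->48, 48->72 HAI) the
#' log2 fold change `mean(t[i+1]) - mean(t[i])`. A contrast with fewer than
#' two detected replicates on either side is flagged `detected_both = FALSE`
#' and is never imputed.
#'
#' @param x Expression-set tibble, one layer.
#' @return Tibble with one row per gene x contrast: `gene`, `layer`,
#'   `contrast` (index), `contrast_label`, `log2fc`, `v` (contrast variance
#'   factor `1/n_i + 1/n_j`), `stderr_unmoderated`, `s2`, `df_residual`,
#'   `detected_both`.
#' @export
fit_contrasts <- function(x) {
  validate_expression_set(x)
  if (length(unique(x$layer)) != 1L) abort("fit one layer at a time")
  m <- es_matrices(x)
  t_n <- length(m$times)
  if (t_n < 2L) abort("need at least two time points")
  n_rep <- length(m$reps)
  det <- m$detected
  val <- m$values
  val[!det] <- 0 # masked; only detected entries enter sums

  # per-time detected counts, means, and within-time sums of squares
  n_gene <- length(m$genes)
  per_time <- function(f) {
    matrix(
      unlist(lapply(seq_len(t_n), f), use.names = FALSE),
      nrow = n_gene, ncol = t_n
    )
  }
  n_t <- per_time(function(i) {
    rowSums(det[, m$time_of_col == m$times[i], drop = FALSE])
  })
  sum_t <- per_time(function(i) {
    rowSums(val[, m$time_of_col == m$times[i], drop = FALSE])
  })
  mean_t <- sum_t / ifelse(n_t > 0, n_t, NA)
  ss_t <- per_time(function(i) {
    cols <- m$time_of_col == m$times[i]
    centered <- (m$values[, cols, drop = FALSE] - mean_t[, i])^2
    centered[!det[, cols, drop = FALSE]] <- 0
    rowSums(centered, na.rm = TRUE)
  })
  df <- rowSums(n_t) - rowSums(n_t > 0)
  s2 <- ifelse(df > 0, rowSums(ss_t) / df, NA_real_)

  contrasts <- seq_len(t_n - 1L)
  per_contrast <- map(contrasts, function(k) {
    ok <- n_t[, k] >= 2L & n_t[, k + 1L] >= 2L
    v <- ifelse(ok, 1 / n_t[, k] + 1 / n_t[, k + 1L], NA_real_)
    tibble(
      gene = m$genes,
      layer = x$layer[[1L]],
      contrast = k,
      contrast_label = paste0(m$times[k], "-", m$times[k + 1L]),
      log2fc = ifelse(ok, mean_t[, k + 1L] - mean_t[, k], NA_real_),
      v = v,
      stderr_unmoderated = sqrt(s2 * v),
      s2 = s2,
      df_residual = df,
      detected_both = ok
    )
  })
  list_rbind(per_contrast) |> arrange(.data$gene, .data$contrast)
}

# solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone, convex)
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) {
      return(Inf)
    }
    if (yi > 1e7) {
      return(1 / sqrt(yi))
    }
    if (yi < 1e-6) {
      return(1 / yi)
    }
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 1.0)
}

# moment-match the scaled-inverse-chi-square prior on residual variances:
# returns list(d0, s0_sq) from per-gene (s2, df)
estimate_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & df > 0 & s2 > 0
  s2 <- s2[keep]
  df <- df[keep]
  if (length(s2) < 10L) abort("need >= 10 genes with positive residual df")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  n <- length(e)
  ev <- mean((e - e_bar)^2 * n / (n - 1) - trigamma(df / 2))
  if (!is.finite(ev) || ev <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_bar)))
  }
  d0 <- 2 * trigamma_inverse(ev)
  if (!is.finite(d0)) {
    return(list(d0 = Inf, s0_sq = exp(e_bar)))
  }
  s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes variance moderation of contrast fits
#'
#' The per-gene residual variances are shrunk towards a common prior
#' estimated by moment-matching the distribution of `log(s2)` (digamma /
#' trigamma inversion): `s2_tilde = (d0*s0^2 + df*s2) / (d0 + df)`. The
#' moderated t-statistic `log2fc / sqrt(s2_tilde * v)` is referred to a t
#' distribution with `d0 + df` degrees of freedom. Hyperparameters are
#' estimated once per layer, pooled across all contrasts. `d0 = 0` recovers
#' the ordinary per-gene t-test; `d0 = Inf` (also the fallback when the
#' moment estimator is non-finite) uses the common variance `s0^2` for every
#' gene. Benjamini-Hochberg adjustment is applied within each contrast.
#'
#' @param fit Tibble from [fit_contrasts()].
#' @param d0 Optional prior df override (`0`, a positive number, or `Inf`);
#'   default estimates it from the data.
#' @param s0_sq Optional prior variance override (only used with `d0`).
#' @return A `moderated_de` tibble: `fit` columns plus `s2_tilde`, `t_mod`,
#'   `df_total`, `p_raw`, `p_adj`, with hyperparameters in attributes
#'   `d0` and `s0_sq`.
#' @export
ebayes_shrink <- function(fit, d0 = NULL, s0_sq = NULL) {
  gene_level <- fit |> distinct(.data$gene, .data$s2, .data$df_residual)
  if (all(gene_level$s2 == 0 | !is.finite(gene_level$s2), na.rm = TRUE) &&
    !all(is.na(gene_level$s2))) {
    if (is.null(d0)) {
      abort(paste0(
        "all residual variances are zero; the variance prior is unidentifiable. ",
        "Add replicate noise or force full shrinkage with d0 = Inf and s0_sq."
      ))
    }
  }
  if (is.null(d0)) {
    prior <- estimate_variance_prior(gene_level$s2, gene_level$df_residual)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else if (is.null(s0_sq)) {
    if (d0 == 0) {
      s0_sq <- NA_real_
    } else {
      abort("supply s0_sq together with a nonzero d0 override")
    }
  }
  df <- fit$df_residual
  s2_tilde <- if (is.infinite(d0)) {
    rep(s0_sq, nrow(fit))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * s0_sq + df * fit$s2) / (d0 + df)
  }
  df_total <- if (is.infinite(d0)) Inf else d0 + df
  testable <- fit$detected_both & is.finite(s2_tilde) & s2_tilde > 0 & df_total > 0
  t_mod <- ifelse(testable, fit$log2fc / sqrt(s2_tilde * fit$v), NA_real_)
  p_raw <- ifelse(testable, 2 * pt(-abs(t_mod), df_total), NA_real_)
  out <- fit |>
    mutate(
      s2_tilde = s2_tilde, t_mod = t_mod, df_total = df_total, p_raw = p_raw
    ) |>
    group_by(.data$contrast) |>
    mutate(p_adj = bh_adjust(.data$p_raw)) |>
    ungroup()
  structure(out, class = c("moderated_de", class(out)), d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: checks
#' the `[0, 1]` range and propagates missing entries in place.
#'
#' @param p Vector of raw p-values (may contain `NA`).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  assert_prob(p, "p")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differential expression
#'
#' Thresholds the germination analysis uses: `up` if `log2fc > lfc_min` and `p* < alpha`,
#' `down` if `log2fc < -lfc_min` and `p* < alpha`, else `notsig`, where `p*`
#' is the BH-adjusted p by default (`use_adjusted = FALSE` gates on the raw
#' p instead). Contrasts that could not be tested (missing detection on one
#' side) are `notsig` with `untested = TRUE`.
#'
#' @param m `moderated_de` tibble from [ebayes_shrink()].
#' @param lfc_min Absolute log2 fold-change gate (> 0).
#' @param alpha Significance gate (> 0).
#' @param use_adjusted Gate on BH-adjusted p (default) or raw p.
#' @return The input with `call` (`"up"`/`"down"`/`"notsig"`) and
#'   `untested` columns added.
#' @export
call_de <- function(m, lfc_min = 1.0, alpha = 0.05, use_adjusted = TRUE) {
  if (lfc_min <= 0 || alpha <= 0) abort("thresholds must be positive")
  p_star <- if (use_adjusted) m$p_adj else m$p_raw
  tested <- !is.na(p_star) & m$detected_both
  call <- rep("notsig", nrow(m))
  call[tested & m$log2fc > lfc_min & p_star < alpha] <- "up"
  call[tested & m$log2fc < -lfc_min & p_star < alpha] <- "down"
  out <- m |> mutate(call = call, untested = !tested)
  class(out) <- class(m)
  out
}

#' @exportS3Method generics::glance
glance.moderated_de <- function(x, ...) {
  tibble(
    layer = x$layer[[1L]],
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq"),
    n_genes = length(unique(x$gene)),
    n_tests = sum(!is.na(x$p_raw))
  )
}

#' @exportS3Method generics::tidy
tidy.moderated_de <- function(x, ...) {
  as_tibble(x) |>
    select(
      "gene", "layer", "contrast", "contrast_label", "log2fc",
      "t_mod", "p_raw", "p_adj", dplyr::any_of(c("call", "untested"))
    )
}
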