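test_that("first_change picks the earliest significant contrast", {
  calls <- toy_calls(list(
    g1 = c("notsig", "up", "up", "notsig"),
    g2 = c("notsig", "notsig", "notsig", "notsig"),
    g3 = c("down", "up", "notsig", "notsig")
  ))
  fc <- first_change(calls)
  expect_equal(fc$first_contrast[fc$gene == "g1"], 2L)
  expect_equal(fc$first_direction[fc$gene == "g1"], "up")
  expect_true(is.na(fc$first_contrast[fc$gene == "g2"]))
  expect_equal(fc$first_contrast[fc$gene == "g3"], 1L)
  expect_equal(fc$first_direction[fc$gene == "g3"], "down")
  expect_equal(fc$events[fc$gene == "g3"][[1]], c(1L, 2L))
})

test_that("classification applies the direction and shift rules", {
  poly <- toy_calls(list(
    dug = c("up", "notsig", "notsig", "notsig"),
    disc = c("notsig", "up", "notsig", "notsig"),
    conc = c("up", "up", "notsig", "notsig"),
    ponly = rep("notsig", 4),
    unch = rep("notsig", 4),
    big = c("up", "notsig", "notsig", "notsig")
  ))
  prot <- toy_calls(list(
    dug = c("notsig", "notsig", "up", "notsig"), # +2 shift
    disc = c("notsig", "notsig", "down", "notsig"), # direction clash
    conc = c("up", "notsig", "notsig", "notsig"), # same contrast
    ponly = c("notsig", "down", "notsig", "notsig"),
    unch = rep("notsig", 4),
    big = rep("notsig", 4)
  ))
  rec <- classify_delay(poly, prot, detected_genes = unique(poly$gene))
  k <- setNames(rec$klass, rec$gene)
  expect_equal(k[["dug"]], "DUG")
  expect_equal(rec$shift[rec$gene == "dug"], 2L)
  expect_equal(k[["disc"]], "discordant")
  expect_equal(k[["conc"]], "concordant")
  expect_equal(k[["ponly"]], "protein_only")
  expect_equal(k[["unch"]], "unchanged")
  expect_equal(k[["big"]], "unchanged") # poly change, protein never

  # every detected gene gets exactly one class
  expect_equal(sort(rec$gene), sort(unique(poly$gene)))
  expect_false(any(is.na(rec$klass)))

  # genes outside the detection filter are excluded
  rec2 <- classify_delay(poly, prot, detected_genes = c("dug", "conc"))
  expect_setequal(rec2$gene, c("dug", "conc"))
  expect_error(classify_delay(poly, prot, character(0)), "empty")
})

test_that("any_later_change relaxes first-change matching to any later event", {
  poly <- toy_calls(list(g = c("notsig", "up", "notsig", "notsig")))
  # protein dips before the poly change, then rises after it
  prot <- toy_calls(list(g = c("down", "notsig", "up", "notsig")))
  strict <- classify_delay(poly, prot, "g")
  expect_equal(strict$klass, "discordant") # first protein event is the dip
  relaxed <- classify_delay(poly, prot, "g", any_later_change = TRUE)
  expect_equal(relaxed$klass, "DUG")
  expect_equal(relaxed$shift, 1L)
})

test_that("delayed fraction reproduces the study arithmetic", {
  records <- tibble::tibble(
    klass = rep(c("DUG", "DDG", "unchanged"), c(425, 93, 10))
  )
  f <- delayed_fraction(records, proteome_size = 1469)
  expect_equal(round(100 * f), 35)
  expect_equal(f, 518 / 1469, tolerance = 1e-12)
  expect_equal(delayed_fraction(records[records$klass == "unchanged", ], 10), 0)
  all_dug <- tibble::tibble(klass = rep("DUG", 7))
  expect_equal(delayed_fraction(all_dug, 7), 1)
  expect_error(delayed_fraction(records, 0), "positive")
  expect_error(delayed_fraction(records, 100), "smaller")
})

test_that("planted delays are recovered with the scenario's fidelity", {
  scores <- purrr::map(1:3, function(s) {
    cfg <- sim_config(seed = 700 + s)
    omx <- generate_multiomics(cfg)
    det <- protein_detection_filter(omx$protein)
    poly <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$polysomal))))
    prot <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$protein))))
    rec <- classify_delay(poly, prot, det)
    score_delay(rec, omx$truth)
  }) |> purrr::list_rbind()
  expect_true(all(scores$sensitivity >= 0.75))
  expect_true(all(scores$fdp <= 0.1))
  # recovered shift equals the planted lag for the bulk of true positives
  expect_true(all(scores$modal_shift_match > 0.9))
})

test_that("recovery improves with effect size", {
  # detection made effectively complete so the grid isolates classifier
  # power; with abundance-dependent dropout a larger down-step also pushes
  # proteins below the detection limit, which masks the monotonicity
  sens <- vapply(c(1.2, 2, 3), function(eff) {
    cfg <- sim_config(n_genes = 600, seed = 11, effect = eff, detect_midpoint = -20)
    omx <- generate_multiomics(cfg)
    det <- protein_detection_filter(omx$protein)
    poly <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$polysomal))))
    prot <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$protein))))
    score_delay(classify_delay(poly, prot, det), omx$truth)$sensitivity
  }, 1.0)
  expect_true(all(diff(sens) >= 0))
})

test_that("alpha relaxation never demotes a delayed gene to unchanged", {
  cfg <- sim_config(n_genes = 400, seed = 19)
  omx <- generate_multiomics(cfg)
  det <- protein_detection_filter(omx$protein)
  mp <- ebayes_shrink(fit_contrasts(omx$polysomal))
  mr <- ebayes_shrink(fit_contrasts(omx$protein))
  strict <- classify_delay(
    tidy(call_de(mp, alpha = 0.01)), tidy(call_de(mr, alpha = 0.01)), det
  )
  loose <- classify_delay(
    tidy(call_de(mp, alpha = 0.1)), tidy(call_de(mr, alpha = 0.1)), det
  )
  was_delayed <- strict$gene[strict$klass %in% c("DUG", "DDG")]
  now <- setNames(loose$klass, loose$gene)[was_delayed]
  expect_false(any(now == "unchanged"))
})

test_that("shifted profiles align the protein step at the polysomal one", {
  times <- c(0, 6, 26, 48, 72)
  # one clean DUG gene: poly steps at contrast 1, protein at contrast 3
  poly_v <- matrix(rep(c(0, 2, 2, 2, 2), each = 3), 1, 15, byrow = TRUE)
  prot_v <- matrix(rep(c(0, 0, 0, 2, 2), each = 3), 1, 15, byrow = TRUE)
  poly <- toy_expression(poly_v, times, 3, "polysomal_mRNA", genes = "g")
  prot <- toy_expression(prot_v, times, 3, "protein", genes = "g")
  rec <- tibble::tibble(
    gene = "g", poly_first_contrast = 1L, poly_direction = "up",
    prot_first_contrast = 3L, prot_direction = "up", shift = 2L, klass = "DUG"
  )
  prof <- shifted_profiles(rec, poly, prot)
  poly_prof <- prof[prof$layer == "polysomal_mRNA", ]
  prot_prof <- prof[prof$layer == "protein", ]
  step_at <- function(p) min(p$time_index[p$mean_value > 1])
  # raw step positions differ by the shift...
  expect_equal(step_at(prot_prof), step_at(poly_prof) + 2L)
  # ...and the aligned index puts them at the same position
  expect_equal(
    min(prot_prof$aligned_index[prot_prof$mean_value > 1]),
    min(poly_prof$aligned_index[poly_prof$mean_value > 1])
  )
  expect_true(all(prof$n_genes == 1))
})

test_that("profile buckets partition the delayed set and match generator means", {
  cfg <- sim_config(seed = 23)
  omx <- generate_multiomics(cfg)
  det <- protein_detection_filter(omx$protein)
  poly <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$polysomal))))
  prot <- tidy(call_de(ebayes_shrink(fit_contrasts(omx$protein))))
  rec <- classify_delay(poly, prot, det)
  prof <- shifted_profiles(rec, omx$polysomal, omx$protein)
  n_delayed <- sum(rec$klass %in% c("DUG", "DDG"))
  bucket_sizes <- prof |>
    dplyr::distinct(klass, shift, layer, .keep_all = TRUE) |>
    dplyr::filter(layer == "polysomal_mRNA")
  expect_equal(sum(bucket_sizes$n_genes), n_delayed)

  # mean polysomal profile of correctly recovered DUG(+1, change at c=1)
  pure <- rec |>
    dplyr::inner_join(omx$truth, by = "gene") |>
    dplyr::filter(klass.x == "DUG", shift == 1, change_contrast == 1, lag == 1)
  if (nrow(pure) >= 10) {
    m <- omx$polysomal |>
      dplyr::filter(gene %in% pure$gene) |>
      dplyr::group_by(time_hai) |>
      dplyr::summarise(v = mean(value))
    # step of +2 between 0 and 6 HAI, within 2 SEM-ish of the planted effect
    expect_equal(m$v[m$time_hai == 6] - m$v[m$time_hai == 0], 2, tolerance = 0.3)
  }
})

test_that("lag-enhancement summary is positive for the delayed class and flat under the null", {
  cfg <- sim_config(seed = 37)
  omx <- generate_multiomics(cfg)
  det <- protein_detection_filter(omx$protein)
  delayed_obs <- omx$truth$gene[omx$truth$klass %in% c("delayed_up", "delayed_down") &
    omx$truth$observable]
  enh <- delay_correlation_enhancement(
    omx$total, omx$polysomal, omx$protein,
    lags = 0:2, genes = intersect(delayed_obs, det)
  )
  s <- enh$summary[enh$summary$layer_pair == "polysomal_mRNA->protein", ]
  expect_gt(s$mean_rho[s$lag == 1] - s$mean_rho[s$lag == 0], 0.03)
  expect_lt(s$p_vs_lag0[s$lag == 1], 0.001)

  # noise-free constructed lag-1 shift: enormous separation
  times <- c(0, 6, 26, 48, 72)
  set.seed(1)
  poly_v <- matrix(rnorm(20 * 15), 20, 15)
  prot_v <- cbind(poly_v[, 13:15], poly_v[, 1:12])
  poly <- toy_expression(poly_v, times, 3, "polysomal_mRNA")
  prot <- toy_expression(prot_v, times, 3, "protein")
  total <- toy_expression(poly_v, times, 3, "total_mRNA")
  enh2 <- delay_correlation_enhancement(total, poly, prot, lags = 0:1)
  s2 <- enh2$summary[enh2$summary$layer_pair == "polysomal_mRNA->protein", ]
  expect_gt(s2$mean_rho[s2$lag == 1], s2$mean_rho[s2$lag == 0])
  expect_lt(s2$p_vs_lag0[s2$lag == 1], 1e-6)

  expect_error(
    delay_correlation_enhancement(omx$total, omx$polysomal, omx$protein, lags = 1:2),
    "include 0"
  )
})
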