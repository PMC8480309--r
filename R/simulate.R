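#' Configuration for the synthetic multi-omics study
#'
#' Encodes the study design the generator emulates: five germination stages
#' (0/dry, 6, 26, 48, 72 HAI), three biological replicates, three layers
#' (total mRNA, polysomal mRNA, protein), log-normal replicate noise, and a
#' planted delayed-response structure in which a gene's protein-level step
#' lags its polysomal step by 1-3 consecutive-time-point contrasts.
#'
#' @param n_genes Number of genes.
#' @param props Named class proportions over
#'   `null`, `concordant`, `delayed_up`, `delayed_down`, `protein_only`;
#'   must sum to 1. Class counts are `round(props * n_genes)`.
#' @param times Time grid in HAI (dry seed encoded as 0).
#' @param n_rep Biological replicates per time point (>= 2).
#' @param noise_sd Named per-layer replicate noise SD, log2 units.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 abundance
#'   distribution (Normal).
#' @param effect Planted step size in log2 units (>= 0; 0 only for nulls).
#' @param lags Candidate protein lags (in contrasts) for delayed classes,
#'   drawn uniformly.
#' @param change_weights Probabilities over the four consecutive contrasts
#'   for the first polysomal change; defaults favour early germination.
#' @param detect_midpoint,detect_slope Logistic proteome-detection model:
#'   a protein measurement is detected with probability
#'   `plogis(detect_slope * (mean_abundance - detect_midpoint))`.
#' @param motif Planted motif (DNA alphabet) for delayed-up 5'UTRs.
#' @param plant_target,plant_background Motif planting rates for delayed-up
#'   vs all other genes.
#' @param gc GC content of background sequence.
#' @param len_meanlog,len_sdlog Named log-normal region-length parameters
#'   (`utr5`, `cds`, `utr3`), lengths in nucleotides.
#' @param cds_ratio_delayed_up Multiplier on median CDS length for
#'   delayed-up genes (< 1 plants the "shorter CDS" signal).
#' @param mrna_decay_meanlog,mrna_decay_sdlog Log-normal mRNA decay rate
#'   (per hour).
#' @param protein_decay_meanlog,protein_decay_sdlog Log-normal protein decay
#'   rate (per day).
#' @param mrna_decay_mult_delayed_down Multiplier on mRNA decay rate for
#'   delayed-down genes (> 1 plants the "less stable mRNA" signal).
#' @param protein_decay_mult_delayed_up Multiplier on protein decay rate for
#'   delayed-up genes (< 1 plants the "more stable protein" signal).
#' @param seed Integer seed; every generator draws from a stream derived
#'   from it, so identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       props = c(
                         null = 0.70, concordant = 0.10,
                         delayed_up = 0.15, delayed_down = 0.05,
                         protein_only = 0
                       ),
                       times = c(0, 6, 26, 48, 72),
                       n_rep = 3,
                       noise_sd = c(total_mRNA = 0.3, polysomal_mRNA = 0.3, protein = 0.3),
                       baseline_mean = 8, baseline_sd = 2,
                       effect = 2,
                       lags = 1:3,
                       change_weights = c(0.4, 0.3, 0.2, 0.1),
                       detect_midpoint = 5, detect_slope = 1,
                       motif = "TCTTCTTC",
                       plant_target = 0.4, plant_background = 0.05,
                       gc = 0.4,
                       len_meanlog = c(utr5 = log(150), cds = log(1200), utr3 = log(200)),
                       len_sdlog = c(utr5 = 0.5, cds = 0.6, utr3 = 0.5),
                       cds_ratio_delayed_up = 0.6,
                       mrna_decay_meanlog = log(0.06), mrna_decay_sdlog = 0.5,
                       protein_decay_meanlog = log(0.1), protein_decay_sdlog = 0.6,
                       mrna_decay_mult_delayed_down = 2,
                       protein_decay_mult_delayed_up = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), props = props, times = times,
    n_rep = as.integer(n_rep), noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    effect = effect, lags = as.integer(lags), change_weights = change_weights,
    detect_midpoint = detect_midpoint, detect_slope = detect_slope,
    motif = motif, plant_target = plant_target,
    plant_background = plant_background, gc = gc,
    len_meanlog = len_meanlog, len_sdlog = len_sdlog,
    cds_ratio_delayed_up = cds_ratio_delayed_up,
    mrna_decay_meanlog = mrna_decay_meanlog,
    mrna_decay_sdlog = mrna_decay_sdlog,
    protein_decay_meanlog = protein_decay_meanlog,
    protein_decay_sdlog = protein_decay_sdlog,
    mrna_decay_mult_delayed_down = mrna_decay_mult_delayed_down,
    protein_decay_mult_delayed_up = protein_decay_mult_delayed_up,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  need <- c("null", "concordant", "delayed_up", "delayed_down", "protein_only")
  if (!setequal(names(cfg$props), need)) {
    abort(paste0("props must be named ", paste(need, collapse = ", ")))
  }
  if (abs(sum(cfg$props) - 1) > 1e-8) abort("class proportions must sum to 1")
  if (any(cfg$noise_sd <= 0)) abort("noise_sd must be positive")
  if (cfg$n_rep < 2L) abort("need at least 2 replicates")
  any_delayed <- sum(cfg$props[c("delayed_up", "delayed_down")]) > 0
  if (length(cfg$times) < 3L && any_delayed) {
    abort("delayed classes need a time grid of at least 3 points")
  }
  if (length(cfg$change_weights) != length(cfg$times) - 1L) {
    abort("change_weights must have one entry per consecutive contrast")
  }
  invisible(cfg)
}

# deterministic class counts: round(props * n), remainder absorbed by `null`
class_counts <- function(cfg) {
  counts <- round(cfg$props * cfg$n_genes)
  counts[["null"]] <- counts[["null"]] + (cfg$n_genes - sum(counts))
  if (any(counts < 0)) abort("rounded class counts became negative; adjust props")
  counts
}

#' Generate a planted-truth multi-omics time course
#'
#' Gene trajectories are piecewise-constant: baseline plus a single log2
#' step of size `effect` at the gene's first-change contrast on the two mRNA
#' layers, and the same step shifted `lag` contrasts later on the protein
#' layer. Lags that run past the last time point leave the protein flat
#' inside the observation window; such genes keep their planted lag in the
#' truth table but are marked `observable = FALSE`. Protein detection is
#' abundance-dependent (logistic in the gene x time mean), so the detected
#' proteome is biased towards highly expressed genes.
#'
#' @param cfg A [sim_config()].
#' @return List with expression-set tibbles `total`, `polysomal`, `protein`
#'   and a `truth` tibble (`gene`, `klass`, `direction`, `change_contrast`,
#'   `lag`, `effect`, `observable`).
#' @export
generate_multiomics <- function(cfg) {
  validate_sim_config(cfg)
  counts <- class_counts(cfg)
  n <- cfg$n_genes
  t_n <- length(cfg$times)
  n_contrast <- t_n - 1L
  withr::with_seed(cfg$seed, {
    klass <- rep(names(counts), counts)
    gene <- sprintf("G%05d", seq_len(n))
    direction <- integer(n)
    direction[klass == "delayed_up"] <- 1L
    direction[klass == "delayed_down"] <- -1L
    free_dir <- klass %in% c("concordant", "protein_only")
    direction[free_dir] <- sample(c(-1L, 1L), sum(free_dir), replace = TRUE)
    change_contrast <- rep(NA_integer_, n)
    changed <- klass != "null"
    change_contrast[changed] <- sample(seq_len(n_contrast), sum(changed),
      replace = TRUE, prob = cfg$change_weights
    )
    lag <- integer(n)
    delayed <- klass %in% c("delayed_up", "delayed_down")
    lag[delayed] <- sample(cfg$lags, sum(delayed), replace = TRUE)
    effect <- ifelse(klass == "null", 0, cfg$effect)
    observable <- !delayed | (change_contrast + lag <= n_contrast)

    baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    t_idx <- matrix(seq_len(t_n), n, t_n, byrow = TRUE)
    # step on mRNA layers at the polysomal change contrast
    rna_step <- klass %in% c("concordant", "delayed_up", "delayed_down")
    rna_c <- ifelse(rna_step, change_contrast, Inf)
    mean_rna <- baseline + direction * effect * (t_idx > rna_c)
    # protein step shifted by the lag (protein_only steps on its own)
    prot_c <- rep(Inf, n)
    prot_c[klass == "concordant"] <- change_contrast[klass == "concordant"]
    prot_c[delayed & observable] <- change_contrast[delayed & observable] +
      lag[delayed & observable]
    prot_c[klass == "protein_only"] <- change_contrast[klass == "protein_only"]
    mean_prot <- baseline + direction * effect * (t_idx > prot_c)

    layer_values <- function(means, sd) {
      v <- means[, rep(seq_len(t_n), each = cfg$n_rep)]
      v + rnorm(length(v), 0, sd)
    }
    v_total <- layer_values(mean_rna, cfg$noise_sd[["total_mRNA"]])
    v_poly <- layer_values(mean_rna, cfg$noise_sd[["polysomal_mRNA"]])
    v_prot <- layer_values(mean_prot, cfg$noise_sd[["protein"]])
    p_detect <- plogis(cfg$detect_slope *
      (mean_prot[, rep(seq_len(t_n), each = cfg$n_rep)] - cfg$detect_midpoint))
    d_prot <- matrix(
      runif(length(p_detect)) < p_detect,
      nrow(p_detect), ncol(p_detect)
    )

    to_long <- function(values, detected, layer) {
      times_col <- rep(cfg$times, each = cfg$n_rep)
      reps_col <- rep(seq_len(cfg$n_rep), t_n)
      tibble(
        gene = rep(gene, times = ncol(values)),
        layer = layer,
        time_hai = rep(times_col, each = n),
        replicate = rep(reps_col, each = n),
        value = ifelse(as.vector(detected), as.vector(values), NA_real_),
        detected = as.vector(detected)
      )
    }
    all_true <- matrix(TRUE, n, t_n * cfg$n_rep)
    list(
      total = to_long(v_total, all_true, "total_mRNA"),
      polysomal = to_long(v_poly, all_true, "polysomal_mRNA"),
      protein = to_long(v_prot, d_prot, "protein"),
      truth = tibble(
        gene = gene, klass = klass, direction = direction,
        change_contrast = change_contrast, lag = lag,
        effect = effect, observable = observable
      )
    )
  })
}

#' Generate synthetic gene region sequences with a planted motif
#'
#' Background nucleotides are i.i.d. at the configured GC content; region
#' lengths are class-conditional log-normals (delayed-up genes draw a
#' shorter CDS), CDS lengths are multiples of three, and the motif is
#' inserted at a uniform 5'UTR position at rate `plant_target` for
#' delayed-up genes and `plant_background` otherwise.
#'
#' @param truth Truth tibble from [generate_multiomics()].
#' @param cfg The same [sim_config()].
#' @return Sequence tibble (see [sequence_set()]) with an extra
#'   `motif_planted` logical column.
#' @export
generate_sequences <- function(truth, cfg) {
  validate_sim_config(cfg)
  if (nrow(truth) == 0L) abort("truth labels are empty")
  w <- nchar(cfg$motif)
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(truth)
    len_utr5 <- pmax(w + 2L, round(rlnorm(n, cfg$len_meanlog[["utr5"]], cfg$len_sdlog[["utr5"]])))
    cds_meanlog <- cfg$len_meanlog[["cds"]] +
      ifelse(truth$klass == "delayed_up", log(cfg$cds_ratio_delayed_up), 0)
    len_cds <- 3L * pmax(10L, round(rlnorm(n, cds_meanlog, cfg$len_sdlog[["cds"]]) / 3))
    len_utr3 <- pmax(10L, round(rlnorm(n, cfg$len_meanlog[["utr3"]], cfg$len_sdlog[["utr3"]])))
    if (w > min(len_utr5)) abort("motif longer than the shortest 5'UTR")

    random_chunks <- function(lens) {
      bases <- sample(c("A", "C", "G", "T"), sum(lens),
        replace = TRUE,
        prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
      )
      grp <- rep(seq_along(lens), lens)
      out <- vapply(split(bases, grp), paste0, character(1), collapse = "")
      unname(out[order(as.integer(names(out)))])
    }
    utr5 <- random_chunks(len_utr5)
    cds <- random_chunks(len_cds)
    utr3 <- random_chunks(len_utr3)

    rate <- ifelse(truth$klass == "delayed_up", cfg$plant_target, cfg$plant_background)
    planted <- runif(n) < rate
    pos <- 1L + floor(runif(n) * (len_utr5 - w + 1L))
    utr5[planted] <- paste0(
      substr(utr5[planted], 1L, pos[planted] - 1L),
      cfg$motif,
      substr(utr5[planted], pos[planted] + w, len_utr5[planted])
    )
    out <- sequence_set(tibble(
      gene = truth$gene, utr5 = utr5, cds = cds, utr3 = utr3
    ))
    out$motif_planted <- planted
    out
  })
}

#' Generate class-conditional decay-rate tables
#'
#' mRNA decay rates (per hour) and protein decay rates (per day) are drawn
#' from log-normals; delayed-down genes get their mRNA decay multiplied by
#' `mrna_decay_mult_delayed_down` (less stable mRNA) and delayed-up genes
#' their protein decay by `protein_decay_mult_delayed_up` (more stable
#' protein). Half-life is `ln 2 / rate`.
#'
#' @param truth Truth tibble from [generate_multiomics()].
#' @param cfg The same [sim_config()].
#' @return Tibble `gene`, `mrna_decay_rate`, `mrna_half_life`,
#'   `protein_decay_rate`.
#' @export
generate_decay_tables <- function(truth, cfg) {
  validate_sim_config(cfg)
  if (nrow(truth) == 0L) abort("truth labels are empty")
  if (cfg$mrna_decay_mult_delayed_down <= 0 || cfg$protein_decay_mult_delayed_up <= 0) {
    abort("decay-rate multipliers must be positive")
  }
  withr::with_seed(cfg$seed + 2L, {
    n <- nrow(truth)
    mrna_meanlog <- cfg$mrna_decay_meanlog +
      ifelse(truth$klass == "delayed_down", log(cfg$mrna_decay_mult_delayed_down), 0)
    prot_meanlog <- cfg$protein_decay_meanlog +
      ifelse(truth$klass == "delayed_up", log(cfg$protein_decay_mult_delayed_up), 0)
    mrna_rate <- rlnorm(n, mrna_meanlog, cfg$mrna_decay_sdlog)
    prot_rate <- rlnorm(n, prot_meanlog, cfg$protein_decay_sdlog)
    tibble(
      gene = truth$gene,
      mrna_decay_rate = mrna_rate,
      mrna_half_life = log(2) / mrna_rate,
      protein_decay_rate = prot_rate
    )
  })
}

#' Write a complete synthetic study to disk as plain-text fixtures
#'
#' Emits the three expression TSVs, region FASTA files, decay and truth
#' tables, and a YAML serialisation of the config, all in the dialects the
#' readers in this package consume.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  omx <- generate_multiomics(cfg)
  seqs <- generate_sequences(omx$truth, cfg)
  decay <- generate_decay_tables(omx$truth, cfg)
  paths <- list(
    total = file.path(dir, "total_mRNA.tsv"),
    polysomal = file.path(dir, "polysomal_mRNA.tsv"),
    protein = file.path(dir, "protein.tsv"),
    utr5 = file.path(dir, "utr5.fasta"),
    cds = file.path(dir, "cds.fasta"),
    utr3 = file.path(dir, "utr3.fasta"),
    decay = file.path(dir, "decay.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "sim_config.yaml")
  )
  write_expression_tsv(omx$total, paths$total)
  write_expression_tsv(omx$polysomal, paths$polysomal)
  write_expression_tsv(omx$protein, paths$protein)
  write_region_fasta <- function(seqvec, genes, path) {
    keep <- nzchar(seqvec)
    ss <- Biostrings::DNAStringSet(seqvec[keep])
    names(ss) <- genes[keep]
    Biostrings::writeXStringSet(ss, path)
  }
  write_region_fasta(seqs$utr5, seqs$gene, paths$utr5)
  write_region_fasta(seqs$cds, seqs$gene, paths$cds)
  write_region_fasta(seqs$utr3, seqs$gene, paths$utr3)
  readr::write_tsv(decay, paths$decay, progress = FALSE)
  readr::write_tsv(omx$truth, paths$truth, progress = FALSE)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(paths)
}
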