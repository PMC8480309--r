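BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x w column-probability matrix (rows A, C, G, T; each column
#'   sums to 1).
#' @param id Motif identifier.
#' @param background Length-4 0-order background frequencies (sums to 1).
#' @param pseudocount Probability mass folded into every cell to avoid
#'   log(0): `p <- (p + pc) / (1 + 4 pc)`.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 1e-6) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) abort("PWM needs 4 rows (A, C, G, T)")
  rownames(mat) <- BASES
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    abort(sprintf("PWM column %d does not sum to 1", which(abs(colSums(mat) - 1) > 1e-6)[[1L]]))
  }
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  # fold the pseudocount only when a cell could underflow the log-odds;
  # leaves already-regularised matrices untouched so write/read round-trips
  if (any(mat < pseudocount)) {
    mat <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  }
  structure(
    list(
      id = id, width = ncol(mat), mat = mat,
      background = setNames(background, BASES), pseudocount = pseudocount
    ),
    class = "pwm"
  )
}

#' Near-deterministic PWM from a consensus string
#'
#' Each column puts probability `conf` on the consensus base and the rest
#' uniformly on the other three; handy for scanning for a literal motif such
#' as TCTTCTTC.
#'
#' @param consensus Consensus string over `{A,C,G,T,U}` (U mapped to T).
#' @param conf Probability on the consensus base.
#' @inheritParams pwm
#' @return A `pwm` object.
#' @export
consensus_pwm <- function(consensus, conf = 0.997, background = rep(0.25, 4)) {
  consensus <- gsub("U", "T", toupper(consensus), fixed = TRUE)
  letters <- strsplit(consensus, "")[[1L]]
  if (!all(letters %in% BASES)) abort("consensus must be over {A,C,G,T,U}")
  m <- matrix((1 - conf) / 3, 4, length(letters), dimnames = list(BASES, NULL))
  m[cbind(match(letters, BASES), seq_along(letters))] <- conf
  pwm(m, id = consensus, background = background)
}

#' Read motifs from MEME minimal text format
#'
#' @param path Path to a MEME minimal motif file.
#' @param background Optional length-4 override of the file's background
#'   letter frequencies.
#' @param pseudocount Passed to [pwm()].
#' @return List of `pwm` objects.
#' @export
read_meme <- function(path, background = NULL, pseudocount = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort("empty MEME file")
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L) {
    toks <- strsplit(trimws(lines[bg_at[[1L]] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(toks[c(FALSE, TRUE)])
    names(bg) <- toks[c(TRUE, FALSE)]
    bg <- bg[BASES]
  }
  if (!is.null(background)) bg <- background
  motif_at <- grep("^MOTIF\\s", lines)
  if (length(motif_at) == 0L) abort("no MOTIF record in MEME file")
  purrr::map(motif_at, function(i) {
    id <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]][[2L]]
    hdr <- grep("^letter-probability matrix", lines[i:length(lines)])[[1L]] + i - 1L
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[[hdr]]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    m <- vapply(
      rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1L]]),
      numeric(4)
    )
    dimnames(m) <- NULL
    pwm(m, id = id, background = unname(bg), pseudocount = pseudocount)
  })
}

#' Write motifs in MEME minimal text format
#'
#' @param pwms List of `pwm` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1L]]$background
  out <- c(
    "MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", BASES, bg), collapse = " "), ""
  )
  for (p in pwms) {
    out <- c(
      out,
      paste("MOTIF", p$id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$width),
      apply(p$mat, 2, function(col) paste(sprintf("%.9f", col), collapse = " ")),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

# per-column integerised log2-odds scores (granularity eps bits) and the
# exact null distribution of the window score under the 0-order background
pwm_score_table <- function(p, eps = 1e-3) {
  s_bits <- log2(p$mat / p$background)
  s_int <- round(s_bits / eps)
  lo <- sum(apply(s_int, 2, min))
  hi <- sum(apply(s_int, 2, max))
  dist <- 1 # point mass at score 0, offset `off`
  off <- 0
  for (j in seq_len(p$width)) {
    col_scores <- s_int[, j]
    new_lo <- off + min(col_scores)
    new_hi <- off + length(dist) - 1L + max(col_scores)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- off + col_scores[[b]] - new_lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * p$background[[b]]
    }
    dist <- new
    off <- new_lo
  }
  # tail[k] = Pr(score_int >= lo + k - 1)
  tail <- rev(cumsum(rev(dist)))
  list(s_int = s_int, lo = lo, hi = hi, tail = tail, off = off, eps = eps)
}

# exact upper-tail p of an integerised window score
pwm_tail_p <- function(tbl, score_int) {
  k <- score_int - tbl$off + 1L
  p <- rep(1.0, length(score_int))
  inside <- k >= 1L & k <= length(tbl$tail)
  p[inside] <- tbl$tail[k[inside]]
  p[k > length(tbl$tail)] <- 0
  pmin(p, 1)
}

#' Scan sequences with a PWM, with exact position p-values
#'
#' Every window of the chosen region is scored by the integerised log2-odds
#' sum (granularity `eps` bits); the position p-value is the exact tail
#' probability of that score under the 0-order background, obtained by
#' convolving the per-column score distributions. Scanning is sense-strand
#' only (the inputs are mRNA-derived regions). P-values are adjusted across
#' all scanned positions of the run (BH by default, mirroring a FIMO
#' q-value; `adjust = "bonferroni"` available) and a window is reported when
#' `p_raw < alpha_raw` and `p_adj < alpha_adj`.
#'
#' @param p A `pwm` object.
#' @param seqs Sequence tibble.
#' @param region `"utr5"`, `"cds"`, `"utr3"` or `"full_transcript"`.
#' @param alpha_raw Raw-p cutoff (default 1e-4).
#' @param alpha_adj Adjusted-p cutoff (default 1e-3).
#' @param eps Score granularity in bits.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return Hits tibble `motif`, `gene`, `region`, `start`, `stop`, `match`,
#'   `score_bits`, `p_raw`, `p_adj`; attribute `n_positions` records how
#'   many windows were scanned.
#' @export
pwm_scan <- function(p, seqs, region = "utr5", alpha_raw = 1e-4,
                     alpha_adj = 1e-3, eps = 1e-3,
                     adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  sq <- seqs[[region]]
  keep <- nchar(sq) >= p$width
  if (!any(keep)) abort(paste0("every ", region, " is shorter than the motif"))
  tbl <- pwm_score_table(p, eps)
  genes <- seqs$gene[keep]
  sq <- sq[keep]
  hits <- purrr::map(seq_along(sq), function(i) {
    chars <- match(strsplit(sq[[i]], "")[[1L]], BASES)
    L <- length(chars)
    n_win <- L - p$width + 1L
    score <- integer(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(p$width)) {
      b <- chars[j:(j + n_win - 1L)]
      ok <- ok & !is.na(b)
      score <- score + ifelse(is.na(b), 0L, tbl$s_int[cbind(b, j)])
    }
    tibble(gene = genes[[i]], start = which(ok), score_int = score[ok])
  }) |> list_rbind()
  n_positions <- nrow(hits)
  hits$p_raw <- pwm_tail_p(tbl, hits$score_int)
  hits$p_adj <- if (adjust == "BH") {
    bh_adjust(hits$p_raw)
  } else {
    pmin(hits$p_raw * n_positions, 1)
  }
  out <- hits |>
    filter(.data$p_raw < alpha_raw, .data$p_adj < alpha_adj) |>
    mutate(
      motif = p$id,
      region = region,
      stop = .data$start + p$width - 1L,
      match = substr(sq[match(.data$gene, genes)], .data$start, .data$stop),
      score_bits = .data$score_int * eps
    ) |>
    select(
      "motif", "gene", "region", "start", "stop", "match",
      "score_bits", "p_raw", "p_adj"
    )
  attr(out, "n_positions") <- n_positions
  out
}

#' Collapse motif hits to gene sets
#'
#' Overlapping or repeated hits within a gene are collapsed: enrichment
#' counts mRNAs, not sites.
#'
#' @param hits Tibble from [pwm_scan()] (one or more motifs/regions bound
#'   together).
#' @return Tibble `motif`, `region`, `n_genes`, `genes` (list-column).
#' @export
motif_gene_sets <- function(hits) {
  hits |>
    distinct(.data$motif, .data$region, .data$gene) |>
    group_by(.data$motif, .data$region) |>
    summarise(
      n_genes = n(), genes = list(sort(.data$gene)), .groups = "drop"
    )
}

#' Exhaustive k-mer enrichment ranking
#'
#' A deterministic stand-in for de novo motif discovery: every k-mer present
#' in the target sequences is scored by a one-tailed Fisher test on
#' gene-level presence (target vs background genes), BH-adjusted across all
#' tested k-mers, and ranked. The expected per-gene presence rate under a
#' first-order Markov (dinucleotide) model of the background sequences is
#' reported for reference. This is not an EM motif model: it cannot merge
#' degenerate variants, and its width is capped for tractability.
#'
#' @param target_seqs,background_seqs Character vectors of sequences (e.g.
#'   a region column of a sequence tibble); both non-empty.
#' @param k_range Widths to test (k-mers longer than a sequence are skipped
#'   for that sequence; a k larger than every sequence is skipped entirely).
#' @param top_n Rows to return (Inf for all).
#' @return Ranked tibble `kmer`, `k`, `n_target`, `n_background`,
#'   `expected_rate`, `odds_ratio`, `p_value`, `p_adj`.
#' @export
kmer_discovery <- function(target_seqs, background_seqs, k_range = 5:8,
                           top_n = 20) {
  if (length(target_seqs) == 0L || length(background_seqs) == 0L) {
    abort("both sequence groups must be non-empty")
  }
  present_kmers <- function(s, k) {
    L <- nchar(s)
    if (L < k) {
      return(character(0))
    }
    unique(substring(s, 1:(L - k + 1L), k:L))
  }
  n_t <- length(target_seqs)
  n_b <- length(background_seqs)
  # dinucleotide Markov model of the background for expected presence rates
  bg_concat <- background_seqs[nchar(background_seqs) >= 2L]
  firsts <- substr(bg_concat, 1L, 1L)
  p1 <- table(factor(firsts, levels = BASES))
  p1 <- (as.numeric(p1) + 1) / sum(as.numeric(p1) + 1)
  names(p1) <- BASES
  dinucs <- unlist(lapply(bg_concat, function(s) {
    substring(s, 1:(nchar(s) - 1L), 2:nchar(s))
  }), use.names = FALSE)
  trans <- matrix(1, 4, 4, dimnames = list(BASES, BASES)) # +1 smoothing
  tab <- table(substr(dinucs, 1, 1), substr(dinucs, 2, 2))
  trans[rownames(tab), colnames(tab)] <- trans[rownames(tab), colnames(tab)] + tab
  trans <- trans / rowSums(trans)
  mean_len <- mean(nchar(background_seqs))

  res <- purrr::map(k_range, function(k) {
    if (k > max(nchar(target_seqs))) {
      return(NULL)
    }
    t_counts <- table(unlist(lapply(target_seqs, present_kmers, k = k), use.names = FALSE))
    b_counts <- table(unlist(lapply(background_seqs, present_kmers, k = k), use.names = FALSE))
    kmers <- names(t_counts)
    a <- as.integer(t_counts)
    cb <- as.integer(b_counts[kmers])
    cb[is.na(cb)] <- 0L
    # one-tailed hypergeometric: targets drawn from the pooled gene universe
    pv <- phyper(a - 1L, a + cb, n_t + n_b - a - cb, n_t, lower.tail = FALSE)
    orr <- (a * (n_b - cb)) / pmax(1e-12, (n_t - a) * cb)
    markov_p <- vapply(kmers, function(km) {
      ch <- strsplit(km, "")[[1L]]
      pr <- p1[[ch[[1L]]]]
      for (i in seq_len(k - 1L)) pr <- pr * trans[ch[[i]], ch[[i + 1L]]]
      pr
    }, 1.0)
    tibble(
      kmer = kmers, k = k, n_target = a, n_background = cb,
      expected_rate = 1 - (1 - markov_p)^pmax(1, mean_len - k + 1),
      odds_ratio = orr, p_value = pv
    )
  }) |> list_rbind()
  if (nrow(res) == 0L) abort("k_range exceeds every target sequence length")
  res$p_adj <- bh_adjust(res$p_value)
  res <- res |>
    arrange(.data$p_adj, .data$p_value, dplyr::desc(.data$k), .data$kmer)
  head(res, top_n)
}
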