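test_that("MEME motif files round-trip and validate", {
  dir <- withr::local_tempdir()
  p1 <- consensus_pwm("TCTTCTTC")
  expect_equal(p1$width, 8L)
  path <- file.path(dir, "motifs.meme")
  write_meme(list(p1, consensus_pwm("GAAGA")), path)
  back <- read_meme(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$id, "TCTTCTTC")
  expect_equal(back[[1]]$mat, p1$mat, tolerance = 1e-6)
  expect_equal(back[[2]]$width, 5L)

  empty <- file.path(dir, "empty.meme")
  file.create(empty)
  expect_error(read_meme(empty), "empty")

  bad <- matrix(0.3, 4, 5)
  expect_error(pwm(bad), "sum to 1")
})

test_that("pwm scan p-values equal exhaustive enumeration over all words", {
  set.seed(701)
  for (w in c(5, 8)) {
    # a motif with graded columns so scores are spread out
    m <- matrix(rgamma(4 * w, 1), 4, w)
    m <- sweep(m, 2, colSums(m), "/")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    p <- pwm(m, background = bg)
    tbl <- translag:::pwm_score_table(p, eps = 1e-3)
    oracle <- pwm_enum_oracle(p, eps = 1e-3)
    probe <- as.integer(quantile(tbl$lo:tbl$hi, c(0, 0.25, 0.5, 0.9, 1)))
    expect_equal(translag:::pwm_tail_p(tbl, probe), oracle(probe), tolerance = 1e-9)
    # total probability mass on the lattice is 1
    expect_equal(translag:::pwm_tail_p(tbl, tbl$lo), 1, tolerance = 1e-9)
    # monotone nonincreasing in the score
    grid <- translag:::pwm_tail_p(tbl, tbl$lo:tbl$hi)
    expect_true(all(diff(grid) <= 1e-12))
  }
})

test_that("a near-deterministic 8-mer scan keeps only true matches", {
  p <- consensus_pwm("TCTTCTTC", conf = 0.997)
  seqs <- sequence_set(tibble::tibble(
    gene = c("hit", "miss"),
    utr5 = c(
      paste0("AAAAGG", "TCTTCTTC", "GGAAAA"),
      paste0(strrep("AG", 10))
    ),
    cds = c("ATGTAA", "ATGTAA"),
    utr3 = c("", "")
  ))
  hits <- pwm_scan(p, seqs, region = "utr5")
  expect_equal(hits$gene, "hit")
  expect_equal(hits$start, 7L)
  expect_equal(hits$match, "TCTTCTTC")
  # a perfect match under uniform background: p close to 4^-8
  expect_lt(hits$p_raw, 1e-4)
  expect_gt(hits$p_raw, 0.5 * 4^-8)
  expect_error(pwm_scan(p, seqs, region = "cds"), "shorter")
})

test_that("motif gene sets deduplicate hits per gene", {
  hits <- tibble::tibble(
    motif = "m", region = "utr5",
    gene = c("a", "a", "a", "b", "c", "d", "e", "f"),
    start = 1:8
  )
  gs <- motif_gene_sets(hits)
  expect_equal(gs$n_genes, 6L)
  expect_equal(gs$genes[[1]], letters[1:6])
})

test_that("fisher enrichment equals hypergeometric enumeration on all small tables", {
  # hand-computed table: a=3, b=1, c=1, d=3 -> tail p = 17/70
  r <- fisher_enrichment(
    sprintf("s%d", 1:4), sprintf("s%d", 1:8),
    c(sprintf("s%d", 1:3), "s5")
  )
  expect_equal(r$a, 3L)
  expect_equal(r$p_value, 17 / 70, tolerance = 1e-12)

  # a = 0: p = 1 for enrichment
  r0 <- fisher_enrichment("s1", sprintf("s%d", 1:10), sprintf("s%d", 2:4))
  expect_equal(r0$p_value, 1)
  expect_true(r0$haldane_corrected)

  # exhaustive agreement for every margin combination up to N = 14 here
  # (the acceptance suite pushes this to 30)
  for (N in c(6, 10, 14)) {
    bg <- sprintf("g%d", 1:N)
    for (m in 1:(N - 1)) {
      for (k in 1:(N - 1)) {
        ann <- bg[1:m]
        amax <- min(m, k)
        for (a in max(0, k - (N - m)):amax) {
          set <- c(ann[seq_len(a)], setdiff(bg, ann)[seq_len(k - a)])
          got <- fisher_enrichment(set, bg, ann)$p_value
          expect_equal(got, hyper_tail_oracle(a, m, N - m, k), tolerance = 1e-12)
        }
      }
    }
  }

  expect_error(fisher_enrichment("x", sprintf("g%d", 1:5), "g1"), "contained")

  # cross-check against base fisher.test on a random table
  ft <- fisher.test(matrix(c(7, 3, 5, 15), 2, byrow = TRUE), alternative = "greater")
  bg30 <- sprintf("g%d", 1:30)
  got <- fisher_enrichment(
    bg30[1:10], bg30,
    c(bg30[1:7], bg30[11:15]) # 7 annotated in set, 5 outside
  )
  expect_equal(got$p_value, ft$p.value, tolerance = 1e-12)
})

test_that("k-mer ranking finds a planted motif and stays quiet under the null", {
  cfg <- sim_config(n_genes = 500, seed = 31, plant_target = 0.4, plant_background = 0.05)
  truth <- generate_multiomics(cfg)$truth
  seqs <- generate_sequences(truth, cfg)
  targets <- seqs$utr5[truth$klass == "delayed_up"]
  background <- seqs$utr5[truth$klass != "delayed_up"]
  tab <- kmer_discovery(targets, background, k_range = 5:8)
  shifts <- unlist(lapply(5:8, function(k) {
    substring("TCTTCTTC", 1:(8 - k + 1), k:(8))
  }))
  expect_true(tab$kmer[1] %in% shifts)
  expect_lt(tab$p_adj[1], 1e-6)
  # deterministic: same input, same ranking
  expect_identical(tab, kmer_discovery(targets, background, k_range = 5:8))
  # absent k-mers are not reported
  expect_false(any(!vapply(
    tab$kmer, function(km) any(grepl(km, targets, fixed = TRUE)), TRUE
  )))

  # null: target sample from the same pool rarely yields small p_adj
  set.seed(702)
  null_seqs <- seqs$utr5[truth$klass == "null"]
  min_padj <- replicate(10, {
    idx <- sample(length(null_seqs), 50)
    min(kmer_discovery(null_seqs[idx], null_seqs[-idx], k_range = 6)$p_adj)
  })
  expect_gte(mean(min_padj > 0.05), 0.9)

  expect_error(kmer_discovery(character(0), "ACGT"), "non-empty")
  expect_error(kmer_discovery(c("ACG"), c("ACGT"), k_range = 9), "exceeds")
})

test_that("GO enrichment flags a planted term and stays calibrated under permutation", {
  bg <- sprintf("g%d", 1:1000)
  set <- sprintf("g%d", 1:20)
  ann <- tibble::tibble(
    gene = c(set, sprintf("g%d", 21:100), sprintf("g%d", 101:200)),
    term = c(rep("GO:planted", 100), rep("GO:neutral", 100))
  )
  res <- go_enrichment(set, bg, ann)
  planted <- res[res$term == "GO:planted", ]
  expect_lt(planted$p_value, 1e-10)
  expect_true(planted$significant)
  expect_true(all(res$p_adj >= res$p_value))

  # a term with background-identical proportions is not significant
  ann2 <- tibble::tibble(gene = sprintf("g%d", seq(1, 1000, by = 10)), term = "GO:flat")
  # set with the background's 10% annotation rate: 2 of 20
  res2 <- go_enrichment(c("g1", "g11", sprintf("g%d", 2:19)), bg, ann2)
  expect_gt(res2$p_value, 0.2)

  # permuted labels: few significant terms
  set.seed(703)
  ann3 <- tibble::tibble(
    gene = rep(bg, 2),
    term = paste0("GO:", sample(rep(1:20, 100)))
  )
  sig_frac <- replicate(50, {
    rnd <- sample(bg, 50)
    r <- go_enrichment(rnd, bg, ann3)
    mean(r$significant)
  })
  expect_lte(mean(sig_frac), 0.05)
  expect_error(go_enrichment(set, bg, ann[0, ]), "empty")
})
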