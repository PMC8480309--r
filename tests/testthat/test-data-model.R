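test_that("expression TSV reading parses headers, masks empty cells, rejects bad input", {
  tsv <- file.path(withr::local_tempdir(), "expr.tsv")
  writeLines(c(
    "gene\t0_1\t0_2\t6_1\t6_2",
    "AT1G01010\t1.5\t1.6\t\t2.1",
    "AT1G01020\t0.2\t\t0.4\t"
  ), tsv)
  es <- read_expression_tsv(tsv, layer = "protein")
  expect_equal(nrow(es), 8L)
  expect_equal(sum(!es$detected), 3L)
  expect_true(all(is.na(es$value[!es$detected])))
  expect_equal(sort(unique(es$time_hai)), c(0, 6))
  expect_equal(
    es$value[es$gene == "AT1G01010" & es$time_hai == 6 & es$replicate == 2], 2.1
  )

  # all-filled file gives an all-true mask
  tsv2 <- file.path(withr::local_tempdir(), "full.tsv")
  writeLines(c("gene\t0_1\t6_1\t26_1", "g1\t1\t2\t3", "g2\t4\t5\t6"), tsv2)
  expect_true(all(read_expression_tsv(tsv2, "total_mRNA")$detected))

  dup <- file.path(withr::local_tempdir(), "dup.tsv")
  writeLines(c("gene\t0_1\t6_1", "AT1G01010\t1\t2", "AT1G01010\t3\t4"), dup)
  expect_error(read_expression_tsv(dup, "protein"), "AT1G01010")

  badh <- file.path(withr::local_tempdir(), "badh.tsv")
  writeLines(c("gene\t0_1\tsampleX", "g1\t1\t2"), badh)
  expect_error(read_expression_tsv(badh, "protein"), "sampleX")

  badc <- file.path(withr::local_tempdir(), "badc.tsv")
  writeLines(c("gene\t0_1\t6_1", "g1\t1\tabc"), badc)
  expect_error(read_expression_tsv(badc, "protein"), "non-numeric")
})

test_that("write/read round trip reproduces values, mask and metadata exactly", {
  cfg <- sim_config(n_genes = 40, seed = 7)
  prot <- generate_multiomics(cfg)$protein
  path <- file.path(withr::local_tempdir(), "prot.tsv")
  write_expression_tsv(prot, path)
  back <- read_expression_tsv(path, layer = "protein")
  key <- function(x) dplyr::arrange(x, gene, time_hai, replicate)
  expect_equal(key(back)$detected, key(prot)$detected)
  expect_equal(key(back)$value, key(prot)$value, tolerance = 1e-12)
  expect_equal(key(back)$time_hai, key(prot)$time_hai)
  expect_equal(key(back)$replicate, key(prot)$replicate)
})

test_that("fasta region reader keeps first splice form, maps U to T, unions genes", {
  dir <- withr::local_tempdir()
  utr5 <- file.path(dir, "u5.fa")
  cds <- file.path(dir, "cds.fa")
  utr3 <- file.path(dir, "u3.fa")
  writeLines(c(">g1.1", "UCUU", ">g1.2", "AAAA", ">g2", "ACGT"), utr5)
  writeLines(c(">g1", "ATGAAATAA", ">g2.1", "ATGTAA", ">g3", "ATGCCCTAA"), cds)
  writeLines(c(">g1", "GGGG"), utr3)
  ss <- read_fasta_regions(utr5, cds, utr3)
  expect_setequal(ss$gene, c("g1", "g2", "g3"))
  expect_equal(ss$utr5[ss$gene == "g1"], "TCTT") # first form, U->T
  expect_equal(ss$utr3[ss$gene == "g2"], "")
  expect_equal(ss$utr3[ss$gene == "g3"], "")
  expect_equal(
    ss$full_transcript[ss$gene == "g1"],
    paste0("TCTT", "ATGAAATAA", "GGGG")
  )

  empty_cds <- file.path(dir, "bad.fa")
  writeLines(c(">g1", ""), empty_cds)
  expect_error(read_fasta_regions(NULL, empty_cds, NULL), "empty CDS")

  bad <- file.path(dir, "badchar.fa")
  writeLines(c(">g1", "ACXT"), bad)
  expect_error(read_fasta_regions(NULL, bad, NULL), "non-IUPAC")
})

test_that("proteome detection filter keeps genes complete in all replicates at some stage", {
  times <- c(0, 6, 26, 48, 72)
  # 5 genes x 15 samples; NA = not detected
  v <- matrix(1, 5, 15)
  rownames <- c("A", "B", "C", "D", "E")
  v[2, seq(3, 15, by = 3)] <- NA # B: only 2/3 replicates everywhere
  v[3, 1:12] <- NA # C: full only at 72
  v[4, ] <- NA # D: never detected
  v[1, 4:15] <- NA # A: full at t = 0 only
  # E: full at two time points (cols 1:6), absent later
  v[5, 7:15] <- NA
  prot <- toy_expression(v, times, n_rep = 3, layer = "protein", genes = rownames)
  expect_equal(protein_detection_filter(prot), c("A", "C", "E"))

  # minimal satisfying case: detected in 3/3 at 26 HAI only
  v2 <- matrix(NA_real_, 2, 15)
  v2[1, 7:9] <- 5 # 26 HAI block
  v2[2, c(7, 8)] <- 5 # 2/3 only
  prot2 <- toy_expression(v2, times, 3, "protein", genes = c("yes", "no"))
  expect_equal(protein_detection_filter(prot2), "yes")

  expect_error(
    protein_detection_filter(toy_expression(v2, times, 3, "total_mRNA")),
    "protein"
  )
})

test_that("detection filter is monotone: adding detections never drops a gene", {
  cfg <- sim_config(n_genes = 120, seed = 3)
  prot <- generate_multiomics(cfg)$protein
  before <- protein_detection_filter(prot)
  # flip a batch of undetected cells to detected
  idx <- which(!prot$detected)[1:200]
  prot$detected[idx] <- TRUE
  prot$value[idx] <- 5
  after <- protein_detection_filter(prot)
  expect_true(all(before %in% after))
})

test_that("subcellular ratios sum to one and match hand counts", {
  ann <- tibble::tibble(
    gene = sprintf("g%d", 1:14),
    location = rep(c("chloroplast", "cytoplasm", "nucleus", "mitochondrion"), c(5, 4, 3, 2))
  )
  genes <- sprintf("g%d", 1:20) # 6 unannotated
  r <- subcellular_ratios(genes, ann)
  expect_equal(sum(r$fraction), 1, tolerance = 1e-12)
  expect_equal(r$fraction[r$location == "chloroplast"], 0.25)
  expect_equal(r$fraction[r$location == "unannotated"], 0.3)

  r2 <- subcellular_ratios(c("x", "y"), ann)
  expect_equal(r2$location, "unannotated")
  expect_equal(r2$fraction, 1)
  expect_error(subcellular_ratios(character(0), ann), "empty")

  # simple 10-gene case
  ann3 <- tibble::tibble(gene = sprintf("g%d", 1:10), location = rep(c("chloroplast", "cytoplasm"), c(4, 6)))
  r3 <- subcellular_ratios(sprintf("g%d", 1:10), ann3)
  expect_equal(r3$fraction[order(r3$location)], c(0.4, 0.6))
})

test_that("expression bias summary flags abundance-dependent proteome detection", {
  cfg <- sim_config(n_genes = 2000, seed = 5)
  omx <- generate_multiomics(cfg)
  det <- protein_detection_filter(omx$protein)
  bias <- expression_bias_summary(dplyr::bind_rows(omx$total, omx$polysomal), det)
  expect_equal(nrow(bias), 2L)
  expect_true(all(bias$median_subset > bias$median_full))
  expect_true(all(bias$p_value < 0.01))

  # subset = full set: identical distributions
  full <- omx$total
  same <- expression_bias_summary(full, unique(full$gene))
  expect_equal(same$median_subset, same$median_full)
  expect_gt(same$p_value, 0.9)

  # top decile by mean is shifted up by construction
  means <- full |>
    dplyr::group_by(gene) |>
    dplyr::summarise(m = mean(value))
  top <- means$gene[means$m >= quantile(means$m, 0.9)]
  b2 <- expression_bias_summary(full, top)
  expect_gt(b2$median_subset, b2$median_full)

  expect_error(expression_bias_summary(full, character(0)), "empty")
})
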