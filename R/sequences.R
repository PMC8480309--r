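#' Read 5'UTR / CDS / 3'UTR region FASTA files into a sequence table
#'
#' Region sequences are keyed by gene id; records named `<gene>.<n>` are
#' treated as splice forms and only the first encountered form per gene is
#' kept (the representative form convention). `U` is normalised to `T` so RNA
#' motifs and DNA database sequences share one alphabet. Genes missing from a
#' region file get an empty string for that region; the gene universe is the
#' union over the three files.
#'
#' @param utr5_path,cds_path,utr3_path FASTA paths; `utr5_path`/`utr3_path`
#'   may be `NULL` (all-empty region).
#' @return Tibble with columns `gene`, `utr5`, `cds`, `utr3`,
#'   `full_transcript`.
#' @export
read_fasta_regions <- function(utr5_path, cds_path, utr3_path) {
  utr5 <- read_region_fasta(utr5_path)
  cds <- read_region_fasta(cds_path)
  utr3 <- read_region_fasta(utr3_path)
  if (any(!nzchar(cds))) {
    abort(paste0("empty CDS sequence for gene ", names(cds)[!nzchar(cds)][[1L]]))
  }
  genes <- unique(c(names(utr5), names(cds), names(utr3)))
  sequence_set(tibble(
    gene = genes,
    utr5 = unname(utr5[genes]) %|0|% genes,
    cds = unname(cds[genes]) %|0|% genes,
    utr3 = unname(utr3[genes]) %|0|% genes
  ))
}

# named character of sequences, first splice form wins, U -> T
read_region_fasta <- function(path) {
  if (is.null(path)) {
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(seqs))
  gene <- sub("\\.[0-9]+$", "", ids)
  seqs <- seqs[!duplicated(gene)]
  gene <- gene[!duplicated(gene)]
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-IUPAC character in sequence for gene ", gene[bad][[1L]]))
  }
  setNames(seqs, gene)
}

# replace NA lookups by "" (helper for region union)
`%|0|%` <- function(x, genes) {
  x[is.na(x)] <- ""
  x
}

#' Assemble and validate a sequence table
#'
#' @param data Data frame with columns `gene`, `utr5`, `cds`, `utr3`
#'   (character, `{A,C,G,T}` after normalisation; UTRs may be empty).
#' @return Tibble with an added `full_transcript = utr5 + cds + utr3` column.
#' @export
sequence_set <- function(data) {
  x <- as_tibble(data)[, c("gene", "utr5", "cds", "utr3")]
  if (anyDuplicated(x$gene)) abort("duplicate gene id in sequence set")
  for (region in c("utr5", "cds", "utr3")) {
    bad <- grepl("[^ACGTN]", x[[region]])
    if (any(bad)) abort(paste0("non-IUPAC character in ", region, " of ", x$gene[bad][[1L]]))
  }
  x$full_transcript <- paste0(x$utr5, x$cds, x$utr3)
  x
}
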