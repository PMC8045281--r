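#' Read and write 12-column tabular homology hits
#'
#' The standard 12-column tabular dialect of similarity-search output:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. No header line.
#'
#' @param file Path to a tab-separated hits file.
#' @return A tibble with the 12 standard columns.
#' @export
read_hits <- function(file) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = cols,
                          colClasses = c("character", "character",
                                         rep("numeric", 10)))
  tibble::as_tibble(df)
}

#' @rdname read_hits
#' @param hits A hits tibble (12 standard columns).
#' @export
write_hits <- function(hits, file) {
  utils::write.table(hits[, c("qseqid", "sseqid", "pident", "length",
                              "mismatch", "gapopen", "qstart", "qend",
                              "sstart", "send", "evalue", "bitscore")],
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

empty_hits <- function() {
  tibble::tibble(qseqid = character(), sseqid = character(),
                 pident = numeric(), length = numeric(),
                 mismatch = numeric(), gapopen = numeric(),
                 qstart = numeric(), qend = numeric(),
                 sstart = numeric(), send = numeric(),
                 evalue = numeric(), bitscore = numeric())
}

#' Read and write simple gene tables as GFF3
#'
#' Gene models inside the package are plain tibbles with columns
#' `gene_id`, `scaffold`, `start`, `end`, `strand` (1-based inclusive).
#' These helpers round-trip them through GFF3 via rtracklayer.
#'
#' @param genes Tibble of gene models.
#' @param file Path to a GFF3 file.
#' @export
write_genes_gff3 <- function(genes, file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 output")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 input")
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[gr$type == "gene"]
  tibble::tibble(gene_id = as.character(gr$ID),
                 scaffold = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)))
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param d Square numeric matrix with dimnames.
#' @param file Output path.
#' @param strict Truncate/pad labels to the classic 10-character field
#'   (default `FALSE`: full labels, whitespace-separated).
#' @export
write_phylip_dist <- function(d, file, strict = FALSE) {
  labs <- rownames(d)
  if (strict) labs <- formatC(substr(labs, 1, 10), width = 10, flag = "-")
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(labs[i], paste(sprintf("%.6f", d[i, ]), collapse = "  "),
                     sep = "  ")
             }, character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[[`, character(1), 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}

#' Run code with a private, seeded RNG state
#'
#' Every stochastic operation in the package takes an explicit `seed` and
#' evaluates under a local RNG: the caller's `.Random.seed` is untouched and
#' identical seeds give byte-identical results.
#' @noRd
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
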