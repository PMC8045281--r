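#' Assembly: a named set of genome scaffolds
#'
#' The universal sequence container consumed by every stage of the pipeline.
#' An assembly is a named character vector of upper-case nucleotide sequences
#' over the alphabet A/C/G/T/N, with unique, non-empty scaffold ids.
#' Coordinates throughout the package are 1-based and inclusive (GFF3
#' convention).
#'
#' @param scaffolds Named character vector of nucleotide sequences.
#' @return An object of class `assembly` (a validated named character vector).
#' @examples
#' asm <- assembly(c(s1 = "ACGTACGT", s2 = "GGGCCC"))
#' scaffold_lengths(asm)
#' @export
assembly <- function(scaffolds) {
  if (is.list(scaffolds)) scaffolds <- unlist(scaffolds)
  if (!is.character(scaffolds) || length(scaffolds) == 0)
    stop("scaffolds must be a non-empty named character vector")
  ids <- names(scaffolds)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("all scaffolds must have non-empty ids")
  if (anyDuplicated(ids)) stop("scaffold ids must be unique")
  scaffolds <- toupper(scaffolds)
  if (any(!nzchar(scaffolds))) stop("scaffold sequences must be non-empty")
  if (any(grepl("[^ACGTN]", scaffolds)))
    stop("scaffold sequences must contain only A, C, G, T or N")
  structure(scaffolds, class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d scaffold(s), %s bp total\n",
              length(x), format(sum(nchar(unclass(x))), big.mark = ",")))
  invisible(x)
}

#' @rdname assembly
#' @param asm An `assembly`.
#' @export
scaffold_lengths <- function(asm) {
  stats::setNames(nchar(unclass(asm)), names(asm))
}

#' G+C fraction of sequences
#'
#' Computed over unambiguous bases only: N (and any non-ACGT symbol) is
#' excluded from both numerator and denominator.
#'
#' @param x Character vector of sequences (or an `assembly`).
#' @return Numeric vector of G+C fractions; `NaN` where no A/C/G/T base exists.
#' @export
gc_content <- function(x) {
  x <- toupper(unclass(x))
  gc <- nchar(gsub("[^GC]", "", x))
  acgt <- nchar(gsub("[^ACGT]", "", x))
  gc / acgt
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read and write assemblies as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param file Path to a FASTA file.
#' @return `read_assembly()` returns an `assembly`.
#' @export
read_assembly <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  assembly(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' @rdname read_assembly
#' @param asm An `assembly`.
#' @export
write_assembly <- function(asm, file) {
  ss <- Biostrings::DNAStringSet(unclass(asm))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Nucleotide counts of an assembly or sequence set
#'
#' @param x An `assembly` or character vector of sequences.
#' @return Named integer vector with counts of A, C, G and T (N excluded).
#' @export
base_counts <- function(x) {
  ss <- Biostrings::DNAStringSet(unclass(x))
  af <- Biostrings::alphabetFrequency(ss)
  colSums(af[, c("A", "C", "G", "T"), drop = FALSE])
}
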