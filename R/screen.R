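#' Significance filter for contamination-screen hits
#'
#' Keeps hits with E <= `max_evalue` and bit score >= `min_bitscore`
#' (defaults: E <= 1e-20 and bitscore >= 1000).
#'
#' @param hits 12-column hits tibble (see [read_hits()]).
#' @param max_evalue Maximum E-value (inclusive).
#' @param min_bitscore Minimum bit score (inclusive).
#' @return The significant subset.
#' @export
significant_hits <- function(hits, max_evalue = 1e-20, min_bitscore = 1000) {
  hits[hits$evalue <= max_evalue & hits$bitscore >= min_bitscore, ,
       drop = FALSE]
}

#' Fraction of a scaffold covered by hits
#'
#' The union of hit query intervals divided by the scaffold length. Hits
#' should already be significance-filtered.
#'
#' @param scaffold_length Scaffold length in bp.
#' @param hits Hits on this scaffold (query intervals qstart/qend).
#' @return Covered fraction in \[0, 1\].
#' @export
hit_coverage <- function(scaffold_length, hits) {
  if (nrow(hits) == 0) return(0)
  st <- pmin(hits$qstart, hits$qend)
  en <- pmax(hits$qstart, hits$qend)
  union_length(rep("x", nrow(hits)), st, en) / scaffold_length
}

#' Screen an assembly for putative contaminant scaffolds
#'
#' Applies the decontamination rules in order:
#' 1. short: scaffold length < `min_len` (default 1000 bp);
#' 2. hit_coverage: significant hits cover >= `cov` (default 5%) of the
#'    scaffold;
#' 3. gc_outlier: scaffold longer than `gc_len` (default 100 kb) with G+C
#'    <= `gc_low` (45%) or >= `gc_high` (60%); G+C is computed over
#'    unambiguous bases only.
#' A removed scaffold carries the first rule that triggered as its reason.
#'
#' @param asm An [assembly()].
#' @param hits 12-column hits tibble (query ids are scaffold ids); filtered
#'   through [significant_hits()] internally.
#' @param min_len Minimum scaffold length (strictly shorter is removed).
#' @param cov Hit-coverage removal threshold (inclusive).
#' @param gc_len Length above which (strictly) the G+C rule applies.
#' @param gc_low,gc_high Inclusive G+C bounds for the outlier rule.
#' @param max_evalue,min_bitscore Hit significance thresholds.
#' @return List with `assembly` (kept scaffolds) and `report` (tibble:
#'   scaffold, length, gc, covered_fraction, status, reason).
#' @export
screen_assembly <- function(asm, hits, min_len = 1000, cov = 0.05,
                            gc_len = 100000, gc_low = 0.45, gc_high = 0.60,
                            max_evalue = 1e-20, min_bitscore = 1000) {
  stopifnot(inherits(asm, "assembly"))
  if (nrow(hits) > 0) {
    missing <- setdiff(unique(hits$qseqid), names(asm))
    if (length(missing))
      stop(sprintf("hits reference scaffolds absent from the assembly: %s",
                   paste(missing, collapse = ", ")))
  }
  sig <- significant_hits(hits, max_evalue, min_bitscore)
  lens <- scaffold_lengths(asm)
  gc <- gc_content(asm)
  covered <- vapply(names(asm), function(id) {
    hit_coverage(lens[[id]], sig[sig$qseqid == id, , drop = FALSE])
  }, numeric(1))
  reason <- rep(NA_character_, length(asm))
  reason[lens < min_len] <- "short"
  sel <- is.na(reason) & covered >= cov
  reason[sel] <- "hit_coverage"
  sel <- is.na(reason) & lens > gc_len & (gc <= gc_low | gc >= gc_high)
  reason[sel] <- "gc_outlier"
  report <- tibble::tibble(
    scaffold = names(asm), length = unname(lens), gc = unname(gc),
    covered_fraction = unname(covered),
    status = ifelse(is.na(reason), "kept", "removed"),
    reason = reason)
  kept <- names(asm)[is.na(reason)]
  list(assembly = assembly(unclass(asm)[kept]), report = report)
}
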