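#' Kimura 2-parameter distance between an aligned repeat copy and consensus
#'
#' Over alignment columns where both strings carry an unambiguous base
#' (columns with a gap or N in either string are excluded from numerator and
#' denominator), P_ts is the transition fraction and P_tv the transversion
#' fraction, and K = -1/2 ln((1 - 2 P_ts - P_tv) sqrt(1 - 2 P_tv)). When
#' the log argument is non-positive the distance is saturated: K_percent is
#' capped at `max_k` and flagged.
#'
#' @param copy_aln,cons_aln Equal-length aligned strings (gap character
#'   `-`).
#' @param max_k Cap for K_percent on saturation (default 50).
#' @return List with `P_ts`, `P_tv`, `K_percent`, `saturated`,
#'   `n_columns` (comparable columns).
#' @examples
#' kimura_distance("ACGT", "ACGT")$K_percent  # 0
#' @export
kimura_distance <- function(copy_aln, cons_aln, max_k = 50) {
  if (nchar(copy_aln) != nchar(cons_aln))
    stop("aligned strings must have equal length")
  a <- seq_to_codes(toupper(copy_aln))
  b <- seq_to_codes(toupper(cons_aln))
  ok <- a >= 1L & a <= 4L & b >= 1L & b <= 4L
  if (!any(ok)) stop("no comparable (ungapped, unambiguous) columns")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  # transitions: A<->G (codes 1,3), C<->T (codes 2,4): same parity
  ts <- diff & ((a %% 2L) == (b %% 2L))
  p <- sum(ts) / n
  q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * p - q
  arg2 <- 1 - 2 * q
  saturated <- arg1 <= 0 || arg2 <= 0
  k_pct <- if (saturated) max_k
           else min(max_k, 100 * (-0.5 * log(arg1 * sqrt(arg2))))
  list(P_ts = p, P_tv = q, K_percent = k_pct, saturated = saturated,
       n_columns = n)
}

#' Build a Kimura-divergence repeat landscape
#'
#' Each repeat copy contributes its ungapped genomic length to the integer
#' Kimura-percent bin floor(K_percent) of its repeat class (bins \[0,1) ...
#' \[49,50); saturated copies go to the top bin). This is the per-genome
#' repeat landscape binned by divergence from the family consensus, a proxy
#' for insertion age.
#'
#' @param copies Tibble with columns family, repeat_class, copy_aln,
#'   cons_aln (e.g. from [repeat_copies_from_truth()]).
#' @param n_bins Number of 1%-wide bins (default 50).
#' @param max_k Saturation cap passed to [kimura_distance()].
#' @return A `repeat_landscape`: numeric matrix (classes x bins, bp) with
#'   bin labels "0".."49".
#' @export
build_landscape <- function(copies, n_bins = 50, max_k = 50) {
  classes <- sort(unique(as.character(copies$repeat_class)))
  if (length(classes) == 0) classes <- character(0)
  land <- matrix(0, nrow = length(classes), ncol = n_bins,
                 dimnames = list(classes, as.character(0:(n_bins - 1))))
  for (i in seq_len(nrow(copies))) {
    kd <- kimura_distance(copies$copy_aln[i], copies$cons_aln[i],
                          max_k = max_k)
    bin <- if (kd$saturated) n_bins - 1L
           else min(n_bins - 1L, floor(kd$K_percent))
    len <- nchar(gsub("-", "", copies$copy_aln[i], fixed = TRUE))
    land[copies$repeat_class[i], bin + 1L] <-
      land[copies$repeat_class[i], bin + 1L] + len
  }
  structure(land, class = c("repeat_landscape", "matrix", "array"))
}

#' Per-class repeat totals
#'
#' @param copies Tibble of repeat copies (repeat_class, copy_aln).
#' @param genome_length Optional genome length in bp for percentages.
#' @return Tibble with repeat_class, total_bp and (if `genome_length`
#'   given) percent.
#' @export
class_totals <- function(copies, genome_length = NULL) {
  if (nrow(copies) == 0) {
    out <- tibble::tibble(repeat_class = character(), total_bp = numeric())
    if (!is.null(genome_length)) out$percent <- numeric()
    return(out)
  }
  len <- nchar(gsub("-", "", copies$copy_aln, fixed = TRUE))
  agg <- tapply(len, copies$repeat_class, sum)
  out <- tibble::tibble(repeat_class = names(agg),
                        total_bp = as.numeric(agg))
  if (!is.null(genome_length))
    out$percent <- 100 * out$total_bp / genome_length
  out
}

#' Write a repeat landscape as TSV (class x bin matrix)
#' @param land A `repeat_landscape`.
#' @param file Output path.
#' @export
write_landscape <- function(land, file) {
  df <- data.frame(repeat_class = rownames(land),
                   unclass(land), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
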