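#' Count canonical k-mers
#'
#' Every window of k consecutive non-N bases contributes one count to the
#' lexicographically smaller of the window and its reverse complement. k must
#' be odd so that no k-mer equals its own reverse complement (canonical
#' counting is ill-defined for palindromic even-k words).
#'
#' @param x An [assembly()], a character vector of sequences/reads, or a
#'   `Biostrings::DNAStringSet`.
#' @param k Odd integer in \[1, 31\].
#' @return A `kmer_profile`: list with `k`, `kmer` (canonical words) and
#'   `count`.
#' @examples
#' count_kmers(c(r1 = "ACGTACGT"), k = 5)
#' @export
count_kmers <- function(x, k) {
  k <- check_k(k)
  prof <- cpp_kmer_profile(as_seqchar(x), k)
  structure(list(k = k, kmer = as.character(prof$kmer),
                 count = as.integer(prof$count)),
            class = "kmer_profile")
}

check_k <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > 31) stop("k must be an integer in [1, 31]")
  if (k %% 2 == 0) stop("k must be odd")
  k
}

as_seqchar <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  stats::setNames(as.character(unclass(x)), names(x))
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> k=%d, %d distinct canonical k-mers, %s instances\n",
              x$k, length(x$kmer),
              format(sum(as.numeric(x$count)), big.mark = ",")))
  invisible(x)
}

#' k-mer multiplicity histogram
#'
#' `bins[m]` is the number of distinct canonical k-mers whose count is
#' exactly m. Given sequences (rather than a profile), the histogram is
#' computed directly without materialising the word strings.
#'
#' @param x A `kmer_profile` from [count_kmers()], or sequences (then `k`
#'   is required).
#' @param k Odd integer, used when `x` is a sequence set.
#' @return A `kmer_histogram`: list with `k`, `m` (multiplicities, sorted)
#'   and `count` (f_m).
#' @export
kmer_histogram <- function(x, k = NULL) {
  if (inherits(x, "kmer_profile")) {
    if (length(x$count) == 0) {
      h <- list(m = integer(0), count = numeric(0))
    } else {
      tab <- table(x$count)
      h <- list(m = as.integer(names(tab)), count = as.numeric(tab))
    }
    return(structure(list(k = x$k, m = h$m, count = h$count),
                     class = "kmer_histogram"))
  }
  k <- check_k(k)
  h <- cpp_kmer_histogram(as_seqchar(x), k)
  structure(list(k = k, m = as.integer(h$m), count = as.numeric(h$count)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> k=%d, %d occupied multiplicities, %s instances\n",
              x$k, length(x$m),
              format(sum(as.numeric(x$m) * x$count), big.mark = ",")))
  invisible(x)
}

#' Write a k-mer histogram as two-column TSV (m, f_m)
#' @param hist A `kmer_histogram`.
#' @param file Output path.
#' @export
write_histogram <- function(hist, file) {
  utils::write.table(data.frame(m = hist$m, count = hist$count), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Dense f vector over m = 1..max(m), optionally median-smoothed (window 3;
# robust to single-bin noise).
dense_f <- function(hist, smooth = FALSE) {
  if (length(hist$m) == 0) return(numeric(0))
  f <- numeric(max(hist$m))
  f[hist$m] <- hist$count
  if (smooth && length(f) >= 3) f <- stats::runmed(f, 3)
  f
}

# Error cutoff: the first local minimum of f separating the low-multiplicity
# error tail from the main coverage peak. If f is not descending at m = 1
# (no error tail) or no interior minimum exists, the cutoff is 1.
error_cutoff_of <- function(f) {
  n <- length(f)
  if (n < 3 || f[1] <= f[2]) return(1L)
  for (m in 2:(n - 1)) {
    if (f[m] < f[m - 1] && f[m] <= f[m + 1]) return(m)
  }
  1L
}

#' Estimate genome size from multi-k histograms
#'
#' Per k: the error cutoff is the first local minimum of f_m (1 if the
#' distribution is unimodal); the coverage peak is the multiplicity with the
#' largest f_m at or above the cutoff; and size = total observed k-mer
#' instances at or above the cutoff divided by the peak coverage (the error
#' tail below the cutoff is excluded, since error k-mers inflate the total).
#' The final estimate is the arithmetic mean of the per-k sizes.
#'
#' @param histograms A list of `kmer_histogram` objects (one per k), or a
#'   single histogram.
#' @return A `size_estimate`: list with `per_k` (tibble: k, error_cutoff,
#'   peak_coverage, size, boundary_warning) and `mean_size` (bp).
#' @export
estimate_genome_size <- function(histograms) {
  if (inherits(histograms, "kmer_histogram")) histograms <- list(histograms)
  rows <- lapply(histograms, function(h) {
    if (length(h$m) == 0)
      stop(structure(class = c("no_signal", "error", "condition"),
                     list(message = "empty histogram: no k-mer signal",
                          call = NULL)))
    f <- dense_f(h)
    cutoff <- error_cutoff_of(f)
    ms <- cutoff:length(f)
    peak <- ms[which.max(f[ms])]
    size <- sum(ms * f[ms]) / peak
    tibble::tibble(k = h$k, error_cutoff = cutoff, peak_coverage = peak,
                   size = size,
                   boundary_warning = peak == length(f) || peak == cutoff)
  })
  per_k <- do.call(rbind, rows)
  structure(list(per_k = per_k, mean_size = mean(per_k$size)),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("<size_estimate> mean size %.0f bp over %d k value(s)\n",
              x$mean_size, nrow(x$per_k)))
  print(x$per_k)
  invisible(x)
}

#' Assess ploidy from a k-mer histogram
#'
#' Peaks are local maxima of the (median-smoothed, window 3) histogram at or
#' above the error cutoff, keeping peaks of height >= `min_peak_frac` of the
#' tallest. A single peak suggests a haploid genome; two peaks whose
#' coverage ratio is approximately twofold (within `ratio_range`) with the
#' minor peak at least 10% the height of the major suggest a diploid genome
#' (the half-coverage peak carries heterozygous k-mers); anything else is
#' ambiguous.
#'
#' @param hist A `kmer_histogram`.
#' @param min_peak_frac Minimum peak height as a fraction of the tallest
#'   peak (default 0.1).
#' @param ratio_range Acceptable coverage ratio between the two peaks for a
#'   diploid call (default `c(1.8, 2.2)`, "exactly or approximately
#'   twofold").
#' @return List with `peaks` (tibble: coverage, height), `call` (one of
#'   "haploid", "diploid", "ambiguous") and `ratio` (coverage ratio if two
#'   peaks, else NA).
#' @export
assess_ploidy <- function(hist, min_peak_frac = 0.1,
                          ratio_range = c(1.8, 2.2)) {
  if (length(hist$m) == 0) stop("histogram is empty")
  f <- dense_f(hist, smooth = TRUE)
  # degenerate case: median smoothing can erase an isolated spike entirely
  if (max(f) == 0) f <- dense_f(hist)
  cutoff <- error_cutoff_of(f)
  n <- length(f)
  peaks <- integer(0)
  m <- max(cutoff, 2L)
  while (m <= n) {
    if (f[m] > f[m - 1]) {
      # climb a (possibly flat-topped) peak
      top <- m
      while (top < n && f[top + 1] >= f[top]) top <- top + 1L
      if (top == n || f[top + 1] < f[top]) peaks <- c(peaks, top)
      m <- top + 1L
    } else m <- m + 1L
  }
  if (length(peaks) == 0 && n >= 1) peaks <- cutoff + which.max(f[cutoff:n]) - 1L
  heights <- f[peaks]
  keep <- heights >= min_peak_frac * max(heights)
  peaks <- peaks[keep]; heights <- heights[keep]
  pk <- tibble::tibble(coverage = peaks, height = heights)
  ratio <- NA_real_
  call <- "ambiguous"
  if (nrow(pk) == 1) {
    call <- "haploid"
  } else if (nrow(pk) == 2) {
    ratio <- max(pk$coverage) / min(pk$coverage)
    minor_frac <- min(pk$height) / max(pk$height)
    if (ratio >= ratio_range[1] && ratio <= ratio_range[2] &&
        minor_frac >= 0.1)
      call <- "diploid"
  }
  list(peaks = pk, call = call, ratio = ratio)
}

#' Distinct/unique k-mer proportions across k (k-selection diagnostic)
#'
#' For each k: distinct_fraction = distinct canonical k-mers / total k-mer
#' instances; unique_fraction = k-mers seen exactly once / total instances.
#' The suggested k is the smallest whose successive increase in
#' unique_fraction falls below `plateau_tol` (the uniqueness plateau).
#'
#' @param asm An [assembly()] (or read set).
#' @param ks Ascending vector of odd k values.
#' @param plateau_tol Plateau tolerance on the unique-fraction increase
#'   (default 0.01).
#' @return List with `per_k` (tibble: k, distinct_fraction, unique_fraction)
#'   and `suggested_k`.
#' @export
uniqueness_curve <- function(asm, ks, plateau_tol = 0.01) {
  if (length(ks) == 0) stop("ks must be non-empty")
  ks <- sort(vapply(ks, check_k, integer(1)))
  seqs <- as_seqchar(asm)
  rows <- lapply(ks, function(k) {
    h <- kmer_histogram(seqs, k)
    total <- sum(as.numeric(h$m) * h$count)
    distinct <- sum(h$count)
    uniq <- if (length(h$m) && h$m[1] == 1L) h$count[1] else 0
    tibble::tibble(k = k, distinct_fraction = distinct / total,
                   unique_fraction = uniq / total)
  })
  per_k <- do.call(rbind, rows)
  suggested <- per_k$k[length(ks)]
  if (length(ks) >= 2) {
    inc <- diff(per_k$unique_fraction)
    hit <- which(inc < plateau_tol)
    if (length(hit)) suggested <- per_k$k[hit[1] + 1L]
  } else suggested <- per_k$k[1]
  list(per_k = per_k, suggested_k = suggested)
}

#' Assembled fraction of the estimated genome size
#'
#' @param assembly_length Total assembly length in bp.
#' @param size A `size_estimate` from [estimate_genome_size()], or a numeric
#'   genome size in bp.
#' @return Percentage (2 decimals): 100 * assembly_length / mean size.
#' @examples
#' assembled_fraction(813744491, 1120150369)  # 72.65
#' @export
assembled_fraction <- function(assembly_length, size) {
  mean_size <- if (inherits(size, "size_estimate")) size$mean_size
               else as.numeric(size)
  if (!is.finite(mean_size) || mean_size <= 0)
    stop("genome size must be positive")
  if (assembly_length <= 0) stop("assembly length must be positive")
  round(100 * assembly_length / mean_size, 2)
}
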