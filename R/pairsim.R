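#' Parse a whole-genome alignment coordinates table
#'
#' Reads the tab-delimited coordinate dump of a whole-genome aligner with
#' columns S1 E1 S2 E2 LEN1 LEN2 %IDY REF QRY (no header). Reversed query
#' intervals (S2 > E2) are normalised to qry_start <= qry_end with
#' orientation "-".
#'
#' @param file Path to the coords table, or a data.frame with those columns.
#' @param ref_lengths,qry_lengths Optional named vectors of sequence lengths
#'   used to validate coordinates (errors carry the offending line number).
#' @return Tibble of alignment records: ref_id, ref_start, ref_end, qry_id,
#'   qry_start, qry_end, pct_identity, orientation.
#' @export
parse_coords <- function(file, ref_lengths = NULL, qry_lengths = NULL) {
  if (is.character(file)) {
    df <- tryCatch(
      utils::read.table(file, sep = "\t", header = FALSE,
                        col.names = c("S1", "E1", "S2", "E2", "LEN1", "LEN2",
                                      "IDY", "REF", "QRY"),
                        colClasses = c(rep("numeric", 7),
                                       "character", "character")),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e)))
          return(NULL)
        stop(e)
      })
    if (is.null(df)) return(empty_alignment_records())
  } else df <- file
  if (nrow(df) == 0) return(empty_alignment_records())
  rev_q <- df$S2 > df$E2
  rec <- tibble::tibble(
    ref_id = df$REF, ref_start = df$S1, ref_end = df$E1,
    qry_id = df$QRY,
    qry_start = ifelse(rev_q, df$E2, df$S2),
    qry_end = ifelse(rev_q, df$S2, df$E2),
    pct_identity = df$IDY,
    orientation = ifelse(rev_q, "-", "+"))
  bad <- which(rec$ref_start > rec$ref_end)
  if (length(bad))
    stop(sprintf("line %d: reference start > end", bad[1]))
  if (any(rec$pct_identity < 0 | rec$pct_identity > 100))
    stop("percent identity must be in [0, 100]")
  check_bounds <- function(ids, ends, lengths, side) {
    if (is.null(lengths)) return(invisible())
    unknown <- which(!(ids %in% names(lengths)))
    if (length(unknown))
      stop(sprintf("line %d: unknown %s sequence '%s'",
                   unknown[1], side, ids[unknown[1]]))
    over <- which(ends > lengths[ids])
    if (length(over))
      stop(sprintf("line %d: %s coordinate %d exceeds declared length %d",
                   over[1], side, as.integer(ends[over[1]]),
                   as.integer(lengths[ids[over[1]]])))
  }
  check_bounds(rec$ref_id, rec$ref_end, ref_lengths, "reference")
  check_bounds(rec$qry_id, rec$qry_end, qry_lengths, "query")
  rec
}

empty_alignment_records <- function() {
  tibble::tibble(ref_id = character(), ref_start = numeric(),
                 ref_end = numeric(), qry_id = character(),
                 qry_start = numeric(), qry_end = numeric(),
                 pct_identity = numeric(), orientation = character())
}

# Total length of the union of intervals, grouped by sequence id.
union_length <- function(ids, starts, ends) {
  if (length(ids) == 0) return(0)
  total <- 0
  for (id in unique(ids)) {
    sel <- ids == id
    ir <- IRanges::reduce(IRanges::IRanges(as.integer(starts[sel]),
                                           as.integer(ends[sel])))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

#' Q: percent of the query genome covered by alignments
#'
#' Q = 100 * |union of query intervals across all records| /
#' total query genome length. Union semantics make Q invariant to record
#' duplication and ordering.
#'
#' @param records Alignment records from [parse_coords()].
#' @param qry_total_length Total query genome length in bp (> 0).
#' @return Q (percent).
#' @export
query_aligned_percent <- function(records, qry_total_length) {
  if (qry_total_length <= 0) stop("query genome length must be positive")
  100 * union_length(records$qry_id, records$qry_start, records$qry_end) /
    qry_total_length
}

#' Greedy reciprocal one-to-one filtering of alignment records
#'
#' Emulates a delta-filter-style 1-to-1 selection: records are ranked by
#' score = query-side aligned length x percent identity (descending; ties
#' broken by ref_id then ref_start) and kept greedily if they overlap no
#' already-kept record on either the reference or the query coordinates.
#'
#' @param records Alignment records.
#' @return The kept subset, in input order.
#' @export
one_to_one_filter <- function(records) {
  n <- nrow(records)
  if (n == 0) return(records)
  score <- (records$qry_end - records$qry_start + 1) * records$pct_identity
  ord <- order(-score, records$ref_id, records$ref_start)
  kept <- logical(n)
  for (i in ord) {
    clash <- FALSE
    for (j in which(kept)) {
      if (records$ref_id[i] == records$ref_id[j] &&
          records$ref_start[i] <= records$ref_end[j] &&
          records$ref_end[i] >= records$ref_start[j]) { clash <- TRUE; break }
      if (records$qry_id[i] == records$qry_id[j] &&
          records$qry_start[i] <= records$qry_end[j] &&
          records$qry_end[i] >= records$qry_start[j]) { clash <- TRUE; break }
    }
    if (!clash) kept[i] <- TRUE
  }
  records[kept, , drop = FALSE]
}

#' I: mean percent identity of one-to-one alignments
#'
#' Length-weighted by default (weights = query-side aligned length); the
#' unweighted per-alignment mean is available with `weighted = FALSE`.
#'
#' @param records One-to-one filtered alignment records (>= 1 row).
#' @param weighted Length-weight the mean (default TRUE).
#' @return I (percent).
#' @export
mean_identity <- function(records, weighted = TRUE) {
  if (nrow(records) == 0)
    stop(structure(class = c("undefined_identity", "error", "condition"),
                   list(message = "I is undefined: no one-to-one alignments",
                        call = NULL)))
  if (!weighted) return(mean(records$pct_identity))
  w <- records$qry_end - records$qry_start + 1
  sum(w * records$pct_identity) / sum(w)
}

#' Whole-genome pair similarity report (Q and I)
#'
#' @param records Alignment records from [parse_coords()].
#' @param qry_total_length Total query genome length (bp).
#' @param weighted Length-weight I (default TRUE).
#' @return Tibble with Q, I, n_alignments, n_one_to_one.
#' @export
genome_pair_similarity <- function(records, qry_total_length,
                                   weighted = TRUE) {
  one <- one_to_one_filter(records)
  tibble::tibble(
    Q = query_aligned_percent(records, qry_total_length),
    I = if (nrow(one)) mean_identity(one, weighted) else NA_real_,
    n_alignments = nrow(records),
    n_one_to_one = nrow(one))
}
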