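#' Mask gene regions with N
#'
#' Replaces every base inside an annotated gene interval with N, so that
#' downstream pseudogene calls cannot overlap predicted gene models.
#' Overlapping genes are masked once (union semantics).
#'
#' @param asm An [assembly()].
#' @param genes Tibble of gene models (scaffold, start, end).
#' @return The masked assembly.
#' @export
mask_gene_regions <- function(asm, genes) {
  stopifnot(inherits(asm, "assembly"))
  seqs <- unclass(asm)
  if (nrow(genes) == 0) return(asm)
  missing <- setdiff(unique(genes$scaffold), names(seqs))
  if (length(missing))
    stop(sprintf("genes reference unknown scaffolds: %s",
                 paste(missing, collapse = ", ")))
  lens <- nchar(seqs)
  if (any(genes$start < 1 | genes$end > lens[genes$scaffold] |
          genes$start > genes$end))
    stop("gene interval out of scaffold bounds")
  for (scf in unique(genes$scaffold)) {
    sel <- genes$scaffold == scf
    ir <- IRanges::reduce(IRanges::IRanges(genes$start[sel], genes$end[sel]))
    for (i in seq_along(ir)) {
      st <- IRanges::start(ir)[i]; en <- IRanges::end(ir)[i]
      substr(seqs[[scf]], st, en) <- strrep("N", en - st + 1L)
    }
  }
  assembly(seqs)
}

#' Call pseudogenes by merging protein-hit fragments
#'
#' Protein-vs-genome hit fragments with >= `min_identity` percent identity
#' are grouped by scaffold and genomic strand (derived from subject
#' coordinate order: sstart > send means minus strand) and chained by
#' single linkage: after sorting by start, a fragment joins the current
#' chain when the gap to the chain (its start minus the largest end seen so
#' far) is at most `max_gap`; touching or overlapping fragments always
#' merge. Each chain becomes one pseudogene call spanning the hull of its
#' fragments.
#'
#' @param hits 12-column hits tibble (protein query vs masked genome).
#' @param min_identity Minimum percent identity (default 75, inclusive).
#' @param max_gap Maximum inter-fragment gap in bp (default 1000).
#' @return Tibble of calls: scaffold, start, end, strand, n_fragments,
#'   fragments (list of start/end tibbles), proteins (comma-joined source
#'   protein ids).
#' @export
call_pseudogenes <- function(hits, min_identity = 75, max_gap = 1000) {
  hits <- hits[hits$pident >= min_identity, , drop = FALSE]
  if (nrow(hits) == 0)
    return(tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_fragments = integer(), fragments = list(),
                          proteins = character()))
  frag <- tibble::tibble(
    scaffold = hits$sseqid,
    start = as.integer(pmin(hits$sstart, hits$send)),
    end = as.integer(pmax(hits$sstart, hits$send)),
    strand = ifelse(hits$sstart <= hits$send, "+", "-"),
    protein = hits$qseqid)
  frag <- frag[order(frag$scaffold, frag$strand, frag$start, frag$end), ]
  key <- paste(frag$scaffold, frag$strand)
  out <- lapply(split(seq_len(nrow(frag)), key), function(idx) {
    g <- frag[idx, , drop = FALSE]
    hi <- cummax(g$end)
    new_chain <- c(TRUE, g$start[-1] - hi[-nrow(g)] > max_gap)
    chain <- cumsum(new_chain)
    lapply(split(seq_len(nrow(g)), chain), function(ii) {
      gg <- g[ii, , drop = FALSE]
      tibble::tibble(scaffold = gg$scaffold[1], start = min(gg$start),
                     end = max(gg$end), strand = gg$strand[1],
                     n_fragments = nrow(gg),
                     fragments = list(gg[, c("start", "end")]),
                     proteins = paste(sort(unique(gg$protein)),
                                      collapse = ","))
    })
  })
  calls <- do.call(rbind, unlist(out, recursive = FALSE))
  calls <- calls[order(calls$scaffold, calls$start, calls$strand), ]
  rownames(calls) <- NULL
  calls
}

# Ungapped seed-and-extend local alignment of `motif` against `subject`.
# For every exact seed of length seed_len, the full ungapped overlap at that
# offset is scored (match +1, mismatch -mismatch_penalty) and the best
# -scoring local segment (Kadane) containing a seed is reported.
ungapped_motif_hits <- function(subject, motif, seed_len, min_identity,
                                mismatch_penalty = 2) {
  ls <- nchar(subject); lm <- nchar(motif)
  if (ls < seed_len || lm < seed_len) return(NULL)
  sub_codes <- seq_to_codes(subject)
  mot_codes <- seq_to_codes(motif)
  offsets <- integer(0)
  for (i in seq_len(lm - seed_len + 1)) {
    seed <- substr(motif, i, i + seed_len - 1L)
    m <- gregexpr(seed, subject, fixed = TRUE)[[1]]
    if (m[1] != -1) offsets <- c(offsets, as.integer(m) - i)
  }
  offsets <- sort(unique(offsets))
  hits <- NULL
  for (o in offsets) {
    mpos <- seq_len(lm)
    spos <- mpos + o
    ok <- spos >= 1 & spos <= ls
    mpos <- mpos[ok]; spos <- spos[ok]
    is_match <- mot_codes[mpos] == sub_codes[spos] & mot_codes[mpos] <= 4L
    score <- ifelse(is_match, 1, -mismatch_penalty)
    # best-scoring contiguous segment (Kadane with segment tracking)
    best <- c(0, 0L, 0L); cur <- 0; cur_st <- 1L
    for (t in seq_along(score)) {
      if (cur <= 0) { cur <- score[t]; cur_st <- t }
      else cur <- cur + score[t]
      if (cur > best[1]) best <- c(cur, cur_st, t)
    }
    if (best[1] <= 0) next
    seg <- best[2]:best[3]
    # require an exact run of >= seed_len inside the segment
    runs <- rle(is_match[seg])
    if (!any(runs$values & runs$lengths >= seed_len)) next
    ident <- 100 * mean(is_match[seg])
    if (ident < min_identity) next
    hits <- rbind(hits, data.frame(
      sub_start = spos[seg[1]], sub_end = spos[seg[length(seg)]],
      motif_start = mpos[seg[1]], motif_end = mpos[seg[length(seg)]],
      identity = ident, score = best[1]))
  }
  if (is.null(hits)) return(NULL)
  # collapse overlapping hits on the subject, keeping the best score
  hits <- hits[order(-hits$score, hits$sub_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j == i || !keep[j]) next
      if (hits$sub_start[j] <= hits$sub_end[i] &&
          hits$sub_end[j] >= hits$sub_start[i] &&
          hits$score[j] <= hits$score[i] && i < j) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Scan gene upstream regions for DinoSL relicts
#'
#' For each gene, up to `window` bp immediately 5' of the gene start on the
#' coding strand are extracted (reverse-complemented for minus-strand genes,
#' truncated at scaffold edges) and scanned for local, ungapped alignments
#' of the spliced-leader motif that contain an exact match of at least
#' `seed_len` bases and reach at least `min_identity` percent identity over
#' the aligned span (emulating a word-size-9 nucleotide search).
#'
#' @param asm An [assembly()].
#' @param genes Tibble of gene models (gene_id, scaffold, start, end,
#'   strand).
#' @param window Upstream window length (default 500 bp).
#' @param motif Spliced-leader motif (default [DINOSL_MOTIF]).
#' @param seed_len Exact-seed length (default 9).
#' @param min_identity Minimum percent identity over the aligned span
#'   (default 80).
#' @return Tibble of hits: kind ("upstream_of_gene"), gene_id, scaffold,
#'   start, end (scaffold coordinates of the aligned span), strand,
#'   identity, offset (bp between the motif's 3' end and the gene start on
#'   the coding strand).
#' @export
scan_dinoSL_upstream <- function(asm, genes, window = 500,
                                 motif = DINOSL_MOTIF, seed_len = 9,
                                 min_identity = 80) {
  stopifnot(inherits(asm, "assembly"))
  if (nchar(motif) < seed_len) stop("motif shorter than seed length")
  seqs <- unclass(asm)
  lens <- nchar(seqs)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      wst <- max(1L, g$start - window); wen <- g$start - 1L
      if (wen < wst) next
      wseq <- substr(seqs[[g$scaffold]], wst, wen)
    } else {
      wst <- g$end + 1L; wen <- min(lens[[g$scaffold]], g$end + window)
      if (wen < wst) next
      wseq <- revcomp(substr(seqs[[g$scaffold]], wst, wen))
    }
    h <- ungapped_motif_hits(wseq, motif, seed_len, min_identity)
    if (is.null(h) || nrow(h) == 0) next
    for (j in seq_len(nrow(h))) {
      wlen <- nchar(wseq)
      if (g$strand == "+") {
        sst <- wst + h$sub_start[j] - 1L
        sen <- wst + h$sub_end[j] - 1L
        off <- g$start - sen - 1L
      } else {
        # window coordinates run 3'->5' on the scaffold
        sst <- wen - h$sub_end[j] + 1L
        sen <- wen - h$sub_start[j] + 1L
        off <- sst - g$end - 1L
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "upstream_of_gene", gene_id = g$gene_id,
        scaffold = g$scaffold, start = sst, end = sen, strand = g$strand,
        identity = h$identity[j], offset = off)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(kind = character(), gene_id = character(),
                          scaffold = character(), start = integer(),
                          end = integer(), strand = character(),
                          identity = numeric(), offset = integer()))
  do.call(rbind, out)
}

#' Genome-wide DinoSL scan with tandem-array grouping
#'
#' Locates full-length motif matches on both strands of every scaffold
#' (allowing up to `max_mismatch` substitutions) and groups hits on the same
#' scaffold and strand whose gap is at most `array_gap` into arrays,
#' reporting per-array copy numbers (singletons have copy number 1).
#'
#' @param asm An [assembly()].
#' @param motif Motif to search (default [DINOSL_MOTIF]).
#' @param max_mismatch Maximum substitutions over the full motif length
#'   (default 4, i.e. >= 80% identity for the 21-nt motif).
#' @param array_gap Maximum gap between consecutive hits in an array
#'   (default 500 bp).
#' @return List with `hits` (tibble: kind "genomic", scaffold, start, end,
#'   strand, identity) and `arrays` (tibble: scaffold, strand, start, end,
#'   copy_number).
#' @export
scan_dinoSL_genome <- function(asm, motif = DINOSL_MOTIF, max_mismatch = 4,
                               array_gap = 500) {
  stopifnot(inherits(asm, "assembly"))
  ss <- Biostrings::DNAStringSet(unclass(asm))
  pat <- Biostrings::DNAString(motif)
  lm <- nchar(motif)
  rows <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
    mm <- Biostrings::vmatchPattern(p, ss, max.mismatch = max_mismatch)
    for (s in seq_along(mm)) {
      ir <- mm[[s]]
      if (length(ir) == 0) next
      st <- IRanges::start(ir); en <- IRanges::end(ir)
      scf_seq <- unclass(asm)[[s]]
      nmis <- vapply(seq_along(ir), function(j) {
        seg <- substr(scf_seq, st[j], en[j])
        if (strand == "-") seg <- revcomp(seg)
        sum(seq_to_codes(seg) != seq_to_codes(motif))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "genomic", scaffold = names(asm)[s], start = st, end = en,
        strand = strand, identity = 100 * (lm - nmis) / lm)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows)
          else tibble::tibble(kind = character(), scaffold = character(),
                              start = integer(), end = integer(),
                              strand = character(), identity = numeric())
  hits <- hits[order(hits$scaffold, hits$strand, hits$start), ]
  arrays <- if (nrow(hits) == 0)
    tibble::tibble(scaffold = character(), strand = character(),
                   start = integer(), end = integer(),
                   copy_number = integer())
  else {
    key <- paste(hits$scaffold, hits$strand)
    do.call(rbind, lapply(split(seq_len(nrow(hits)), key), function(idx) {
      g <- hits[idx, , drop = FALSE]
      gap_new <- c(TRUE, g$start[-1] - g$end[-nrow(g)] - 1L > array_gap)
      grp <- cumsum(gap_new)
      do.call(rbind, lapply(split(seq_len(nrow(g)), grp), function(ii) {
        tibble::tibble(scaffold = g$scaffold[1], strand = g$strand[1],
                       start = min(g$start[ii]), end = max(g$end[ii]),
                       copy_number = length(ii))
      }))
    }))
  }
  rownames(arrays) <- NULL
  list(hits = hits, arrays = arrays)
}
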