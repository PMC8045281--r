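#' Gene order of a genome
#'
#' Orders gene models by scaffold and start coordinate (ties broken by gene
#' id) and attaches a within-scaffold index; the positional input to
#' synteny and tandem-array detection.
#'
#' @param genes Tibble with columns gene_id, scaffold, start, family,
#'   strand (end optional).
#' @return A `gene_order` tibble with an added `index` column.
#' @export
gene_order <- function(genes) {
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  genes <- genes[order(genes$scaffold, genes$start, genes$gene_id), ,
                 drop = FALSE]
  genes$index <- stats::ave(seq_len(nrow(genes)), genes$scaffold,
                            FUN = seq_along)
  structure(genes, class = c("gene_order", class(tibble::tibble())))
}

# All maximal collinear chains between two ordered gene lists (one scaffold
# each). Pairs are family matches; a chain advances with at most `max_gap`
# intervening genes on either side, monotone increasing on side a and
# increasing (parallel) or decreasing (antiparallel) on side b, with the
# per-pair strand relation fixed by the orientation class.
chains_for_scaffolds <- function(fa, sa, fb, sb, max_gap,
                                 ids_a = NULL, ids_b = NULL) {
  pairs <- list()
  for (o in c("parallel", "antiparallel")) {
    idx <- which(outer(fa, fb, "==") &
                   (outer(sa, sb, "==") == (o == "parallel")),
                 arr.ind = TRUE)
    if (!is.null(ids_a) && nrow(idx))  # drop trivial self-pairs
      idx <- idx[ids_a[idx[, 1]] != ids_b[idx[, 2]], , drop = FALSE]
    if (nrow(idx) == 0) next
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    np <- nrow(idx)
    succ <- vector("list", np)
    has_pred <- logical(np)
    for (u in seq_len(np)) {
      for (v in seq_len(np)) {
        di <- idx[v, 1] - idx[u, 1]
        dj <- if (o == "parallel") idx[v, 2] - idx[u, 2]
              else idx[u, 2] - idx[v, 2]
        if (di >= 1 && di <= max_gap + 1 && dj >= 1 && dj <= max_gap + 1) {
          succ[[u]] <- c(succ[[u]], v)
          has_pred[v] <- TRUE
        }
      }
    }
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (length(succ[[u]]) == 0) {
        paths[[length(paths) + 1L]] <<- path
      } else {
        for (v in succ[[u]]) walk(c(path, v))
      }
    }
    for (u in which(!has_pred)) walk(u)
    for (p in paths) {
      pairs[[length(pairs) + 1L]] <-
        list(orientation = o, a_idx = idx[p, 1], b_idx = idx[p, 2])
    }
  }
  pairs
}

#' Find collinear syntenic gene blocks between two genomes
#'
#' A block is a maximal chain of at least `min_genes` homologous gene pairs
#' (shared family labels) in which genes are consecutive on both scaffolds
#' up to `max_gap` intervening non-member genes per side and keep a
#' consistent relative orientation: parallel blocks preserve strand
#' agreement and gene order, antiparallel blocks reverse the order and flip
#' strands. With `self = TRUE` (duplicated-block search within one genome)
#' trivial self-pairs are excluded and mirrored blocks are reported once.
#'
#' @param a,b `gene_order` objects (see [gene_order()]); pass the same
#'   object twice with `self = TRUE` for intra-genome search.
#' @param min_genes Minimum chain length (default 5).
#' @param max_gap Maximum intervening non-member genes per side (default 0,
#'   the strict "same order and orientation" definition).
#' @param self Intra-genome mode.
#' @return Tibble of blocks: scaffold_a, scaffold_b, orientation, size,
#'   genes_a, genes_b (list columns of gene ids).
#' @export
find_collinear_blocks <- function(a, b, min_genes = 5, max_gap = 0,
                                  self = FALSE) {
  blocks <- list()
  for (scf_a in unique(a$scaffold)) {
    ga <- a[a$scaffold == scf_a, , drop = FALSE]
    for (scf_b in unique(b$scaffold)) {
      gb <- b[b$scaffold == scf_b, , drop = FALSE]
      if (self && scf_a > scf_b) next
      same_scf <- self && scf_a == scf_b
      ch <- chains_for_scaffolds(ga$family, ga$strand, gb$family, gb$strand,
                                 max_gap,
                                 ids_a = if (same_scf) ga$gene_id else NULL,
                                 ids_b = if (same_scf) gb$gene_id else NULL)
      for (c0 in ch) {
        if (length(c0$a_idx) < min_genes) next
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          scaffold_a = scf_a, scaffold_b = scf_b,
          orientation = c0$orientation, size = length(c0$a_idx),
          genes_a = list(ga$gene_id[c0$a_idx]),
          genes_b = list(gb$gene_id[c0$b_idx]))
      }
    }
  }
  if (length(blocks) == 0)
    return(tibble::tibble(scaffold_a = character(), scaffold_b = character(),
                          orientation = character(), size = integer(),
                          genes_a = list(), genes_b = list()))
  out <- do.call(rbind, blocks)
  if (self) out <- dedupe_mirror_blocks(out)
  out
}

dedupe_mirror_blocks <- function(blocks) {
  key <- vapply(seq_len(nrow(blocks)), function(i) {
    fwd <- paste(blocks$genes_a[[i]], blocks$genes_b[[i]], collapse = "|")
    # the mirrored block lists the pairs from the other side's perspective,
    # sorted back into side-a order
    gb <- blocks$genes_b[[i]]; ga <- blocks$genes_a[[i]]
    ord <- order(gb)
    rev_key <- paste(gb[ord], ga[ord], collapse = "|")
    min(fwd, rev_key)
  }, character(1))
  blocks[!duplicated(key), , drop = FALSE]
}

#' Find tandem gene arrays
#'
#' Maximal runs of genes of the same family on one scaffold, allowing up to
#' `max_intervening` genes of other families between consecutive members;
#' runs of length >= 2 are reported with their copy number.
#'
#' @param g A `gene_order`.
#' @param max_intervening Maximum intervening non-member genes (default 0).
#' @return Tibble: scaffold, family, copy_number, genes (list of gene ids).
#' @export
find_tandem_arrays <- function(g, max_intervening = 0) {
  out <- list()
  for (scf in unique(g$scaffold)) {
    gs <- g[g$scaffold == scf, , drop = FALSE]
    for (fam in unique(gs$family)) {
      pos <- which(gs$family == fam)
      if (length(pos) < 2) next
      grp <- cumsum(c(TRUE, diff(pos) - 1 > max_intervening))
      for (run in split(pos, grp)) {
        if (length(run) >= 2)
          out[[length(out) + 1L]] <- tibble::tibble(
            scaffold = scf, family = fam, copy_number = length(run),
            genes = list(gs$gene_id[run]))
      }
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(scaffold = character(), family = character(),
                          copy_number = integer(), genes = list()))
  do.call(rbind, out)
}

#' Feature length ratio between two genomes
#'
#' The ratio Delta of the total length of a genome feature in genome A to
#' the equivalent length in genome B, with its log2 transform.
#'
#' @param len_a,len_b Total feature lengths in bp (`len_b` > 0).
#' @return List with `delta` and `log2_delta`.
#' @examples
#' feature_ratio(1287259774, 740100732)$delta  # 1.74 (estimated sizes)
#' @export
feature_ratio <- function(len_a, len_b) {
  if (!is.numeric(len_b) || len_b <= 0) stop("len_b must be positive")
  delta <- len_a / len_b
  list(delta = delta, log2_delta = log2(delta))
}

#' Fisher exact tests on gene-family sizes between two genomes
#'
#' For each family, the 2x2 table (family count vs remaining genes, per
#' genome) is tested with a two-tailed Fisher exact test; p values are
#' Benjamini-Hochberg adjusted across families, with significance at
#' adjusted p <= `alpha`.
#'
#' @param counts Matrix or data frame of gene counts (families x 2 genomes)
#'   with family rownames.
#' @param totals Column totals (default: column sums of `counts`).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return Tibble: family, count_a, count_b, p, p_adjusted, larger_in,
#'   significant.
#' @export
family_size_fisher <- function(counts, totals = NULL, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("counts must have exactly two genome columns")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(counts < 0) || any(apply(counts, 2, max) > totals))
    stop("family count exceeds genome total")
  labs <- colnames(counts)
  if (is.null(labs)) labs <- c("a", "b")
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts[i, 1], totals[1] - counts[i, 1],
                    counts[i, 2], totals[2] - counts[i, 2]), nrow = 2)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  prop <- sweep(counts, 2, totals, "/")
  larger <- unname(ifelse(prop[, 1] > prop[, 2], labs[1],
                          ifelse(prop[, 2] > prop[, 1], labs[2], "equal")))
  tibble::tibble(
    family = if (is.null(rownames(counts)))
      as.character(seq_len(nrow(counts))) else rownames(counts),
    count_a = counts[, 1], count_b = counts[, 2],
    p = p, p_adjusted = padj, larger_in = larger,
    significant = padj <= alpha)
}

#' Z-score matrix of feature abundances across genomes
#'
#' Per feature row, Z_g = (x_g - mean(x)) / sd(x) with the population
#' standard deviation (divisor n; the genome set is the whole population,
#' not a sample). Rows with zero spread yield all-zero Z and are flagged in
#' the `degenerate` attribute.
#'
#' @param abundance Numeric matrix (features x genomes) of relative
#'   abundances.
#' @return Z matrix of the same shape, with attribute `degenerate`
#'   (logical per row).
#' @export
zscore_matrix <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 2) stop("need >= 2 genomes per feature")
  mu <- rowMeans(abundance)
  sd_pop <- sqrt(rowMeans((abundance - mu)^2))
  degenerate <- sd_pop == 0
  z <- (abundance - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- degenerate
  z
}

# Wright's synonymous-family partition of the standard genetic code.
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  fam <- split(names(sense), sense)
  deg <- vapply(fam, length, integer(1))
  list(families = fam, degeneracy = deg)
}

#' GC3 and effective number of codons (Nc) per coding sequence
#'
#' For complete CDS only (length divisible by 3, leading ATG, trailing stop,
#' no internal stop; others are skipped with a warning):
#' GC3 is the G+C fraction at third positions of synonymous codons (Met,
#' Trp and stop codons excluded). Nc is Wright's effective number of
#' codons: per amino acid, codon homozygosity F = (n S - 1)/(n - 1) with
#' S the sum of squared codon frequencies; F is averaged within degeneracy
#' classes, a missing threefold class is interpolated as the mean of the
#' two- and fourfold averages (the standard fallback), and
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to \[20, 61\].
#'
#' @param cds Named character vector of CDS (or `DNAStringSet`).
#' @return Tibble: gene, gc3, nc, n_codons (complete CDS only).
#' @export
gc3_and_nc <- function(cds) {
  cds <- as_seqchar(cds)
  if (is.null(names(cds))) names(cds) <- sprintf("cds%03d", seq_along(cds))
  code <- Biostrings::GENETIC_CODE
  cf <- codon_families()
  out <- list()
  skipped <- character(0)
  for (g in names(cds)) {
    s <- toupper(cds[[g]])
    n <- nchar(s)
    if (n %% 3 != 0 || n < 6) { skipped <- c(skipped, g); next }
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    if (codons[1] != "ATG" ||
        is.na(code[codons[n / 3]]) || code[codons[n / 3]] != "*") {
      skipped <- c(skipped, g); next
    }
    aas <- code[codons]
    if (any(is.na(aas)) || any(aas[-length(aas)] == "*")) {
      skipped <- c(skipped, g); next
    }
    body <- codons[aas != "*"]
    aa_body <- code[body]
    # GC3 over synonymous codons only
    syn <- cf$degeneracy[aa_body] >= 2
    third <- substr(body[syn], 3, 3)
    gc3 <- if (length(third)) mean(third %in% c("G", "C")) else NA_real_
    # Wright's Nc
    f_by_aa <- sapply(unique(aa_body), function(aa) {
      obs <- body[aa_body == aa]
      k <- cf$degeneracy[[aa]]
      if (k == 1) return(c(k = k, f = NA_real_))
      nn <- length(obs)
      if (nn < 2) return(c(k = k, f = NA_real_))
      pr <- table(factor(obs, levels = cf$families[[aa]])) / nn
      ssum <- sum(pr^2)
      c(k = k, f = (nn * ssum - 1) / (nn - 1))
    })
    fk <- function(k) {
      v <- f_by_aa["f", f_by_aa["k", ] == k]
      v <- v[!is.na(v) & v > 0]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    f2 <- fk(2); f3 <- fk(3); f4 <- fk(4); f6 <- fk(6)
    if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
    nc <- if (any(is.na(c(f2, f3, f4, f6)))) NA_real_
          else min(61, max(20, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
    out[[g]] <- tibble::tibble(gene = g, gc3 = gc3, nc = nc,
                               n_codons = length(body))
  }
  if (length(skipped))
    warning(sprintf("skipped %d incomplete CDS: %s", length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  if (length(out) == 0)
    return(tibble::tibble(gene = character(), gc3 = numeric(),
                          nc = numeric(), n_codons = integer()))
  do.call(rbind, out)
}
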