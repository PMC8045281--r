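#' Generate a random root genome
#'
#' Draws a single scaffold of i.i.d. bases with a prescribed G+C fraction
#' (G and C equiprobable, likewise A and T). This is the ancestral sequence
#' from which [evolve_along_tree()] derives diverged leaf genomes.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target G+C fraction in \[0, 1\].
#' @param seed Integer seed; identical seeds give identical output.
#' @param scaffold_id Name of the single scaffold.
#' @return An [assembly()] with one scaffold of exactly `length` bases.
#' @examples
#' asm <- generate_root_genome(1000, gc = 0.5, seed = 7)
#' nchar(asm)
#' @export
generate_root_genome <- function(length, gc = 0.5, seed = 1,
                                 scaffold_id = "scf1") {
  if (!is.numeric(length) || length < 1) stop("length must be >= 1")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  seq <- with_local_seed(seed, {
    idx <- sample.int(4L, size = length, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste(c("A", "C", "G", "T")[idx], collapse = "")
  })
  assembly(stats::setNames(seq, scaffold_id))
}

# K2P (Kimura two-parameter) per-site substitution probabilities for a branch
# of expected length d substitutions/site and transition:transversion rate
# ratio kappa. Returns c(p_same, p_ts, p_tv_each).
k2p_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)        # beta * t  (each transversion rate)
  at <- kappa * bt             # alpha * t (transition rate)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

#' Expected proportion of differing sites under K2P
#'
#' Closed-form expected p-distance (and its transition/transversion split)
#' after evolving a total path of `d` expected substitutions/site with
#' transition:transversion rate ratio `kappa`. Used as the independent oracle
#' for simulation tests.
#'
#' @param d Expected substitutions per site along the whole path.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return Named vector with `p` (total), `p_ts` and `p_tv`.
#' @export
k2p_expected_p <- function(d, kappa = 2) {
  pr <- k2p_probs(d, kappa)
  c(p = unname(pr["ts"] + 2 * pr["tv"]), p_ts = unname(pr["ts"]),
    p_tv = unname(2 * pr["tv"]))
}

# Substitute a coded sequence (ints 1..4 = ACGT, 5 = N) along one K2P branch.
k2p_mutate_codes <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  pr <- k2p_probs(d, kappa)
  n <- length(codes)
  u <- stats::runif(n)
  ts_partner <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)          # A->C, C->A, G->C, T->A
  tv2 <- c(4L, 3L, 4L, 3L)          # A->T, C->G, G->T, T->G
  ok <- codes <= 4L
  sel_ts <- ok & u < pr["ts"]
  sel_tv1 <- ok & u >= pr["ts"] & u < pr["ts"] + pr["tv"]
  sel_tv2 <- ok & u >= pr["ts"] + pr["tv"] & u < pr["ts"] + 2 * pr["tv"]
  out <- codes
  out[sel_ts] <- ts_partner[codes[sel_ts]]
  out[sel_tv1] <- tv1[codes[sel_tv1]]
  out[sel_tv2] <- tv2[codes[sel_tv2]]
  out
}

seq_to_codes <- function(s) {
  lookup <- integer(128)
  lookup[utf8ToInt("ACGTN")] <- 1:5
  lookup[utf8ToInt(s)]
}

codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("ACGTN")[codes])
}

# Apply optional structural events to one coded scaffold along a branch.
branch_structural <- function(codes, branch_len, indel_rate, inversion_rate,
                              duplication_rate) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  if (indel_rate > 0) {
    n_ev <- stats::rpois(1, indel_rate * branch_len * length(codes))
    for (i in seq_len(n_ev)) {
      len <- stats::rgeom(1, 1 / 3) + 1L
      pos <- sample.int(length(codes), 1)
      if (stats::runif(1) < 0.5) {  # insertion
        ins <- sample.int(4L, len, replace = TRUE)
        codes <- append(codes, ins, after = pos)
      } else {                      # deletion
        del <- pos:min(length(codes), pos + len - 1L)
        if (length(del) < length(codes)) codes <- codes[-del]
      }
    }
  }
  if (inversion_rate > 0) {
    for (i in seq_len(stats::rpois(1, inversion_rate))) {
      len <- min(length(codes) - 1L, stats::rgeom(1, 1 / 5000) + 1L)
      pos <- sample.int(length(codes) - len, 1)
      seg <- codes[pos:(pos + len - 1L)]
      codes[pos:(pos + len - 1L)] <- rev(comp[seg])
    }
  }
  if (duplication_rate > 0) {
    for (i in seq_len(stats::rpois(1, duplication_rate))) {
      len <- min(length(codes) - 1L, stats::rgeom(1, 1 / 5000) + 1L)
      pos <- sample.int(length(codes) - len, 1)
      seg <- codes[pos:(pos + len - 1L)]
      codes <- append(codes, seg, after = pos + len - 1L)
    }
  }
  codes
}

#' Evolve a root genome along a tree under the K2P model
#'
#' Each branch of length b applies per-site substitutions with the exact K2P
#' exponential probabilities (expected b substitutions/site, transition to
#' transversion rate ratio `kappa`), followed by optional indels, inversions
#' and segmental duplications. With all structural rates at 0 the genome
#' length is conserved at every leaf.
#'
#' @param root An [assembly()]: the ancestral genome.
#' @param spec A list with elements `tree` (an [ape::read.tree()] `phylo`
#'   object or a Newick string; branch lengths in expected
#'   substitutions/site), `kappa` (> 0, default 2), `indel_rate`
#'   (events/site, default 0), `inversion_rate` and `duplication_rate`
#'   (events/genome/branch, default 0), and `seed`.
#' @return Named list of leaf assemblies (one per tree tip).
#' @export
evolve_along_tree <- function(root, spec) {
  tree <- spec$tree
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) NULL)
    if (is.null(tree)) stop("malformed tree: could not parse Newick")
  }
  if (!inherits(tree, "phylo")) stop("spec$tree must be a phylo or Newick")
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  kappa <- if (is.null(spec$kappa)) 2 else spec$kappa
  if (kappa <= 0) stop("kappa must be > 0")
  indel_rate <- if (is.null(spec$indel_rate)) 0 else spec$indel_rate
  inv_rate <- if (is.null(spec$inversion_rate)) 0 else spec$inversion_rate
  dup_rate <- if (is.null(spec$duplication_rate)) 0 else spec$duplication_rate
  seed <- if (is.null(spec$seed)) 1 else spec$seed

  root_codes <- lapply(unclass(root), seq_to_codes)
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  leaves <- vector("list", n_tip)
  with_local_seed(seed, {
    walk <- function(node, codes) {
      for (e in kids[[as.character(node)]]) {
        child <- tree$edge[e, 2]
        b <- tree$edge.length[e]
        child_codes <- lapply(codes, function(cd) {
          cd <- k2p_mutate_codes(cd, b, kappa)
          branch_structural(cd, b, indel_rate, inv_rate, dup_rate)
        })
        if (child <= n_tip) {
          leaves[[child]] <<- assembly(vapply(child_codes, codes_to_seq,
                                              character(1)))
        } else {
          walk(child, child_codes)
        }
      }
    }
    walk(root_node, root_codes)
  })
  stats::setNames(leaves, tree$tip.label)
}

#' The DinoSL spliced-leader motif
#'
#' The conserved 21-nt DNA form of the dinoflagellate spliced leader, with
#' the ambiguous leading position excluded.
#' @export
DINOSL_MOTIF <- "CCGTAGCCATTTTGGCTCAAG"

empty_truth <- function() {
  tibble::tibble(kind = character(), scaffold = character(),
                 start = integer(), end = integer(), strand = character(),
                 label = character(), divergence = numeric(),
                 covered_fraction = numeric())
}

# Pick a non-overlapping window of `len` bases on one scaffold, given a
# per-scaffold list of occupied IRanges. Returns start or NA.
place_window <- function(occupied, scaffold_len, len, tries = 2000) {
  if (scaffold_len < len) return(NA_integer_)
  for (i in seq_len(tries)) {
    st <- sample.int(scaffold_len - len + 1L, 1)
    cand <- IRanges::IRanges(st, st + len - 1L)
    if (length(occupied) == 0 ||
        !any(IRanges::overlapsAny(cand, occupied)))
      return(st)
  }
  NA_integer_
}

# Point-mutate a sequence at K2P divergence `div` (fraction), kappa = 2.
mutate_copy <- function(seq, div, kappa = 2) {
  if (div <= 0) return(seq)
  codes_to_seq(k2p_mutate_codes(seq_to_codes(seq), div, kappa))
}

#' Plant ground-truth features into an assembly
#'
#' Writes repeat copies, pseudogene fragments, DinoSL motifs and contaminant
#' scaffolds into a host assembly and returns a truth table describing every
#' insertion. Features overwrite a same-length window of the host scaffold at
#' a non-overlapping position (so coordinates of previously planted features
#' remain valid); contaminant scaffolds are appended as whole new scaffolds.
#'
#' @param asm Host [assembly()].
#' @param repeats `NULL` or a list/tibble with fields `family`, `class`,
#'   `n_copies`, `length`, `divergence` (percent K2P divergence from the
#'   family consensus). One row per family.
#' @param pseudogenes `NULL` or a list with `n`, `n_fragments`,
#'   `fragment_length`, `gap` (bp between consecutive fragments) and
#'   `identity` (percent). Each planted pseudogene is a same-strand chain of
#'   fragments copied (with point substitutions) from a per-pseudogene
#'   protein-source sequence.
#' @param dinosl `NULL` or a list with optional elements `upstream`
#'   (list with `n`, `offset`, optional `gene_length`, `strand`) and `tandem`
#'   (list with `n_arrays`, `copies`, `spacing`).
#' @param contaminants `NULL` or a tibble/list with `length`, `gc`,
#'   `covered_fraction` (fraction of the scaffold that
#'   [make_hit_table()] will cover with significant hits) and `label`.
#' @param seed Integer seed.
#' @return A list with elements `assembly` (host plus any contaminant
#'   scaffolds), `truth` (tibble: kind, scaffold, start, end, strand, label,
#'   divergence, covered_fraction), `genes` (tibble of gene models created
#'   for upstream DinoSL layouts), and `consensus` (named list of repeat
#'   family consensus and pseudogene source sequences).
#' @export
plant_features <- function(asm, repeats = NULL, pseudogenes = NULL,
                           dinosl = NULL, contaminants = NULL, seed = 1) {
  stopifnot(inherits(asm, "assembly"))
  with_local_seed(seed, {
    seqs <- unclass(asm)
    occupied <- lapply(seqs, function(s) IRanges::IRanges())
    truth <- empty_truth()
    genes <- tibble::tibble(gene_id = character(), scaffold = character(),
                            start = integer(), end = integer(),
                            strand = character())
    consensus <- list()

    overwrite <- function(scf, start, piece) {
      substr(seqs[[scf]], start, start + nchar(piece) - 1L) <<- piece
      occupied[[scf]] <<- c(occupied[[scf]],
                            IRanges::IRanges(start,
                                             start + nchar(piece) - 1L))
    }
    pick_scaffold <- function(len) {
      lens <- nchar(seqs)
      ok <- names(seqs)[lens >= len]
      if (length(ok) == 0) placement_failure(len)
      sample(ok, 1)
    }
    placement_failure <- function(len) {
      stop(structure(class = c("placement_failure", "error", "condition"),
                     list(message = sprintf(
                       "could not place a %d bp feature without overlap", len),
                       call = sys.call(-1))))
    }
    plant_piece <- function(piece, kind, label, divergence, strand) {
      len <- nchar(piece)
      scf <- pick_scaffold(len)
      st <- place_window(occupied[[scf]], nchar(seqs[[scf]]), len)
      if (is.na(st)) placement_failure(len)
      overwrite(scf, st, if (strand == "-") revcomp(piece) else piece)
      truth <<- rbind(truth, tibble::tibble(
        kind = kind, scaffold = scf, start = st, end = st + len - 1L,
        strand = strand, label = label, divergence = divergence,
        covered_fraction = NA_real_))
      list(scaffold = scf, start = st, end = st + len - 1L)
    }

    ## repeat copies
    if (!is.null(repeats)) {
      repeats <- tibble::as_tibble(as.list(repeats))
      for (i in seq_len(nrow(repeats))) {
        fam <- repeats$family[i]
        cons <- paste(sample(c("A", "C", "G", "T"), repeats$length[i],
                             replace = TRUE), collapse = "")
        consensus[[fam]] <- cons
        for (j in seq_len(repeats$n_copies[i])) {
          copy <- mutate_copy(cons, repeats$divergence[i] / 100)
          strand <- sample(c("+", "-"), 1)
          plant_piece(copy, "repeat_copy", fam, repeats$divergence[i], strand)
        }
      }
      if ("class" %in% names(repeats))
        attr(truth, "repeat_class") <-
          stats::setNames(repeats$class, repeats$family)
    }

    ## pseudogenes: chains of fragments on one strand, fixed gaps
    if (!is.null(pseudogenes)) {
      p <- pseudogenes
      nfrag <- p$n_fragments
      for (i in seq_len(p$n)) {
        label <- sprintf("P%03d", i)
        src_len <- nfrag * p$fragment_length
        src <- paste(sample(c("A", "C", "G", "T"), src_len, replace = TRUE),
                     collapse = "")
        consensus[[label]] <- src
        span <- nfrag * p$fragment_length + (nfrag - 1L) * p$gap
        scf <- pick_scaffold(span)
        st <- place_window(occupied[[scf]], nchar(seqs[[scf]]), span)
        if (is.na(st)) placement_failure(span)
        strand <- sample(c("+", "-"), 1)
        for (j in seq_len(nfrag)) {
          fst <- st + (j - 1L) * (p$fragment_length + p$gap)
          frag_src <- substr(src, (j - 1L) * p$fragment_length + 1L,
                             j * p$fragment_length)
          frag <- mutate_sub_identity(frag_src, p$identity)
          overwrite(scf, fst, if (strand == "-") revcomp(frag) else frag)
          truth <- rbind(truth, tibble::tibble(
            kind = "pseudogene", scaffold = scf, start = fst,
            end = fst + p$fragment_length - 1L, strand = strand,
            label = label, divergence = 100 - p$identity,
            covered_fraction = NA_real_))
        }
      }
    }

    ## DinoSL motifs
    if (!is.null(dinosl)) {
      motif <- if (is.null(dinosl$motif)) DINOSL_MOTIF else dinosl$motif
      if (!is.null(dinosl$upstream)) {
        u <- dinosl$upstream
        glen <- if (is.null(u$gene_length)) 300L else as.integer(u$gene_length)
        for (i in seq_len(u$n)) {
          strand <- if (is.null(u$strand)) sample(c("+", "-"), 1) else u$strand
          span <- nchar(motif) + u$offset + glen
          scf <- pick_scaffold(span)
          st <- place_window(occupied[[scf]], nchar(seqs[[scf]]), span)
          if (is.na(st)) placement_failure(span)
          gid <- sprintf("g%03d", nrow(genes) + 1L)
          if (strand == "+") {
            overwrite(scf, st, motif)
            gstart <- st + nchar(motif) + u$offset
            genes <- rbind(genes, tibble::tibble(
              gene_id = gid, scaffold = scf, start = gstart,
              end = gstart + glen - 1L, strand = "+"))
            truth <- rbind(truth, tibble::tibble(
              kind = "dinosl", scaffold = scf, start = st,
              end = st + nchar(motif) - 1L, strand = "+", label = gid,
              divergence = 0, covered_fraction = NA_real_))
          } else {
            # gene first (on scaffold), motif downstream in scaffold coords
            gstart <- st
            mstart <- st + glen + u$offset
            overwrite(scf, mstart, revcomp(motif))
            genes <- rbind(genes, tibble::tibble(
              gene_id = gid, scaffold = scf, start = gstart,
              end = gstart + glen - 1L, strand = "-"))
            truth <- rbind(truth, tibble::tibble(
              kind = "dinosl", scaffold = scf, start = mstart,
              end = mstart + nchar(motif) - 1L, strand = "-", label = gid,
              divergence = 0, covered_fraction = NA_real_))
          }
        }
      }
      if (!is.null(dinosl$tandem)) {
        td <- dinosl$tandem
        spacing <- if (is.null(td$spacing)) 10L else as.integer(td$spacing)
        for (a in seq_len(td$n_arrays)) {
          span <- td$copies * nchar(motif) + (td$copies - 1L) * spacing
          scf <- pick_scaffold(span)
          st <- place_window(occupied[[scf]], nchar(seqs[[scf]]), span)
          if (is.na(st)) placement_failure(span)
          strand <- sample(c("+", "-"), 1)
          for (j in seq_len(td$copies)) {
            mst <- st + (j - 1L) * (nchar(motif) + spacing)
            overwrite(scf, mst,
                      if (strand == "-") revcomp(motif) else motif)
            truth <- rbind(truth, tibble::tibble(
              kind = "dinosl", scaffold = scf, start = mst,
              end = mst + nchar(motif) - 1L, strand = strand,
              label = sprintf("array%02d", a), divergence = 0,
              covered_fraction = NA_real_))
          }
        }
      }
    }

    ## contaminant scaffolds: appended whole
    if (!is.null(contaminants)) {
      contaminants <- tibble::as_tibble(as.list(contaminants))
      for (i in seq_len(nrow(contaminants))) {
        len <- contaminants$length[i]
        gc <- contaminants$gc[i]
        cf <- if (!"covered_fraction" %in% names(contaminants))
          NA_real_ else contaminants$covered_fraction[i]
        lab <- if (!"label" %in% names(contaminants))
          sprintf("contam%02d", i) else contaminants$label[i]
        id <- sprintf("contam_scf%02d", i)
        idx <- sample.int(4L, len, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                   (1 - gc) / 2))
        seqs[[id]] <- paste(c("A", "C", "G", "T")[idx], collapse = "")
        occupied[[id]] <- IRanges::IRanges()
        truth <- rbind(truth, tibble::tibble(
          kind = "contaminant_scaffold", scaffold = id, start = 1L,
          end = len, strand = "+", label = lab, divergence = NA_real_,
          covered_fraction = cf))
      }
    }

    list(assembly = assembly(unlist(seqs)), truth = truth, genes = genes,
         consensus = consensus)
  })
}

# Substitute bases uniformly so the copy has ~`identity` percent identity to
# the source (each chosen site is changed to a different base).
mutate_sub_identity <- function(seq, identity) {
  n <- nchar(seq)
  n_mut <- round(n * (100 - identity) / 100)
  if (n_mut == 0) return(seq)
  codes <- seq_to_codes(seq)
  pos <- sample.int(n, n_mut)
  codes[pos] <- ((codes[pos] - 1L + sample.int(3L, n_mut, replace = TRUE))
                 %% 4L) + 1L
  codes_to_seq(codes)
}

#' Simulate uniform-coverage shotgun reads
#'
#' Single-end reads with uniform start positions, per-base substitution
#' errors, and optional diploid heterozygosity: with `heterozygosity > 0`
#' the genome is duplicated into two haplotypes differing at that fraction
#' of sites before sampling (reads drawn evenly from both).
#'
#' @param asm An [assembly()].
#' @param coverage Target fold-coverage (> 0).
#' @param read_len Read length in bases (<= shortest scaffold).
#' @param error_rate Per-base substitution error rate.
#' @param heterozygosity Fraction of heterozygous sites (0 = haploid).
#' @param seed Integer seed.
#' @return Character vector of reads (named `read000001`, ...).
#' @export
simulate_reads <- function(asm, coverage, read_len, error_rate = 0,
                           heterozygosity = 0, seed = 1) {
  stopifnot(inherits(asm, "assembly"))
  if (coverage <= 0) stop("coverage must be > 0")
  lens <- scaffold_lengths(asm)
  if (read_len > min(lens)) stop("read_len exceeds shortest scaffold length")
  with_local_seed(seed, {
    hap1 <- unclass(asm)
    haps <- list(hap1)
    if (heterozygosity > 0) {
      haps[[2]] <- vapply(hap1, mutate_sub_identity,
                          character(1), identity = 100 * (1 - heterozygosity))
    }
    genome_len <- sum(lens)
    n_reads <- round(coverage * genome_len / read_len)
    scf <- sample(names(lens), n_reads, replace = TRUE,
                  prob = pmax(lens - read_len + 1, 0))
    hap_idx <- if (length(haps) == 2)
      sample.int(2L, n_reads, replace = TRUE) else rep(1L, n_reads)
    starts <- floor(stats::runif(n_reads) * (lens[scf] - read_len + 1)) + 1L
    reads <- character(n_reads)
    for (h in seq_along(haps)) {
      sel <- hap_idx == h
      reads[sel] <- substring(unlist(haps[[h]])[scf[sel]], starts[sel],
                              starts[sel] + read_len - 1L)
    }
    rc <- stats::runif(n_reads) < 0.5
    if (any(rc)) {
      ss <- Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[rc]))
      reads[rc] <- as.character(ss)
    }
    if (error_rate > 0) {
      n_err <- stats::rbinom(n_reads, read_len, error_rate)
      which_err <- which(n_err > 0)
      bases <- c("A", "C", "G", "T")
      for (i in which_err) {
        codes <- seq_to_codes(reads[i])
        pos <- sample.int(read_len, n_err[i])
        ok <- codes[pos] <= 4L
        pos <- pos[ok]
        if (length(pos)) {
          codes[pos] <- ((codes[pos] - 1L +
                          sample.int(3L, length(pos), replace = TRUE))
                         %% 4L) + 1L
          reads[i] <- codes_to_seq(codes)
        }
      }
    }
    stats::setNames(reads, sprintf("read%06d", seq_len(n_reads)))
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named character vector from [simulate_reads()].
#' @param file Output path.
#' @export
write_reads_fastq <- function(reads, file) {
  ss <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(ss, file, format = "fastq")
  invisible(file)
}

#' Synthesise a tabular hit file from planted truth
#'
#' Emulates the similarity-search evidence the real analysis obtains from
#' external database searches. In `contaminant` mode, each planted
#' contaminant scaffold receives significant hits (E <= 1e-30,
#' bitscore 1500) whose interval union covers the planted
#' `covered_fraction` of the scaffold. In `pseudogene` mode, each planted
#' fragment becomes one protein-vs-genome hit at the planted identity,
#' interval and strand (minus-strand fragments have sstart > send).
#'
#' @param truth Truth tibble from [plant_features()].
#' @param mode `"contaminant"` or `"pseudogene"`.
#' @return A 12-column hits tibble (see [read_hits()]).
#' @export
make_hit_table <- function(truth, mode = c("contaminant", "pseudogene")) {
  mode <- match.arg(mode)
  if (mode == "contaminant") {
    tr <- truth[truth$kind == "contaminant_scaffold", , drop = FALSE]
    if (nrow(tr) == 0) return(empty_hits())
    out <- lapply(seq_len(nrow(tr)), function(i) {
      len <- tr$end[i]
      cov <- round(tr$covered_fraction[i] * len)
      if (is.na(cov) || cov < 1) return(empty_hits())
      # split covered bases into up to 3 disjoint chunks along the scaffold
      n_chunk <- min(3L, cov)
      sizes <- diff(round(seq(0, cov, length.out = n_chunk + 1)))
      sizes <- sizes[sizes > 0]
      gap <- max(1L, floor((len - cov) / (length(sizes) + 1)))
      starts <- cumsum(c(1L + gap, utils::head(sizes, -1) + gap))
      tibble::tibble(qseqid = tr$scaffold[i], sseqid = tr$label[i],
                     pident = 95, length = sizes, mismatch = 0, gapopen = 0,
                     qstart = starts, qend = starts + sizes - 1,
                     sstart = 1, send = sizes,
                     evalue = 1e-30, bitscore = 1500)
    })
    do.call(rbind, out)
  } else {
    tr <- truth[truth$kind == "pseudogene", , drop = FALSE]
    if (nrow(tr) == 0) return(empty_hits())
    frag_idx <- stats::ave(seq_len(nrow(tr)), tr$label, FUN = seq_along)
    flen <- tr$end - tr$start + 1L
    minus <- tr$strand == "-"
    tibble::tibble(
      qseqid = tr$label, sseqid = tr$scaffold,
      pident = 100 - tr$divergence,
      length = ceiling(flen / 3), mismatch = 0, gapopen = 0,
      qstart = (frag_idx - 1L) * ceiling(flen / 3) + 1L,
      qend = frag_idx * ceiling(flen / 3),
      sstart = ifelse(minus, tr$end, tr$start),
      send = ifelse(minus, tr$start, tr$end),
      evalue = 1e-40, bitscore = 800)
  }
}

#' Write a planted-truth table as TSV
#'
#' @param truth Truth tibble from [plant_features()].
#' @param file Output path.
#' @export
write_truth <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Build repeat-copy alignments from planted truth
#'
#' Extracts every planted repeat copy from the assembly, orients it back to
#' the consensus strand and pairs it with the family consensus as equal
#' length gap-free alignment strings, ready for [build_landscape()].
#'
#' @param asm Assembly returned by [plant_features()].
#' @param truth Truth tibble (rows of kind `repeat_copy` are used).
#' @param consensus Named list of family consensus sequences.
#' @param classes Optional named character vector family -> repeat class
#'   (defaults to the `repeat_class` attribute of `truth`, else "Unknown").
#' @return Tibble with columns family, repeat_class, scaffold, start, end,
#'   copy_aln, cons_aln.
#' @export
repeat_copies_from_truth <- function(asm, truth, consensus, classes = NULL) {
  if (is.null(classes)) classes <- attr(truth, "repeat_class")
  tr <- truth[truth$kind == "repeat_copy", , drop = FALSE]
  seqs <- unclass(asm)
  copy <- substr(seqs[tr$scaffold], tr$start, tr$end)
  copy <- ifelse(tr$strand == "-", revcomp(copy), copy)
  cls <- if (is.null(classes)) rep("Unknown", nrow(tr))
         else unname(classes[tr$label])
  tibble::tibble(family = tr$label, repeat_class = cls,
                 scaffold = tr$scaffold, start = tr$start, end = tr$end,
                 copy_aln = unname(copy),
                 cons_aln = unname(unlist(consensus[tr$label])))
}
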