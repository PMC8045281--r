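# Small fixture builders shared across test files.

# Random hits table for pseudogene-merging tests: n fragments scattered on
# a couple of scaffolds, both strands, gaps around the 1 kb threshold.
random_pseudo_hits <- function(n, seed) {
  withr::with_seed(seed, {
    scf <- sample(c("s1", "s2"), n, replace = TRUE)
    start <- sample.int(20000, n)
    len <- sample(100:600, n, replace = TRUE)
    minus <- runif(n) < 0.5
    tibble::tibble(
      qseqid = sprintf("prot%02d", sample.int(8, n, replace = TRUE)),
      sseqid = scf, pident = runif(n, 70, 100),
      length = len %/% 3, mismatch = 0, gapopen = 0,
      qstart = 1, qend = len %/% 3,
      sstart = ifelse(minus, start + len - 1, start),
      send = ifelse(minus, start, start + len - 1),
      evalue = 1e-30, bitscore = 500)
  })
}

# Random alignment records for one-to-one filter tests.
random_alignment_records <- function(n, seed) {
  withr::with_seed(seed, {
    rs <- sample.int(5000, n); qs <- sample.int(5000, n)
    rl <- sample(50:400, n, replace = TRUE)
    ql <- sample(50:400, n, replace = TRUE)
    tibble::tibble(
      ref_id = sample(c("r1", "r2"), n, replace = TRUE),
      ref_start = rs, ref_end = rs + rl,
      qry_id = sample(c("q1", "q2"), n, replace = TRUE),
      qry_start = qs, qry_end = qs + ql,
      pct_identity = round(runif(n, 80, 100), 2),
      orientation = sample(c("+", "-"), n, replace = TRUE))
  })
}

# Random single-scaffold gene orders with a small family vocabulary, used
# for collinear-block oracle tests.
random_gene_order <- function(n_genes, n_fams, seed, prefix = "g") {
  withr::with_seed(seed, {
    tibble::tibble(
      gene_id = sprintf("%s%03d", prefix, seq_len(n_genes)),
      scaffold = "s1",
      start = sort(sample.int(10 * n_genes, n_genes)),
      family = sprintf("F%d", sample.int(n_fams, n_genes, replace = TRUE)),
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  })
}

empty_truth_tbl <- function() dinocomp:::empty_truth()

# Simulate one repeat copy at K2P divergence t from a consensus and return
# the aligned pair (gap-free).
simulated_copy_pair <- function(consensus, t) {
  copy <- dinocomp:::mutate_copy(consensus, t)
  list(copy = copy, cons = consensus)
}
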