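# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately use naive enumeration, not the implementation's code
# paths.

# Greedy one-to-one selection, written as plain quadratic loops.
oracle_one_to_one <- function(rec) {
  score <- (rec$qry_end - rec$qry_start + 1) * rec$pct_identity
  ord <- order(-score, rec$ref_id, rec$ref_start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      same_ref <- rec$ref_id[i] == rec$ref_id[j] &&
        max(rec$ref_start[i], rec$ref_start[j]) <=
        min(rec$ref_end[i], rec$ref_end[j])
      same_qry <- rec$qry_id[i] == rec$qry_id[j] &&
        max(rec$qry_start[i], rec$qry_start[j]) <=
        min(rec$qry_end[i], rec$qry_end[j])
      if (same_ref || same_qry) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Transitive-closure clustering of pseudogene fragments: connect fragments
# on the same scaffold and strand whose interval gap is <= max_gap, then
# take connected components.
oracle_fragment_clusters <- function(frag, max_gap) {
  n <- nrow(frag)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (frag$scaffold[i] != frag$scaffold[j]) next
      if (frag$strand[i] != frag$strand[j]) next
      gap <- max(frag$start[i], frag$start[j]) -
        min(frag$end[i], frag$end[j])
      if (gap <= max_gap) adj[i, j] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# All maximal collinear chains between two single-scaffold gene orders,
# by exhaustive recursive extension over match pairs.
oracle_blocks <- function(fa, sa, fb, sb, min_genes, max_gap) {
  pairs <- list()
  for (i in seq_along(fa)) for (j in seq_along(fb)) {
    if (fa[i] == fb[j])
      pairs[[length(pairs) + 1L]] <-
        list(i = i, j = j, o = if (sa[i] == sb[j]) "parallel" else "antiparallel")
  }
  np <- length(pairs)
  if (np == 0) return(list())
  can_follow <- function(u, v) {
    if (pairs[[u]]$o != pairs[[v]]$o) return(FALSE)
    di <- pairs[[v]]$i - pairs[[u]]$i
    dj <- if (pairs[[u]]$o == "parallel") pairs[[v]]$j - pairs[[u]]$j
          else pairs[[u]]$j - pairs[[v]]$j
    di >= 1 && di <= max_gap + 1 && dj >= 1 && dj <= max_gap + 1
  }
  chains <- list()
  extend <- function(chain) {
    last <- chain[length(chain)]
    nxt <- Filter(function(v) can_follow(last, v), seq_len(np))
    if (length(nxt) == 0) {
      # maximal at the right end; check left-maximality
      first <- chain[1]
      pre <- Filter(function(u) can_follow(u, first), seq_len(np))
      if (length(pre) == 0) chains[[length(chains) + 1L]] <<- chain
    } else {
      for (v in nxt) extend(c(chain, v))
    }
  }
  for (u in seq_len(np)) extend(u)
  chains <- unique(chains)
  out <- list()
  for (ch in chains) {
    if (length(ch) < min_genes) next
    out[[length(out) + 1L]] <- list(
      orientation = pairs[[ch[1]]]$o,
      a_idx = vapply(ch, function(u) pairs[[u]]$i, integer(1)),
      b_idx = vapply(ch, function(u) pairs[[u]]$j, integer(1)))
  }
  out
}

# Two-sided Fisher exact p by direct hypergeometric enumeration: sum the
# probabilities of all tables (with the same margins) no more probable than
# the observed one.
oracle_fisher_p <- function(xa, xb, tot_a, tot_b) {
  k <- xa + xb
  lo <- max(0, k - tot_b); hi <- min(k, tot_a)
  probs <- stats::dhyper(lo:hi, tot_a, tot_b, k)
  obs <- stats::dhyper(xa, tot_a, tot_b, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Canonical serialisation of a block set for comparison.
block_key <- function(a_idx, b_idx, orientation) {
  paste(orientation, paste(a_idx, collapse = ","),
        paste(b_idx, collapse = ","), sep = ";")
}
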