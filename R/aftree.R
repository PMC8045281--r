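#' Zero-order strand-symmetric background model
#'
#' The expectation model used to centre k-mer counts in the D2S statistic:
#' a zero-order (i.i.d. base) model symmetrised over strands, so that
#' p(A) = p(T) = (cA + cT) / (2 * total) and p(C) = p(G) = (cC + cG) /
#' (2 * total).
#'
#' @param profile A `kmer_profile` (supplies n, the total k-mer instances).
#' @param counts Named nucleotide counts of the source sequences
#'   (A, C, G, T), e.g. from [base_counts()].
#' @return A `background_model`: list with `p` (named probabilities) and `n`.
#' @export
background_model <- function(profile, counts) {
  counts <- counts[c("A", "C", "G", "T")]
  if (any(is.na(counts)) || sum(counts) <= 0)
    stop("nucleotide counts must be positive")
  tot <- sum(counts)
  pat <- (counts[["A"]] + counts[["T"]]) / (2 * tot)
  pcg <- (counts[["C"]] + counts[["G"]]) / (2 * tot)
  structure(list(p = c(A = pat, C = pcg, G = pcg, T = pat),
                 n = sum(as.numeric(profile$count))),
            class = "background_model")
}

#' Profile + background model for one genome
#'
#' Convenience constructor bundling the canonical k-mer profile of a genome
#' with its strand-symmetric background model, the per-genome input to
#' [d2s_distance()] and [distance_matrix()].
#'
#' @param x An [assembly()] or sequence set.
#' @param k Odd k-mer size (default 21, the uniqueness-adequate choice for
#'   these genomes).
#' @return List with elements `profile` and `model`, class `d2s_genome`.
#' @export
d2s_genome <- function(x, k = 21) {
  prof <- count_kmers(x, k)
  structure(list(profile = prof, model = background_model(prof, base_counts(x))),
            class = "d2s_genome")
}

# Centred counts of `words` under one genome's profile + background:
# X~_w = X_w - n * (p(w) + p(revcomp(w))).
centred_counts <- function(words, genome) {
  cnt <- numeric(length(words))
  idx <- match(words, genome$profile$kmer)
  hit <- !is.na(idx)
  cnt[hit] <- genome$profile$count[idx[hit]]
  pw <- cpp_word_background(words, unname(genome$model$p))
  cnt - genome$model$n * pw
}

d2s_sum <- function(xt, yt) {
  denom <- sqrt(xt^2 + yt^2)
  keep <- denom > 0
  sum(xt[keep] * yt[keep] / denom[keep])
}

#' D2S statistic and distance between two genomes
#'
#' Over the union of canonical words of the two profiles, counts are centred
#' under each genome's own background model and combined as
#' D2S = sum_w X~_w Y~_w / sqrt(X~_w^2 + Y~_w^2) (words absent from both
#' profiles are skipped; zero-denominator terms contribute 0). The
#' normalised similarity is S = D2S(X,Y) / sqrt(D2S(X,X) * D2S(Y,Y)) and the
#' distance is d = -ln(S), with S floored at `epsilon` so the log is always
#' defined.
#'
#' @param x,y `d2s_genome` objects (same k).
#' @param epsilon Floor for S before the log (default 1e-9).
#' @return List with `D2S`, `S` and `d`.
#' @export
d2s_distance <- function(x, y, epsilon = 1e-9) {
  if (x$profile$k != y$profile$k) stop("profiles have different k")
  ux <- x$profile$kmer
  uy <- y$profile$kmer
  words <- unique(c(ux, uy))
  xt <- centred_counts(words, x)
  yt <- centred_counts(words, y)
  d2s_xy <- d2s_sum(xt, yt)
  d2s_xx <- d2s_sum(xt[match(ux, words)], xt[match(ux, words)])
  d2s_yy <- d2s_sum(yt[match(uy, words)], yt[match(uy, words)])
  if (!is.finite(d2s_xx) || !is.finite(d2s_yy) || d2s_xx <= 0 || d2s_yy <= 0)
    stop(structure(class = c("degenerate_input", "error", "condition"),
                   list(message = "non-positive D2S self-statistic",
                        call = NULL)))
  s <- d2s_xy / sqrt(d2s_xx * d2s_yy)
  list(D2S = d2s_xy, S = s, d = max(0, -log(max(s, epsilon))))
}

#' Pairwise D2S distance matrix
#'
#' @param genomes Named list of `d2s_genome` objects (>= 2, common k).
#' @param epsilon Floor for S (see [d2s_distance()]).
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(genomes, epsilon = 1e-9) {
  n <- length(genomes)
  if (n < 2) stop("need >= 2 genomes")
  labs <- names(genomes)
  if (is.null(labs) || anyDuplicated(labs))
    stop("genomes must be uniquely named")
  ks <- vapply(genomes, function(g) g$profile$k, integer(1))
  if (length(unique(ks)) != 1) stop("all profiles must share the same k")
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- tryCatch(d2s_distance(genomes[[i]], genomes[[j]], epsilon)$d,
                      error = function(e) {
                        stop(sprintf("pair (%s, %s): %s", labs[i], labs[j],
                                     conditionMessage(e)), call. = FALSE)
                      })
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

check_dist_matrix <- function(dm, tol = 1e-9) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix must be symmetric")
  if (is.null(rownames(dm))) stop("distance matrix must have labels")
  invisible(dm)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: iteratively join the pair minimising
#' the Q-criterion, with ties broken by the lowest index pair (PHYLIP
#' Neighbor behaviour, for reproducibility). Negative branch lengths are
#' clamped to 0 in the returned tree; the raw (unclamped) edge lengths are
#' kept in the `raw_edge.length` attribute.
#'
#' @param dm Symmetric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  check_dist_matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("need >= 3 taxa")
  labs <- rownames(dm)
  # active nodes as newick fragments
  node <- labs
  d <- dm
  while (length(node) > 3) {
    m <- length(node)
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    nn <- sprintf("(%s:%.12g,%s:%.12g)", node[i], li, node[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], nn)
    d <- d2
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 node[1], l1, node[2], l2, node[3], l3)
  tree <- ape::read.tree(text = nwk)
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge.length") <- raw
  tree
}

#' Threshold similarity network
#'
#' Pairwise similarity is 10 - d; an edge joins genomes i and j whenever
#' their similarity is at least the threshold T.
#'
#' @param dm Distance matrix.
#' @param threshold Similarity threshold T.
#' @return A `similarity_network`: list with `nodes`, `edges` (tibble:
#'   node_i, node_j, similarity) and `threshold`.
#' @export
similarity_network <- function(dm, threshold) {
  check_dist_matrix(dm)
  labs <- rownames(dm)
  n <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  sim <- 10 - dm[pairs]
  keep <- sim >= threshold
  edges <- tibble::tibble(node_i = labs[pairs[keep, 1]],
                          node_j = labs[pairs[keep, 2]],
                          similarity = sim[keep])
  structure(list(nodes = labs, edges = edges, threshold = threshold),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges at T >= %g\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write network edges as TSV
#' @param net A `similarity_network`.
#' @param file Output path.
#' @export
write_network_edges <- function(net, file) {
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Mean inter-clade distance
#'
#' The arithmetic mean of pairwise distances over the cross-product of two
#' disjoint label sets (the clade-average delta annotated on the tree).
#'
#' @param dm Distance matrix.
#' @param set_a,set_b Disjoint, non-empty subsets of the matrix labels.
#' @return Mean distance (delta).
#' @export
mean_clade_distance <- function(dm, set_a, set_b) {
  check_dist_matrix(dm)
  labs <- rownames(dm)
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("both sets must be non-empty")
  if (!all(c(set_a, set_b) %in% labs))
    stop("sets must be subsets of the matrix labels")
  if (length(intersect(set_a, set_b)) > 0) stop("sets must be disjoint")
  mean(dm[set_a, set_b, drop = FALSE])
}
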