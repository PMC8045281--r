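mkorder <- function(fams, strands, scf = "s1", prefix = "g") {
  gene_order(tibble::tibble(
    gene_id = sprintf("%s%03d", prefix, seq_along(fams)),
    scaffold = scf, start = seq_along(fams) * 10,
    family = fams, strand = strands))
}

test_that("collinear blocks respect the five-gene, order and strand rules", {
  fams <- sprintf("F%d", 1:5)
  a <- mkorder(fams, rep("+", 5), prefix = "a")
  b <- mkorder(fams, rep("+", 5), prefix = "b")
  bl <- find_collinear_blocks(a, b)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$size, 5)
  expect_equal(bl$orientation, "parallel")

  # four shared genes fall below the threshold
  a4 <- mkorder(fams[1:4], rep("+", 4), prefix = "a")
  b4 <- mkorder(fams[1:4], rep("+", 4), prefix = "b")
  expect_equal(nrow(find_collinear_blocks(a4, b4)), 0)

  # an inverted region is reported as an antiparallel block
  b_inv <- mkorder(rev(fams), rep("-", 5), prefix = "b")
  bl_inv <- find_collinear_blocks(a, b_inv)
  expect_equal(nrow(bl_inv), 1)
  expect_equal(bl_inv$orientation, "antiparallel")

  # strand disagreement in a parallel run breaks the chain
  b_bad <- mkorder(fams, c("+", "+", "-", "+", "+"), prefix = "b")
  expect_equal(nrow(find_collinear_blocks(a, b_bad)), 0)

  expect_error(gene_order(tibble::tibble(
    gene_id = c("x", "x"), scaffold = "s", start = 1:2,
    family = c("F1", "F2"), strand = "+")), "unique")
})

test_that("block finding is mirror-symmetric and matches the oracle", {
  n_checked <- 0
  for (seed in 1:60) {
    a <- random_gene_order(12, 4, seed, prefix = "a")
    b <- random_gene_order(12, 4, seed + 1000, prefix = "b")
    ga <- gene_order(a); gb <- gene_order(b)
    min_genes <- 3
    bl <- find_collinear_blocks(ga, gb, min_genes = min_genes)
    want <- oracle_blocks(ga$family, ga$strand, gb$family, gb$strand,
                          min_genes, 0)
    keys_got <- sort(vapply(seq_len(nrow(bl)), function(i) {
      block_key(match(bl$genes_a[[i]], ga$gene_id),
                match(bl$genes_b[[i]], gb$gene_id), bl$orientation[i])
    }, character(1)))
    keys_want <- sort(vapply(want, function(w)
      block_key(w$a_idx, w$b_idx, w$orientation), character(1)))
    expect_equal(keys_got, keys_want)
    n_checked <- n_checked + length(want)

    # mirror symmetry: (a, b) and (b, a) give the same pair sets
    bl_rev <- find_collinear_blocks(gb, ga, min_genes = min_genes)
    keys_rev <- sort(vapply(seq_len(nrow(bl_rev)), function(i) {
      pa <- match(bl_rev$genes_b[[i]], ga$gene_id)
      pb <- match(bl_rev$genes_a[[i]], gb$gene_id)
      o <- order(pa)
      block_key(pa[o], pb[o], bl_rev$orientation[i])
    }, character(1)))
    expect_equal(keys_rev, keys_got)
  }
  expect_gt(n_checked, 10)  # the random instances actually produced blocks
})

test_that("intra-genome mode excludes self-pairs and reports mirrors once", {
  fams <- c(sprintf("F%d", 1:5), "X", sprintf("F%d", 1:5))
  g <- mkorder(fams, rep("+", 11))
  bl <- find_collinear_blocks(g, g, min_genes = 5, self = TRUE)
  expect_equal(nrow(bl), 1)  # the duplicated run, reported once
  expect_equal(bl$size, 5)
  expect_false(any(mapply(identical, bl$genes_a[[1]], bl$genes_b[[1]])))
})

test_that("tandem arrays follow the intervening-gene parameter", {
  g <- mkorder(c("F", "F", "F", "G"), rep("+", 4))
  arr <- find_tandem_arrays(g)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$copy_number, 3)

  g2 <- mkorder(c("F", "X", "F"), rep("+", 3))
  expect_equal(nrow(find_tandem_arrays(g2, max_intervening = 0)), 0)
  arr2 <- find_tandem_arrays(g2, max_intervening = 1)
  expect_equal(arr2$copy_number, 2)

  g3 <- mkorder(c("A", "B", "C"), rep("+", 3))
  expect_equal(nrow(find_tandem_arrays(g3)), 0)
})

test_that("feature ratios reproduce the published genome-size comparison", {
  fr <- feature_ratio(1287259774, 740100732)
  expect_equal(round(fr$delta, 2), 1.74)
  expect_equal(feature_ratio(100, 100)$delta, 1)
  expect_equal(feature_ratio(100, 100)$log2_delta, 0)
  expect_equal(round(feature_ratio(6.32, 1)$log2_delta, 2), 2.66)
  expect_error(feature_ratio(10, 0), "positive")
})

test_that("family-size Fisher tests match exact enumeration with BH control", {
  counts <- matrix(c(3, 5, 0, 5), nrow = 2,
                   dimnames = list(c("fam1", "fam2"), c("ga", "gb")))
  res <- family_size_fisher(counts, totals = c(10, 10))
  expect_equal(res$p[1], 4 / 19, tolerance = 1e-9)  # = 0.21053 to 5 d.p.
  expect_equal(res$p[2], 1)  # symmetric family
  expect_equal(res$larger_in[1], "ga")

  # enumeration oracle over random tables
  for (seed in 1:100) {
    withr::with_seed(seed, {
      tot <- sample(20:50, 2)
      xa <- sample(0:tot[1], 1); xb <- sample(0:tot[2], 1)
    })
    p_pkg <- family_size_fisher(matrix(c(xa, xb), 1), totals = tot)$p
    expect_equal(p_pkg, oracle_fisher_p(xa, xb, tot[1], tot[2]),
                 tolerance = 1e-9)
  }

  # BH adjustment is monotone non-decreasing in p-value rank
  withr::with_seed(7, {
    cm <- matrix(rpois(40, 4), ncol = 2)
    rownames(cm) <- sprintf("f%02d", 1:20)
  })
  res2 <- family_size_fisher(cm, totals = c(200, 220))
  ord <- order(res2$p)
  expect_true(all(diff(res2$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res2$p >= 0 & res2$p <= 1))

  expect_error(family_size_fisher(matrix(c(30, 1), 1), totals = c(10, 10)),
               "exceeds")
})

test_that("Z-scores standardise rows with the population SD", {
  z <- zscore_matrix(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(unname(z[1, ]), (c(1, 2, 3) - 2) / sqrt(2 / 3))

  zc <- zscore_matrix(matrix(c(5, 5, 5, 1, 2, 3), nrow = 2, byrow = TRUE))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  expect_equal(attr(zc, "degenerate"), c(TRUE, FALSE))

  withr::with_seed(3, m <- matrix(runif(30), nrow = 5))
  zm <- zscore_matrix(m)
  expect_equal(unname(rowMeans(zm)), rep(0, 5))
  expect_equal(unname(sqrt(rowMeans(zm^2))), rep(1, 5))
})

test_that("GC3 and Nc follow Wright's estimator on constructed CDS", {
  # single synonymous codon GGG between start and stop: GC3 = 1
  res <- gc3_and_nc(c(g1 = "ATGGGGTAA"))
  expect_equal(res$gc3, 1.0)

  # one codon per amino-acid family, each family observed several times:
  # maximal bias, Nc = 20
  aas <- Biostrings::GENETIC_CODE
  sense <- aas[aas != "*"]
  fams <- split(names(sense), sense)
  one_per_fam <- vapply(fams, `[`, character(1), 1)
  cds <- paste0("ATG", paste(rep(unname(one_per_fam), 6), collapse = ""),
                "TAA")
  res20 <- gc3_and_nc(setNames(cds, "biased"))
  expect_equal(res20$nc, 20)

  # uniform usage within every family approaches Nc = 61
  withr::with_seed(12, {
    draw <- unlist(lapply(rep(names(fams), 120), function(aa)
      sample(fams[[aa]], 1)))
    cds_u <- paste0("ATG", paste(sample(draw), collapse = ""), "TAA")
  })
  res61 <- gc3_and_nc(setNames(cds_u, "uniform"))
  expect_gt(res61$nc, 55)

  # incomplete CDS are skipped with a warning
  expect_warning(out <- gc3_and_nc(c(bad = "ATGCCC", ok = "ATGGGGTAA")),
                 "skipped")
  expect_equal(out$gene, "ok")
  # internal stop codons disqualify a gene
  expect_warning(out2 <- gc3_and_nc(c(x = "ATGTAACCCTAA")), "skipped")
  expect_equal(nrow(out2), 0)
})
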