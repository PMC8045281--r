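test_that("root genome generation respects length, composition and seed", {
  asm <- generate_root_genome(1000, gc = 0.5, seed = 7)
  expect_s3_class(asm, "assembly")
  expect_equal(unname(nchar(asm)), 1000)

  pure_gc <- generate_root_genome(500, gc = 1.0, seed = 3)
  expect_true(grepl("^[GC]+$", unclass(pure_gc)))
  pure_at <- generate_root_genome(500, gc = 0.0, seed = 3)
  expect_true(grepl("^[AT]+$", unclass(pure_at)))

  # observed GC within 3 binomial standard deviations of the target
  big <- generate_root_genome(1e6, gc = 0.5, seed = 42)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(gc_content(big) - 0.5), sd3)

  expect_identical(generate_root_genome(2000, 0.4, seed = 9),
                   generate_root_genome(2000, 0.4, seed = 9))
  expect_false(identical(generate_root_genome(2000, 0.4, seed = 9),
                         generate_root_genome(2000, 0.4, seed = 10)))

  expect_error(generate_root_genome(0, 0.5, 1), "length")
  expect_error(generate_root_genome(100, 1.5, 1), "gc")
})

test_that("K2P evolution matches the closed-form p-distance and conserves length", {
  root <- generate_root_genome(50000, 0.5, seed = 11)

  # zero-length branches reproduce the root exactly
  flat <- evolve_along_tree(root, list(tree = "(A:0,B:0);", seed = 2))
  expect_identical(unclass(flat$A), unclass(root))
  expect_identical(unclass(flat$B), unclass(root))

  # two leaves at total path 0.02: observed mismatch within 3 SD of the
  # K2P expectation
  lv <- evolve_along_tree(root, list(tree = "(A:0.01,B:0.01);", kappa = 2,
                                     seed = 5))
  a <- utf8ToInt(unclass(lv$A)); b <- utf8ToInt(unclass(lv$B))
  p_obs <- mean(a != b)
  p_exp <- unname(k2p_expected_p(0.02, kappa = 2)["p"])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 50000))
  # substitution-only evolution conserves genome length
  expect_equal(nchar(lv$A), nchar(root))

  # a shallow cherry is closer within than to a deeper outgroup
  tr <- "((A:0.02,B:0.02):0.08,C:0.1);"
  lv3 <- evolve_along_tree(root, list(tree = tr, seed = 8))
  pd <- function(x, y) mean(utf8ToInt(unclass(x)) != utf8ToInt(unclass(y)))
  expect_lt(pd(lv3$A, lv3$B), pd(lv3$A, lv3$C))
  expect_lt(pd(lv3$A, lv3$B), pd(lv3$B, lv3$C))

  # determinism under a fixed seed
  lv_again <- evolve_along_tree(root, list(tree = "(A:0.01,B:0.01);",
                                           kappa = 2, seed = 5))
  expect_identical(lv, lv_again)

  expect_error(evolve_along_tree(root, list(tree = "not a tree;", seed = 1)),
               "tree")
})

test_that("planted features are consistent with the emitted truth table", {
  host <- generate_root_genome(60000, 0.5, seed = 21)

  # repeat copies at 0% divergence are identical to the family consensus
  pf <- plant_features(host,
                       repeats = list(family = "L1", class = "LINE",
                                      n_copies = 10, length = 400,
                                      divergence = 0),
                       seed = 3)
  tr <- pf$truth[pf$truth$kind == "repeat_copy", ]
  expect_equal(nrow(tr), 10)
  for (i in seq_len(nrow(tr))) {
    seg <- substr(unclass(pf$assembly)[[tr$scaffold[i]]], tr$start[i],
                  tr$end[i])
    if (tr$strand[i] == "-") seg <- revcomp(seg)
    expect_identical(seg, pf$consensus$L1)
  }

  # DinoSL upstream layout: the motif interval ends `offset` bp before the
  # gene start on the coding strand
  up <- plant_features(host,
                       dinosl = list(upstream = list(n = 1, offset = 40,
                                                     strand = "+")),
                       seed = 4)
  g <- up$genes[1, ]; t1 <- up$truth[1, ]
  expect_identical(t1$kind, "dinosl")
  expect_equal(g$start - t1$end - 1L, 40L)
  seg <- substr(unclass(up$assembly)[[t1$scaffold]], t1$start, t1$end)
  expect_identical(seg, DINOSL_MOTIF)

  upm <- plant_features(host,
                        dinosl = list(upstream = list(n = 1, offset = 25,
                                                      strand = "-")),
                        seed = 6)
  gm <- upm$genes[1, ]; tm <- upm$truth[1, ]
  expect_equal(tm$start - gm$end - 1L, 25L)
  seg <- revcomp(substr(unclass(upm$assembly)[[tm$scaffold]], tm$start,
                        tm$end))
  expect_identical(seg, DINOSL_MOTIF)

  # contaminant scaffolds are appended whole, at the requested length and GC
  cf <- plant_features(host,
                       contaminants = list(length = 20000, gc = 0.62,
                                           covered_fraction = 0.06),
                       seed = 5)
  ct <- cf$truth[cf$truth$kind == "contaminant_scaffold", ]
  expect_equal(nrow(ct), 1)
  cseq <- unclass(cf$assembly)[[ct$scaffold]]
  expect_equal(nchar(cseq), 20000)
  expect_lt(abs(gc_content(cseq) - 0.62), 3 * sqrt(0.62 * 0.38 / 20000))

  # determinism
  expect_identical(pf, plant_features(host,
                                      repeats = list(family = "L1",
                                                     class = "LINE",
                                                     n_copies = 10,
                                                     length = 400,
                                                     divergence = 0),
                                      seed = 3))
})

test_that("simulated reads have the expected count, content and determinism", {
  asm <- generate_root_genome(20000, 0.5, seed = 31)
  reads <- simulate_reads(asm, coverage = 10, read_len = 100, seed = 1)
  expect_lte(abs(length(reads) - 10 * 20000 / 100), 1)
  expect_true(all(nchar(reads) == 100))

  # error-free reads are exact substrings of the genome or its revcomp
  fwd <- unclass(asm)[[1]]; rev <- revcomp(fwd)
  some <- reads[seq(1, length(reads), by = 40)]
  expect_true(all(vapply(some, function(r) {
    grepl(r, fwd, fixed = TRUE) || grepl(r, rev, fixed = TRUE)
  }, logical(1))))

  expect_identical(reads, simulate_reads(asm, 10, 100, seed = 1))
  expect_error(simulate_reads(asm, 10, read_len = 30000, seed = 1),
               "read_len")

  # substitution errors make some reads inexact
  noisy <- simulate_reads(asm, coverage = 2, read_len = 100,
                          error_rate = 0.05, seed = 2)
  frac_exact <- mean(vapply(noisy[1:50], function(r) {
    grepl(r, fwd, fixed = TRUE) || grepl(r, rev, fixed = TRUE)
  }, logical(1)))
  expect_lt(frac_exact, 0.5)
})

test_that("synthetic hit tables mirror the planted truth", {
  host <- generate_root_genome(30000, 0.5, seed = 41)
  pf <- plant_features(host,
                       contaminants = list(length = 10000, gc = 0.62,
                                           covered_fraction = 0.06),
                       pseudogenes = list(n = 2, n_fragments = 2,
                                          fragment_length = 300, gap = 500,
                                          identity = 80),
                       seed = 7)

  ch <- make_hit_table(pf$truth, "contaminant")
  expect_true(all(ch$evalue <= 1e-20 & ch$bitscore >= 1000))
  covered <- sum(ch$qend - ch$qstart + 1)
  expect_lte(abs(covered - 0.06 * 10000), 1)

  ph <- make_hit_table(pf$truth, "pseudogene")
  expect_true(all(ph$pident == 80))
  expect_equal(nrow(ph), 4)  # 2 pseudogenes x 2 fragments
  minus <- ph$sstart > ph$send
  truth_minus <- pf$truth$strand[pf$truth$kind == "pseudogene"] == "-"
  expect_equal(sort(minus), sort(truth_minus))

  expect_equal(nrow(make_hit_table(empty_truth_tbl(), "contaminant")), 0)
  expect_error(make_hit_table(pf$truth, "nonsense"))
})
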