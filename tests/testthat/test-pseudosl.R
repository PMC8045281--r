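test_that("gene masking replaces exactly the annotated intervals with N", {
  asm <- assembly(c(s1 = strrep("A", 30)))
  genes <- tibble::tibble(gene_id = "g1", scaffold = "s1", start = 11,
                          end = 20, strand = "+")
  m <- mask_gene_regions(asm, genes)
  expect_equal(substr(unclass(m)[["s1"]], 11, 20), strrep("N", 10))
  expect_equal(substr(unclass(m)[["s1"]], 1, 10), strrep("A", 10))
  expect_equal(substr(unclass(m)[["s1"]], 21, 30), strrep("A", 10))

  expect_identical(mask_gene_regions(asm, genes[0, ]), asm)

  # overlapping genes mask the union once
  genes2 <- rbind(genes, tibble::tibble(gene_id = "g2", scaffold = "s1",
                                        start = 15, end = 25, strand = "-"))
  m2 <- mask_gene_regions(asm, genes2)
  expect_equal(unclass(m2)[["s1"]],
               paste0(strrep("A", 10), strrep("N", 15), strrep("A", 5)))

  genes3 <- tibble::tibble(gene_id = "g3", scaffold = "s1", start = 25,
                           end = 35, strand = "+")
  expect_error(mask_gene_regions(asm, genes3), "bounds")
})

mkfrag <- function(sstart, send, pident = 90, scf = "s1", prot = "p1") {
  tibble::tibble(qseqid = prot, sseqid = scf, pident = pident,
                 length = abs(send - sstart) + 1, mismatch = 0, gapopen = 0,
                 qstart = 1, qend = 10, sstart = sstart, send = send,
                 evalue = 1e-30, bitscore = 500)
}

test_that("pseudogene fragments merge by the gap and orientation rules", {
  # gaps 500 (merge) and 1400 (split)
  hits <- rbind(mkfrag(100, 400), mkfrag(900, 1200), mkfrag(2600, 2900))
  calls <- call_pseudogenes(hits)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$n_fragments, c(2L, 1L))
  expect_equal(calls$start, c(100L, 2600L))
  expect_equal(calls$end, c(1200L, 2900L))

  # opposite orientation never merges
  hits2 <- rbind(mkfrag(100, 400), mkfrag(1200, 900))
  calls2 <- call_pseudogenes(hits2)
  expect_equal(nrow(calls2), 2)
  expect_setequal(calls2$strand, c("+", "-"))

  # identity strictly below 75 is excluded entirely
  hits3 <- rbind(mkfrag(100, 400, pident = 74.9),
                 mkfrag(900, 1200, pident = 75))
  calls3 <- call_pseudogenes(hits3)
  expect_equal(nrow(calls3), 1)
  expect_equal(calls3$start, 900L)

  # merging is order-invariant
  perm <- rbind(mkfrag(2600, 2900), mkfrag(100, 400), mkfrag(900, 1200))
  expect_equal(call_pseudogenes(perm), calls)
})

test_that("merging equals the transitive-closure oracle on random instances", {
  for (seed in 1:200) {
    hits <- random_pseudo_hits(sample(2:20, 1), seed)
    calls <- call_pseudogenes(hits, min_identity = 75, max_gap = 1000)
    keep <- hits$pident >= 75
    frag <- tibble::tibble(
      scaffold = hits$sseqid[keep],
      start = pmin(hits$sstart, hits$send)[keep],
      end = pmax(hits$sstart, hits$send)[keep],
      strand = ifelse(hits$sstart <= hits$send, "+", "-")[keep])
    if (nrow(frag) == 0) {
      expect_equal(nrow(calls), 0)
      next
    }
    comp <- oracle_fragment_clusters(frag, 1000)
    expect_equal(nrow(calls), length(unique(comp)))
    # cluster hulls agree
    want <- sort(vapply(split(seq_len(nrow(frag)), comp), function(ii)
      paste(frag$scaffold[ii][1], frag$strand[ii][1], min(frag$start[ii]),
            max(frag$end[ii])), character(1)))
    got <- sort(paste(calls$scaffold, calls$strand, calls$start, calls$end))
    expect_equal(unname(got), unname(want))
  }
})

test_that("planted pseudogenes are each recovered as exactly one call", {
  host <- generate_root_genome(80000, 0.5, seed = 55)
  # fragments 600 bp apart merge into one call per planted pseudogene
  pf <- plant_features(host, pseudogenes = list(n = 4, n_fragments = 3,
                                                fragment_length = 300,
                                                gap = 600, identity = 80),
                       seed = 9)
  calls <- call_pseudogenes(make_hit_table(pf$truth, "pseudogene"))
  expect_equal(nrow(calls), 4)
  expect_true(all(calls$n_fragments == 3))

  # gaps wider than 1 kb split into the planted number of chains
  pf2 <- plant_features(host, pseudogenes = list(n = 3, n_fragments = 2,
                                                 fragment_length = 300,
                                                 gap = 1500, identity = 85),
                        seed = 10)
  calls2 <- call_pseudogenes(make_hit_table(pf2$truth, "pseudogene"))
  expect_equal(nrow(calls2), 6)
  expect_true(all(calls2$n_fragments == 1))
})

test_that("upstream DinoSL scanning recovers planted motifs with offsets", {
  host <- generate_root_genome(40000, 0.5, seed = 66)
  for (strand in c("+", "-")) {
    pf <- plant_features(host,
                         dinosl = list(upstream = list(n = 3, offset = 40,
                                                       strand = strand)),
                         seed = if (strand == "+") 11 else 12)
    hits <- scan_dinoSL_upstream(pf$assembly, pf$genes)
    # every planted gene has a perfect full-length hit at the planted offset
    perfect <- hits[hits$identity == 100 &
                      hits$end - hits$start + 1 == nchar(DINOSL_MOTIF), ]
    expect_setequal(perfect$gene_id, pf$genes$gene_id)
    expect_true(all(perfect$offset == 40))
    expect_true(all(perfect$strand == strand))
    # hit coordinates match the truth intervals
    tr <- pf$truth[pf$truth$kind == "dinosl", ]
    key_t <- paste(tr$scaffold, tr$start, tr$end)
    key_h <- paste(perfect$scaffold, perfect$start, perfect$end)
    expect_setequal(key_h, key_t)
  }
})

test_that("degenerate motifs with an exact core match the local-alignment oracle", {
  # motif with 2 substitutions outside a 9-base exact core
  motif <- DINOSL_MOTIF
  diverged <- motif
  substr(diverged, 2, 2) <- "T"   # C -> T
  substr(diverged, 20, 20) <- "C" # A -> C
  win <- paste0(strrep("T", 100), diverged, strrep("T", 80))
  asm <- assembly(c(s1 = paste0(win, strrep("G", 300))))
  genes <- tibble::tibble(gene_id = "g1", scaffold = "s1",
                          start = nchar(win) + 1, end = nchar(win) + 100,
                          strand = "+")
  hits <- scan_dinoSL_upstream(asm, genes, window = nchar(win))
  expect_equal(nrow(hits), 1)
  # the best local segment trims the flanking mismatches (score 17 beats
  # any segment that pays the -2 mismatch penalty), leaving a perfect core
  expect_equal(hits$identity, 100)
  expect_equal(hits$end - hits$start + 1, 17)

  # independent Smith-Waterman oracle with the same scoring
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(motif), Biostrings::DNAString(win),
    type = "local", substitutionMatrix = mat,
    gapOpening = 100, gapExtension = 100)
  sw_start <- Biostrings::start(Biostrings::subject(aln))
  sw_end <- Biostrings::end(Biostrings::subject(aln))
  expect_equal(hits$start, sw_start)
  expect_equal(hits$end, sw_end)
})

test_that("genome-wide scanning groups hits into tandem arrays", {
  host <- generate_root_genome(30000, 0.5, seed = 77)
  pf <- plant_features(host,
                       dinosl = list(tandem = list(n_arrays = 1, copies = 4,
                                                   spacing = 30)),
                       seed = 13)
  res <- scan_dinoSL_genome(pf$assembly)
  expect_gte(nrow(res$hits), 4)
  expect_true(any(res$arrays$copy_number == 4))

  # constructed case: two close hits plus one distant, same strand
  m <- DINOSL_MOTIF
  s <- paste0(strrep("A", 100), m, strrep("A", 40), m,
              strrep("A", 5000), m, strrep("A", 100))
  res2 <- scan_dinoSL_genome(assembly(c(s1 = s)))
  plus <- res2$arrays[res2$arrays$strand == "+", ]
  expect_setequal(plus$copy_number, c(2L, 1L))

  # no matches in a motif-free sequence
  res3 <- scan_dinoSL_genome(assembly(c(s1 = strrep("A", 2000))))
  expect_equal(nrow(res3$hits), 0)
  expect_equal(nrow(res3$arrays), 0)
})
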