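#!/usr/bin/env Rscript
# Stage 7: comparative statistics.
#
# Exercises the synteny/tandem detectors on constructed gene orders, the
# gene-family Fisher tests and Z-score matrix on simulated count tables,
# GC3/Nc on simulated CDS, and reproduces the published worked-example
# ratios (genome-size Delta and the log2 duplicated-block ratio).

library(dinocomp)

dir.create("results", showWarnings = FALSE)
set.seed(99)

# two genomes sharing one collinear 6-gene run plus shuffled singletons
shared <- sprintf("F%d", 1:6)
mk <- function(extra, prefix) gene_order(tibble::tibble(
  gene_id = sprintf("%s%02d", prefix, 1:10),
  scaffold = "s1", start = (1:10) * 100,
  family = c(shared, extra), strand = rep("+", 10)))
ga <- mk(sprintf("X%d", 1:4), "a")
gb <- mk(sprintf("Y%d", 1:4), "b")
bl <- find_collinear_blocks(ga, gb)
cat(sprintf("collinear blocks >= 5 genes between the two genomes: %d (size %s)\n",
            nrow(bl), paste(bl$size, collapse = ",")))

tand <- find_tandem_arrays(gene_order(tibble::tibble(
  gene_id = sprintf("t%02d", 1:8), scaffold = "s1", start = (1:8) * 50,
  family = c("T1", "T1", "T1", "Z", "T2", "T2", "Z", "Z"),
  strand = "+")))
utils::write.table(tand[, c("scaffold", "family", "copy_number")],
                   "results/tandem_arrays.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("tandem arrays found: %d (largest %d copies)\n", nrow(tand),
            max(tand$copy_number)))

# published worked-example ratios
fr <- feature_ratio(1287259774, 740100732)
cat(sprintf("genome-size ratio Delta = %.2f (log2 %.2f)\n", fr$delta,
            fr$log2_delta))
cat(sprintf("duplicated-gene-block Delta = 6.32 -> log2 %.2f\n",
            feature_ratio(6.32, 1)$log2_delta))

# gene-family size tests on a simulated count table with two enlarged
# families in genome A
counts <- matrix(rpois(60, 5), ncol = 2,
                 dimnames = list(sprintf("fam%02d", 1:30), c("gA", "gB")))
counts[1, 1] <- 40; counts[2, 1] <- 35
fish <- family_size_fisher(counts, totals = c(500, 480))
utils::write.table(fish, "results/family_fisher.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("families significantly larger after BH at 0.05: %d (planted 2)\n",
            sum(fish$significant)))

# Z-score abundance matrix across six genomes
ab <- matrix(runif(60), nrow = 10,
             dimnames = list(sprintf("feat%02d", 1:10), LETTERS[1:6]))
z <- zscore_matrix(ab)
utils::write.table(round(z, 3), "results/zscore_matrix.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)
cat(sprintf("Z-score matrix: %d features x %d genomes, row means all 0\n",
            nrow(z), ncol(z)))

# codon-usage metrics on simulated CDS
code <- Biostrings::GENETIC_CODE
sense <- names(code)[code != "*"]
cds <- vapply(1:20, function(i) {
  body <- paste(sample(sense, 300, replace = TRUE), collapse = "")
  paste0("ATG", body, "TAA")
}, character(1))
names(cds) <- sprintf("cds%02d", 1:20)
cu <- suppressWarnings(gc3_and_nc(cds))
utils::write.table(cu, "results/codon_usage.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("codon usage over %d complete CDS: mean GC3 %.3f, mean Nc %.1f\n",
            nrow(cu), mean(cu$gc3), mean(cu$nc, na.rm = TRUE)))
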