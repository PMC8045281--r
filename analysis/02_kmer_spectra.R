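#!/usr/bin/env Rscript
# Stage 2: k-mer spectrum analyses.
#
# Estimates genome size from the simulated read sets across k = 17..31,
# calls ploidy from the spectrum shape, and computes the distinct/unique
# k-mer diagnostic used to choose k for the alignment-free comparisons.

library(dinocomp)

read_fastq_seqs <- function(f)
  as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
reads_hap <- read_fastq_seqs("results/reads_haploid.fastq")
reads_dip <- read_fastq_seqs("results/reads_diploid.fastq")
truth_bp <- sum(nchar(unclass(read_assembly("results/genome_A.fasta"))))

ks <- seq(17, 31, by = 2)
est <- estimate_genome_size(lapply(ks, function(k)
  kmer_histogram(reads_hap, k)))
utils::write.table(est$per_k, "results/genome_size_per_k.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("mean genome-size estimate %.0f bp (truth %d bp, error %.2f%%)\n",
            est$mean_size, truth_bp,
            100 * abs(est$mean_size - truth_bp) / truth_bp))
cat(sprintf("assembled fraction at truth length: %.2f%%\n",
            assembled_fraction(truth_bp, est)))

h21 <- kmer_histogram(reads_hap, 21)
write_histogram(h21, "results/spectrum_haploid_k21.tsv")
pl_h <- assess_ploidy(h21)
h21d <- kmer_histogram(reads_dip, 21)
write_histogram(h21d, "results/spectrum_diploid_k21.tsv")
pl_d <- assess_ploidy(h21d)
cat(sprintf("ploidy calls: haploid reads -> %s; 1%%-het reads -> %s (peak ratio %.2f)\n",
            pl_h$call, pl_d$call, pl_d$ratio))

asm <- read_assembly("results/genome_A.fasta")
uc <- uniqueness_curve(asm, ks = seq(11, 31, by = 4))
utils::write.table(uc$per_k, "results/uniqueness_curve.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("unique-fraction plateau reached at k = %d\n", uc$suggested_k))
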