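#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A 150 kb ancestral genome is evolved along a known 6-taxon tree under the
# K2P substitution model; the focal genome additionally receives planted
# repeat families, pseudogene fragment chains, DinoSL motifs (upstream of
# genes and in a tandem array) and contaminant scaffolds, with every
# insertion recorded in a ground-truth table. Downstream stages test their
# recovery.

library(dinocomp)

dir.create("results", showWarnings = FALSE)
seed <- 42

tree_txt <- "((A:0.02,B:0.03):0.05,(C:0.04,D:0.02):0.06,(E:0.08,F:0.15):0.02);"
root <- generate_root_genome(150000, gc = 0.5, seed = seed)
leaves <- evolve_along_tree(root, list(tree = tree_txt, kappa = 2,
                                       seed = seed + 1))
for (nm in names(leaves))
  write_assembly(leaves[[nm]], file.path("results",
                                         sprintf("genome_%s.fasta", nm)))
writeLines(tree_txt, "results/true_tree.nwk")
cat(sprintf("evolved %d leaf genomes of %d bp from a common ancestor\n",
            length(leaves), nchar(root)))

# focal genome: plant features with known truth
pf <- plant_features(
  leaves$A,
  repeats = list(family = c("L1", "GYPSY1"), class = c("LINE", "LTR"),
                 n_copies = c(40, 25), length = c(400, 300),
                 divergence = c(20, 4)),
  pseudogenes = list(n = 6, n_fragments = 3, fragment_length = 250,
                     gap = 700, identity = 82),
  dinosl = list(upstream = list(n = 5, offset = 40),
                tandem = list(n_arrays = 1, copies = 4, spacing = 30)),
  contaminants = list(length = c(5000, 4000), gc = c(0.63, 0.40),
                      covered_fraction = c(0.10, 0.25)),
  seed = seed + 2)

write_assembly(pf$assembly, "results/focal_genome.fasta")
write_truth(pf$truth, "results/focal_truth.tsv")
utils::write.table(pf$genes, "results/focal_genes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(unlist(pf$consensus)),
  "results/focal_consensus.fasta")
write_hits(make_hit_table(pf$truth, "contaminant"),
           "results/focal_contaminant_hits.tsv")
write_hits(make_hit_table(pf$truth, "pseudogene"),
           "results/focal_pseudogene_hits.tsv")

cat(sprintf("planted %d features on the focal genome (%d scaffolds)\n",
            nrow(pf$truth), length(pf$assembly)))

# reads for the spectrum stage: haploid 30x and diploid 60x (1% het)
reads_hap <- simulate_reads(leaves$A, coverage = 30, read_len = 100,
                            seed = seed + 3)
write_reads_fastq(reads_hap, "results/reads_haploid.fastq")
reads_dip <- simulate_reads(leaves$A, coverage = 60, read_len = 100,
                            heterozygosity = 0.01, seed = seed + 4)
write_reads_fastq(reads_dip, "results/reads_diploid.fastq")
cat(sprintf("simulated %d haploid and %d diploid reads\n",
            length(reads_hap), length(reads_dip)))
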