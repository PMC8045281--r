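#!/usr/bin/env Rscript
# Stage 6: Kimura repeat landscape.
#
# Pairs every planted repeat copy with its family consensus, computes K2P
# divergences, and bins copy lengths into the per-class 0-50% landscape.
# The planted families (an old LINE family at 20% and a young LTR family
# at 4%) should appear as separate modes.

library(dinocomp)

asm <- read_assembly("results/focal_genome.fasta")
truth <- tibble::as_tibble(utils::read.table("results/focal_truth.tsv",
                                             header = TRUE, sep = "\t"))
cons <- as.character(Biostrings::readDNAStringSet(
  "results/focal_consensus.fasta"))
classes <- c(L1 = "LINE", GYPSY1 = "LTR")

copies <- repeat_copies_from_truth(asm, truth, as.list(cons),
                                   classes = classes)
land <- build_landscape(copies)
write_landscape(land, "results/repeat_landscape.tsv")

tot <- class_totals(copies,
                    genome_length = sum(nchar(unclass(asm))))
utils::write.table(tot, "results/repeat_class_totals.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(tot)
for (cl in rownames(land)) {
  mode_bin <- as.integer(colnames(land)[which.max(land[cl, ])])
  cat(sprintf("%s landscape mode at Kimura bin %d (%.0f bp total)\n",
              cl, mode_bin, sum(land[cl, ])))
}
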