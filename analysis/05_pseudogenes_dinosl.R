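#!/usr/bin/env Rscript
# Stage 5: pseudogene calling and DinoSL relict scanning.
#
# Masks the annotated gene models, merges the protein-vs-genome hit
# fragments into pseudogene calls (>= 75% identity, <= 1 kb gaps, same
# orientation), scans gene upstream regions for the spliced-leader motif,
# and locates genome-wide DinoSL copies and tandem arrays.

library(dinocomp)

asm <- read_assembly("results/focal_genome.fasta")
genes <- tibble::as_tibble(utils::read.table("results/focal_genes.tsv",
                                             header = TRUE, sep = "\t"))
truth <- utils::read.table("results/focal_truth.tsv", header = TRUE,
                           sep = "\t")

masked <- mask_gene_regions(asm, genes)
hits <- read_hits("results/focal_pseudogene_hits.tsv")
calls <- call_pseudogenes(hits)
utils::write.table(calls[, c("scaffold", "start", "end", "strand",
                             "n_fragments", "proteins")],
                   "results/pseudogene_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
n_planted <- length(unique(truth$label[truth$kind == "pseudogene"]))
cat(sprintf("pseudogenes: %d calls (%d fragments) from %d planted chains\n",
            nrow(calls), sum(calls$n_fragments), n_planted))

up <- scan_dinoSL_upstream(asm, genes)
utils::write.table(up, "results/dinosl_upstream.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("DinoSL upstream of genes: %d hits across %d genes\n",
            nrow(up), length(unique(up$gene_id))))

gen <- scan_dinoSL_genome(asm)
utils::write.table(gen$arrays, "results/dinosl_arrays.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
biggest <- if (nrow(gen$arrays)) max(gen$arrays$copy_number) else 0
cat(sprintf("genome-wide DinoSL: %d hits, largest tandem array %d copies\n",
            nrow(gen$hits), biggest))
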