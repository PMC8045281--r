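# dinocomp

Comparative genomics of highly divergent dinoflagellate (Symbiodiniaceae)
genomes, as one tested R package. Congeneric Symbiodiniaceae isolates can be
so diverged that whole-genome alignments cover under 2% of either genome;
`dinocomp` implements the computational stages a genome-divergence study
needs when alignment carries little signal, plus a synthetic-data forge so
every stage is testable against known ground truth without touching
multi-Gbp external datasets.

## What it computes

* **k-mer spectra** — canonical k-mer counting (C++ core, k ≤ 31, odd),
  genome-size estimation averaged over k = 17…31
  (size = retained k-mer instances / coverage peak), ploidy calls from
  spectrum shape (haploid / diploid / ambiguous), distinct-and-unique
  k-mer diagnostics for choosing k, assembled fraction.
* **Alignment-free phylogenetics** — D2S statistic over centred canonical
  k-mer counts under a strand-symmetric zero-order background;
  `d = −ln(D2S / √(D2S_XX · D2S_YY))`; distance matrices;
  Saitou–Nei neighbour joining (PHYLIP-style tie-breaks, negative branches
  clamped); similarity networks at thresholds on `10 − d`; inter-clade
  mean distances (δ).
* **Whole-genome similarity** — Q (percent of the query genome covered by
  alignment intervals, union semantics) and I (length-weighted mean
  identity of greedy reciprocal one-to-one alignments) from an aligner's
  coordinate dump.
* **Decontamination** — remove scaffolds < 1 kb; scaffolds with
  significant hits (E ≤ 1e-20, bitscore ≥ 1000) covering ≥ 5%; scaffolds
  > 100 kb with G+C ≤ 45% or ≥ 60%.
* **Pseudogenes and DinoSL** — merge protein-vs-genome fragments
  (≥ 75% identity, same strand, gaps ≤ 1 kb, transitive closure) into
  pseudogene calls on gene-masked assemblies; scan 500 bp upstream of
  genes and genome-wide for the 21-nt dinoflagellate spliced-leader motif
  (9-base exact seed, ≥ 80% identity) with tandem-array reporting.
* **Repeat landscapes** — Kimura-2-parameter divergence of repeat copies
  from family consensus, binned 0–50% per repeat class.
* **Comparative statistics** — collinear synteny blocks (≥ 5 genes, same
  order and orientation, antiparallel blocks flagged), tandem gene arrays,
  feature-length ratios (Δ, log2 Δ), two-sided Fisher exact tests on
  gene-family sizes with BH correction, Z-score abundance matrices
  (population SD), GC3 and Wright's effective number of codons (Nc).
* **Synthetic data** — root genomes, K2P evolution along a tree
  (exact per-branch substitution probabilities, κ configurable), planted
  repeats / pseudogenes / DinoSL motifs / contaminant scaffolds with a
  ground-truth table, uniform shotgun reads with errors and
  heterozygosity, synthetic 12-column hit tables.

## Worked example

The `analysis/` scripts chain the stages end-to-end on synthetic genomes
(run them in order from the repository root; outputs land in `results/`).
Stage 1 evolves six 150 kb genomes along a known tree and plants features
in the focal genome; the later stages recover them:

```sh
$ Rscript analysis/01_simulate.R
evolved 6 leaf genomes of 150000 bp from a common ancestor
planted 94 features on the focal genome (3 scaffolds)
simulated 45000 haploid and 90000 diploid reads

$ Rscript analysis/02_kmer_spectra.R
mean genome-size estimate 150729 bp (truth 150000 bp, error 0.49%)
ploidy calls: haploid reads -> haploid; 1%-het reads -> diploid (peak ratio 2.09)
unique-fraction plateau reached at k = 19

$ Rscript analysis/03_afree_phylo.R
NJ topology vs simulation truth: Robinson-Foulds distance 0
similarity network at T = 6: 9 of 15 possible edges
mean inter-clade distance delta(AB, EF) = 4.163

$ Rscript analysis/04_screen_decontaminate.R
removed 2 of 3 scaffolds (5.66% of assembled bases)
planted contaminants recovered exactly: TRUE

$ Rscript analysis/05_pseudogenes_dinosl.R
pseudogenes: 6 calls (18 fragments) from 6 planted chains
genome-wide DinoSL: 9 hits, largest tandem array 4 copies

$ Rscript analysis/06_repeat_landscape.R
LINE landscape mode at Kimura bin 20 (16000 bp total)
LTR landscape mode at Kimura bin 3 (7500 bp total)
```

Reading the numbers: the size estimate recovers the simulated 150 kb
genome to 0.5%; the diploid read set shows the half-coverage heterozygous
peak at ratio ≈ 2 of the homozygous peak; the neighbour-joining tree from
D2S distances matches the simulation topology exactly (RF = 0); the
screen removes exactly the two planted contaminant scaffolds; the six
planted three-fragment pseudogene chains merge back into six calls; and
the repeat landscape separates the old LINE family (planted at 20%
divergence) from the young LTR family (4%).

Published worked-example arithmetic is reproduced by the same functions,
e.g.:

```r
assembled_fraction(813744491, 1120150369)        # 72.65 (%)
feature_ratio(1287259774, 740100732)$delta       # 1.739 -> Delta = 1.74
kimura_distance(copy, cons)$K_percent            # 17.02 at P_ts=0.10, P_tv=0.05
```

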