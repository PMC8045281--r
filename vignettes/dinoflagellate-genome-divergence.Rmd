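---
title: "Methods: alignment-free comparative genomics of dinoflagellate genomes"
author: "dinocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free comparative genomics of dinoflagellate genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinocomp)
```

## Scope and design

Symbiodiniaceae are dinoflagellate microalgae with large (0.7–2 Gbp),
repeat-rich, intron-dense genomes whose divergence defeats many standard
comparative tools: whole-genome alignments between congeneric isolates can
cover under 2% of either genome, so alignment-based phylogenetics and
synteny-first comparisons carry little signal. `dinocomp` re-implements, as
one tested R package, the computational stages such a comparison needs:

* k-mer spectrum genome-size and ploidy estimation from short reads;
* alignment-free D2S phylogenetics (distance matrix, neighbour-joining
  tree, threshold similarity networks, inter-clade mean distances);
* pairwise whole-genome similarity metrics Q (query fraction aligned) and
  I (identity of reciprocal best one-to-one alignments) from an aligner's
  coordinate dump;
* scaffold decontamination by hit coverage, G+C content and length;
* pseudogene calling by protein-hit fragment merging, and detection of
  dinoflagellate spliced-leader (DinoSL) relicts;
* Kimura-2-parameter repeat divergence landscapes;
* collinear synteny blocks, tandem arrays, gene-family Fisher tests,
  Z-score abundance matrices, and codon-usage metrics (GC3, Nc).

Because the real inputs are multi-Gbp read sets and assemblies, the package
ships a synthetic-data module (`generate_root_genome()`,
`evolve_along_tree()`, `plant_features()`, `simulate_reads()`,
`make_hit_table()`) that builds genomes with *known ground truth*, so every
stage is validated by recovery tests at desk scale. The `analysis/`
directory of the source repository chains the stages into a worked
end-to-end study on synthetic genomes.

## The synthetic study system

`evolve_along_tree()` evolves an i.i.d. random ancestor along a tree whose
branch lengths are expected substitutions/site, using the exact Kimura
two-parameter (K2P) per-branch substitution probabilities

$$P_{ts}(b) = \tfrac14 + \tfrac14 e^{-4\beta b'} - \tfrac12 e^{-2(\alpha+\beta)b'},
\qquad P_{tv}(b) = \tfrac12 - \tfrac12 e^{-4\beta b'},$$

with $\alpha/\beta = \kappa$ (default 2) and $b'$ scaled so a branch of
length $b$ yields $b$ expected substitutions/site. We use the exact
exponential form rather than a Jukes–Cantor approximation because the
repeat-landscape stage must *recover* K2P divergences from the same model;
`k2p_expected_p()` exposes the closed-form expected p-distance used as the
oracle in tests. Optional indels, inversions and duplications are Poisson
events (geometric lengths, mean 3 bp for indels, ~5 kb for segmental
events); they default to 0 so that length is conserved and coordinates stay
interpretable.

`plant_features()` writes features *over* a same-length window of the host
scaffold (never splice-inserting), so coordinates of previously planted
features remain valid; placement is rejection-sampled to be non-overlapping
and fails loudly (`placement_failure`) when the plan cannot fit.
Contaminant scaffolds are appended whole, mirroring the decontamination
rule that removes whole scaffolds. Every insertion is recorded in a truth
table (kind, scaffold, 1-based inclusive interval, strand, label,
divergence). Coordinates are 1-based inclusive everywhere (GFF3
convention), and every stochastic operation takes an explicit `seed` and
runs under a private RNG (`withr::with_seed`), so identical calls are
byte-identical and the caller's RNG state is untouched.

`simulate_reads()` draws uniform single-end reads; heterozygosity $h$
duplicates the genome into two haplotypes differing at a fraction $h$ of
sites and samples both evenly, which is what produces the half-coverage
heterozygous peak that the ploidy caller looks for. Insert-size models,
long-read error profiles and codon-aware gene evolution are deliberately
out of scope.

What the generator does *not* emulate matters for interpretation: real
Symbiodiniaceae genomes have skewed base composition, nested and truncated
repeats, segmental duplications and assembly artefacts. Passing recovery
tests therefore demonstrates the *correctness of the algorithms under
their stated models*, not field performance on real assemblies.

## k-mer spectra, genome size and ploidy

`count_kmers()` counts canonical k-mers (the lexicographically smaller of
each window and its reverse complement) in C++, 2-bit encoding windows and
sorting the codes; k must be odd (canonicalisation is ill-defined for
palindromic even-k words) and at most 31 (62 bits). Windows containing N
are skipped.

For each k in 17, 19, ..., 31, `estimate_genome_size()` finds the error
cutoff as the first local minimum of the multiplicity distribution $f_m$
(1 if the distribution is not descending at $m=1$, i.e. no error tail),
takes the coverage peak as the modal multiplicity at or above the cutoff,
and estimates

$$\hat G = \sum_{m \ge \text{cutoff}} m\, f_m \;/\; m_{\text{peak}},$$

averaging $\hat G$ over k. The error tail below the cutoff is excluded
from the numerator: error k-mers would otherwise inflate the estimate, and
the peak-based coverage already excludes them from the denominator. On the
reference conditions (1 Mbp genome, 30-fold error-free reads of 100 bp)
the estimate lands within ~2% of truth; with 1% per-base read error,
within ~3% (both recomputed by `scripts/acceptance.R`). The residual bias
is peak quantisation: the true k-mer coverage $C(L-k+1)/L$ is rounded to
an integer multiplicity.

`assess_ploidy()` median-smooths the spectrum (window 3, robust to
single-bin noise), keeps local maxima at least 10% the height of the
tallest peak, and calls *diploid* when exactly two peaks have a coverage
ratio within [1.8, 2.2] ("exactly or approximately twofold") and the minor
peak is at least 10% of the major; one peak is *haploid*; anything else is
*ambiguous*, which is a valid call, not an error. `uniqueness_curve()`
reports distinct and unique k-mer fractions per k and suggests the
smallest k where the unique-fraction gain drops below `plateau_tol`
(default 0.01/step) — the diagnostic behind choosing k = 21 for the
alignment-free comparisons. The proportions are computed on assemblies
(the spectrum-vs-assembly choice is configurable simply by what you pass
in).

## D2S distances, trees and networks

For genome X with total k-mer count $n_X$ and strand-symmetric zero-order
base probabilities, counts are centred as
$\tilde X_w = X_w - n_X\,(p(w) + p(\bar w))$ and combined over the union
of the two profiles' words:

$$D_2^S(X,Y) = \sum_w \frac{\tilde X_w \tilde Y_w}
{\sqrt{\tilde X_w^2 + \tilde Y_w^2}},\qquad
S = \frac{D_2^S(X,Y)}{\sqrt{D_2^S(X,X)\,D_2^S(Y,Y)}},\qquad
d = -\ln S.$$

Words absent from both profiles are skipped (0/0 terms contribute 0), and
$S$ is floored at `epsilon` (default 1e-9) before the log so anti-correlated
profiles stay finite. The package's normalisation
$d = -\ln(S)$ is a design choice: it is self-normalising (d(X,X) = 0
exactly), unbounded on a log scale, and compatible with the similarity
transform $10 - d$ used for the networks, where published distances of
roughly 4–8 map to similarities 2–6. Published distance tables from other
implementations are therefore not asserted numerically; all validation is
property-based (identity, symmetry, monotonicity with simulated
divergence, and tree recovery).

`neighbor_joining()` is a classic Saitou–Nei implementation with PHYLIP
Neighbor's lowest-index tie-break for reproducibility; negative branch
lengths are clamped to 0 in the returned tree with the raw lengths kept in
`attr(tree, "raw_edge.length")`. On additive matrices it reproduces path
lengths to numerical precision (checked against `ape::cophenetic.phylo`,
with `ape::nj` as an independent topology cross-check). Under the
reference conditions (six 200 kb genomes, branch lengths 0.02–0.15, k=21)
the D2S + NJ pipeline recovers the true topology (Robinson–Foulds 0) in
20/20 replicates.

## Q and I from alignment coordinates

Running a whole-genome aligner is out of scope; `parse_coords()` consumes
its nine-column coordinate dump (S1 E1 S2 E2 LEN1 LEN2 %IDY REF QRY),
normalising reversed query intervals to orientation "−". Q is the
percentage of the query genome covered by the union of query intervals, so
it is invariant to duplicated or reordered records. The one-to-one filter
is greedy by score = query-aligned-length × identity (delta-filter-like
and deterministic; ties by reference coordinate), and I is the
length-weighted mean identity of the kept records — weighting prevents
many short high-identity fragments from dominating; the unweighted
per-alignment mean is available via `weighted = FALSE`. An empty
one-to-one set signals `undefined_identity` rather than returning 0.

## Decontamination rules

`screen_assembly()` applies, in order: remove scaffolds shorter than
1000 bp; remove scaffolds whose significant hits (E ≤ 1e-20 and bit score
≥ 1000) cover ≥ 5% of their length; remove scaffolds longer than 100 kb
with G+C ≤ 45% or ≥ 60% (boundaries inclusive as stated; the length bound
strict). G+C is computed over unambiguous bases only. Each removed
scaffold carries exactly the first rule that triggered, and the report
partitions the input. On randomized synthetic plans with margins clear of
the thresholds, exactly the planted contaminant scaffolds are removed in
50/50 plans.

## Pseudogenes and DinoSL relicts

`mask_gene_regions()` Ns out annotated gene intervals so pseudogene calls
cannot overlap gene models. `call_pseudogenes()` keeps protein-vs-genome
fragments with ≥ 75% identity, splits them by scaffold and genomic strand
(subject coordinate order encodes strand), sorts by start and chains by
single linkage with a running maximum end: a fragment joins the chain when
its start is within `max_gap` (1 kb) of the furthest end seen, so touching
or overlapping fragments always merge and the result equals the
transitive closure of the pairwise gap predicate (verified against a
brute-force closure oracle on 1000 random instances). Merging is
order-invariant by construction.

The DinoSL scan emulates a word-size-9 nucleotide search for the 21-nt
spliced-leader motif (the ambiguous leading base excluded): within up to
500 bp 5′ of each gene start on the coding strand (windows truncated at
scaffold edges, not discarded), exact 9-mer seeds anchor ungapped
extensions scored +1/−2, the best local segment is kept (Kadane over the
aligned columns), and hits must contain a ≥ 9-base exact run and reach
≥ 80% identity over the reported span. The 80% default is a package
choice (the upstream search tool's identity behaviour is not specified
beyond the word size) and is fully configurable. Tests check the reported
spans against a Smith–Waterman oracle (`Biostrings::pairwiseAlignment`)
under the same scoring. Genome-wide, full-length motif copies (both
strands, ≤ 4 mismatches ≈ the same 80%) are grouped into tandem arrays
when same-strand neighbours lie within `array_gap` (500 bp); singletons
report copy number 1.

## Repeat landscapes

`kimura_distance()` compares aligned copy/consensus strings over columns
where both carry an unambiguous base (gaps and N excluded from numerator
and denominator) and evaluates
$K = -\tfrac12 \ln\!\big((1 - 2P_{ts} - P_{tv})\sqrt{1 - 2P_{tv}}\big)$.
Saturated alignments (non-positive log argument) are flagged and capped at
50%. `build_landscape()` bins each copy's ungapped length into integer
percent bins [0,1)…[49,50) per repeat class — the RepeatMasker-style
landscape convention — with saturated copies in the top bin. No CpG
adjustment is applied (the plain two-parameter distance is the reference
behaviour; a future flag is reserved). Simulated copies at true divergence
t ∈ {5, 10, 20, 30}% recover mean K within 3 standard errors over 200
copies.

## Comparative statistics

`find_collinear_blocks()` enumerates *all maximal* chains of
family-matched gene pairs that advance monotonically on both genomes with
at most `max_gap` intervening genes per side (default 0, the literal
"same order and orientation" definition; a gap parameter exposes
MCScanX-like tolerance). Parallel chains require strand agreement at every
pair; antiparallel chains (inversions) reverse order and flip strands and
are reported with their orientation rather than silently merged. Blocks
shorter than `min_genes` (default 5) are discarded; in intra-genome mode
trivial self-pairs are excluded and mirrored blocks reported once.
Exhaustive-path enumeration can in principle blow up on pathological
inputs with massively duplicated families; at realistic gene orders
(and in all oracle tests) it is cheap. The implementation is checked
against an independent recursive enumeration on 500+ random instances.

`family_size_fisher()` delegates to `stats::fisher.test` (two-sided) per
family with `p.adjust(method = "BH")` across families — these are exactly
the hypergeometric tail-sum and step-up procedure, verified against direct
`dhyper` enumeration. `zscore_matrix()` standardises each feature row with
the *population* standard deviation (divisor n): the genome set is the
entire population under comparison, not a sample from one. Degenerate
(constant) rows return zeros and are flagged rather than NaN.

`gc3_and_nc()` restricts to complete CDS (ATG start, terminal stop, no
internal stop, length divisible by 3; others are skipped with a warning).
GC3 is the G+C fraction at third positions of synonymous codons (Met, Trp
and stops excluded). Nc is Wright's estimator: per amino acid,
$\hat F = (n\hat S - 1)/(n - 1)$ with $\hat S$ the sum of squared codon
frequencies; $\hat F$ is averaged within degeneracy classes (9 twofold, 1
threefold, 5 fourfold, 3 sixfold under the standard code), a missing
threefold class is interpolated as the mean of the two- and fourfold
averages, and $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped to [20, 61].

## Numerical choices and degenerate inputs

* k-mer counting: sort-and-run-length rather than hashing — deterministic,
  cache-friendly, and profiles come out lexicographically sorted.
* Spectrum smoothing: running median, window 3; if smoothing erases an
  isolated spike entirely the raw spectrum is used for peak detection.
* D2S: terms with zero denominator contribute 0; non-positive
  self-statistics raise `degenerate_input`; d is clamped at ≥ 0 against
  floating-point drift on near-identical profiles.
* NJ ties: strictly-better comparison with a 1e-12 guard keeps the lowest
  index pair, matching PHYLIP Neighbor.
* Fisher enumeration tolerance: tables with probability within a 1e-7
  relative factor of the observed one count as "as extreme" (the standard
  guard against floating-point equality).
* Empty inputs return typed empty tibbles (hits, calls, arrays, networks)
  rather than NULL; undefined statistics signal classed conditions.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 1 Mbp genomes at 30-fold
coverage for size recovery; 300 kb at 60-fold (1% heterozygosity) for
ploidy; six 200 kb genomes × 20 replicates for tree recovery; 1000, 500,
500 and 50 randomized instances for the pseudogene, synteny, Fisher and
screening oracles; 200 copies × 4 divergence depths for Kimura recovery.
These sizes are the package's reference study conditions, chosen so the
peaks, distances and recovery rates they probe are statistically
well-resolved.

## Known limitations

* The D2S background model is zero-order; higher-order Markov backgrounds
  (sometimes used for alignment-free comparison) are not implemented.
* The spectrum model is not a full mixture fit (no GenomeScope-style
  error/heterozygosity decomposition); calls outside clean one- or
  two-peak shapes are `ambiguous` by design.
* The one-to-one filter is greedy, not an optimal interval scheduling —
  intentionally, to mirror common delta-filter behaviour.
* Synteny detection assumes unique gene ids and start-coordinate order;
  family inference itself (orthology) is an input, not a product.
* The pseudogene caller counts merged calls and fragments; it does not
  classify source families or validate reading frames.
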