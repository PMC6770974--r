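---
title: "Methods behind famevo: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind famevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevo)
```

famevo reimplements, as one tested toolkit, the analysis stages of a
genome-wide gene-family survey of the kind applied to the soybean laccase
(multicopper oxidase) family: identify the family from domain architecture,
place it on a phylogeny, type its duplication history, classify its
expression patterns, and scan for domestication sweeps over it. This
vignette explains the models and rules each stage applies, the parameters
that matter, and the choices made where the procedure was genuinely open.

## Family identification

A locus belongs to the family iff at least one of its transcripts carries
all three Cu-oxidase Pfam-style domains (Cu-oxidase, Cu-oxidase_2,
Cu-oxidase_3), each hit at E-value at or below `1e-5`, and that transcript
has a complete coding sequence. "Complete" is operationalized as: starts
with ATG, ends with a stop codon, no internal stop, length divisible by
three. Domain hits are consumed from a generic one-hit-per-row TSV rather
than any particular search tool's native output; running the HMM/BLAST
search itself is out of scope. When several transcripts of one locus
qualify, the longest peptide is kept, with ties broken by the
lexicographically smallest transcript id — the source study removed
multi-transcript redundancy without stating a rule, so determinism was the
deciding criterion here.

Protein properties use standard formulas: molecular weight is the sum of
average residue masses plus one water (18.0153 Da); the isoelectric point is
solved by bisection on the Henderson–Hasselbalch net charge using the EMBOSS
pKa set (N-term 8.6, C-term 3.6; K 10.8, R 12.5, H 6.5; D 3.9, E 4.1,
C 8.5, Y 10.1). Published pKa tables differ (ExPASy's Bjellqvist set gives
systematically different values), so pI values are comparable across tools
only as ranges, never digit for digit. Bisection converges to a net charge
below `1e-4` well within 100 iterations for any peptide, which the test
suite asserts as a property.

Coordinates are 1-based inclusive on disk (GFF3) and converted at the
boundaries; all window arithmetic downstream is 0-based half-open, which
keeps the sliding-window bookkeeping free of off-by-one cases.

## Phylogeny and class assignment

Distances come from an existing peptide alignment (computing the alignment
is out of scope). The default is the uncorrected p-distance on
complete-deletion columns — columns without a gap in any row, matching the
"conserved sites" convention of desktop phylogeny tools; pairwise deletion
and a Poisson correction are available behind flags. The class assignment
downstream depends only on tree topology, not on the distance scale, which
is why the simplest defensible model is the default.

The neighbor-joining implementation is the standard Saitou–Nei
agglomeration on the Q-criterion with two deliberate conventions:

* **Determinism.** Q-ties (within `1e-12`) are broken by the
  lexicographically smallest pair of cluster labels, a cluster being
  labelled by its smallest member taxon. Every run of every function in the
  package is reproducible byte for byte given its inputs and seed.
* **Negative branches.** A negative branch length is clamped to zero and
  the deficit transferred to the sibling edge, the usual practice; path
  lengths through the join are preserved, so additive matrices are still
  reproduced exactly. The test suite checks exact topology and path-length
  recovery on random additive matrices up to 12 taxa against an
  independently constructed generating tree, and cross-checks topologies
  against `ape::nj`.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports for each internal edge the percentage
of replicates containing the same bipartition (counted with
`ape::prop.clades`, unrooted). The seed is mandatory; resampling touches
columns only, so supports are invariant under taxon reordering.

Class labels propagate from reference leaves (e.g. the Arabidopsis laccase
set with its published class structure): after midpoint rooting, each
unlabeled leaf takes the class of the smallest enclosing clade that
contains at least one reference, provided all references in that clade
agree; otherwise the leaf is `unresolved`. Midpoint rooting was chosen
because the original figure's rooting is unstated; the rule never invents a
class absent from the reference set.

## Duplication typing, Ka/Ks and dating

Collinear (synteny) blocks are chained on gene *ranks*, not base pairs:
within a chromosome pair, anchors (homology hits at E ≤ 1e-5) are chained
by a maximum-weight strictly monotone chain (layered dynamic program,
weight = summed bit score) allowing rank gaps of at most 25 in both
genomes, in both orientations. Chains with at least 5 anchors are reported;
when chains could share anchors the heaviest wins and the remainder may
form further blocks, so no hit is used twice. The layering matters: the
program maximizes weight *subject to* the minimum-anchor count, so a heavy
short chain cannot mask a valid five-anchor block. An exhaustive-search
oracle over all anchor subsets verifies the chain on instances up to 15
hits.

Tandem duplicates are family members on one chromosome separated by at most
one non-family gene, taken as the union of all linked clusters of size two
or more. Segmental duplicates are family members anchored in a block whose
matched anchor is also a family member; the matched pairs are the
"collinear family pairs" carried forward to Ka/Ks and expression
comparison.

Ka/Ks uses the Nei–Gojobori (1986) counting method, chosen because the
source study used an external calculator without naming its model and NG86
is the classical, fully specifiable estimator; exact agreement with a
model-averaging calculator is explicitly not a goal. Per codon, each
position contributes the fraction of its non-stop single-nucleotide changes
that are synonymous (changes creating stop codons are excluded from
numerator and denominator); site counts are averaged over the two
sequences. Differences between codons are averaged over all minimal
mutational pathways with equal weights; pathways through a stop codon are
discarded, and only if every pathway is discarded are all pathways used
with stop-crossing steps counted as nonsynonymous. Codons containing gaps,
ambiguity characters or stops in either sequence are skipped pairwise, not
end-trimmed. Proportions are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − 4p/3). A saturated rate (p ≥ 3/4) yields `Inf` with a
warning rather than an error: on very short toys a single synonymous change
can sit exactly on the boundary and the meaningful statements (Ka = 0,
ω = 0) survive the infinity.

Ks bins map pairs to whole-genome duplication events with half-open
intervals, boundary to the older event: [0, 0.3) *Glycine*-genus WGD,
[0.3, 1.5) legume WGD, ≥ 1.5 the gamma event. Dating uses the molecular
clock T = Ks/(2λ) with λ = 6.1e-9 synonymous substitutions per site per
year, reported in Mya; λ's units are taken as per synonymous site per year,
the usual convention where a source states only "clocklike rate".
Percentages in summaries are rounded half-up to one decimal; note that
42/93 = 45.16% therefore prints as 45.2.

## Expression classification

All rules operate on FPKM matrices (genes × samples).

* **High/constitutive**: a gene is high iff its across-sample mean is at
  least 3× the grand mean of the matrix (every gene × sample entry). The
  grand mean can be supplied externally when the matrix at hand is a
  subset of the genome-wide table it was calibrated on.
* **Tissue specificity** is formalized as the tau index,
  τ = Σᵢ(1 − xᵢ/x_max)/(n − 1), with a call of `specific` at τ ≥ 0.85 and
  peak ≥ 10 FPKM. τ was chosen over a max/second-max ratio because it
  tolerates one secondary tissue with moderate signal — the published
  organ-specific set includes genes with exactly that profile (a pod gene
  with stem signal; a root gene with nodule signal), and the packaged
  printed table reproduces every published specific call under τ while a
  ratio rule fails some of them.
* **Inactive**: below 1 FPKM in every sample (a sample at exactly the floor
  is active). Conventional, configurable.
* **Infection response**: per time point
  L_t = log2((FPKM_t + 0.001)/(FPKM_0 + 0.001)) against the 0 h baseline;
  induced iff max L_t ≥ +1 and min L_t > −1, suppressed symmetrically, both
  → mixed, neither → unchanged. Genes never reaching 0.5 FPKM are
  unchanged regardless, since the pseudocount can otherwise turn noise on a
  silent gene into huge fold changes. The threshold comparison carries a
  1e-3 tolerance so that an exact k-fold change, pushed infinitesimally
  under the threshold by the pseudocount, is still called. The source study
  stated no numeric rule for its induced/suppressed sets; these thresholds
  are not claimed to reproduce its exact counts on the real data.
* **Pair divergence**: Pearson correlation of log2(FPKM + 1) across
  samples, `similar` at r ≥ 0.5; constant rows are `distinct` unless both
  are constant and equal. This, too, is a formalization the source lacks.
* **2^−ΔΔCt** is the textbook computation against a reference gene and a
  control condition.

## Diversity scan and sweep calling

SNPs are filtered on the combined panel — missingness ≤ 10% of alleles and
minor allele frequency ≥ 5% — before any population split. The study
filtered before splitting too, but the order within its pipeline is
ambiguous; combined-panel filtering is the documented choice here.

Windows are 20 kb sliding by 10 kb, half-open, truncated at chromosome
ends. Per site with n called alleles split n_a/n_b the unbiased
heterozygosity is h = n/(n−1)·(1 − (n_a/n)² − (n_b/n)²); window π sums h
over contained sites and divides by the window *span* in bp, so
monomorphic positions count as zero diversity (the common windowed-π
convention; the source does not specify its tool's edge handling, and no
claim of identity is made). Diploid genotypes contribute both alleles;
half-missing calls contribute their called allele. An explicit
pairwise-difference oracle (sum over all allele pairs of per-site
mismatches over C(n,2), divided by span) is algebraically identical and the
suite asserts agreement to 1e-12.

The scan statistic is the ratio π_cultivated/π_wild per window — low values
mark diversity lost under domestication. Windows with π_wild = 0 get an
undefined ratio and never enter rankings. Two comparisons are reported per
gene: against the chromosome baseline (arithmetic mean of that chromosome's
defined ratios, the gene's region ratio being the mean over its overlapping
windows), and against the genome-wide lowest-5% window set. The 5% cut is
implemented as the largest ratio value whose cumulative frequency does not
exceed the quantile, ties included at or below it; this reduces to "the 20
lowest of 400 windows" for continuous ratios while handling the degenerate
all-tied case sensibly (under massive ties at the minimum — e.g. many
zero-diversity windows — the minimum is used and the selected fraction can
exceed 5%). A gene is sweep-selected iff any overlapping window is in the
set. The accession tree over selected gene regions uses 1 − IBS
(identity-by-state over fully called shared sites) and the same NJ engine.

## The synthetic data and what it does (not) show

Every input the pipeline consumes can be generated with ground truth
(`simGenome`, `simExpression`, `simPopulation`, `simulateBundle`), so every
stage is testable without downloads. The generator's defaults are the study
conditions the package targets:

* a genome of 4 chromosomes × 1 Mb × 150 genes with a 40-member family,
  planted tandem arrays (sizes 3, 2, 2, 3), three 6-anchor duplicated
  segments, decoy loci carrying only one or two domains, and a fraction of
  family loci with a second, shorter transcript;
* family CDS of 450 codons evolved along a five-class tree (between-class
  Ks 0.8, within-class 0.15, ω 0.2) by per-site proposals where synonymous
  changes are always accepted, nonsynonymous ones with probability ω, and
  stops never — acceptance-thinning rather than a full codon rate matrix,
  which is sufficient to validate a counting estimator but does not model
  transition/transversion bias or codon-usage effects;
* nine-tissue and five-timepoint FPKM tables with planted
  constitutive-high, tissue-specific (τ ≥ 0.9 by construction), inactive,
  induced and suppressed genes under multiplicative lognormal noise
  (sdlog 0.1);
* a 62 wild + 240 cultivated accession panel: wild allele frequencies from
  a truncated 1/f spectrum scaled to π = 0.003/bp, cultivated frequencies
  derived by 20 generations of Wright–Fisher drift at size 30 (a
  domestication bottleneck leaving π_cult/π_wild ≈ 0.7), and three planted
  80 kb sweep regions with an extra 10-fold heterozygosity reduction;
  genotypes sampled per accession with 2% missingness plus a 2% fraction of
  high-missingness sites that exercise the filter.

This is frequency-level simulation, not a coalescent: there is no linkage
disequilibrium, no recombination map, no demography beyond the single
bottleneck, and sites are independent. Passing the recovery experiments
therefore shows the *rules* behave as specified on data with the planted
signal structure — it does not show how the pipeline behaves under LD,
population structure, or annotation errors in real resequencing panels.
Genome-scale published figures (93 members, class sizes 15/13/8/8/49, 85
collinear pairs, 10 sweep genes) require the real genome, infection
RNA-Seq, and the 302-accession panel, none of which are packaged; the
package instead reproduces the study's worked numbers from its printed
counts and validates each algorithm against independent oracles.

Problem sizes used by the test suite and the acceptance script — 200
random additive matrices (≤ 12 taxa), all 61 × 61 sense-codon pairs, 20
CDS-pair simulations at 500 codons, 10 sweep-scan and 10 expression-recovery
seeds, one full end-to-end run — were chosen so the whole suite completes
in a few minutes on a single core while keeping every estimate's Monte
Carlo error well inside the asserted margins.

## Known limitations

* pI values depend on the pKa table; only ranges are comparable to other
  tools' output.
* NG86 with equal pathway weighting underestimates ω when
  transition/transversion bias is strong; the generator is bias-free, so
  recovery there is calibrated but real-data estimates inherit NG86's known
  behaviour.
* The chaining DP scores chains by summed bit score only; it does not
  reimplement MCScanX's full scoring, and dot-plot style diagnostics are
  out of scope.
* The sweep scan is a π-ratio method; haplotype statistics (XP-EHH,
  XP-CLR), Tajima's D and association testing are out of scope.

## A short worked run

```{r, eval = FALSE}
dir_in <- tempfile(); dir_out <- tempfile()
simulateBundle(dir_in, simConfig(), seed = 1)
report <- runAll(runConfig(dir_in, dir_out, seed = 1))
report$family_size        # 40 planted members recovered
report$duplication$bins   # WGD-bin counts over the collinear pairs
report$sweep$n_selected   # genes over the lowest-5% ratio windows
```
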