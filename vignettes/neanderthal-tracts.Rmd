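---
title: "Detecting and dating Neanderthal ancestry tracts in ancient genomes"
author: "ntracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating Neanderthal ancestry tracts in ancient genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntracts)
```

# Scope and model overview

`ntracts` implements the population-genetic analysis chain used to
characterize archaic (Neanderthal) ancestry in low-coverage ancient human
genomes: authentication and quality control of ancient-DNA fragments,
f-statistics with block-jackknife uncertainty, direct f4-ratio estimation of
genome-wide archaic ancestry, admixture-graph fitting, hidden-Markov-model
detection of ancestry tracts in genetic-map coordinates, maximum-likelihood
dating of a recent Neanderthal ancestor from long tract lengths, and
permutation tests of tract overlap with introgression deserts.

Real capture data sets of this kind are hundreds of gigabytes; the package
is validated instead against its own synthetic-data module, which generates
inputs with the statistical structure every stage assumes. This vignette
records the models, the default parameters and why they were chosen, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

# The synthetic-data generator

## Allele frequencies on an admixture graph

`simulateGraphFrequencies()` draws a root allele frequency uniformly on
[0.05, 0.95] per SNP and propagates it down a directed acyclic graph. A
drift edge of length f resamples the child frequency from a Beta
distribution with mean p and variance f, so the edge length *is* the edge's
realized f2 (mean squared frequency difference) and, by the law of total
variance, f2 is exactly additive along drift paths — the property the
f-statistic and graph-fitting tests rely on. A proper Beta requires
variance < p(1 − p), so the variance is capped at 0.9 p(1 − p); the cap
slightly compresses drift at frequencies near the boundaries, which is why
additivity tests use a Monte-Carlo tolerance rather than exact equality.
Admixture nodes mix parent frequencies linearly,
p = α p₁ + (1 − α) p₂.

## Pedigree recombination

`simulatePedigreeTracts()` models one haplotype of a diploid individual as
the end product of `g` successive meioses descending from a fully
Neanderthal ancestor, using the Haldane (no-interference) model: crossovers
are a Poisson process at 1 per 100 cM with a uniform start phase. The first
meiosis acts on a fully Neanderthal diploid, so it creates no ancestry
boundaries; `g − 1` meioses do. Consequences worth knowing:

* the expected diploid genome fraction of recent Neanderthal ancestry is
  2^−g (each meiosis halves the expectation, and the carrier is one of two
  haplotypes);
* interior tract lengths are approximately exponential with mean
  100/(g − 1) cM, shortened by chromosome-end truncation — direct
  simulation on a human-scale 3,500-cM map gives a mean of about 17.2 cM at
  g = 6. The *inference* model used for dating (below) uses mean 100/g;
  the discrepancy between the two conventions is within the uncertainty the
  profile likelihood reports at realistic segment counts, and the coverage
  experiments in the test suite confirm near-nominal interval coverage.

Both haplotypes additionally carry "background" introgression from a
stationary two-state Markov process with stationary fraction `alpha_bg`
(default 0.02) and mean Neanderthal tract length 100/`T_bg` cM. The default
background age `T_bg` = 2,000 generations corresponds to the shared
introgression pulse at roughly 50–60 kyr ago under a 25-year generation
time (the package's only use of a generation time, and a default, not an
inference); background tracts then average 0.05 cM and essentially never
reach the 5-cM threshold used for dating, which is the point of that
threshold.

## Reads

`simulateReads()` emulates capture data over a SNP panel: per-SNP depth is
Poisson with mean `coverage` (halved on the X for males); each read is a
present-day contaminant with probability `contamination` (allele drawn from
the contaminant population frequency, never deaminated) or endogenous from
a uniformly chosen haplotype. Haplotype alleles are drawn once per
individual (`simulateGenotypes()`, seeded from the truth set) so repeated
"libraries" of one individual share a genome. Sequencing error flips
alleles with probability `error`. Terminal cytosine deamination marks
appear at distance k from either fragment end with probability
δ·ρ^(k−1)·P(reference C) (defaults δ = 0.3, ρ = 0.5,
P(ref C) = 0.25), and a C (forward strand) or G-read-as-A (reverse strand)
at the SNP itself is damage-flipped with the positional probability — the
substrate for damage masking. Fragment lengths are 35 + geometric with mean
55 bp.

Panels come in two ascertainments: `"archaic"` (Neanderthal-African fixed
differences, African frequency Beta(0.5, 9), Neanderthal Beta(9, 0.5)),
emulating archaic-admixture capture arrays and used for tract detection;
and `"modern"` (common polymorphisms, Beta(0.7, 0.7)), used for identity
and contamination work where heterozygosity carries the signal. The default
marker density for simulations, 50 SNPs/cM, is a deliberate scale-down of
real archaic panels (~500 SNPs/cM) chosen so that a full-genome simulation
decodes in seconds while leaving ~2.5 informative SNPs per 0.05-cM bin —
enough that detection operates in the same information regime
(tens of reads per centiMorgan) as 2× capture data.

What the generator does *not* emulate: linkage disequilibrium between panel
SNPs within a population (frequencies are drawn independently per SNP),
library-specific damage profiles, mapping bias, and reference bias. Tests
passing on this generator therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to those real-data
pathologies.

# Ancient-DNA quality control

**Deamination filter.** `filterDeaminated()` keeps fragments with a C-to-T
substitution in the first and/or last k positions (inclusive OR, k = 3 by
default) — the standard authentication filter. The fragment table stores
the position of the nearest terminal substitution (`ct5_pos`/`ct3_pos`), so
other window widths remain computable.

**Pseudo-haploid calling.** `pseudohaploidCall()` samples one read per
covered SNP (seeded and deterministic), requiring base quality ≥ 30 and
masking damage-consistent alleles — T on forward-strand reads and A on
reverse-strand reads — within 5 bp of either fragment end. The masking
window (5) is deliberately wider than the authentication window (3): the
former guards genotypes against damage, the latter merely certifies a
fragment as ancient. Both are configurable.

**Contamination.** Two estimators:

* `estimateContaminationDeam()` uses the fact that contaminant molecules
  are not deaminated: the 5'-terminal C-to-T rate over all fragments,
  r_u, is depressed by the contaminant fraction relative to the same rate
  among fragments already deaminated at the 3' end (r_c, all endogenous),
  giving ĉ = 1 − r_u/r_c. The estimate averages both end orderings; the SE
  is a binomial delta-method combination. The method assumes deamination at
  the two ends is independent within a molecule; the conditioning subset is
  small (a minority of fragments are deaminated at a given end), so at
  20,000 fragments the sampling SE is several percentage points — recovery
  to ±0.05 is what the validation asserts.
* `estimateContaminationX()` applies to males only (single X): X reads
  should match the site consensus up to error, and excess mismatch tracking
  the contaminant-population allele frequency is attributed to
  contamination. The (c, e) likelihood is maximized with L-BFGS-B and the
  SE taken from the observed information. Fewer than 50 informative sites
  flags the estimate low-confidence.

These are stated replacements for the published estimators they emulate,
formulated from the descriptions available; they are not line-by-line
reimplementations of those tools.

**Sex.** `determineSex()` compares per-site fragment rates on the X and the
autosomes; the X/autosome ratio is ~0.5 in males and ~1 in females. The
binomial CI on the fragment split is transformed to the ratio scale; a male
call requires the whole CI below 0.6, a female call above 0.8, otherwise
unresolved — at very low coverage the honest answer is "unresolved", and
the validation requires zero *errors*, not zero unresolved calls.

**Identity.** `pairwiseMismatchRate()` compares two pseudo-haploid call
sets: two samplings of one individual disagree only at heterozygous sites
(rate ≈ H/2), unrelated individuals at about twice that. The default
verdict threshold 0.18 is a midpoint between those cohort baselines on
common-polymorphism panels and is configurable because it is
panel-dependent; with fewer than 500 shared sites the verdict is
"inconclusive".

# f-statistics

Per-SNP contributions: f2 = (p_i − p_j)², f3 = (p_c − p_a)(p_c − p_b),
f4 = (p_a − p_b)(p_c − p_d), and D with the ABBA–BABA denominator
(p_a + p_b − 2p_a p_b)(p_c + p_d − 2p_c p_d). D and the f4-ratio are
ratios of sums over SNPs, not means of ratios. Finite-sample
heterozygosity corrections p(1 − p)/(n − 1) are applied by default to f2
(both populations) and f3 (the target population); f4 and D are unbiased
without correction. For a population observed on a single chromosome
(pseudo-haploid individuals) the correction is undefined and dropped —
such f2/f3 values retain a small upward bias, which is why the f4-ratio
(correction-free) is the estimator of choice for ancestry proportions in
pseudo-haploid ancients.

A SNP enters a statistic only if all populations in that statistic are
non-missing there (listwise per statistic), and all statistics are
invariant under SNP reordering.

**Weighted block jackknife.** Blocks are fixed 5-Mb physical windows
anchored at position 0 on each chromosome — the paper-standard size; fixed
anchoring makes the block layout deterministic. The SE uses the
Busing-style weighted delete-one-block jackknife with block weights equal
to SNP counts, which reduces exactly to the unweighted formula for equal
blocks; the test suite checks it against a brute-force leave-one-out oracle
to 1% and calibrates |Z| ≥ 3 rates at ≤ 2% on null simulations.

**f4-ratio.** α = f4(A, O; X, C)/f4(A, O; B, C) over the SNPs shared by
all five populations, with the jackknife run on the ratio. In the intended
design A and B are two high-coverage archaic genomes (Altai and Vindija
roles), O and C two African populations and X the test individual; the
population roles are arguments, not hard-coded names. The result is
flagged unreliable when the denominator has |Z| < 3. The 95% CI is
α ± 1.96 SE.

# Admixture-graph fitting

Expected statistics under a graph follow the standard path formalism:
`lineageWeights()` gives the probability a lineage sampled in a leaf
traverses each edge (admixture nodes split flow by their proportions), and
expected f2(i, j) = Σ_e ℓ_e (w_i(e) − w_j(e))², with f3/f4 derived from
the f2 identities. The fitted basis is the outgroup-f3 set
f3(O; i, j) over all pairs of non-outgroup leaves, including i = j (which
is f2(O, i) and receives both populations' sampling corrections); its
covariance comes from the block jackknife, regularized by adding
10⁻⁶·mean(diag) to the diagonal because jackknife covariances at modest
block counts are noisy.

Fitting is a nested optimization: free drift lengths by non-negative
generalized least squares (Cholesky-whitened design solved with NNLS), free
admixture proportions by a deterministic grid over [0, 1] in steps of 0.02
followed by golden-section refinement, coordinate-descent when several are
free. The root-to-outgroup edge cannot be separated from the root's other
child edge by this basis and is fixed to 0 by convention; other
rank-deficiencies (e.g. unbranched internal chains) are detected by a QR
rank check and flagged `identifiable = FALSE`, with a ridge-stabilized
fallback solve so a fit is still reported.

Model diagnostics follow the worst-residual convention: every f2, f3 and
f4 combination of the leaves is compared between observation and fitted
expectation, standardized by the observed statistic's jackknife SE, and
the largest |Z| summarizes the fit. A caveat: the residual SE is that of
the observed statistic, not of the observed-minus-fitted difference, which
is conservative for statistics close to the fitted basis. With five or
fewer leaves and an admixture the basis barely overdetermines the
parameters; misfit detection in the tests therefore uses the full residual
table, which includes f4 combinations that are not linear images of a
well-fitting basis when the topology is wrong.

# Tract detection HMM

Detection operates on fixed genetic-distance bins (default 0.05 cM) so that
the transition process is homogeneous in recombination units. The hidden
state is the number of Neanderthal haplotypes (0, 1, 2); transitions
factorize over two independent haplotype chains, each a two-state Markov
process with stationary Neanderthal fraction F (default 0.03) and switch
intensity τ per cM (default 0.05, i.e. an a-priori tract scale of 20 cM);
the three-state chain is the exact lumping of the product chain, and its
stationary law is Hardy–Weinberg in F. Emissions are per-read:
P(derived | k) = c·p_cont + (1 − c)[(1 − e)q_k + e(1 − q_k)] with
q_k = (k/2)p_nea + (1 − k/2)p_afr, summed over the reads in a bin.
Per-read emissions ignore that reads at one SNP sample the same two
haplotypes — a documented approximation that overstates evidence at high
depth; at the ≤5× depths intended here its effect is small. The model is a
deliberately reduced relative of read-based archaic-ancestry callers: no
per-library contamination, no Denisovan third source, no parameter
re-estimation — c and e are supplied (typically from the QC module).

Decoding is forward–backward in log space; the forward and backward total
log-likelihoods agree to 10⁻⁶ as an internal consistency check, and
posteriors are renormalized per bin. Probabilities inside emissions are
floored at 10⁻³⁰⁰ so impossible configurations yield large negative
log-likelihoods rather than −Inf. Segments are maximal runs of bins with
P(k ≥ 1) ≥ 0.9; runs separated by less than one bin are merged; segments
shorter than 0.2 cM are discarded (the reporting cutoff; threshold, bin
width and cutoff are all arguments). Segment bp coordinates are obtained
by inverse interpolation of the genetic map. When fragments carry
deamination, `mask_k = 5` applies the same damage-masking rule as
pseudo-haploid calling to the read counts, since the emission model does
not model damage.

Two practical notes from validation. First, called segments are diploid
unions: truth tracts on both haplotypes, or nearby tracts on one, merge
into single called segments. Length-weighted precision and recall against
planted tracts exceed 0.99 at 2× coverage with 5% contamination, but the
*partition* into segments is coarser than the truth, which propagates into
dating (below). Second, increasing coverage monotonically improves recall
in the tested 0.5–5× range.

# Dating the most recent Neanderthal ancestor

Tract lengths from an ancestor g generations back are modelled i.i.d.
exponential with mean 100/g cM. Left-truncation at t (default 5 cM)
leaves the excesses exponential with the same mean by memorylessness, so
ĝ = 100·n / Σ(ℓ_i − t), with log-likelihood
L(g) = n·log(g/100) − (g/100)·Σ(ℓ_i − t), strictly concave in g. The
5-cM threshold excludes the old background: under the default background
model a background tract exceeds 5 cM with probability e^−100. The
likelihood deliberately uses lengths only — the *number* of long segments
depends on detection power and the background mixture, so a count term
(optional, not default) would import those nuisances.

The default 95% interval is the profile likelihood (drop of 1.92 log-units,
grid g ∈ [1, 200] step 0.01, open ends flagged at the grid edges). A
parametric percentile bootstrap is provided as an alternative; at the
segment counts a single genome yields (often 1–4), percentile intervals of
a scale parameter undercover (measured ~83% against a nominal 95% at
g = 7), so the profile interval is the recommended one — its measured
coverage is ≥ 90% at g ∈ {4, 7, 12} in the end-to-end experiments.

Because called segments are diploid unions (see above), dating from called
segments is biased toward fewer, longer tracts — i.e. toward smaller ĝ —
relative to dating from per-haplotype truth lengths. The profile interval
at the small n involved is wide enough that coverage survives; users
comparing individuals should hold the detection settings fixed across them.

# Overlap and desert statistics

`ancestryVector()` reduces a segment set to a binary indicator over a
shared registry of fixed 100-kb windows; `overlapCorrelation()` computes
the Pearson correlation of two such vectors with a percentile CI from a
block bootstrap over 5-Mb blocks of windows (windows are autocorrelated on
the scale of tract lengths, so i.i.d. bootstrap would be anticonservative).
Group contrasts use the two-sided Wilcoxon rank-sum test (exact for small
tie-free samples, normal approximation with tie and continuity correction
otherwise), which matches exhaustive enumeration for group sizes ≤ 5 in
the tests.

`desertOverlapTest()` measures the total bp of segments inside desert
regions and compares it with a null in which each segment is independently
re-placed uniformly within the *callable portion of its own chromosome*.
Placement happens in concatenated callable coordinates, which preserves
each segment's bp length exactly (the conservation property the tests
assert) and sidesteps the fit problem in fragmented callable regions; a
within-chromosome scheme preserves chromosome-level segment budgets, which
a genome-wide scheme would not. Depletion is the tested direction:
p = (1 + #\{null ≤ observed\}) / (1 + n_perm), so p is never 0 and equals
1 in degenerate configurations (no deserts, or deserts covering
everything). Under a random-segment null the p-value is approximately
uniform provided the overlap statistic is effectively continuous; when
most datasets have zero observed overlap the discrete atom makes the test
conservative (a property of permutation p-values, not a defect), which is
why the calibration experiment uses segment and desert sizes large enough
to avoid the atom.

# Problem sizes used in validation

The test suite runs entirely on synthetic data at sizes chosen to exercise
each property at meaningful statistical resolution: 10,000-SNP oracle
comparisons; 200 null panels of 20,000 SNPs for Z calibration; 100
f4-ratio replicates at 100,000 SNPs; 50 graph-fit replicates at 100,000
SNPs; full-genome (3,500-cM) pedigree simulations, 200 per generation
count for interval coverage; tract detection on 600–900-cM genomes at 50
SNPs/cM; 200 desert datasets at 199 permutations. `scripts/acceptance.R`
runs one complete pipeline pass (a 22-chromosome individual at 2×
coverage plus the frequency-level experiments) and writes every headline
quantity it computes to JSON.

# Known limitations

* No linkage disequilibrium in simulated frequencies; detection power on
  real, LD-structured panels will differ.
* The emission model ignores within-individual read correlation and
  damage; damage is handled by masking, not modelling.
* Contamination estimators assume end-independence of deamination
  (conditional method) and a single X (X method).
* The graph fitter searches admixture proportions on a grid per admixture
  node with coordinate descent; many simultaneous free admixtures may need
  more starts than the deterministic default provides.
* Residual Z uses the observed statistic's SE, not the SE of the residual.
* Dating assumes a single recent ancestor and exponential tract lengths;
  called-segment merging biases ĝ downward when tracts are clustered.
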