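---
title: "Models and methods behind mthapnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mthapnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthapnet)
```

`mthapnet` implements the statistical chain of a worldwide mtDNA
control-region survey: harmonize an alignment into a fixed
reference-coordinate window, collapse it into haplotypes, classify the
haplotypes into two deep haplogroups by diagnostic motifs, and then
quantify diversity, demographic history, hierarchical structure and
network topology. This vignette explains the models, the tunable
parameters and the design decisions, in the order the pipeline applies
them.

## Coordinates and harmonization

All positions are 1-based coordinates on a designated reference
sequence; windows are inclusive on both ends. The default analysis
window is positions 15476–15749 — the 274-bp hypervariable segment of
the donkey control region that published datasets share — and
`trim_to_window()` maps alignment columns to reference coordinates via
a reference row in the alignment (columns where the reference is
gapped carry no coordinate and are dropped). `drop_indel_columns()`
then removes every column containing a gap in any sequence, so that
all downstream statistics operate on a gapless fixed-width matrix;
both operations are idempotent.

In `site_summary()`, `N` and IUPAC ambiguity characters are treated as
missing when deciding site classes, following common practice of
diversity software. For multi-allelic columns the counting rule is a
documented package decision (the field's tools do not publish theirs):
a column with *k* distinct observed bases contributes *k* − 1
substitutions, each classified as transition or transversion against
the column's majority base, with majority ties broken towards the
alphabetically first base. The rule is isolated in one function so an
alternative convention is a one-line change.

## Haplotypes, motifs and the "intermediate" call

Haplotypes are exact string classes (sequences containing `N` merge
only with identical strings — wildcard merging would silently inflate
frequencies). Names are frequency-ranked within haplogroup
(`A001` = the most frequent haplogroup-A haplotype), with ties broken
by lexicographic sequence order, which makes naming invariant to input
order.

Haplogroup classification is motif-based: for each haplogroup the
match fraction is computed over *informative* motif positions (present
in the window, unambiguous base). A single complete match
(fraction ≥ `complete_floor`, default 1.0) assigns the label; two
haplogroups both reaching the partial floor (default 0.5) without any
complete match yield `intermediate`; everything else is `unassigned`.

The default motif set deserves a note. Eleven positions separate the
two haplogroup core haplotypes, but a motif built from *all* eleven
with complementary states makes the intermediate rule undecidable: a
chimera's two match fractions always sum to 1, so "both ≥ 0.5" would
require an exact even split that eleven positions cannot produce. The
published signature of an intermediate haplotype is the combination of
two key *triplets* (15484/15490/15503 carried from one haplogroup,
15599/15645/15667 from the other), so the default motifs cover those
six positions per haplogroup; a chimera then matches each haplogroup
at 3/6 and is flagged. The base states at these positions are not
published: the defaults are synthetic states consistent with the
package's simulator and are intended for simulated data and as a
configuration template (`read_motifs()`), not as empirical claims.
One published position list prints 15667 where a later passage prints
15669; the default uses 15667 (the value in the 11-position list) and
either can be supplied in configuration.

## Diversity statistics

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{N}{N-1}\bigl(1 - \sum_i p_i^2\bigr)$, which equals the
probability that two individuals drawn without replacement carry
different haplotypes (the test suite checks this by exhaustive
enumeration over every frequency spectrum with $N \le 8$). Groups with
a single haplotype report a missing marker rather than 0, matching the
reporting convention of published summary tables.

Nucleotide diversity is
$\pi = \frac{N}{N-1}\sum_{i<j} 2 f_i f_j d_{ij} / L$ with haplotype
frequencies $f$, pairwise difference counts $d$ and the *fixed*
number of retained positions $L$. Missing data are handled by pairwise
deletion (sites where either sequence is ambiguous are skipped for
that pair) while $L$ stays fixed — GenBank records containing `N`
should not deflate diversity asymmetrically. A `complete` deletion
switch removes every column containing any ambiguity first, for
comparison with software that does so; which convention the published
worldwide values used is not stated, so both are available.

## Mismatch distributions and the sudden-expansion model

The observed mismatch distribution enumerates all $\binom{N}{2}$
sample pairs (haplotype counts expanded, matching how population
packages treat samples). The sudden-expansion model describes a
population at equilibrium $\theta_0$ that expanded to $\theta_1$
(default $\infty$) at mutational time $\tau = 2ut$ before present. Its
machinery reduces to a coalescence-time mixture: the equilibrium
distribution is geometric,
$\hat F_i(\theta) = \theta^i / (1+\theta)^{i+1}$, and with
$\theta_1 = \infty$ the transient distribution is the convolution of
$\hat F(\theta_0)$ with a Poisson($\tau$) pulse. For finite $\theta_1$
the pair may coalesce during the post-expansion phase; integrating the
truncated exponential coalescence time gives an incomplete-gamma term,

$$F_i = \hat F_i(\theta_1)\,P(i{+}1, \tau\tfrac{1+\theta_1}{\theta_1})
      + e^{-\tau/\theta_1} \sum_{j=0}^{i}
        \mathrm{Pois}(j;\tau)\,\hat F_{i-j}(\theta_0),$$

which the tests verify against both analytic limits
($\theta_1 \to \infty$ and $\tau \to 0$). Mass beyond the observed
maximum is folded into the last cell, so observed and expected vectors
share a support and both sum to one.

Fitting minimizes the sum of squared deviations over
$(\tau, \theta_0)$ with `stats::optim` (L-BFGS-B, parameters bounded
below by 0) from several moment-based starts — the model mean is
$\tau + \theta_0$ — keeping the best optimum. Goodness of fit uses a
parametric bootstrap: samples of the observed size are simulated under
the fitted model with the package's coalescent, refitted, and the
simulated SSD and raggedness values form the null distributions, with
$P = (b+1)/(B+1)$. The τ confidence interval is the 2.5–97.5%
percentile interval of the refitted τ values, widened if necessary to
contain the point estimate. Replicates default to 1000 in the
function; the pipeline default is 100 (its report is regenerable with
any count). A degenerate observation with all mass at zero differences
fits $\tau = 0$ with a warning.

Harpending's raggedness index is the sum of squared successive
differences of the mismatch frequencies with the distribution padded
by a zero cell on *both* sides (so a point mass scores 2 and a uniform
distribution over $0..k$ scores $2/(k+1)^2$); the leading term is
included deliberately — conventions differ in the literature, and this
one is pinned by the package's worked examples.

## Fu's Fs

$S'$ is the exact probability of observing at least the sampled number
of haplotypes under the Ewens sampling distribution at
$\theta = \hat\pi$ (the observed mean pairwise differences):
$\Pr(K = k) = |s(N,k)|\,\theta^k / \prod_{i=0}^{N-1}(\theta+i)$, with
unsigned Stirling numbers of the first kind computed entirely in log
space (the row for $N = 1392$ is far beyond double range), and
$F_s = \ln\bigl(S'/(1-S')\bigr)$. P-values come from neutral
constant-size coalescent simulation at the same $\theta$, each
replicate scored with its own haplotype count and mean pairwise
difference, $P = \Pr(F_s^{sim} \le F_s^{obs})$; replicates that are
degenerate (one haplotype or zero diversity) take $F_s = +\infty$ and
so never count towards significance. Following the statistic's
original convention, significance is conventionally claimed at
$P < 0.02$; the package reports P and leaves the threshold to the
user.

## Expansion time

$t = \tau / (2u)$ with $u = \mu \cdot g \cdot L$ the mutation rate per
sequence per generation. Defaults: $\mu = 6.13\times10^{-8}$
substitutions/site/year, $g = 8$ years, $L = 274$ sites. In years the
generation interval cancels, $t_{years} = \tau/(2\mu L)$, which the
tests assert. All three constants are arguments: published expansion
ages depend on this scaling, and surveys differ in the $\mu$ they
adopt.

## AMOVA

Variation is partitioned over one or two hierarchical levels from
sums of squares of (squared-convention) pairwise distances — for
haplotype data the pairwise difference count itself plays the role of
$d^2$, following the framework the method was defined in. Variance
components use the expected-mean-square coefficients for unbalanced
sizes; Φ-statistics are the usual ratios
($\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$ at two levels).
Negative components are reported as-is with a warning rather than
truncated, matching common AMOVA output. Permutation P-values use the
standard per-level schemes — samples among populations within groups
(Φ_SC), whole populations among groups (Φ_CT), samples among all
populations (Φ_ST) — with $(b+1)/(B+1)$; 10000 permutations by
default in the function, 200 in the pipeline report. Note that the
population-level Φ_CT test is resolution-limited when few populations
exist (the permutation space is the set of arrangements of populations
into groups). In the pipeline's two-level design, populations are
nested as haplogroup:region units because every region hosts both
haplogroups.

The tests validate the engine against an independent route: Hamming
difference counts equal squared Euclidean distances of one-hot encoded
sequences (scaled by $1/\sqrt 2$), so every sum of squares can be
recomputed as centroid deviations in that embedding, and the exact
decomposition $SS_{total} = SS_{AG} + SS_{AP} + SS_{WP}$ must hold.

## Median-joining networks

`build_mjn()` iterates: (1) an ε-relaxed minimum spanning network over
the current node set (an edge of weight $w$ is kept iff its endpoints
are disconnected by edges of weight $< w - \varepsilon$; with
$\varepsilon = 0$ this is the union of all minimum spanning trees);
(2) for each triple of nodes spanned by adjacent links, quasi-medians
(per-column majority state, branching over all resolutions of
three-way ties, restricted to the triple's segregating columns, with
the candidate set bounded on pathological input); candidates are added
one at a time, in lexicographic order, whenever they strictly reduce
the minimum-spanning-tree cost of the node set — so total network
length never increases; (3) repeat to a fixpoint; (4) remove obsolete
median vectors (degree ≤ 2 and on no shortest connection between
observed haplotypes). Determinism comes from sorted candidate
processing and lexicographic edge tie-breaks; the suite rebuilds a
network from 20 shuffled input orders and requires identical output.

Position weights (default 1 everywhere) raise the cost of mutations at
recurrent positions and thereby discourage cross-links; published
networks use hand-tuned weights whose values are not available, so
weights are a configuration input. The maximum-parsimony
post-processing step of the original network software is out of scope.

## Consensus calling and QC thresholds

`call_consensus()` consumes per-position base counts that are assumed
base-quality filtered upstream (the conventional filter is quality
≥ 20): depth < 5 (or an absent position) gives `N`; a second base at
≥ 0.15 of the passing depth gives the two-base IUPAC code (the
comparison is ≥, "reaching" the threshold); otherwise the majority
base. Exclusion thresholds derive from the Tukey boxplot upper whisker
(largest observation ≤ Q3 + 1.5·IQR) of the per-sequence metric
distributions; whiskers are quartile-method sensitive, so the method
is pinned to linear interpolation between order statistics (R type 7)
and documented. The published procedure arrived at thresholds of 5
missing positions for clade A, 12 for clade B, and 5 heteroplasmies
for both; `filter_sequences()` defaults to those values and is
monotone in all thresholds. Reference-choice effects are compared with
two-sided Wilcoxon rank-sum tests per metric. Read mapping itself is
out of scope: the module consumes count tables, and each pileup is
tagged with the reference its coordinates refer to (lift-over between
references is not attempted).

## What the synthetic generator emulates — and what it does not

`simulate_two_haplogroup_dataset()` emulates the structure the
analyses assume: two founder haplotypes separated by the 11 diagnostic
positions; within-haplogroup samples from a coalescent with
instantaneous size change (star-like for small θ₀); regional sample
sizes and haplogroup-A percentages defaulting to the published
worldwide survey's regional table (13 regions, 1392 samples,
%A from 19% to 92%), with largest-remainder rounding; and truth tables
sufficient to verify every downstream statistic without re-simulation.

Two generator choices matter for interpretation:

* **Time scale.** τ defaults (1.6 for A, 0.8 for B, θ₀ = 0.1/0.05)
  were set once from the published within-haplogroup nucleotide
  diversities (mean pairwise differences ≈ 1.7 and ≈ 0.9 over 274 bp).
  They are *diversity*-calibrated, not calibrated to the published
  expansion ages; converted through `expansion_time()` they give ages
  older than the published kya values, whose underlying τ estimates
  are not available. Conclusions about the time conversion should use
  the conversion function directly.
* **Mutation model.** A pure infinite-sites star at these rates would
  scatter almost every private mutation into its own haplotype,
  producing ~4× more haplotypes than real data show. Real
  control-region variation concentrates in a few transition-biased
  hotspots, so within-haplogroup mutations default to a finite-sites
  model: 10 hotspot columns per haplogroup (disjoint between
  haplogroups and from the diagnostic positions) with deterministic
  transition toggling, which reproduces the observed ratio of
  haplotypes to samples (~115–135 haplotypes from 1392) and overall
  haplotype diversity (~0.83). The cost is a smaller variable-site
  count (~31 versus 65 in real data) and the absence of
  transversions and between-haplogroup homoplasy. Passing tests on
  these data therefore demonstrate correctness of the statistics, not
  realism of every feature of real alignments; `n_hypervariable =
  NULL` restores infinite-sites mutation when that is preferable.

`simulate_expansion_sample()` measures time in mutational units (pair
coalescence hazard $1/\theta$, branch mutation rate $1/2$), so the
model mean pairwise difference is exactly $\tau + \theta_0$ — a
property the suite checks by Monte-Carlo. If the realized mutation
count exceeds the available columns the generator falls back to
finite sites (columns drawn with replacement) and flags it.

## Numerical and reproducibility choices

* All stochastic functions take explicit integer seeds; the pipeline
  derives stage seeds from the single configured seed and records them
  in the manifest, and reruns are byte-identical.
* P-values are $(b+1)/(B+1)$ throughout; bootstrap/permutation tie
  comparisons use a $10^{-12}$ tolerance so exact ties count.
* Ewens probabilities, the geometric mismatch term and Fs are computed
  in log space; the Stirling row is memoized across the simulation
  loop.
* Distance matrices are computed as BLAS cross-products of indicator
  matrices (valid-site mass minus equal-site mass), which keeps the
  1392-sample pipeline run in minutes on one CPU.
* Degenerate inputs have pinned conventions: zero-variance AMOVA gives
  Φ = 0 with permutation P ≈ 1; single-haplotype groups report missing
  diversity; all-mass-at-zero mismatch fits τ = 0 with a warning;
  Fu's Fs is undefined (NA) for one haplotype or zero diversity.

## Problem sizes used by the test suite

The suite exercises the full-size synthetic survey (1392 samples)
through the simulator tests, and uses scaled problem sizes where
replication multiplies cost: the τ-recovery study runs 100 datasets of
N = 50 over 274 sites without bootstrap; confidence-interval coverage
uses 15 datasets × 99 bootstrap replicates with a ≥ 80% coverage
bound; pipeline determinism is demonstrated on a 50–75-sample
configuration with reduced replicate counts, which is sufficient
because determinism is scale-free. Exhaustive oracles (diversity,
Ewens, minimum spanning networks) run at N ≤ 8 where enumeration is
exact.

## Known limitations

* Multiple sequence alignment, read mapping and tree building are out
  of scope; the package consumes their products (alignments, count
  tables, motif configurations).
* The default motif states are synthetic; real analyses must supply
  observed motif states.
* Sub-haplogroups B1/B2 are supported as labels in coding-region motif
  configurations but ship with no default motifs (their control-region
  motifs are not published).
* The finite-θ₁ mismatch model is available for expectation and
  fitting with θ₁ held fixed; θ₁ is not itself estimated.
* The Φ_CT permutation test is conservative/granular with few
  populations per group, a property of the permutation scheme rather
  than the implementation.
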