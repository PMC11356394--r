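# mthapnet

Population analysis of mitochondrial control-region haplotypes in R.

`mthapnet` packages the analytic chain used in worldwide mtDNA
control-region surveys of livestock — the motivating system is the
domestic donkey, whose maternal phylogeny splits into two deep
haplogroups (A and B) separated by 11 diagnostic positions of the
hypervariable region I — into tested, reusable building blocks:

* **Alignment harmonization** — trim an externally produced multiple
  alignment to a reference-coordinate window (default nps 15476–15749
  of the donkey reference sequence, 274 bp), remove indel columns, and
  summarize variable sites (parsimony-informative vs singleton;
  transitions vs transversions).
* **Haplotypes and haplogroups** — collapse sequences into haplotypes
  with stable frequency-ranked names (`A001`, `B001`, …), classify them
  into haplogroups by diagnostic motif matching (with detection of
  chimeric "intermediate" motifs), and build (optionally
  position-weighted) pairwise difference matrices.
* **Diversity** — Nei's unbiased haplotype diversity
  *h* = N/(N−1)·(1 − Σ pᵢ²) and nucleotide diversity
  *π* = N/(N−1)·Σᵢ<ⱼ 2fᵢfⱼdᵢⱼ/L, per group and per haplogroup.
* **Demography** — observed mismatch distributions; the
  sudden-expansion model F(τ, θ₀, θ₁) fitted by least squares with
  parametric-bootstrap P-values for the SSD and Harpending's
  raggedness index plus a percentile CI for τ; Fu's *F*ₛ from the exact
  Ewens sampling distribution (log-space Stirling numbers) with
  coalescent-simulation P-values; expansion-time conversion
  *t* = τ/2u (defaults: μ = 6.13×10⁻⁸ subs/site/year, 8-year
  generations, L = 274).
* **AMOVA** — one- and two-level hierarchical variance decomposition
  of pairwise distances with Φ-statistics (Φ_ST, Φ_SC, Φ_CT) and the
  standard per-level permutation tests.
* **Median-joining networks** — ε-relaxed minimum spanning networks
  with quasi-median (Steiner) vector insertion and obsolete-median
  cleanup, per-node regional frequencies, regional backbone
  projections, and GraphML/TSV export.
* **Consensus QC** — clade-aware mitogenome consensus calling from
  per-position base counts (depth ≥ 5, heteroplasmy as IUPAC codes at
  minor frequency ≥ 0.15), Tukey upper-whisker exclusion thresholds,
  and rank-sum comparisons of reference choices.
* **Synthetic data** — a coalescent generator (instantaneous size
  change, infinite-sites with a finite-sites hotspot fallback) that
  emulates a two-haplogroup worldwide sample with regional frequency
  skews, plus noisy pileups for the QC module.
* **Pipeline** — `run_pipeline()` drives everything from one YAML
  configuration with explicit seeds and writes a report bundle plus a
  JSON manifest; reruns are byte-identical.

## Worked example

Simulate a three-region two-haplogroup dataset and run the core
analyses:

```r
library(mthapnet)

cfg <- sim_config(seed = 42,
                  n_per_region = c(AFE = 60, AFW = 40, EUI = 50),
                  haplogroup_fractions = c(AFE = 61, AFW = 92, EUI = 26))
sim <- simulate_two_haplogroup_dataset(cfg)

tb <- collapse_haplotypes(sim$aln, group_by = "region")
tb <- name_haplotypes(tb, classify_haplotypes(tb, default_motifs()))
tb
#> Haplotype table: 39 haplotypes from 150 samples (274 positions)
#> Grouped by region: AFE, AFW, EUI

summarize_groups(tb, data.frame(name = tb$haps$name,
                                label = tb$haps$haplogroup))
#>   group   N nh     h     pi pct_A pct_B
#> 1   AFE  60 16 0.836 0.0231    60    40
#> 2   AFW  40 22 0.842 0.0118    92     8
#> 3   EUI  50 20 0.798 0.0198    26    74
#> 4   ALL 150 39 0.862 0.0242    57    43

md  <- mismatch_distribution(tb)
fit_sudden_expansion(md, n_boot = 100, seed = 1)
#> Sudden-expansion fit: tau = 0.0820, theta0 = 4.7802, theta1 = Inf
#> SSD = 0.07841 (P = 0.0990099); raggedness = 0.06522 (P = 0.5148515)
#> tau 95% CI: 0.0000-9.9549 (100 bootstrap replicates)

build_mjn(tb)
#> Median-joining network: 39 nodes (39 observed, 0 median), 57 edges
```

Reading the output: each region reproduces its configured haplogroup-A
percentage (AFW 92%, EUI 26%); the pooled mismatch distribution is
bimodal (the two haplogroups sit 11 mutations apart), so the pooled
sudden-expansion fit degenerates towards a high-θ₀ equilibrium — the
model is meant for within-haplogroup samples, where the same call
returns τ near the simulated expansion age. Fu's
`fus_fs(150, 39, pi_hat, ...)` on these data gives
*F*ₛ = −10.8 (P = 0.03), the haplotype excess expected after
expansion.

The full chain from a configuration file:

```r
run_pipeline(list(seed = 11, simulate = list(), out_dir = "run1"))
# writes diversity.tsv, demography.tsv, amova_*.tsv, network.graphml,
# network_{nodes,edges}.tsv, haplotypes.tsv/.fasta, site_summary.tsv,
# truth.tsv and manifest.json
```

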