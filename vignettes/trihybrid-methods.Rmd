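---
title: "Methods: diagnostic panels and hybrid classification for a three-lineage admixture zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic panels and hybrid classification for a three-lineage admixture zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`trihybrid` analyses hybrid zones among three diverged diploid lineages —
the motivating system is black bass, with a Delta largemouth lineage (DLB),
the widespread northern largemouth (NLB), and Florida bass (FLB), plus
naturally admixed intergrades (ILB) — from biallelic SNP genotypes. The
package covers the full workflow: SNP quality control, differentiation and
diversity statistics, maximum-likelihood ancestry estimation, reduction of
a genome-wide SNP set to a small diagnostic panel, simulation-based
validation of hybrid classification rules, and geographic modelling of
introgressed ancestry. A seedable synthetic-data generator stands in for
raw genotyping data so that every stage is testable end to end.

# Genotype representation and quality control

Genotypes are alternate-allele dosages (0/1/2, `NA` missing) in a
`genotype_matrix` with per-locus metadata. The filter cascade is fixed:

1. **Minor-allele filter** — strict MAF > 0.05 *and* minor-allele count
   > 4, pooled over all called genotypes. The strict inequalities matter at
   the boundary: a locus at exactly MAF 0.05 is removed.
2. **Call-rate filter** — a locus must be called in at least 3 of the 4
   population groups and missing in under 15% of individuals.
3. **Hardy–Weinberg filter** — the exact conditional test on genotype
   counts (the standard variant-QC exact test, summing probabilities of
   heterozygote configurations no more likely than the observed one); a
   locus is removed only when p < 0.05 in **two or more** sampling sites,
   so site-specific demography is not punished. Sites with fewer than five
   individuals are not tested, mirroring the reporting rule for summary
   statistics.
4. **LD pruning** — greedy left-to-right by position within chromosome:
   drop a locus within 1000 bp of the last kept locus or with composite
   genotype-dosage r² > 0.2 against any kept locus on the same chromosome.
   Greedy-by-position is deterministic and matches pruning-tool behaviour
   on unphased data.

Each filter returns a report so every removed locus is attributable to
exactly one step, and each step is idempotent.

# Differentiation and diversity

Per-group observed heterozygosity and Nei–Chesser small-sample-corrected
gene diversity are averaged across loci; `F_IS = 1 − mean(Ho)/mean(Hs)`
with a percentile bootstrap over loci (1000 replicates by default),
matching the convention of locus-resampling intervals. `F_ST` is the
Weir–Cockerham variance-components estimator with multi-locus ratio-of-sums
combining; negative per-locus components are retained in the sums, and
monomorphic loci contribute zero. Loci where fewer than two groups have two
or more called individuals are dropped from the sums. "Fixed" SNPs between
two groups use the operational rule frequency ≥ 0.98 in one group and
< 0.02 in the other, on either allele orientation; the asymmetric
boundary tolerates singleton genotyping errors.

Both estimators are cross-checked in the test suite against independent
scalar-loop implementations of the defining formulas, to 1e-10.

# Ancestry estimation

Bayesian MCMC clustering is replaced by deterministic maximum-likelihood
point estimation, because the pipeline consumes only point ancestry values
and an ML fit is reproducible and directly testable.

**Supervised mode.** Reference allele frequencies `p_kl` are estimated from
flagged reference individuals only and never updated from test individuals
(preventing leakage, analogous to fixed-prior population information).
Frequencies are clamped to `[1e-6, 1 − 1e-6]` so the likelihood stays
finite at fixed loci. Each individual's ancestry vector `q` maximizes
`Σ_l [g_l log π_l + (2 − g_l) log(1 − π_l)]` with `π_l = Σ_k q_k p_kl`,
by EM. The likelihood factorizes over individuals, so each row is frozen
once its own log-likelihood gain per sweep falls below `tol = 1e-6`
(a global total-gain criterion would implicitly tighten per-individual
tolerance with cohort size). The EM weight identity is computed with dense
matrix products; because weights reach ~1/ε at clamped loci, Q rows are
renormalized every sweep to absorb float drift. Missing genotypes
contribute nothing. Estimates are invariant to locus order and to ref/alt
allele flips.

**Unsupervised mode.** Joint block EM over (Q, P) with `n_init` random
restarts, best fit by log-likelihood. Cluster labels are arbitrary; they
are matched to reference lineages by minimal summed squared frequency
distance when a reference panel is available. Model choice across K uses
the Evanno second-difference statistic over replicate log-likelihoods.

**PCA.** Column-centred dosage PCA (optionally unit-variance scaled;
default unscaled, since scaling is not part of the reference protocol and
up-weights rare variants). Missing data are first imputed by binomial
draws from the individual's group allele frequency — preferable to mean
imputation when groups are strongly differentiated, because mean imputation
shrinks group separation.

# Diagnostic panel design

The panel pipeline reduces thousands of filtered SNPs to a small assayable
panel whose supervised ancestry estimates track the full-data estimates:

1. **Candidate screen** — a locus qualifies when some lineage pair is
   strongly contrasted: frequency > 0.9 in one and < 0.1 in the other
   (either orientation). A literal "extreme in two of three lineages"
   reading would also admit loci extreme in the same direction in two
   lineages, which carry no between-lineage information, so the pair rule
   is used.
2. **Loading filter** — PCA on pure individuals at the candidate loci;
   keep the union over PC1 and PC2 of the top 10% of loci by absolute
   loading. Selection is rank-based (exactly the top share per PC, ties
   broken by locus order) rather than thresholded at the quantile value:
   strongly diagnostic loci with near-identical frequency patterns produce
   tied loading blocks that would otherwise inflate the selection several-fold.
   PC1 typically separates the most diverged lineage and PC2 the remaining
   pair, so the union balances the pairwise contrasts in the candidate pool.
3. **Iterative subset search** — 300 random subsets of 80–100 candidates;
   each subset's supervised Q is compared with the full-data Q and scored
   by the number of individuals deviating by more than 0.05 in any
   component. Iterations are ranked by that score (ties to the earlier
   iteration) and the panel is the union of loci from the best iterations,
   grown to the target size and then truncated. The construction of the
   final panel from ranked iterations is genuinely open; the rule here is
   deterministic: truncation keeps loci selected by the most included
   iterations, with ties resolved by each locus's marginal quality (the
   mean score of all iterations that sampled it) and finally candidate
   order. The marginal-quality tie-break matters when a single iteration
   already covers the target size.

A legacy-style two-lineage estimator (`allele_count_ancestry`) counts
focal-lineage alleles over called panel alleles, for comparison with older
allele-counting panels.

# Simulation-based validation

Hybrid cohorts are simulated from the reference panel frequencies:
pure individuals are Binomial(2, p) draws (random mating within lineage);
all later generations use individual-based Mendelian transmission — each
offspring samples one parent per pool and each parent transmits one of its
two alleles per locus, independently across loci. Individual-based
transmission preserves realistic between-individual ancestry variance in
backcross and advanced generations, which frequency-based gamete draws
would understate. There is no linkage, mutation, or genotyping error by
default; an optional per-call error rate supports robustness experiments.

The default design simulates 100 per pure lineage, 50 per pairwise F1, 150
per pairwise pooled F2–F4 (equal thirds), 200 per pairwise backcross (both
directions), and 300 triple hybrids — 1800 genotypes. Triple hybrids are
half F1(i,j) × pure(k) over the three lineage combinations and half
backcrosses of those triples to a pure lineage drawn uniformly (the mixing
ratio between the two constructions is not externally fixed; 50/50 is the
default and configurable).

Assignment uses the Q-threshold rule: pure when `q_k ≥ 0.94`; else triple
hybrid when every component ≥ 0.06; else the two-lineage hybrid of the two
largest components. The rule partitions the simplex. Evaluation reports,
per category, efficiency (correct/simulated, generations pooled into their
pair category), accuracy (correct/assigned) and performance (their
product), at full precision internally and two decimals in printed output.
A threshold scan maximizes mean per-category performance, ties toward the
stricter threshold.

# Geographic cline modelling

Great-circle distances use the haversine formula on a sphere of radius
6371.0088 km; at continental scales the discrepancy from an ellipsoidal
geodesic is below 0.5% and immaterial here. Focal-lineage ancestry for all
individuals is modelled by fractional logistic regression —
`glm(q ~ distance * stocking, family = quasibinomial)` — with dispersion
estimated by Pearson χ²/df. Nested models are compared by a χ² test on the
dispersion-scaled deviance reduction (the protocol's stated test; an
F-test would be the common alternative). The "extent shift" inverts both
strata's fitted curves at an ancestry cutoff (default 0.06, the intergrade
boundary) by root-finding to 0.1 km and reports the Reservoir-minus-River
difference.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the biology that produced it:

* **Lineage frequencies.** Ancestral frequencies are uniform on
  (0.05, 0.95); each lineage drifts under the Balding–Nichols model
  (`Beta(p(1−F)/F, (1−p)(1−F)/F)`), the standard correlated-frequencies
  drift model. Fixed differences are planted exactly (1 vs 0) rather than
  left to drift so their counts are controllable: defaults 46 DLB–NLB,
  1275 DLB–FLB and 1807 NLB–FLB per 8582 loci. The planted sets are
  **nested**: every DLB–FLB fixed locus is also NLB–FLB fixed (an
  FLB-specific 0/0/1 pattern), and the remaining NLB–FLB loci leave DLB
  free to drift — real three-lineage data show exactly this overlap
  (most loci fixed against the most diverged lineage are fixed against it
  in both other lineages), and the overlap determines how much
  panel information separates the two closer lineages. With disjoint
  planting, simulated DLB–FLB hybrids acquire spurious NLB ancestry and
  leak into the triple category at several times the realistic rate.
* **Calibration.** The three drift parameters are tuned so realized
  pairwise Weir–Cockerham θ between 30-diploid samples matches the targets
  (0.459 / 0.677 / 0.749) on a 2000-locus pilot. Because the three
  parameters couple through the three pairwise targets, a per-parameter
  bisection is ill-posed; a damped multiplicative fixed-point update
  (θ is monotone in each F) converges in a handful of rounds and is
  deterministic under its fixed pilot seed. Accepted tolerance is 0.02 on
  the pilot, leaving margin inside the ±0.05 acceptance band at full scale.
* **Study layout.** The default survey has 62 reference individuals
  (24 DLB, 24 NLB, 14 FLB — the reference-set sizes of the motivating
  study) and nine admixed sites of 12 individuals. Admixed-site FLB
  ancestry follows a configured logit of distance from the FLB reference
  site, with an intercept shift for stocked reservoirs; the non-FLB
  remainder splits between DLB and NLB by a per-site weight. Genotypes are
  Binomial(2, Σ_k q_k p_kl) draws — i.e. the admixture model itself —
  with a 3% missing-call rate (typical post-filter missingness for
  reduced-representation data; the QC threshold is 15%).
* **What it does not emulate.** No linkage or haplotype structure, no
  site-level drift within lineages, no genotyping error model in the study
  generator, no coalescent history: admixed individuals are
  admixture-proportion draws, not forward-simulated pedigrees. Passing
  tests therefore demonstrate the pipeline's statistical correctness under
  the admixture model, not robustness to artefacts real GBS data may
  carry. Each locus sits on its own scaffold (short-scaffold reference
  convention), so the LD pruner's window rule is exercised by the unit
  tests rather than the generator.

# Numerical and design choices

* Frequencies clamped at 1e-6; EM likelihood π clamped at 1e-12 when
  logged; Q rows renormalized per sweep (EM weights at clamped loci reach
  ~1e6 and break the row-sum identity in floats at ~1e-6).
* Half-calls in VCF input (`./1`) are treated as missing — the safest
  contract, and typical callers for this data type do not emit them.
  Phase separators are accepted and discarded.
* Supervised EM tolerance 1e-6 per individual, cap 2000 sweeps; a
  non-converged fit is returned with a warning rather than an error.
* The problem sizes used by the test suite and the acceptance script are
  the study conditions themselves: 8582 loci, 170 study individuals, the
  1800-genotype simulation design, 30 diploids per lineage and 10 seeds
  for the calibration check, and n = 880 with 500 null replicates for the
  cline calibration.
* Ties: ΔK ties resolve to the smallest K; threshold-scan ties to the
  largest threshold; LD pruning keeps the earlier-position locus;
  panel truncation as described above.

# Known limitations

* The ML ancestry estimator gives boundary point estimates (a true-zero
  component estimates to exactly 0 about half the time); it carries no
  posterior uncertainty, and no credible intervals are provided.
* Classification near the 0.06 minor-ancestry boundary is intrinsically
  noisy with ~73 loci; with the default design the dominant error mode is
  two-lineage hybrids of the closest pair acquiring a small spurious
  third-lineage component, the same mode the threshold rule is known to
  show on real panels.
* The cline model attaches every individual to its site's distance and
  stocking stratum; within-site variation in exposure is not modelled.
* `wc_fst` is a two-level estimator; hierarchical (site-within-lineage)
  F-statistics are out of scope.
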