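---
title: "Methods: profiling low-biomass genitourinary microbiomes with urobiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling low-biomass genitourinary microbiomes with urobiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urobiome)
```

## The problem

Midstream urine carries very little microbial biomass. Amplicon (16S rRNA)
surveys of such specimens are therefore dominated by three nuisance signals
that swamp the biology unless they are removed explicitly: DNA introduced by
extraction and PCR reagents (the "kitome"), reads misassigned between
multiplexed samples (index hopping / cross-talk), and sampling noise from
very unequal library sizes. `urobiome` implements a complete analysis chain
for this setting: negative-control-based decontamination, rarefaction and
core-microbiota profiling, alpha/beta diversity, community-type ("urotype")
discovery, co-occurrence networks with keystone detection, gender/age cohort
comparisons, and a sequencing-depth / cohort-size design tool. A synthetic
cohort generator with planted ground truth makes every stage testable.

## Decontamination against negative controls

`apply_qc()` applies four rules. The three ASV-level flags are computed on
the *unfiltered* matrix and then applied jointly, so the audit trail does not
depend on rule order.

1. **Prevalence test.** For each ASV, the 2x2 presence table (GU vs NC x
   present vs absent) is tested by a chi-square test of independence without
   continuity correction, switching to Fisher's exact test whenever an
   expected cell is below 5. The ASV is flagged when p < 0.5 *and* its NC
   prevalence fraction strictly exceeds its GU prevalence fraction. The
   permissive default alpha of 0.5 is deliberate: in low-biomass work this
   rule is a screen, and the direction condition carries most of the
   specificity. ASVs never seen in a control cannot be flagged.
2. **NC read fraction.** An ASV is flagged when more than 5% of its total
   reads come from negative controls, or when the number of NC samples
   containing it exceeds 6% of all samples. The second clause follows a
   deliberately literal reading of a procedure whose published phrasing is
   ambiguous; note that it is inert whenever controls make up less than 6%
   of the cohort (the realistic regime -- e.g. 10 NCs against hundreds of
   specimens) but it binds hard in small pilot designs with proportionally
   many controls. For such designs raise `max_nc_sample_frac` explicitly;
   the package's own tiny-scale smoke tests do exactly that.
3. **Cross-talk.** ASVs present in fewer than 3 GU samples whose relative
   abundance stays below 5 per mille in every sample where they occur are
   flagged as index-hopping artifacts. Abundance is summarized as the
   maximum over occupied samples (the most retention-conservative choice;
   `abund_stat = "mean"` is available).
4. **Sample retention.** After column removal, GU samples retaining no more
   than 50% of their own pre-filter reads are dropped -- strictly more than
   50% is kept, so a sample at exactly one half goes. A `cohort_average`
   mode compares retained reads against half the cohort-average library
   instead, for users who prefer that reading.

All thresholds are strict inequalities, matching the "more than"/"less
than" phrasing they implement. Flags, per-ASV scores, p-values, and
per-sample retention are returned in a `contaminant_report` that serializes
losslessly to JSON.

## Rarefaction and profiling

Relative abundances are computed after subsampling every library without
replacement to a common depth (default 4,000 reads, `rarefy()`); samples
below the target are dropped, not scaled, so the hypergeometric semantics
stay exact. Mean relative abundance (MRA) is the per-taxon mean of
per-sample relative abundances with zeros included, and prevalence is the
fraction of samples where a taxon is detected -- both computed
post-rarefaction for internal consistency (whether prevalence should be
computed pre- or post-rarefaction is a genuinely open convention; the
package picks post and says so). `core_taxa()` stratifies taxa at MRA
> 5% ("dominant"), [0.01%, 5%] ("low-abundance"), and below 0.01%.

## Diversity

All four metrics are implemented from first principles and checked in the
test suite against brute-force oracles (and against `picante` where it
offers the same quantity):

* **Shannon** uses log base 2 (bits), the convention of the QIIME
  q2-diversity plugin; the base is a parameter because published analyses
  rarely state it.
* **Faith's PD** is the branch length of the minimal subtree spanning the
  root and the observed leaves, computed by post-order accumulation of
  per-edge leaf incidence.
* **Bray-Curtis** on relative abundances.
* **Unweighted UniFrac** classifies every edge as observed-in-either /
  unique-to-one by the same per-edge incidence machinery, so both
  tree metrics share one audited code path.

Between-group comparisons of alpha diversity use Wilcoxon rank-sum tests.
For beta diversity the package compares within-group pairwise distance
distributions between groups, again by Wilcoxon; pairwise distances are not
independent observations, so these p-values are heuristic and the output
says so. This is a declared convention, not a claim about how any
particular published analysis did it.

## Urotypes

Samples are clustered on the Bray-Curtis distance of the rich-genus matrix
(genera with MRA > 0.1%; everything else pooled into an explicit `Others`
column so rows still sum to 1 -- `Others` participates in the distance) with
Ward's criterion on squared dissimilarities (`ward.D2`). Ward's variance
interpretation formally assumes Euclidean input and Bray-Curtis is not
Euclidean; the package follows the field's established practice and
documents the caveat rather than substituting a different algorithm.

The number of clusters is chosen by mean silhouette width, with the
Calinski-Harabasz curve computed and reported alongside; when the two
criteria disagree, silhouette decides (a declared tie-break -- published
analyses typically report both without stating a combination rule).
Silhouette widths of singleton clusters are set to 0. Clusters are named by
the genus with the highest within-cluster MRA, or `mixed` when that genus
stays below 25% -- "mixed" community types are real, but no numeric
definition is in general use, so 25% is a package constant.

Genus abundance-distribution *modality* is classified by fitting 1- and
2-component Gaussian mixtures (unequal variances, `mclust`) to log positive
abundances: `multimodal` requires the 2-component fit to win by a BIC
margin above 10 *and* component means separated by more than one pooled
standard deviation; anything weaker stays `unimodal_lognormal`. Fewer than
50 positive observations (or a degenerate constant input) yields an
`insufficient_data` outcome instead of an error. The margins are
conservative on purpose: a mild, well-mixed heterogeneity should not be
called bimodal.

## Co-occurrence networks

`spearman_network()` computes all pairwise genus Spearman correlations
(midranks under ties; p-values from the large-sample t approximation),
adjusts the whole family of pairs by Benjamini-Hochberg in one shot, and
keeps edges with |rho| > 0.35 and q < 0.05. Correlations are computed on
rarefied relative abundances with zeros included. Keystone genera are
ranked by degree, ties broken by summed |rho| of incident edges -- "highly
connected" made concrete. The trio analysis reports joint-presence counts
with a 4-df chi-square test of mutual independence on the 2x2x2 presence
table, pairwise Spearman correlations, and the Pearson correlation of
summed trio abundance with per-sample Shannon diversity.

## Cohort comparisons

Per-taxon abundance differences between genders or age groups (T1: 45-54,
T2: 55-64, T3: 65-74, T4: 75+) use Wilcoxon rank-sum tests on relative
abundances; prevalence differences use chi-square with the same Fisher
fallback as QC rule 1. Raw p-values are the primary output with BH-adjusted
q-values always alongside. `exclusive_taxa()` lists taxa present in at
least five samples of one group and in zero samples of the other -- the
zero is strict.

## Depth and cohort-size design

`depth_sensitivity()` subsamples every library to min(d, library size) --
capping rather than dropping keeps every sample in play at every depth, so
the curve is monotone by construction and reaches exactly 1 at the largest
library. `samplesize_sensitivity()` draws n samples without replacement.
Sensitivity is the fraction of the full-data ASV set re-detected (count
>= 1; the threshold is a parameter). `recommend_design()` returns the
smallest grid value attaining the target (default 90%), linearly
interpolating between bracketing grid points and flagging interpolated
answers. Depth bins for descriptive grouping follow the conventional
20k...80k grid as eight left-closed bins; the final boundary is 80,000 (one
published rendering of this grid contains an internal typo in its last
bin; the package uses the consistent reading).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, and its defaults *are* the
study conditions for the package's validation:

* **Cohort shape** (desk scale): 300 GU + 10 NC samples; 63.7% female; ages
  uniform on 45-86; GU library sizes log-normal with mean ~40,000 reads;
  NC libraries log-normal with mean ~2,000 reads, reflecting the far lower
  DNA mass of sterile-water controls. `tiny` (30 GU + 5 NC) exists for
  smoke tests and `full` (1,165 GU) for scale checks.
* **Community structure**: 140 genera -- six dominants (a Prevotella-analog
  plus five others), a three-genus trio (Peptoniphilus / Ezakiella /
  Porphyromonas analogs), and a long log-normal tail of 131 low-abundance
  genera. Each genus owns 1-10 ASVs with Dirichlet(1) internal splits, and
  the tree is a random coalescent grafted genus-by-genus so genera are
  monophyletic and UniFrac/Faith's PD reflect the taxonomy.
* **Urotypes**: six clusters, each boosting one dominant genus. The
  Prevotella-analog urotype is the commonest (weight 0.40) and its boost is
  mild (1.7x against sigma 0.5), so that genus's marginal stays close to a
  single log-normal; the other five dominants get 40x boosts against sigma
  0.45, making their marginals clearly bimodal -- the generator plants the
  one-process/two-process contrast the modality classifier is designed to
  detect.
* **Trio and diversity coupling**: a per-sample latent factor z (sd 0.7
  within urotype, mean +0.8 in the Prevotella-analog urotype and -0.2
  elsewhere) drives the trio through a Gaussian copula normalized to the
  configured correlation (default rho = 0.8), lifts every tail genus with
  loading 0.6, and lifts the Prevotella-analog with loading 0.5. The trio
  additionally gets a direct +1.8/-0.6 log-mean shift by urotype. One
  mechanism therefore produces all three reported phenomena at once: tight
  trio co-abundance, trio-tail co-occurrence (keystone connectivity), and a
  positive association between trio abundance and Shannon diversity --
  nothing is hard-coded downstream. The evenness coupling is implemented as
  this shared log-scale factor rather than as a Dirichlet concentration
  multiplier; the two are equivalent for the diversity association, and the
  factor formulation also yields the genus-genus correlations the network
  stage needs.
* **Contamination** is compositional: reagent-contaminant ASVs (default 30)
  share one Dirichlet profile that makes up ~80% of each NC library and a
  log-normal ~0.4% of each GU library, so NC libraries being small is
  represented faithfully. The GU contamination load is a free parameter
  (`contaminant_gu_load`): no quantitative GU-side load is published for
  this setting, so it was set once to a plausible kitome level.
* **Cross-talk artifacts** (default 50) each land in at most two GU samples
  with reads capped below 5 per mille of the library, i.e. they satisfy the
  cross-talk signature by construction; `hop_rate = 0` disables them
  entirely.
* **Covariates**: male samples shift a handful of named genera
  multiplicatively; a few genera get per-year log-slopes centred at 65.

All randomness flows from a single seeded stream, so identical configs are
byte-identical. What the generator does *not* emulate: raw reads, chimeras,
PCR/primer bias, batch structure across sequencing runs, positive-control
mocks, and a realistic ultra-rare tail (its rarest ASVs are still a few
reads per cohort). Consequently a green test suite demonstrates that the
*algorithms* behave as specified under planted truth -- not that any real
cohort satisfies the generator's assumptions; in particular the
depth/cohort-size curves saturate earlier on synthetic data than they would
on a survey with a heavier rare tail.

## Validation scales and numerical choices

The package validates itself at the desk scale (300 GU + 10 NC, ~780 ASVs):
contaminant-recovery F1 and true-ASV loss over 20 seeds, urotype k-selection
and adjusted-Rand recovery over 10 seeds, trio/keystone recovery over 20
seeds, FDR calibration over 100 null matrices (20 genera x 200 samples),
type-I calibration of the cohort tests over 200 null datasets, and
hypergeometric detection checks with 1,000 replicates. Exact-arithmetic
oracles (Fisher enumeration, Lance-Williams agglomeration, naive-loop
formulas) are compared at 1e-9 or tighter. Distance and diversity code
treats empty denominators as distance 0; silhouette of singletons is 0;
merge ties in clustering resolve by lowest index through `stats::hclust`,
making results platform-stable.

## Limitations

* Decontamination is prevalence-based only; no DNA-concentration
  (frequency) model is included, and batch-aware decontamination is out of
  scope.
* Beta-diversity group tests use non-independent distance observations
  (flagged in the output); a permutation framework (e.g. PERMANOVA) is a
  deliberate non-goal here.
* Compositionality-aware correlation (SparCC-style) is not provided; the
  Spearman network inherits the usual compositional caveats.
* A single flat urotype cut is produced; nested subcluster splitting is not
  attempted.
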