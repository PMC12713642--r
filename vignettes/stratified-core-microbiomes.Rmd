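---
title: "Stratified core microbiomes: models, parameters and design choices"
author: "phyllocore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified core microbiomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `phyllocore`: the
models it fits, the parameters that matter, the numerical choices that
were genuinely open, and what the synthetic-data generator does and does
not emulate. It states no empirical results beyond what the test suite
and `scripts/acceptance.R` compute.

## The system and the question

The package targets vertically stratified host–environment systems:
three habitats (here labelled `litter`, `sphagnum`, `soil`), one of which
is a focal host, sampled in a nested design of sites and plots with one
sample per habitat per plot. The scientific question is twofold: (i) is
the host community assembled deterministically (host filtering) or
stochastically (dispersal from the surroundings), and (ii) of the taxa
that are consistently present in the host — the core microbiome — which
are genuinely host-associated and which are environmental generalists,
and what does each group contribute to community stability?

## Core detection and stratification

A taxon is **core** when its mean relative abundance across host samples
is at least `minRA` (default 0.001, i.e. 0.1%) *and* it occurs in at
least `minPrev` (default 0.8) of the host samples. Both thresholds are
inclusive; comparisons carry a 1e-9 relative floating-point guard so
that a mean mathematically equal to a threshold always passes,
independent of summation order. "Mean across host samples" is one of two
defensible readings of an abundance threshold; the per-sample-minimum
reading is available via `perSampleRA = TRUE`.

Core taxa are stratified by `classifyCore()`:

* **SU** — zero counts in every non-host sample. This is decided on the
  raw counts, before any model fitting.
* **ES** — both host-vs-litter and host-vs-soil contrasts significant at
  `alpha` (familywise-adjusted) with a higher host mean.
* **EC** — present in all three habitats and not ES.
* **core-unresolved** — present in exactly two habitats and not
  enriched. Such taxa fit none of the three published categories; we
  keep them visible rather than forcing them into EC.

The enrichment test is a two-part zero-inflated beta model fitted by
maximum likelihood with `glmmTMB`: a logistic model for the structural
zero mass (`logit(pi) ~ habitat`, dropped to an intercept or omitted
when the zero pattern cannot support it) and a beta model for the
positive abundances (`logit(mu) ~ habitat`, constant precision phi).
Relative abundances equal to 1 are squeezed to (n − 0.5)/n. Random
site/plot effects are deliberately omitted from the default fit: a mixed
zero-inflated beta is out of proportion to the binary decision it feeds,
and with 25 host samples per habitat the fixed-effect Wald test is the
pragmatic choice. Groups with no positive observations yield no mean
contrast; the contrast is flagged `NA` and classification falls back to
the presence pattern.

The two host-vs-other contrasts form a family; the default adjustment is
the single-step multivariate-normal (Tukey-style) bound computed from
the joint Wald distribution with the deterministic Miwa algorithm, with
Holm as a fallback (`adjust = "holm"`). For two contrasts the two
methods rarely disagree at `alpha = 0.05`.

## Sloan's neutral community model

Under neutral assembly with immigration, the stationary relative
abundance x of a taxon with metacommunity mean abundance p follows
Beta(Nmp, Nm(1 − p)), where N is the community size (reads per sample
after rarefaction) and m the immigration probability per birth–death
event. The predicted occurrence frequency is the beta tail mass above a
detection limit d, and `fitNCM()` estimates m by least squares over the
occurrence–abundance cloud: a 200-point log-spaced scan of (1e-6, 1]
followed by golden-section refinement on the log scale. R² = 1 − SSE/SST
is reported as-is and may be negative for pathological fits.

Two numerical choices deserve note:

* **Detection limit.** For whole-community count data at granularity
  1/N, a taxon is recorded absent when its count is 0, i.e. when its
  underlying frequency lies below *half* a count. The default is
  therefore d = (smallest nonzero within-sample relative abundance)/2.
  On exactly-neutral simulations (whose stationary variance we verified
  against the Beta law directly) the uncorrected boundary d = 1/N
  overestimates m by ~30–50%; the midpoint correction removes the bias.
  `d` remains a user-settable argument.
* **Envelope.** The partition band is a Wilson score interval at
  `ciLevel` (default 0.95) around the predicted frequency with n = the
  number of samples, the common choice in NCM implementations;
  Clopper–Pearson exact bounds are available via `exact = TRUE`.

The companion simulator `simulateNeutralCommunities()` runs a Moran
process with immigration: per replacement event a uniformly chosen
individual dies and is replaced from the source pool with probability m,
else by a local offspring. `generations` counts these single-individual
events; the per-taxon frequency distribution relaxes to its Beta
stationary form on a timescale of ~N/(2m) events, so validation runs use
50·N events (50,000 for N = 1000), several relaxation times.

## Cohesion, networks and robustness

Connectedness follows the taxa-shuffle variant of the Herren–McMahon
method: each observed pairwise Spearman correlation is corrected by
subtracting its mean under `nullReps` (default 200) independent
permutations of the partner taxon across samples; a taxon's positive
(negative) connectedness is the mean of its positive (negative)
corrected correlations, and a sample's cohesion of each sign is the
abundance-weighted sum. The null magnitude of connectedness scales as
~0.8/sqrt(n samples) — with few samples even independent taxa show
non-trivial connectedness, which is why the calibration checks use
hundreds of samples. Whether cohesion should use all corrected
correlations or only network-thresholded ones is not settled in the
literature; the default uses all (method-faithful), and the thresholded
network is built separately.

Networks keep an edge when |rho| ≥ `rThreshold` (default 0.6, inclusive)
and the t-approximation p ≤ `pThreshold` (default 0.05); edge p-values
are deliberately unadjusted by default because the edge set is
threshold-driven, with a Benjamini–Hochberg switch. Robustness is the
trapezoidal area under the mean largest-connected-component fraction
over a removal-fraction grid (step 0.05) across `nOrders` (default 100)
uniform random node orders. A complete graph scores ~0.5 (pure removal
loss) and this is an upper bound up to grid effects. Worth knowing:
under *random* removal a hub topology is not measurably more fragile
than a ring — by exact enumeration E[AUC] is 0.380 for a 10-node star
vs 0.374 for a 10-node ring — hub fragility only appears under targeted
(degree-ordered) attack, which is out of scope here.

## Distance statistics

Bray–Curtis, PERMANOVA (`vegan::adonis2`, 999 permutations by default),
beta-dispersion (`vegan::betadisper`, centroid type) and Mantel tests
(Pearson on lower triangles, one-sided greater) follow the standard
toolchain, seeded. Centroid distances between habitat groups are
computed directly from the distance matrix via the centroid identity on
squared distances, which carries the negative-eigenvalue correction of
the principal-coordinate embedding automatically.

NMDS is implemented in-package because its optimisation contract —
Kruskal stress-1 with a per-iteration stress trace that never increases
within a run — is part of the package's guarantees and is not observable
through `monoMDS`. Each run alternates isotonic regression of the
configuration distances on the dissimilarity order (primary tie
handling: tied dissimilarities are pre-ordered by current configuration
distance, so no constraint binds within a tie block) with a Guttman
majorization step, halved as needed so stress-1 is monotone. Defaults:
k = 2, 20 starts (the first from classical scaling, the rest random
seeded), 300 iterations, tolerance 1e-7. The first axis feeds the path
models as the community-structure variable.

## Stability indicators

AVD is the per-sample mean absolute z-score of taxon abundances against
the sample-set mean profile, over the taxa with non-zero variation; the
per-sample variant is used because the stability regressions pair it
with per-sample group abundances. On iid standard-normal input its
expectation is E|Z| = sqrt(2/pi) ≈ 0.798, which the calibration tests
exploit. Association strength is positive/|negative| cohesion with an
explicit undefined flag (not an error) when negative cohesion is zero;
flagged samples are dropped from regressions and counted.

Network robustness is a community-level quantity with no natural
per-sample variation; to regress it against group abundance the package
offers bootstrap replicates (network rebuilt on resampled sample sets,
default 20–30 replicates) as the default mode, pairing each replicate's
robustness with the replicate-mean group abundance. A leave-one-out
jackknife variant would be the alternative reading; both are explicit
interpretations of an under-specified published analysis, and the mode
used is recorded in the outputs.

## Piecewise path models

`fitPaths()` fits one OLS regression per endogenous variable on its
parents and standardises coefficients by sd(x)/sd(y). The test of
overall structure is Fisher's C = −2Σln p over the d-separation basis
set: one claim per non-adjacent pair, conditioned on the union of the
parents of both variables, with the causally later variable regressed on
the earlier. This conditioning convention (parents of both, not just of
the dependent) matches the piecewise-SEM practice for claims involving
correlated exogenous variables and is pinned by hand-worked small graphs
in the tests. C is referred to chi-square with 2k df; the acceptance
rule is df = 0 (saturated), or C/df ≤ 2 and p > 0.05. Note the C/df ≤ 2
clause is *stricter* than p > 0.05 for small df (for df = 2 it amounts
to p ≥ e^−2 ≈ 0.135). Model simplification by path pruning is not
automated: the package fits the declared specification and reports.

Component models are plain linear regressions: the endogenous variables
in this design (NRI of neighbouring habitats, NMDS axis 1, summed group
abundances, a pathway-abundance proxy) are continuous, and mixed-effect
components would add nothing to the d-separation logic at these sample
sizes.

## The synthetic generator

`simulateStratifiedSystem()` emulates the study design: 5 sites × 5
plots × 3 habitats = 75 samples, elevation varying by site
(1000–1900 m), pH varying by colony with habitat offsets (host most
acidic). Taxa fall into five classes — SU (20), ES (20), EC (20),
habitat specialists of the two non-host habitats (40) and background
generalists (100). Abundances are log-normal: a per-taxon base log-mean
(class-specific location, sd 0.4), habitat multipliers (ES:
`enrichmentFold` = 5 in the host vs elsewhere, acting multiplicatively
on the mean; SU and specialists: zero outside their habitat), covariate
effects on the log scale (standardised pH on EC, +0.5; standardised
elevation on SU/ES, −0.5, matching the directions the path models are
meant to detect), per-taxon-sample log-normal noise (sd 0.6), structural
zeros per class (5% for core classes, 20%/50% for
specialists/background) inserted *after* the abundance draw so the
zero-inflated beta model downstream is correctly specified, and Poisson
count sampling. Class sizes, folds and zero-inflation rates were chosen
once to make the planted core classes sit comfortably above the
detection thresholds (host expectations of 25–40 counts per sample at
library sizes of a few thousand) while leaving a realistic majority of
non-core taxa; they are the package's fixed study conditions, not tuning
knobs.

What the generator does **not** emulate: phylogenetic signal in habitat
preference (the simulated tree is independent of the class labels, so
NRI has no planted effect), taxonomic structure, sequencing-depth
artefacts beyond Poisson sampling, compositional bias, or temporal
dynamics. Passing tests therefore certify the estimators against the
generating model — threshold logic, enrichment recovery, neutral-model
recovery, calibration constants — not robustness to every property of
real amplicon data.

## Problem sizes and determinism

Validation runs use deliberately modest sizes chosen for statistical
sufficiency: 50 neutral communities of N = 1000 over 50,000 events for
migration-rate recovery; 100–500 replicate null simulations for type-I
error checks; 100 simulations for Fisher's C calibration; the
study-sized 75 × 200 scenario for end-to-end recovery. Every stochastic
function takes an explicit seed; the pipeline derives per-stage seeds
from a master seed via a small string hash, records them in the
manifest, and reproduces its outputs byte for byte under the same inputs
and configuration.

## Known limitations

* ES calling inherits the power of the zero-inflated beta Wald test:
  with fewer than ~10 host samples, truly enriched taxa will often fall
  back to EC or core-unresolved.
* The NCM fit treats taxa as independent observations of the
  occurrence–abundance law; strongly correlated taxa (e.g. one dominant
  clade) can distort both m and the envelope coverage.
* Cohesion magnitudes are sample-size dependent (null scale
  ~0.8/sqrt(n)); compare cohesion only across communities with equal
  sample support.
* PERMANOVA covariate partitions are sequential (order-dependent); the
  term order is the user's statement of priority, and is recorded.
* Bray–Curtis is a semi-metric; the principal-coordinate embeddings
  behind dispersion and centroid distances may involve negative
  eigenvalues, handled by the standard imaginary-part correction.
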