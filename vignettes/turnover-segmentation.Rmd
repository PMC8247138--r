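---
title: "Segmenting longitudinal microbiome turnover: models, parameters and design choices"
author: "microdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting longitudinal microbiome turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In long confinement or isolation studies, the same subjects donate
saliva (or other) samples repeatedly over hundreds of days. Two
complementary quantities describe how their microbial communities move:

* **within-subject turnover** — the dissimilarity between one subject's
  community at consecutive timepoints. A rising series means the
  subject's microbiota is reorganizing faster and faster; a falling one
  means it is settling.
* **between-subject divergence** — the mean pairwise dissimilarity among
  subjects at a single timepoint. Its trend tells whether cohabiting
  subjects' microbiotas converge (microbiota exchange) or stay
  personalized.

microdyn models both series as piecewise-linear functions of study day
and asks *where the regime changes are*: the change-points partition the
mission into phases (outbound, return, recovery after isolation), and
per-phase slopes with subject-level random intercepts quantify how fast
turnover changes in each phase. Around this core it carries the rest of
a standard longitudinal 16S workflow: normalization, alpha/beta
diversity, ordination and PERMANOVA, persistence-based classification of
ASVs into a stable core and an inconsistent (transient) fraction,
bipartite subject-ASV network dynamics, and per-ASV "driver" selection
with enrichment analysis.

# Data model

`LongitudinalASVTable` extends `SummarizedExperiment`: an ASV x sample
integer count matrix with per-sample `subject`, `day` (1-based days
since mission start), `diet` (FV/TV/NR food variants), `phase`
(outbound/return/followup) and a derived `in_isolation` flag
(`day <= isolationEnd(x)`, default 520). Validity enforces unique
(subject, day) pairs, positive column sums, and diet-phase consistency
(the normal unsupervised diet NR exactly during follow-up).

# Preprocessing

* **Depth normalization** uses median-of-ratios size factors with a
  positive-counts reference (the geometric mean of each ASV over the
  samples where it is nonzero). Zero-inflated amplicon tables leave the
  classic all-sample geometric mean undefined for most ASVs; the
  positive-counts variant is the standard remedy. Factors are rescaled
  to geometric mean one.
* **Rare-ASV filtering** removes ASVs that occur in fewer than
  `ceiling(0.05 * n_samples)` samples *and* have total abundance below
  10. Requiring both conditions targets the extremely rare taxa that
  dominate qualitative (presence/absence) indexes without deleting
  prevalent-but-low-count organisms. The filter runs before
  beta-diversity computation; alpha diversity uses unfiltered scaled
  counts, because removing rare taxa directly biases richness-sensitive
  indexes.
* **Wisconsin double standardization + square root** (each ASV row
  divided by its row maximum, each sample column by its column sum, then
  a square root) is applied to the scaled counts for **ordination and
  PERMANOVA** distance matrices.

A deliberate choice: the **turnover series are computed on size-factor
scaled counts, not on the Wisconsin transform**. The row-maximum
standardization gives every ASV identical weight, so on a table where
sporadic low-count ASVs outnumber the abundant core ten to one, a
"quantitative" turnover series computed after Wisconsin standardization
is in effect a presence/absence series of the transient fraction and
masks abundance reorganization of the core. On scaled counts the
Bray-Curtis turnover tracks compositional change of the whole community.

# Diversity machinery

Alpha diversity is the inverse Simpson index, `1 / sum(p_i^2)`.
Pairwise beta diversity offers Sorensen `(A + B - 2J)/(A + B)`,
Bray-Curtis `sum|x - y| / sum(x + y)` — returned together with its
similarity/loss/gain decomposition `(A, B, C)`, for which
`(B + C)/(2A + B + C)` is an exact algebraic identity — and
unweighted/weighted (normalized) UniFrac against a rooted ASV
phylogeny. Within-subject turnover values are assigned to the **later
day** of each transition, so the effect of leaving isolation lands on
the post-isolation transitions. Between-subject divergence per timepoint
is the arithmetic mean of all pairwise distances that day — the only
summary that yields one point per timepoint.

# Change-point detection

`peltChangepoints()` performs exact penalized segmentation with the PELT
recursion. The segment cost is nonparametric: minus twice the empirical
distribution log-likelihood summed over K quantiles of the series
(K = `ceiling(4 log n)`), each quantile carrying weight
`2 log(2n - 1)/K`, with quantile probabilities spaced evenly on the
logit scale so the grid concentrates in the distribution tails. Because
the cost depends only on ranks relative to a fixed quantile grid,
detections are invariant to strictly monotone transforms of the values.

The penalty is a modified BIC: a `log(segment length)` term per segment
plus a constant per change-point. We use `4 log n` for the constant,
counting the segment's empirical-CDF profile as a (location, shape)
object with two effective parameters: with `3 log n`, roughly one in
five i.i.d. 100-point series acquires a spurious change-point under
this cost, while `4 log n` keeps i.i.d. series clean (about 96% with no
detection) and still pins a clear distributional step to within one
position. Minimum segment length defaults to 2 observations. Pruning
uses a conservative slack of `log n` so the log-length correction can
never prune the optimal candidate; tests verify exact agreement with an
unpruned dynamic program.

# Genetic-algorithm refinement

PELT runs per subject, but an empirical-CDF cost places breaks where the
*distribution of values* shifts — at level crossings — whereas a
piecewise-linear trend has its scientifically meaningful break at the
slope vertex, where the value distribution barely changes. The second
stage therefore reconciles detection with regression: a genetic
algorithm searches binary inclusion masks over **all observed transition
days**, with the pooled per-subject PELT detections and the empty mask
(no change-points, one global model) seeding the initial population.

Fitness of a mask is `1 / sum_k RMSE(lmm_k)`: each induced segment is
fitted with `value ~ day` plus a subject random intercept (plain least
squares for the one-point-per-day between-subjects series), and the
root-mean-square errors are summed. Summing — not averaging — makes
extra segments costly: a split is kept only when it removes enough
systematic lack-of-fit to pay for an additional RMSE term, which is why
a genuinely unsegmented series (the between-subjects case) returns the
empty mask. Two numerical choices matter:

* RMSE is the **df-corrected residual standard error** (REML residual
  sigma for the mixed model). Raw `sqrt(mean(r^2))` rewards overfitting
  two-point segments and biases boundaries toward the series edges.
* Masks creating a segment with fewer than `min_segment_transitions`
  (default 2) observed transitions per subject on average get fitness 0
  rather than erroring. A guard of 3 would outlaw the follow-up segment
  of the emulated design itself (16 samples over 6 subjects average
  2.67 transitions).

GA hyperparameters: population 200, at most 100 generations with a stop
after 30 stagnant ones, uniform crossover (p = 0.8), per-bit mutation
(p = 0.1), 5% elitism, tournament selection. With at most ~13 candidate
bits the search space is small; the GA exists to optimize a noisy,
guard-constrained fitness without exhaustive refitting, and segment
models are memoized so fitness evaluation is a cache lookup.

Per-segment inference (`fitSegments()`) reports slope, SE, t,
Satterthwaite degrees of freedom and p per segment, plus the cumulative
effect (slope x segment day span). A change-point at day d closes its
segment at d inclusive.

# Mixed models

All random-intercept models are REML fits (lme4) with Satterthwaite
degrees of freedom (lmerTest) — fractional df are expected output.
Degenerate designs fail loudly: fewer than two groups, singular fixed
effects, or one observation per group are errors, never silently
arbitrary variance estimates.

# Persistence, clustering, networks

The persistence of an ASV at a timepoint is the number of subjects in
which it is detected (count >= 1 on the filtered table; threshold
configurable). Rows of the persistence matrix are centered and scaled
(constant rows become zeros, not NaN), pairwise dynamic-time-warping
distances are computed (symmetric step pattern, L1 local cost,
unconstrained window — at 15 timepoints a warping band would gain
nothing), and partitioning around medoids with k = 2 yields the
inconsistent (cluster 1) and stable (cluster 2, higher mean raw
persistence) fractions. PAM with BUILD initialization is deterministic,
which keeps the whole stage reproducible.

Bipartite networks link subjects to the ASVs detected in their sample at
each timepoint. Edge deltas per subject transition (formed = newly
present, destroyed = newly absent) obey the exact conservation law
`E_after = E_before + formed - destroyed`. Mixed models
`formed ~ day + post_isolation` (and the same for destroyed) quantify
the temporal trend and the level shift at the end of isolation.

# Drivers and enrichment

For each subject and ASV, the absolute differences of scaled abundance
at consecutive transitions are z-standardized and regressed on day with
segment-specific intercepts and slopes (segments from the global
within-subject segmentation). An ASV is a *driver of diversity* when
the model F-test survives Benjamini-Hochberg correction across the
subject's ASVs (adjusted p < 0.05) and every segment slope sign matches
the global within-subject pattern. Driver sets are then tested for
enrichment of the stable cluster by an upper-tail hypergeometric test
(universe = all clustered ASVs), BH-corrected across subjects, with
fold enrichment `(k/n)/(K/N)`. Note the selection rule controls FDR for
the F-test only; the sign-concordance filter is applied after
correction, so realized driver sets include noise-concordant taxa at a
rate the enrichment test treats as background.

# The synthetic study generator

`generateSynthetic()` emulates a 6-subject, 720-day isolation study: 15
sampling days (7 outbound at days 1-176, 5 return at 271-480, 3
follow-up at 540-716), isolation ending at day 520, diet FV during
outbound, TV during return, NR during follow-up, and the final
follow-up sample discarded for the last two subjects — phase totals
42 + 30 + 16 = 88 samples. Counts are negative-binomial (size 60) at a
uniformly drawn library depth of 20k-120k reads.

Mechanisms, and what they emulate:

* **Stable core** (600 ASVs, high abundance): per-subject log-abundances
  follow a mean-reverting AR(1) whose per-transition step standard
  deviation is calibrated so the expected consecutive-timepoint
  Bray-Curtis equals the planted piecewise-linear trajectory
  (baseline 0.35 at day 1, change-points at days 123 and 480, per-day
  slopes +0.00103 / -0.00064 / +0.00123). The calibration inverts the
  closed-form expectation of |1 - W| for a lognormal-mixture abundance
  ratio W, after subtracting a floor (0.04) for the turnover that
  sampling noise and transient churn contribute regardless of drift.
  Mean reversion (stationary log-sd 1.1) keeps between-subject
  divergence flat in time — the observed between-subjects behaviour —
  where a pure random walk would make subjects diverge without bound.
* **Step-direction mixture**: each drift step mixes a fixed-magnitude
  random-direction component (weight 0.8) with Gaussian noise. This
  emulates coordinated community shifts and controls how tightly
  realized turnover tracks the planted trajectory. Fully Gaussian steps
  leave the per-point noise at a level where the summed-RMSE fitness
  cannot distinguish segmented from global models; fully concentrated
  steps make per-ASV abundance ratios bimodal, which destabilizes
  median-of-ratios normalization. The realized series tracks the target
  closely with mild attenuation of the slopes; the recovery suite
  checks change-point positions, slope signs and slope magnitudes
  directly.
* **Transient fraction** (1200 ASVs, low abundance): losses are per-ASV
  Bernoulli switches (rate 0.45 per transition), gains a Poisson number
  of activations drawn from the off-pool. Exogenous gains make gain and
  loss events genuinely independent and let the planted post-isolation
  increase in formed edges (+28 per subject-transition) enter the
  expectation additively and exactly. Both rates decline 20% across the
  mission (slightly fading churn).
* **Drivers** (15 stable ASVs): deterministic alternating-direction
  steps of 1.5x the transition step size, so their |difference| series
  follows the planted segment pattern cleanly while staying bounded.
* **Diet response**: 15% of stable ASVs shift +0.6 log-units during FV.
* **Subject individuality**: per-subject per-ASV offsets (log-sd 0.35).

What the generator does **not** emulate: taxonomic structure and
phylogenetic signal (the random coalescent tree is independent of the
abundance model, so UniFrac on synthetic data exercises the code path,
not ecological realism), compositional interactions between taxa,
sequencing error and chimeras (inputs are post-denoising counts), and
heavy-tailed abundance spectra. Passing recovery tests therefore shows
the pipeline recovers planted temporal structure under realistic
sampling noise — not that real salivary data contain such structure.

Two emergent behaviours are worth knowing. First, detection flicker:
stable ASVs whose abundance wanders near the one-read detection limit
enter and leave the networks, which couples formed and destroyed edge
counts through subject- and depth-level heterogeneity (Spearman rho
around -0.2 to -0.4 on the default design). The independence of gain
and loss *processes* is therefore asserted on a churn-isolating design
(few, well-detected stable ASVs and flat drift), where |rho| < 0.2
holds essentially always. Second, the alpha-diversity series is
stationary by construction, matching the observed constancy of total
diversity.

# Problem sizes and reproducibility

Every stochastic stage draws its seed deterministically from the master
seed keyed by stage name, so adding a stage never perturbs another
stage's stream and reruns are bit-identical. The validation suite sizes
its simulations to the method, not the machine: change-point and
edge-jump recovery use 50 replicates of the full 88-sample design,
clustering recovery 20, PERMANOVA calibration 500 null datasets at 199
permutations, and the mixed-model study 200 replicates of the
6 x 15 design; unit tests use a reduced design (60 stable + 150
transient ASVs) where the full one adds nothing.

# Known limitations

* The unrestricted permutation scheme in PERMANOVA ignores the
  repeated-measures structure; subject enters first in the sequential
  decomposition as the conservative mitigation, and p-values for
  time-varying factors should be read as approximate.
* The GA optimizes a noisy fitness; change-point placement on a coarse
  14-transition grid is accurate to about one grid position, not to the
  day.
* Per-ASV driver selection inherits the usual caveats of fitting many
  small models: with ~13 transitions per subject, power is limited and
  sign-concordance can be satisfied by chance in about one of eight
  noise ASVs that pass the F-test.
* Weighted UniFrac uses the normalized variant so all four indexes share
  the [0, 1] range; raw weighted UniFrac values are not comparable
  across studies that skip normalization.
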