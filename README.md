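# microdyn

Longitudinal microbiome turnover, segmentation and resilience analysis.

## What this package is for

Long isolation and confinement studies sample the same subjects'
microbiota repeatedly over hundreds of days and ask how the community
moves: does each subject's microbiota reorganize faster or slower as the
study progresses, do cohabiting subjects' communities converge, and
which taxa carry the change? microdyn implements the full analysis path
for such designs, from an ASV count table to resilience statements:

- **Temporal beta-diversity series.** Within-subject turnover
  d(x<sub>t</sub>, x<sub>t+1</sub>) at consecutive timepoints (Sorensen,
  Bray-Curtis with its similarity/loss/gain decomposition A, B, C, or
  UniFrac), and between-subject divergence (mean pairwise distance per
  timepoint).
- **Temporal segmentation.** Nonparametric PELT change-point detection
  (empirical-CDF cost on a logit-spaced quantile grid, modified-BIC
  penalty), followed by genetic-algorithm refinement over all observed
  transition days with fitness 1/&Sigma;<sub>k</sub> RMSE(lmm<sub>k</sub>),
  and per-segment random-intercept models
  value ~ day + (1 | subject) with Satterthwaite degrees of freedom.
- **Stable vs. inconsistent microbiota.** ASV persistence profiles
  (subjects carrying each ASV per timepoint) clustered by dynamic time
  warping + partitioning around medoids into a stable core and a
  transient fraction, plus the persistence-abundance regression.
- **Network dynamics.** Bipartite subject-ASV snapshots per timepoint,
  formed/destroyed edge counts per transition with the conservation law
  E<sub>t+1</sub> = E<sub>t</sub> + formed − destroyed, and mixed models
  for the temporal trend and the post-isolation shift.
- **Drivers and enrichment.** Per-ASV trend models on standardized
  absolute consecutive differences, driver selection by BH-corrected
  significance plus sign concordance with the global pattern, and
  upper-tail hypergeometric enrichment of the stable cluster.
- **A synthetic study generator** that emulates the 6-subject,
  15-timepoint, 720-day design (88 samples after two discarded
  follow-ups) with planted change-points, segment slopes, churn, diet
  and subject effects — so the entire pipeline is testable without
  sequencing data.

Standard steps ride on the field's standard packages (vegan, phyloseq,
lme4/lmerTest, ape, cluster); the data container extends
SummarizedExperiment.

## Worked example

```r
library(microdyn)

# emulated isolation study: 6 subjects x 15 timepoints, 88 samples
tab  <- generateSynthetic(syntheticDesign(), seed = 1)
tab
#> LongitudinalASVTable: 1800 ASVs x 88 samples
#>   subjects: 6  days: 15  span: 1-716
#>   assays: counts

# normalize, filter, transform
filt <- transformCounts(scaleCounts(filterRare(scaleCounts(tab))))

# within-subject turnover series and its segmentation
cfg  <- analysisConfig(seed = 1)
w    <- withinSubjectSeries(filt, "bray_curtis")
seg  <- segmentSeries(w, cfg)
seg
#> Segmentation: 2 change-point(s) at day(s) 114, 425
#>   fitness (1/sum RMSE): 18.161

fitSegments(w, seg)
#>   segment start_day end_day         b       SE     t   df        p cumulative_effect
#> 1       1        21     114  0.001139 9.57e-05  11.9 17.0 1.14e-09             0.106
#> 2       2       114     425 -0.000711 2.79e-05 -25.5 29.0 2.09e-21            -0.221
#> 3       3       425     716  0.001119 5.71e-05  19.6 15.2 3.55e-12             0.326
```

The segmentation splits the mission into three phases: turnover rises
during the outbound leg (slope +0.00114 per day), falls through the
return leg (−0.00071), and rises again around the end of isolation
(+0.00112) — recovering the planted structure (change-points at days
123 and 480; slopes +0.00103 / −0.00064 / +0.00123) to within one
sampling position. The same run classifies the ASVs into a stable core
and a transient fraction and estimates the post-isolation burst of
newly acquired ASVs:

```r
pm <- persistenceMatrix(filt, 1)
dtwCluster(pm, 2)
#> Persistence clustering (DTW + PAM):
#>  cluster size mean_persistence
#>        1 1180         1.484859
#>        2  620         5.672796

em <- edgeModels(edgeDeltas(buildNetworks(filt, 1)), isolationEnd(filt))
lmmCoef(em$formed, "post_isolation")
#>             term    b   SE    t df        p
#> 3 post_isolation 29.2 6.66 4.38 79 3.56e-05
```

(Planted jump: +28 formed edges per subject-transition; the planted
stable core has 600 ASVs, the transient tail 1200.)

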