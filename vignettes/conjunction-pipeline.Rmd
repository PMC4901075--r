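---
title: "Minimal-t conjunction analysis of multi-task fMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal-t conjunction analysis of multi-task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conjfmri)
```

## The scientific problem

Within-subject multi-task designs ask where in the brain responses to
different cognitive demands overlap and where they are distinct. With three
tasks — a value-based choice task (V), a mathematical task (M) and an emotion
task (E) presented in an identical stimulus format — the suprathreshold
territory of the three group maps partitions into seven categories:
V∩M∩E, V∩M∩~E, V∩~M∩E, ~V∩M∩E, V∩~M∩~E, ~V∩M∩~E and ~V∩~M∩E. `conjfmri`
implements this partition with the minimal-t-statistic rule, the Monte-Carlo
cluster-extent correction that licenses it at the whole-brain level, ROI
response extraction, and a complementary whole-brain spatial-correlation
similarity analysis, all driven by a synthetic-cohort generator with known
ground truth.

## Models and procedures

### Subject-level GLM

Each run is modelled voxel-wise by ordinary least squares:
\(y = X\beta + \varepsilon\). Condition regressors are unit boxcars — 4 s for
the choice phase, 2 s for feedback, per the stimulus durations — convolved on
a 0.1 s microtime grid with the canonical double-gamma HRF
\(h(t) = \Gamma_{(6,1)}(t) - \tfrac{1}{6}\Gamma_{(16,1)}(t)\), peak-normalised,
sampled at scan onsets (TR = 2 s). Six motion parameters and an intercept are
nuisance columns.

Condition grouping follows the study's models: the Value task has 5
difficulty levels × {choice, gain feedback, no-gain feedback} = 15 task
regressors; the Emotion task has {choice, gain feedback, no-gain feedback} =
3. For the Mathematical task the source text's "12 regressors" does not
decompose from 3 levels × {choice, correct fb, incorrect fb}; the default
grouping here is the literal 9, with incorrect-trial choice events kept as
one extra nuisance regressor so that every scan remains modelled while "only
correct trials" contribute to the task contrast. The grouping rule is an
ordinary function argument, so any other decomposition can be plugged in.

Each condition regressor is rescaled so that an isolated event of its
duration peaks at 1. A GLM coefficient is then the peak signal change (in
percent, with the simulator's baseline of 100) attributable to one event —
the same scale on which the synthetic atlas states its effect sizes, which
is what makes "noiseless simulation recovers planted amplitudes to 1e-6" a
meaningful identity rather than a scale coincidence.

Deliberate simplifications, documented rather than hidden: no high-pass
filtering and no prewhitening. The simulator's mild AR(1) noise
(\(\rho = 0.2\)) is treated as unmodelled; OLS point estimates stay unbiased,
and group inference rests on between-subject variance, which is estimated
honestly by the one-sample t-map.

### Subject contrasts and group maps

The task-versus-baseline contrast averages the phase's condition
coefficients (e.g. the 5 choice-level betas). Runs are combined as a
weighted mean with weights defaulting to equal shares per run of the task
(the "weighted for the number of runs" rule; two Value runs each get 1/2).
The group map is the voxel-wise one-sample t of the n = 20 subject
contrasts, df = 19. This is the task-relative-to-baseline cell of the
three-level task factorial; whether the original analysis pooled error
across cells is not stated, so the per-task one-sample form (the more
conservative, assumption-light reading) is used and the df is carried on
the map.

### Conjunctions

For sign = positive, a voxel joins a conjunction iff \(t \ge t_{crit}\) in
every included task and \(t < t_{crit}\) in every excluded one, with
\(t_{crit}\) the one-sided p < 0.001 quantile at the group df. Exclusion
("~") uses the *same* threshold — the strictest literal reading; a more
liberal exclusive-masking threshold is one `voxel_p` argument away.
Negative-sign analyses mirror everything. The per-voxel summary is the
minimum over included t values (the statistic of the conjunction null).
The 50-voxel extent rule is applied per conjunction category, matching the
per-category cluster tables it feeds.

### Monte-Carlo cluster-extent threshold

Per iteration: fill the grid with unit Gaussian noise, smooth with the 8 mm
FWHM separable kernel (\(\sigma = \mathrm{FWHM}/\sqrt{8\ln 2} \approx
3.397\) mm), restandardise to zero mean/unit variance within the simulation
mask, threshold at the one-sided z-cutoff for voxel p, and record the
maximal 26-connected suprathreshold cluster. Over 10,000 iterations,
\(\alpha(k)\) is the fraction of iterations whose maximum reaches k. On the
full 64 × 64 × 38 grid this reproduces the published calibration: the
probability of any ≥ 50-voxel cluster at p < 0.001 is below 0.001. Choices
worth noting:

* **Simulation volume**: the source does not state the simulated mask. The
  full grid is used — it contains more voxels than any brain mask, so the
  estimated α is, if anything, an over-estimate, making the α ≤ 0.001
  acceptance bound conservative.
* **Restandardisation** (rather than a theoretical variance correction)
  makes voxel_p map to the z-cutoff exactly; the two differ only at mask
  edges. The suprathreshold count per iteration is exported so this
  calibration is directly testable.
* **Connectivity** defaults to 26 (faces, edges, corners), the convention of
  the Monte-Carlo cluster tools this procedure follows; 6 and 18 are
  available.

### ROIs

Conjunction ROIs are the surviving clusters of each category, with two
exclusion rules: clusters overlapping a supplied excluded-structures mask
(visual/somatosensory/motor territory, identified anatomically in the
original analysis, supplied as a mask file here) are dropped; and voxels of
a more-exclusive category within `dilation_mm` of a more-inclusive
category's clusters are removed as residual-smoothing periphery. The source
gives no number for "immediate periphery"; the default is 4 mm — one
z-voxel, ≈ one in-plane voxel — and configurable. A-priori ROIs are 5 mm
spheres (voxel-centre distance rule, no partial-volume weighting) at the
meta-analytic MNI coordinates shipped in
`inst/extdata/apriori_rois.json`. ROI comparisons are two-sided paired
t-tests across subjects with 95% CIs; paired (not independent) because the
design is within-subject, though the source does not say which was used.

### Spatial similarity

Per subject, the two tasks' contrast maps are correlated (Pearson) over the
voxels significant in *either* task (group-level voxel p < 0.001, no extent
rule) within the gray-matter mask (probability ≥ 0.8, inclusive boundary),
then Fisher-transformed (z = atanh r) and compared across subjects by
paired t-test, df = n − 1 = 19. Two ambiguities resolved here: "significant
responses during the Value and Mathematical tasks" is read as the union
(intersection is a flag) since the union retains pattern information where
only one task responds; and the significance mask is group-defined, applied
to each subject's own values, which the description supports.

### Behavioural tests

The across-task ANOVA is labelled repeated-measures in the source but
reported with F(2, 57) — between-cells df for 20 subjects × 3 tasks. The
default reproduces the reported layout (between-cells one-way ANOVA,
df = (2, 57)); `repeated = TRUE` gives the within-subject version
(df = (2, 38)). Tukey HSD post-hocs use the studentized range on the
between-cells error term.

## The synthetic world

The generator emulates the study design exactly where it is stated:

* 20 subjects; Value 2 runs × 200 volumes, Mathematical 224, Emotion 108;
  TR 2 s; 64 × 64 × 38 voxels of 3.4375 × 3.4375 × 4 mm.
* 80 / 45 / 20 trials over 5 / 3 / 1 difficulty levels; 4 s choice + 2 s
  feedback; 20 s lead-in/lead-out fixation; predetermined outcome
  frequencies 50/8/12/10 (Value: higher/lower/either/neither) and 10/2/5/3
  (Emotion); Mathematical feedback follows the simulated response.
* ITIs: the distribution is not stated beyond range [1, 5] s and mean
  1.5 s; a shifted exponential truncated at 4 s with its rate solved so the
  truncated mean is exactly 0.5 s above the shift is used — the standard
  shape for rapid event-related designs compatible with both constraints.
* Noise: Gaussian, smoothed to 8 mm FWHM (mimicking post-smoothing data),
  AR(1) with ρ = 0.2 (the GLM does not model autocorrelation, so the
  simulator keeps it mild), marginal voxel SD σ = 1 (≈ 1% of the baseline
  100, a typical event-related magnitude). Smoothed innovations are
  restandardised per voxel by the exact separable kernel norms so σ means
  the same thing at edges and interior.
* Motion: small-amplitude smoothed random-walk drift in six parameters —
  enough to exercise the covariate path, not a physical head model.
* Between-subject variability: per-region amplitude multipliers
  ~ N(1, 0.3), shared across the tasks a region serves (a subject who
  responds strongly in a region does so in every task engaging it);
  behavioural accuracy ~ N(63.4, 5.4), N(78.1, 7.0), N(56.8, 14.3) percent
  and response times N(1982, 436), N(2447, 280), N(1759, 375) ms for
  V/M/E, the observed task means.
* Trial-to-run allocation for the two Value runs is not stated; trials are
  dealt to runs by strict alternation, giving the even 40/40 split.

**Truth atlas.** Published choice-phase peak coordinates are reused as plant
sites, one region per conjunction category (two for V∩M∩~E: the bilateral
putamen pair, the headline value–mathematics overlap), 8 mm radius spheres
with uniform amplitude. Effect sizes (0.6–1.0 percent) were chosen a priori
to encode the qualitative structure of the findings — the shared striatal
V/M response strong, unique-V territory weak, the Emotion response broad —
so the stated world also reproduces the *direction* of the similarity
result (z(V–M) > z(V–E)). They were fixed before any recovery test was run.
For reduced grids, `demo_truth_atlas()` places the same category/effect
structure at synthetic fractional positions (labelled synthetic; these are
not anatomical coordinates).

**What a green test does and does not establish.** The simulator plants
hard-edged spheres in stationary, homoscedastic noise with no physiological
(cardiac/respiratory) structure, no susceptibility dropout, no
inter-subject anatomical variability and no spatial misregistration.
Recovery with Dice ≥ 0.8 therefore validates the *inference chain* —
design, GLM, thresholds, conjunction logic, cluster rules — not robustness
to the messiness of real data. Conversely the similarity power result shows
the paired Fisher-Z test detects a planted covariance-structure difference
at n = 20, not that real value and mathematical processing are similar.

## Numerical choices

* OLS via one QR decomposition per design, shared across voxels; rank
  deficiency is an error naming the collinear columns.
* Zero-variance voxels in group maps become `NA` and are excluded from all
  masks.
* Smoothing renormalises edge taps (constant volumes are exactly
  preserved); σ = FWHM/√(8 ln 2) per axis in voxel units.
* Mask and sphere boundaries are inclusive (≥); lattice coordinates are
  0-based, world coordinates are MNI mm through the affine.
* All randomness descends from one integer seed per entry point
  (generator, MC, pipeline); cohorts are bit-reproducible and the RNG state
  of the caller is never disturbed.
* The demo configuration uses extent_k = 10. A hard-edged 8 mm planted
  sphere spans only ~45 voxels at the 3.4375 × 3.4375 × 4 mm voxel size —
  below the 50-voxel rule, which is calibrated for whole-brain correction
  of smooth, extended real activations. Recovery of the planted partition
  is therefore assessed at a smaller extent (the acceptance target for the
  50-voxel rule itself is the Monte-Carlo α calibration, not sphere
  recovery); planting larger radii or using the MC-calibrated k for a
  given grid are both one argument away.

## Known limitations

* No AR whitening or high-pass filter (by design, documented above);
  t-statistics on single runs are mildly optimistic under ρ = 0.2, while
  group inference is unaffected in expectation.
* The NIfTI-1 layer covers the single-file variant with the common numeric
  datatypes; header extensions are skipped, not preserved.
* Difficulty enters the design as separate regressors only; parametric
  modulation is out of scope, as are omnibus F-maps, random-field-theory
  corrections and searchlight/RSA variants.
* `anova_tasks` treats cells as independent in its default layout purely to
  reproduce the reported df convention; for real inference on within-subject
  data use `repeated = TRUE`.
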