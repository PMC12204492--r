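---
title: "Methods: population analyses of lateral-septum activity during signaled active avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analyses of lateral-septum activity during signaled active avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidpop)
```

# Scope

`avoidpop` implements the statistical pipeline for studying how a neural
population encodes threat and action during two-way signaled active
avoidance (AA): a 10-s tone (CS) predicts foot-shock, and the animal can
shuttle to the opposite chamber to avoid it. Trials where the run occurs
during the tone are *successes* (the tone stops, no shock); otherwise the
shock arrives at tone offset (*failures*). The package covers single-cell
calcium-trace preprocessing, auROC task-modulation classification,
population trajectory geometry, pseudo-population outcome decoding,
functional clustering with anatomical-concentration tests, kernel-convolved
encoding models, bulk photometry afferent analysis, and input-proportion
statistics for monosynaptic rabies tracing — plus a synthetic session
generator with planted ground truth that every analysis is validated
against.

The repository is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions and
write their tables under `results/`; all computation lives in `R/` where
the tests and the acceptance script exercise it.

# Preprocessing model

Raw fluorescence is corrected for neuropil contamination as
$F - 0.7\,F_{\mathrm{neu}}$ (the scale factor is configurable in
`neuropil_correct()`). The baseline $F_0(t)$ is the 10th percentile of the
trace in a 25-s window around each frame and
$\Delta F/F = (F - F_0)/F_0$. The window is *centered* with edge
truncation, and percentiles use linear interpolation between order
statistics (R's default quantile type); a trailing window would be an
equally defensible convention, and both the window length and percentile
are arguments. $\Delta F/F$ traces are spliced across trials, dropped frames
are linearly interpolated, and the session-length trace is z-scored per
neuron, so all downstream amplitudes are in session z-units.

Photometry channels (465 nm signal, 405 nm isosbestic reference) are
smoothed (Gaussian, 100 ms SD) and linearly detrended, the reference is
regressed onto the signal channel by least squares, and the corrected
signal is $100\,(s_{465} - \hat s_{405})/\hat s_{405}$ (percent
$\Delta F/F$). The 100-ms smoothing SD and the linear detrend are package
defaults and both are arguments. For AA sessions the trace is spliced then z-scored; for other
designs z-scoring can precede splicing (both orders are reachable through
the same functions).

Kinematics: speed is the magnitude of the Gaussian-filtered positional
derivative (15-frame / 0.5-s support at 30 Hz, kernel SD = support/6);
avoidance-run onset is the first frame in the CS at which speed reaches
5 cm/s; freezing is speed below 0.25 cm/s sustained for at least 0.5 s;
flight is speed above 50 cm/s. The "center" body point is the default.

Trial tensors slice the z-scored traces around CS onset, run onset or
shock onset with half-open windows $[t_0+\mathrm{pre},\,t_0+\mathrm{post})$
and drop success trials with avoidance latency under 4 s, whose CS and
run responses are not separable.

# auROC modulation classification

For each neuron and task variable the baseline distribution pools the
baseline-window values across trials (CS/run/shock: $[-2,0)$ s;
pre-run: $[-3,-2)$ s before run onset), and the per-timepoint auROC of the
across-trial response values against that baseline is averaged over the
response window (CS/run/shock: $[0,2)$ s; pre-run: $[-2,0)$ s). auROC is
the rank-sum statistic $P(x_r > x_b) + \tfrac12 P(x_r = x_b)$; ties get
half credit, the standard rank-sum convention.
Pooling the baseline across trials is the default; a per-trial baseline
with trial-wise averaging is available (`pool_baseline = FALSE`).

The null distribution circularly shifts the whole session trace by one
uniform random offset per permutation (preserving autocorrelation while
destroying event alignment), rebuilds the trials, and recomputes the
statistic; 1000 permutations by default. A neuron is *activated* above
the 97.5th percentile of its null and *suppressed* below the 2.5th — the
two-sided $\alpha = 0.05$ bounds; both thresholds are configurable.

# Population geometry

Trial-averaged success and failure responses are concatenated per neuron
into an $n \times 2t$ matrix, row-mean-centered, and decomposed by PCA
over time samples. Single trials are projected onto the components
reaching 80% cumulative variance. Outcome divergence is quantified per
bootstrap (100 by default): a random 80% neuron subset (the fraction is
a package default, exposed as `subsample_frac`), PCA
refit, single-trial projection, and a per-timepoint Mahalanobis distance
between the success and failure trial clouds, plus each condition against
its own baseline-period cloud. The covariance is the pooled
within-condition covariance of single-trial projections; when trials do
not exceed dimensions it switches to Ledoit-Wolf shrinkage toward the
scaled identity (and logs that it did). Distances are z-scored to the
baseline period within each bootstrap; a timepoint is significant when
fewer than 5% of bootstraps have $z < 1.65$.

The coding direction is $\mathbf{d} = \bar{\mathbf{x}}^{succ} -
\bar{\mathbf{x}}^{fail}$ averaged over 0-3 s after CS onset, normalized to
unit length. Trials are projected after subtracting the cross-condition
grand mean, which makes the in-window mean success projection positive
and the failure projection negative by construction; a zero difference
vector is returned as a flagged zero vector. Residual PCs are extracted
from the trial-averaged activity after removing its CD component (all
orthogonal to the CD), keeping components to 85% of residual variance.
For run-aligned CD the window defaults to $(-3, 0)$ s before onset.

# Pseudo-population decoding

Single-trial activity is denoised by reconstruction from the PCs
explaining 80% of variance, `n_neurons` are drawn without replacement,
and trials are paired at random within class (each neuron contributes an
independently permuted trial), concatenating the period's timepoints
(CS: 0-2 s; pre-run: −1.4-0 s) into one vector per pseudo-trial. The
pseudo-trial count per class is the minimum class count. A linear-kernel
SVM (cost 1; features standardized on training folds only — both
exposed) is scored by stratified leave-one-out CV, holding out one trial
per class per fold. The label-shuffle null permutes labels and reruns
the full procedure; p-values use the add-one convention
$(1 + \#\{null \ge obs\})/(1 + n_{shuffle})$ so they are never zero.

One property worth stating plainly: with a *fixed* trial pool, the LOO
accuracy concentrates not on 0.5 under the null but on a pool-dependent
value (SD ≈ 0.1 at 10 trials/class with hundreds of features), because
the accidental geometry of the few high-dimensional trial vectors is
shared by all bootstraps. Chance-level calibration is therefore a
property of the *label-reshuffling* null, whose iterations re-partition
the pool — its mean sits within a few percent of 0.5 — and the tests
check it there. Time-resolved decoders train one classifier per time bin
on instantaneous (one value per neuron) vectors.

# Functional clustering and spatial tests

Per neuron, trial-averaged responses in four epochs (CS-success,
CS-failure, shock, avoidance run) are concatenated; PCA keeps components
to 80% variance; k-means runs for $k = 1..20$ with 5 random restarts
plus two deterministic initializations — Ward-linkage centroids, and the
previous $k-1$ solution augmented with its worst-fit point. The warm
start guarantees a nonincreasing inertia curve; Ward centroids reliably
find well-separated optima that sparse random restarts miss. The elbow
is the maximum discrete second difference of *log* inertia: on the raw
scale the second difference is dominated by the first splits whenever
cluster sizes are imbalanced and degenerately selects $k = 2$; the log
scale measures relative curvature and recovers the planted cluster count.
The silhouette score validates the chosen partition; heatmap rows are
min-max normalized per neuron (constant rows map to 0.5) and sorted
within cluster by correlation with the cluster mean.

Anatomical concentration: neurons are binned into 8 equal-width bins
along AP, ML or DV; the relative concentration profile is each bin's mean
value normalized by the summed *absolute* bin means (coefficients can be
negative; the raw bin means are also returned); the statistic is the SD
of the profile, compared against 10,000 value-shuffles; families of tests
are Holm-Bonferroni corrected. Empty bins contribute zero concentration
and are logged.

# Encoding models

Behavioral events (cue onset by outcome, shock onset, run onset, and an
anticipatory run regressor) become binary impulse trains convolved with
an indicator kernel: linear rise over 0.15 s to 1, exponential decay
with constant 0.8 s, truncated at 1.5 s, peak-normalized — the
rise/decay/duration match the indicator's kinetics; the
linear-rise/exponential-decay functional form is the package's choice and
configurable. Regressors may be shifted up to
2 s (forward for onsets, backward for the anticipatory regressor); the
default is no shift except a 1-s backward lead for the anticipatory
regressor, without which it would duplicate the onset column; a
per-predictor grid search maximizing training $R^2$ is available
(`optimize_shifts`). Per-trial segments are concatenated, an intercept
appended, and the model fit by OLS; performance is leave-one-trial-out
cross-validated ($R^2$ over concatenated out-of-fold predictions, MSE per
fold).

Predictor contributions zero the predictor's column *about its mean*
while keeping the fitted coefficients — zeroing the raw column would also
destroy the model's mean prediction and push the sole-predictor drop
above 100% — and report $100\,(R^2_{full} - R^2_{zeroed})/R^2_{full}$
with the nested-comparison F statistic
$((SSE_z - SSE_f)/q)/(SSE_f/(n-p))$. Derived indices:
cue-outcome $= \beta_{CS\text{-}succ} - \beta_{CS\text{-}fail}$;
action $= \beta_{anticip} + \beta_{onset}$; groups are summarized with
one-sample t and Wilcoxon tests against zero. A photometry recording is
wrapped as a one-neuron session, so the bulk-signal path is numerically
identical to the single-neuron path.

# Connectivity statistics

Input counts per subject and brain region are converted to proportions
(zero-total subjects excluded). Each region gets a one-way ANOVA across
subtypes with eta-squared effect size; Benjamini-Hochberg correction runs
across regions; Tukey HSD post hocs where the adjusted p passes 0.05
(eta-squared is the effect-size measure, and is labeled as such). PCA runs on per-region z-scored proportions; for each group
pair, per-PC two-sample t-tests are combined by Fisher's method, the mean
cross-group Euclidean distance in 3-PC space becomes a similarity index
$1/(1+d)$, and a permutation test reassigns samples to groups. The
dendrogram uses average linkage on group-mean PC vectors. The subtype decoder is a one-vs-one linear SVM
on the standardized proportions with leave-one-subject-out CV, a
bootstrap accuracy distribution (resample with replacement, test on the
full set), and a label-shuffle permutation p (add-one convention, so the
separable limit gives $1/(n_{perm}+1)$); significance requires the
observed accuracy to exceed the null's 95th percentile. Hemisphere-summed
counts are the default input; per-hemisphere tables pass through
unchanged.

# The synthetic generator

`generate_session()` plants everything the analyses estimate. Trials:
Bernoulli(0.7) successes (a trained animal past the 33% criterion), ITIs
uniform on 25-40 s, a 10-s CS ceiling; success latencies are uniform on
[4, 10) s — the task fixes only the ceiling and the 4-s analysis
exclusion, so the latency law is a modeling choice recorded in the ground
truth; failures are shocked at CS+10 s with an escape run 0.3-2 s later.
Each neuron draws a response motif; its noiseless trace is the motif's
amplitude-weighted sum of kernel-convolved event trains (sustained CS
motifs use a boxcar over the tone), plus iid Gaussian noise (SD 1 z-unit)
and a slow random-walk baseline. The behavior track crosses the 5-cm/s
run threshold exactly at each planted onset with a speed profile linear
through the threshold, so smoothing does not bias the detected time.

The default dictionary has ten motifs (outcome-biased CS activation,
transient and sustained CS suppression, unresponsive, run onset, pre-run
ramp, shock, mixed shock/cue, safety arrival) with mixing proportions
following the relative sizes of the ten functional clusters reported for
this circuit. Amplitudes are calibrated so that every responsive motif's
noiseless trial-averaged epoch template has comparable norm (about 10
z·frames under default conditions): planting *comparably separated*
clusters is the generator's contract — recovery tests are uninformative
when one motif's template dwarfs the others — and the calibration was
fixed once from the noiseless template geometry, not tuned per analysis.

Photometry: the 465 channel is signal plus a shared low-pass motion
artifact (Gaussian noise smoothed with a 0.5-s kernel) plus white noise;
the 405 channel is the scaled artifact plus noise and no signal, so the
isosbestic regression is testable against ground truth. Input counts are
Dirichlet-multinomial draws around per-subtype region profiles.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: calcium indicator nonlinearity and
saturation, spike-to-fluorescence dynamics beyond the fixed kernel,
correlated (shared latent) noise across neurons, motion artifacts in the
imaging (only photometry), non-stationary behavior and learning across
trials, and real anatomical geometry beyond Gaussian cluster loci.
Estimator calibration under iid Gaussian noise is a necessary check, not
evidence about correlated-noise regimes.

# Numerical choices and reproducibility

Percentiles and null quantiles use R's default interpolating quantile;
auROC ties get half credit; zero difference vectors, constant heatmap
rows and degenerate (constant) reference channels are flagged or
errored rather than silently propagated; the Mahalanobis covariance
switches to Ledoit-Wolf shrinkage whenever trials do not exceed
dimensions; k-means empty-cluster solutions are re-run and logged. All
randomized procedures take explicit seeds; `run_pipeline()` derives
per-stage seeds from one global seed by stage-name hashing so stages
reproduce in isolation; two runs with the same configuration are
byte-identical.

Session bundles are stored as a directory of CSV tables (doubles
serialized at 17 significant digits, which round-trips IEEE doubles
exactly) plus a YAML header — a plain-text container that keeps event
tables human-editable and diffs readable.

The validation suite runs at desk scale, chosen so the full suite
completes in minutes while keeping each check statistically meaningful:
type-I calibration of the modulation classifier uses 500 null neurons
with 1000 circular permutations; clustering recovery uses a 1600-neuron
cohort (mirroring the recorded population's scale); decoder checks use
about 20 usable trials and up to 220 neurons with 50-100 bootstrap or
shuffle iterations; spatial-test calibration uses 200 repetitions of
1000 shuffles; GLM recovery uses 30-trial sessions. Headline fractions
from the recorded animals (per-class modulation percentages, cluster
sizes, specific decoder p-values) depend on the real data and are not
reproduction targets; the analytic auROC reference values and the
calibration/recovery properties above are.

# Known limitations

The shift search in the encoding model is greedy per predictor, not
joint; the elbow rule remains a heuristic and alternative selections
(silhouette maximum, gap statistic) are not implemented; the divergence
analysis assumes per-timepoint Gaussian clouds for the Mahalanobis
z-scores; the pseudo-population construction assumes exchangeable trials
within class across animals; and the photometry model's linear artifact
mixing understates real wavelength-dependent artifacts.
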