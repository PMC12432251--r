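---
title: "Crossmodal flavour decoding: models, assumptions and design choices"
author: "flavdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossmodal flavour decoding: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

During eating, taste and retronasal odour fuse into a single flavour
percept. A central question in chemosensory neuroscience is whether the
two modalities converge onto a *shared* neural code: does a sweet odour
evoke the same fine-grained insular activity pattern as a sweet taste?
`flavdecode` implements the full statistical pipeline used to answer this
with block-design fMRI: first-level GLM estimation of run-wise condition
patterns, multivariate decoding with crossmodal and cross-session
partitions, hierarchical permutation inference, tuning-index overlap
analysis, and run-wise representational-drift modelling — all driven by a
synthetic-data generator that plants exactly the statistical structure
each analysis is meant to detect, so every stage can be verified end to
end without any scanner data.

The experimental design the package models: five conditions — sweet and
savoury tastants (SweT, SavT), sweet and savoury retronasal odorants
(SweO, SavO), and an artificial-saliva control (ArtS) — delivered in 16 s
mini-blocks followed by a 4 s rinse and an 8–12 s inter-trial interval;
15 mini-blocks per run (3 per condition, never the same condition three
times in a row), six runs per session, two sessions per subject, 228
frames per run at TR = 2 s.

# The synthetic generator

`simulate_patterns()` draws, per subject, a voxelwise flavour-specific
component for each flavour in each modality. The single most important
parameter is the crossmodal overlap weight `alpha`: each odour component
is built as

  odour = alpha * paired-taste + sqrt(1 - alpha^2) * independent

so the expected voxelwise correlation between a taste pattern and its
paired odour pattern is exactly `alpha` while the marginal variance does
not depend on it. `alpha = 0` is the null world (no shared code),
`alpha = 1` a perfectly conserved code. On top of the flavour components
sit a per-voxel baseline, mass-univariate modality offset vectors
(`offset_amp`), run-wise drift, and i.i.d. Gaussian sample noise
(`sigma_noise`).

`simulate_betas()` composes one sample per condition per run:
`baseline + flavour component + modality offset + drift + noise`. Drift
is a Gaussian random walk on the pattern vector, restarted per session,
with per-session step SDs `sigma_drift = c(0.25, 0.1)` by default —
stronger on day 1, the asymmetry the drift analysis is designed to
detect. Between sessions the taste components are partially redrawn with
mixing weight `rho_session = 0.7`
(`new = rho * old + sqrt(1 - rho^2) * fresh`), so across-day taste
decoding degrades while odour patterns stay stable.

Parameter defaults are study conditions, not conveniences. The flavour
amplitude default (`amp = 0.05` against `sigma_noise = 0.6`) is
calibrated so that, at the few-hundred-voxel ROI sizes the pipeline
decodes, leave-one-run-out flavour decoding of simulated betas lands in
the mid-50s to 60s percent range and crossmodal decoding in the low 50s,
the regime chemosensory fMRI actually reports (smaller ROIs need a
proportionally larger amplitude, which the scaled-down checks set
explicitly). This matters beyond
realism: the hierarchical permutation test assumes each subject's
observed accuracy is exchangeable with its label-shuffled accuracies.
With implausibly strong unimodal signal the observed crossmodal accuracy
acquires between-subject dispersion (via the random alignment of the
taste and odour flavour axes) that no label shuffle can reproduce, and
the test becomes anticonservative. At realistic signal-to-noise the
calibration holds (measured type-I rate 0.04–0.06 at nominal 0.05).

What the generator deliberately does *not* emulate: autocorrelated BOLD
noise (the GLM stage therefore uses OLS, not prewhitening), physiological
confounds, multi-echo acquisition, spatial realignment errors (data are
born aligned), or spatially structured noise. Passing tests therefore
demonstrate the *statistical machinery* is correct, not that real-data
effect sizes will match.

# First-level GLM

`build_design_matrix()` assembles, per run: HRF-convolved 16 s condition
boxcars and the 4 s rinse regressor of no interest (canonical
double-gamma HRF — response delay 6 s, undershoot delay 16 s, ratio 6,
32 s support, peak-normalised; convolution on a 16-fold upsampled
microtime grid), six motion parameters, one-hot spike regressors for
censored frames, a discrete-cosine high-pass basis with 128 s cutoff
(`floor(2 T / 128)` columns — 7 for a 456 s run), and a run intercept.
Framewise displacement is the 6-parameter backward difference with
rotations converted to arc length at a 50 mm radius; frames are censored
at FD strictly above 1 mm and runs dropped when strictly more than 10% of
frames are censored. Grand-mean scaling maps the in-mask run mean to 100;
global-signal detrending regresses each voxel on the frame-wise in-mask
mean and returns residuals plus the voxel mean.

Estimation is ordinary least squares. This diverges from SPM's AR(1)
prewhitening deliberately: the generator's noise is white, so OLS is the
maximum-likelihood estimator here, and the spike-regressor censoring is
exactly equivalent to deleting the censored frames (verified in the
tests by the delete-one identity). Rank-deficient designs fail loudly
with the offending columns named; constant motion columns (all-zero
traces of a motionless simulation) are dropped because they duplicate
the intercept.

# Decoding

The classifier is a soft-margin linear support-vector machine (C = 1, no
per-voxel standardisation), multi-class by one-vs-one voting. It is
solved natively by an exact SMO (maximal-violating-pair working set) on
precomputed Gram matrices; this makes the permutation machinery feasible
at scale — the Gram matrix and the centred fold kernels are computed once
per dataset and reused across thousands of label shuffles — and the
implementation is cross-checked in the test suite against the LIBSVM
reference (e1071) on hundreds of random problems, where predictions agree
exactly.

Partition schemes are declarative (`make_partitions()`): leave-one-run-out
within a modality, crossmodal (train on all taste samples, test on all
odour samples, and the reverse; the reported accuracy is the unweighted
mean of the two directions), within-day (LORO restricted to each session),
across-day (train on one session, test on the other, both directions),
and a four-class LORO over the non-control conditions whose confusion
matrices carry a 25% chance level.

Crossmodal and cross-session schemes switch on mean centring. The
centring removes mass-univariate activation differences between the
training and testing sides: the training side is centred by the training
mean, and the test side by its own mean. When the two sides share their
mean (as in ordinary cross-validation) this is identical to subtracting
the training mean from both; in cross-side folds it additionally removes
*any* constant per-modality offset exactly, which is the contract the
decoding stage guarantees (and the tests verify to 1e-12): a decoder that
generalises across modalities must not be able to exploit, or be harmed
by, mass-univariate modality differences. Centring only the training
mean into both sides would leave the offset difference in the test set,
where it shifts every SVM decision value by the same amount — exact
invariance is then impossible, which is why the per-side formulation was
chosen.

The searchlight maps `accuracy - chance` in a closed ball of 3 voxels
(centre included, in-mask members only) around every in-mask voxel, and
can smooth the map (6 mm FWHM) for the group stage. Functional ROIs are
generated leave-one-subject-out: a one-sample t-test over the remaining
subjects' contrast maps, thresholded at one-sided uncorrected p < .01,
keeping 6-connected clusters larger than a configurable cut (150 voxels
at brain scale; smaller on toy grids).

# Permutation inference

ROI-level inference is hierarchical: within each subject the condition
labels are shuffled and the full partition scheme re-run (`n_perm` per
subject; the package default 1000 matches the study budget, the
acceptance checks use 200), then a group null is resampled by drawing one
permuted accuracy per subject and averaging, many times (default 1e5,
study scale 1e6). The one-tailed p is the fraction of group-null means at
or above the observed mean, reported as the raw ratio with resolution
1/n_samples (an add-one mode is available for guaranteed-positive p).

The shuffle is stratified within (session, run, modality) cells. Two
properties motivated this reading of "shuffling labels within subject":
the permuted designs stay balanced (every run contributes one sweet and
one savoury label per modality, like the true design), and the train- and
test-side labels of a crossmodal fold remain mutually independent.
Shuffling all four condition labels within a run couples the two sides
negatively (sampling without replacement), and run-shared signal
components — the drift walk — then bias the null *below* chance,
inflating false positives; the stratified shuffle removes the coupling.

Searchlight group inference uses sign-flipping with TFCE. The enhanced
statistic integrates cluster extent and height,
`TFCE(v) = sum_h e(h,v)^E h^H dh` with the canonical E = 0.5, H = 2 and
dh = max/100 over 6-connected components; enhancement is signed
(positive-part minus negative-part TFCE) so the statistic is odd under
map negation. The null records the maximum absolute enhanced statistic
over voxels per sign-flip; voxelwise two-sided p-values against this
max-null are converted to signed z (`z = sign * qnorm(1 - p/2)`), and
survivors are 6-connected clusters of more than 15 voxels with z > 1.65
(one-tailed). Pairwise ROI comparisons use sign-flip paired t-tests with
the repeated-measures effect size
`d_rm = mean(d) / sqrt(s1^2 + s2^2 - 2 r s1 s2) * sqrt(2 (1 - r))`.

# Tuning overlap and drift

A voxel's tuning index is the savoury-minus-sweet T difference within one
modality (the sign convention follows the operational definition;
correlations are sign-invariant, so the choice does not affect any
downstream statistic). From run-wise betas the per-condition T-map is the
across-run one-sample t per voxel. The crossmodal overlap is the Pearson
correlation of the two modality tuning maps over in-mask voxels, and its
across-subject correlation with crossmodal decoding accuracy is the
analysis' endpoint.

Representational drift is quantified from the correlation-distance RDM
(1 minus Pearson r) over the four flavour conditions by run, within
session; same-run and cross-session pairs are excluded, and run distances
are scaled by the largest within-session separation so distal runs are 1
apart. Each unordered pair enters the long table once (double-entering
the symmetric RDM would duplicate every observation and inflate the
residual df without changing the estimates; the df printed alongside
mixed-model t-values is therefore roughly half of what a double-entry
implementation would show). The mixed model has fixed effects
`flavour_dist * run_dist + flavour_dist * session + modality_dist +
session * run_dist` with by-subject random intercepts and slopes for run
distance, modality distance, flavour distance and session, fitted by
maximum likelihood (Satterthwaite df for the t-tests). Session is coded
-0.5 / +0.5, so a negative `run_dist:session_c` coefficient means the
run-distance slope — baseline drift — is smaller on day 2. A fully
parameterised random-effects covariance is tried first; on a singular
fit the model falls back to a diagonal (uncorrelated) structure, which is
reported. The within- vs across-day comparison models per-subject
accuracies with partition type as fixed effect and a by-subject random
intercept; subjects lacking a second session are dropped with a warning.

# Numerical choices and degenerate inputs

* SMO convergence: KKT gap tolerance 1e-8 with multipliers snapped onto
  the box bounds, so at-bound multipliers leave the working sets exactly;
  ties in one-vs-one voting go to the first class in sorted order, making
  predictions deterministic.
* A permuted fold whose training labels collapse to a single class (rare,
  but possible under within-cell shuffles) acts as a constant classifier
  in null construction; the user-facing classifier refuses single-class
  training sets instead.
* Zero-variance voxels get T = 0 rather than NaN; degenerate correlation
  inputs return NA with a warning; a zero-variance difference vector in
  the paired test returns the resolution bound 1/n_perm (pure shift) or
  p = 1 (identical inputs).
* The schedule generator rejection-samples orderings (cap 1e4) and
  re-draws inter-trial intervals until the run fits its nominal length;
  infeasible constraint sets fail with an explicit error.
* Gaussian smoothing renormalises at volume edges so constant volumes are
  preserved exactly; FWHM 0 is the identity.

# Problem sizes used in the checks

The packaged verification runs use desk-scale versions of the study
conditions: 16^3 grids for searchlight recovery (20 seeds, planted 5^3
informative region, peak localised on the smoothed map), 6-subject
single-session cohorts of 40 voxels for the 200-repetition type-I
calibration (n_perm = 200, n_samples = 1e4), 6-subject two-session
cohorts for drift-sign recovery (20 seeds), and 25-subject cohorts for
the overlap-accuracy power check (10 replicate cohorts). The acceptance
script simulates a 25-subject, two-session cohort on a 10 x 10 x 8 grid
at the generator defaults and reports group accuracies, the crossmodal
permutation p, the overlap-accuracy correlation, the within/across-day
contrast and the drift coefficients, alongside the two analytic design
quantities (the six-of-eight triangle-test criterion and the 25%
four-class chance level).

# Known limitations

* White-noise BOLD only; no AR structure, so OLS standard errors would be
  optimistic on real data — on real runs an AR(1) prewhitening step
  should replace `fit_glm()`'s OLS.
* The generator's drift is a single random walk shared by all conditions
  within a run; it produces baseline drift and session asymmetries but
  not flavour-specific drift, so `flavour_dist:run_dist` recovery is not
  claimed.
* Group TFCE inference is the sign-flip max-statistic test; prevalence
  inference variants are out of scope.
* No nonlinear kernels, hyperparameter search, or probability
  calibration in the decoder; no Mahalanobis/crossnobis RDMs.
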