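---
title: "Methods: simulating and analyzing valence encoding in odor conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing valence encoding in odor conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorvalence)
```

## The scientific question

During Pavlovian odor conditioning, a neuron's response to an odor can
reflect at least three latent variables: the *identity* of the odorant, the
*reward contingency* (valence) the animal has learned to attach to it, and
the *vigor of licking* the cue elicits. These variables are correlated by
design — rewarded odors are licked at more — so telling them apart requires
a task structure and an analysis battery built for the purpose.
`odorvalence` implements that battery for two-photon calcium imaging at
5 Hz: a six-odor panel in which chemical class (three ketones, three
terpenes) is balanced against contingency, responses summarized per trial,
and encoding assessed with discriminability, generalization,
dimensionality, and regression-omission tools.

Because the package must be verifiable without any particular recording,
it ships a first-class synthetic-session simulator whose ground truth
(which neuron encodes what, and how strongly) is known exactly. Every
analysis stage is tested as a recovery problem against that ground truth.

## Task structure

Two paradigms are generated by `make_odor_scheme()` /
`build_trial_table()`:

* **Contingency switch** (`exp1`). Each of six odors is presented 2 s,
  followed after a 0.1–0.3 s delay by sucrose (`S`), an airpuff (`P`), or
  nothing (`X`), with a 12–18 s intertrial interval. Each contingency group
  holds exactly one ketone and one terpene. From day 4 every odor's
  contingency is reassigned, so cue meaning and cue identity can be
  dissociated across days.
* **Lick-spout removal** (`exp2`). The lick spout is retracted during
  three odors (`N` group) and present for three (`L` group); sucrose
  probability is 0, 0.5, or 1 within each group, and the delay is extended
  to 1.1–1.3 s. This decouples expected value from the possibility of
  licking: `N_hi` has high value but little licking, `L_lo` the converse.
  Within each spout group every sucrose probability occurs exactly once;
  roles are labelled `L_X, L_lo, L_hi, N_X, N_lo, N_hi`.

Trials are arranged in blocks; each block is a permutation of the six
odors and no odor ever repeats more than twice in a row, enforced across
block boundaries by rejection sampling of block permutations.

## The encoding model behind the simulator

`make_ground_truth()` assigns each neuron to one encoder class and draws
its latent weights; `simulate_population()` turns these into per-trial
response amplitudes

$$a_{nt} = s_n\left(w_{id,n}^\top \mathrm{onehot}(o_t) + w_{val,n}\,v(o_t)
  + w_{lick,n}\,\ell_t\right) + \varepsilon_{nt},$$

with $s_n \in \{\pm 1\}$ a response sign, $v(o)$ the contingency value of
the odor (1 for sucrose-contingent and 0 otherwise in `exp1`; the sucrose
probability in `exp2`), $\ell_t$ a standardized anticipatory-lick
regressor, and $\varepsilon_{nt} \sim N(0, \sigma)$ trial noise. The
default $v(o)$ treats the airpuff cue like the control cue because
aversive contingencies produce far weaker cue responses than appetitive
ones in this circuit; a signed variant (`odor_value(..., signed = TRUE)`)
is available. At zero noise, pure valence and pure vigor populations have
amplitude matrices of rank 1, identity populations rank at most 6 — a
property the tests assert.

**Identity tuning is graded by default.** A neuron tuned to a single odor
that happens to be the control ketone is *categorically indistinguishable*
from a valence encoder in the two-auROC quadrant scheme: it discriminates
sucrose-ketone from control-ketone but not the two sucrose cues. To make
"identity encoder" mean what the recovery analyses require — a neuron
whose response separates any two odors — the default identity tuning is a
random permutation of six equally spaced response levels spanning
$[-1.25, 1.25] \times$ `amp_scale` (lightly jittered). At the study's
3× signal-to-noise ratio this puts adjacent levels 1.5 noise SDs apart.
Sparse tuning (`identity_breadth = k`) remains available for modeling
narrowly tuned units, with the caveat above.

**Key scales.** The conventions used throughout: `amp_scale = 0.3` and
trial-noise `noise_sd = 0.1` (ΔF/F units), i.e. an amplitude of 3× the
trial noise SD — the regime in which the recovery guarantees are stated;
`kernel_tau = 1.5` s single-exponential decay (a GCaMP7s-like indicator at
5 Hz; no rise time, the simplest kernel that exercises the windowing);
baselines 40–80 a.u. with a slow linear drift (SD 0.002 a.u./s) plus a
sinusoid of amplitude 0.5 a.u. and 400–800 s period; frame noise 0.3 a.u.

**Behavior.** Licks are an inhomogeneous Poisson process: baseline
0.2 licks/s, an anticipatory ramp during sucrose-contingent odors that
grows from 0.5 s after onset to the US time and peaks at 8 licks/s in a
trained animal, a consumption burst at sucrose delivery, and a 100-fold
rate suppression while the spout is retracted. The anticipatory gain
follows a logistic curve across trials (`learning_rate`, midpoint trial
60 by default); `learning_rate = 0` is defined to give *zero* gain — a
never-learning animal with odor-independent licking — rather than the
literal half-asymptote of a logistic at zero slope. Locomotion slows and
the eye area shrinks around airpuff cues in proportion to the learning
state. The three face-feature channels (tongue-tip confidence,
mouth-corner confidence, lip distance) are noisy affine functions of the
smoothed lick state, standing in for video keypoint outputs; their
Gaussian noise is a parameter (`feature_noise_sd`).

**What the simulator does not emulate:** pixel-level movies and source
extraction, correlated (shared) noise between neurons, response latency
and adaptation within the odor, spiking dynamics, and day-to-day
representational drift beyond the contingency switch. Passing recovery
tests therefore demonstrates that the analysis code measures what it
claims under the stated statistical structure — not that real data are
this clean.

## Preprocessing

The baseline of each neuron is estimated with a two-component Gaussian
mixture fitted inside a moving window of 2500 frames (500 s at 5 Hz); the
mean of the lower-mean component is the "quiet" fluorescence between
transients. The mixture count (2) and the lower-mean selection rule are
this package's choices; the window is refitted every 100 frames and
interpolated linearly in between, with truncated windows at the edges.
ΔF/F is then $(F_t - F_b)/F_b$, and `align_trials()` cuts a
neurons × trials × frames tensor from 2 s before to (by default) 8 s
after odor onset.

All windows are half-open $[t_0, t_1)$ in seconds relative to odor
onset, with a frame assigned by its start time; the odor period is
$[0, 2)$ (10 frames), the "late" window $[1, 2)$ (5 frames), the pre-odor
baseline $[-2, 0)$. The per-neuron response magnitude ΔΔF/F is the
trial-averaged late-window mean minus the pre-odor mean; scaling divides
by the neuron's largest *positive* ΔΔF/F, and all-negative neurons are
flagged and excluded from scaled analyses rather than scaled by their
minimum, since only a positive reference is defined.

## Responsiveness

For each neuron × odor, ΔF/F at each of the 10 odor-period frames is
compared against the pooled pre-odor distribution (300 samples in a
standard 30-trial session) with a two-sided Wilcoxon rank-sum test. The
10 frame-wise p-values form one Holm family (`p.adjust(method = "holm")`
at FWER 0.05), and a neuron is responsive when at least 4 frames — any 4,
not necessarily consecutive — survive. Direction is the majority sign of
the significant frames; exact ties are labelled `mixed` and excluded from
direction-specific counts. For outcome-locked analyses the same test runs
on a US-locked window ($[t_{US}, t_{US}+2)$ against the same pre-odor
pool). Cross-day transfer takes neuron matching as given (the simulator
knows identity; no image registration is attempted) and counts matched
neurons responsive in both epochs with equal direction.

## Single-neuron discriminability

Per neuron and odor pair, the Z-scored late-window means of the 60 trials
feed an unregularized univariate logistic fit, and the auROC of the
fitted scores — folded to $[0.5, 1]$ — is reported. Because a univariate
logistic score is monotone in its input, this auROC *equals* the folded
tie-corrected Mann-Whitney statistic $\max(A, 1-A)$, which is also the
degenerate-fit fallback (perfect separation leaves the rank statistic
unchanged). The suite asserts this identity against a brute-force
pair-counting oracle on 500 random instances. Scoring is on the training
trials by default (a `method = "cv"` flag provides held-out scoring); the
permutation null permutes labels with class counts preserved and uses the
add-one estimator $p = (1 + \#\{A^* \ge A\})/(n_{shuffle}+1)$, computing
the statistic through the rank identity so 10,000 shuffles never refit a
glm.

Quadrant categorization compares the intervalence auROC (sucrose ketone
vs control ketone) with the intravalence auROC (the two sucrose cues)
against a 0.75 threshold — halfway between chance and perfect:
`valence` (inter > 0.75 ≥ intra), `identity` (both above), `identity_S`
(only intra above), `uninformative` (neither).

## Population decoding

Pairwise decoders are logistic or RBF-kernel SVM (`cost = 1`,
`gamma = 1/(n_features × mean feature variance)`; only the kernel choice
is inherited, the hyperparameters are fixed here), evaluated by
stratified 5-fold cross-validation with features Z-scored by
training-fold statistics. Permutation nulls refit the full CV under label
shuffles; the count is configurable (1,000 in the test suite, 10,000 as
the production default). Cross-pair generalization trains on one odor
pair at each odor-period frame and tests on another pair at the same
frame, reporting the maximum over frames; class labels correspond across
pairs by ordering each pair's odors by contingency (higher-value odor
first, ties broken by contingency group then chemical class), so "class
1" means the same thing on both sides. PCA-restricted decoding computes
the rotation on training folds only — stricter than a whole-data PCA,
which remains available behind `whole_data_pca = TRUE` for comparison.

## Geometry

Distance trajectories subtract each trial's pre-odor mean, trial-average
per odor, and report per-frame Euclidean distances between odor pairs
normalized by the global maximum over pairs and frames. The
participation ratio is $(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2$ over
the eigenvalues of the neuron covariance matrix — 1 when one component
carries all variance, $n$ when all contribute equally. The covariance is
computed over all trial-aligned frames concatenated across trials (the
unbiased $n-1$ denominator; immaterial to PR but fixed for
reproducibility); a trial-averaged mode exists
(`tensor_samples(trial_average = TRUE)`). Population-size dependence is
removed by subsampling `k = 15` neurons without replacement, 1000 times
by default.

## Response profiles

Clustering features are the trial-averaged traces per odor, Z-scored per
neuron across the concatenated time axis (a per-feature variant sits
behind `zscore_across = "features"` since the pooling convention is
ambiguous), then averaged in three windows per odor — first odor second,
last odor second, first post-odor second — giving 18 features on a
six-odor panel. Agglomeration uses Euclidean distance with Ward linkage
(`hclust(method = "ward.D2")`, whose merge-height monotonicity the tests
assert), cut at 6 clusters for the switch paradigm and 3 for the
lick-spout paradigm. Cluster labels are renumbered by ascending mean
profile so "cluster 1" is always the most inhibited — a stable convention
that does not depend on agglomeration order.

## Decoupling contingency from vigor

Per neuron, the per-trial response amplitude is regressed on (1) sucrose
contingency, (2) anticipatory licking (licks in the odor window for
`exp1`; the last 0.5 s of odor plus first 0.5 s of delay for `exp2`, with
face-classifier estimates substituting on spout-absent trials), and (3)
both plus their interaction. The reported quantities are the R² losses
when a variable *and its interaction* are omitted (keeping the
interaction in the reduced model is available behind a flag). Both losses
are non-negative by nesting. At the session level, pairwise decoder
accuracies are regressed on pairwise differences in licking
(range-normalized to [0, 1] within session) and in sucrose probability,
singly and combined with interaction.

Lick bouts — used by the distributed-lag analyses — are defined here as a
first lick after ≥ 1 s without licks, with ≥ 3 licks in the following
second; the distributed-lag model regresses a target on lagged regressor
copies (default lags −2 s to 0 s at frame resolution, so features precede
the target), with contiguous-block cross-validation for out-of-sample R²
and an optional ridge penalty for collinear designs (a degenerate design
aborts, naming its condition number).

## Pipeline and reproducibility

`run_pipeline()` drives simulate → preprocess → analyze → report from a
validated configuration (YAML or list), writing CSV tables, a plain-text
session container (one directory per session with fluorescence, behavior,
trial, and ground-truth tables — the package's session format), and a
manifest with MD5 hashes. A single root seed fans out to named substreams
(`derive_seed()`), so toggling one stage never perturbs another's
randomness, and identical configurations yield identical manifests. Later
stages fail fast with a named dependency error when an upstream output is
missing. A thin command-line wrapper ships in `inst/cli/`.

## Problem sizes used by the test suite

The suite verifies closed forms exactly and statistical properties on
deliberately small instances chosen to make each property measurable:
standard 30-block sessions wherever a claim depends on the study's trial
counts (auROC power, quadrant recovery, the 300-sample baseline pool),
and 4–10-block sessions with 10–50 neurons elsewhere. Recovery claims at
"3× SNR" always use `amp_scale = 0.3`, `noise_sd = 0.1`. Null
calibrations use 200–500 simulated neurons and 200–1,000 permutation
shuffles. The pipeline smoke test runs a full six-stage session (12
neurons, 4 blocks) twice and compares manifests.

## Known limitations

* The moving-baseline estimator assumes transients occupy a minority of
  each 500 s window; dense activity biases the lower mixture component
  upward.
* Training-data auROC is optimistically biased for small trial counts;
  the permutation null, not the auROC point value, carries the inference.
* Unregularized logistic decoders degrade when trials barely exceed
  neurons; the suite's population sizes keep trials ≥ 3× features, and
  the SVM learner is the cross-check.
* The quadrant scheme cannot distinguish a valence encoder from an
  identity encoder tuned solely to a non-sucrose odor of the tested pair;
  this is a property of the categorization, inherited by design.
* Simulated sessions have independent noise across neurons; estimates of
  dimensionality on real, noise-correlated populations will differ.
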