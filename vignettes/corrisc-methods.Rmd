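---
title: "Methods: correlated components and intersubject correlation of EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated components and intersubject correlation of EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When several people watch the same video, part of their EEG is driven by the
shared stimulus and is therefore correlated across viewers. Intersubject
correlation (ISC) quantifies that shared drive; a cohort whose members
synchronize poorly with a reference group — for example, patients with
congenital upper-limb motor dysfunction compared against healthy children —
is processing the stimulus differently. `corrisc` implements the full
analysis chain for such comparisons: preprocessing, correlated components
analysis (CorrCA), leave-one-out and time-resolved ISC, component alpha
power as an attention covariate, automatic movement annotation of the video
from pose keypoints, and the group/covariate statistics. Because clinical
EEG of this kind cannot be shared, the package also contains a synthetic
cohort generator with known ground truth; every claim the test suite makes
is a claim about recovering that ground truth.

## Correlated components analysis

Let `x_i(t)` be subject `i`'s D-channel signal. CorrCA looks for electrode
weightings `w` such that the projected time courses `y_i(t) = w' x_i(t)`
are maximally correlated between subjects. With the within-subject
covariance `Rw = (1/N) sum_k R_kk` and the between-subject covariance
`Rb = (1/(N(N-1))) sum_{k != l} R_kl` (where `R_kl` is the cross-covariance
of subjects `k` and `l`), the maximizers of `w'Rb w / w'Rw w` are the
eigenvectors of `Rw^-1 Rb`, ordered by eigenvalue. Covariances are computed
per video block and averaged over blocks, so one set of projection vectors
serves all stimuli and per-video ISC values can be averaged per subject.
Both groups enter the fit together, so the optimization favors neither.

Numerics: the non-symmetric eigenproblem is solved through the symmetric
equivalent on the `Rw^(-1/2)` transform. `Rw` is shrunk first,
`Rw_reg = (1 - s) Rw + s mean(diag(Rw)) I` with `s = 0.1` by default:
channels zeroed by the preprocessing make `Rw` rank-deficient, and the
shrinkage keeps the problem well posed without noticeably rotating the
leading components. Forward-model scalp maps are `A = Rw W (W'Rw W)^-1`;
each component's sign is fixed by making the largest-magnitude entry of its
forward model positive, so scalp maps are reproducible across runs.

ISC of a component is the mean pairwise Pearson correlation between a
target subject's component time course and each member of the reference
cohort (the target excluded from its own reference set — "leave one out").
The reported per-subject ISC is the sum over the three strongest
components of the across-video mean, in that order: per-video means first,
then the across-video average, then the top-3 sum. Time-resolved ISC slides
a 1.5 s window advanced by 0.3 s (1.2 s overlap) over the recording and
reuses the whole-recording `W`; windows in which more than half of a
subject's samples are zero-filled are set missing for that subject.

One property worth knowing: components are selected as in-sample maximizers
of correlation, so on pure-noise data the leading component's ISC is biased
slightly above zero (about +0.01 at N = 10, T = 30000 in our measurements).
Group comparisons are unaffected — both groups are scored under the same
fit — but absolute null levels should only be read from projections fitted
on independent data, which is how the test suite calibrates them.

## Preprocessing

The cleanup chain runs in a fixed order: segment extraction/alignment,
band-pass, bad-channel zeroing, ocular ICA, outlier zeroing, z-scoring.
No stage changes tensor dimensions, and the chain is deterministic given
the configuration and seed.

* **Band-pass 1–50 Hz.** Implemented as a zero-phase frequency-domain
  filter with raised-cosine transitions (high-pass ramps over
  `[f/2, f]`, low-pass over `[f, 1.3 f]`). A time-domain IIR design was
  not available in the target environment; the frequency-domain filter is
  exactly zero-phase — which matters, since ISC lives off cross-subject
  temporal alignment — and is identically zero one octave into either
  stopband.
* **Bad channels.** A channel is replaced by zeros for the whole segment
  when its average power (mean squared amplitude) exceeds the mean channel
  power by 4 across-channel SDs. A subtlety: because the SD includes the
  candidate channel, the largest attainable z-score is `(D-1)/sqrt(D)` —
  4.13 at D = 19 — so the rule only ever catches channels close to the
  maximal deviation (a broken electrode with tens of times the average
  power), and at D = 17 or fewer it can catch nothing at all. This is a
  property of the rule itself, not of the implementation; the synthetic
  generator injects 30x-power channels, which sit safely in the flaggable
  regime.
* **Ocular ICA.** A deflation FastICA (tanh contrast) extracts components
  one at a time and stops at the first non-converging direction — after
  the stereotyped, strongly non-Gaussian artifacts are out, the EEG
  background is close enough to Gaussian that no further independent
  direction is identifiable, and pressing on would be noise-fitting.
  Components whose time course correlates above 0.7 (in magnitude) with a
  frontal ocular proxy are subtracted. The proxy is the difference of a
  prefrontal and a lateral frontal electrode (`Fp1 - F8` by default):
  ocular transients load maximally at Fp and fall off laterally, so this
  difference retains them, whereas the near-symmetric `Fp1 - Fp2`
  difference cancels most of a blink and makes a poor detector. Both the
  pair and the threshold are configurable.
* **Outliers.** Samples whose magnitude exceeds the channel's mean
  magnitude by 3 channel SDs are zeroed together with 40 ms on each side
  (41 samples per isolated spike at 500 Hz; overlapping pads are unioned).
  The spread term is the SD of the signal, not of its absolute values:
  for Gaussian background the two sit at 3.8 vs 2.6 channel SDs, and the
  lower variant fires on ~0.9% of perfectly clean samples — with the
  mandatory pads that would zero over a third of artifact-free data and
  visibly depress ISC, which contradicts the intended "rare outlier"
  semantics. With the adopted threshold the full chain changes
  component-1 ISC of clean synthetic data by well under 0.05.
* **Z-scoring** uses the population SD (denominator N); at the segment
  lengths involved (10^4 samples and up) the distinction from the sample
  SD is immaterial. All-zero (bad) channels pass through untouched;
  constant non-zero channels cannot be standardized and are zeroed with a
  warning.

## Alpha power

Each subject's attention covariate is the relative alpha power of the
component time courses: per component and video, the 8–12 Hz band power of
a Hann-tapered averaged periodogram (2 s segments, 50% overlap) divided by
the broadband power; values are averaged over videos and summed over the
three strongest components. "Band power" is the integral of the density
over the band, so a flat spectrum yields the band-width ratio (4/250 for
the default broadband). The broadband interval defaults to `[0, fs/2]`:
a nominal 0–500 Hz reference band is not representable at a 500 Hz
sampling rate, and the Nyquist interval is the defensible reading; the
band is configurable (e.g. `[0, 50]` to reference the filtered bandwidth).

## Movement annotation

Pose-estimator output (per-frame JSON, BODY_25 keypoint ordering) is
reduced to per-frame limb displacements: for each consecutive-frame
transition and limb class (arms: elbows + wrists; legs: knees + ankles,
both configurable), the displacement is the maximum over detected people
and keypoints seen with sufficient confidence in both frames — the "max"
aggregation captures any visible limb movement without assuming person
identity tracking. A limb moves when its displacement lies strictly
between two thresholds: at or below the lower threshold is camera jitter,
at or above the upper is a scene cut. Thresholds are data-dependent
configuration with no universal default; the synthetic track generator
constructs tracks against stated thresholds, which is what gives the
recovery tests ground truth. Windows take the modal per-frame joint state
(`arm` / `leg` / `both` / `neither`); ties resolve by the fixed priority
`both > arm > leg > neither`, chosen to favor sensitivity to motor
content and logged when used. The labels partition the windows by
construction.

## The synthetic world

`cohort_spec()` states the world the tests live in: two groups (23 + 23 by
default) of 19-channel, 500 Hz recordings over 4 video blocks; a small
number of latent sources (3) band-limited to 1–45 Hz, mixed into channels
through fixed random orthonormal topographies and shared by every subject;
per-subject gains of 1 (healthy) vs 0.5 (patients); unit-SD channel noise,
20% of whose power sits in the alpha band; optionally, a patient-only
shared source (gain 0.3) giving patients residual mutual synchrony, since
the emulated finding is that patients synchronize with each other while
synchronizing poorly with controls. The default 60 s per video matches the
scale at which the recovery properties are stated; full 360 s blocks are a
parameter away. With these defaults the source-aligned projection has
SNR 1, so the closed-form pairwise correlation of two healthy subjects'
component-1 projections is `lambda^2 / (lambda^2 + sigma^2) = 0.5`, which
the tests verify by simulation.

What the generator does **not** emulate: realistic EEG spectra (1/f
background, line noise), volume-conduction physics, non-stationarity
across a session, or the actual video content. A green test therefore
establishes that the algorithms recover the stated statistical structure,
not that the package reproduces any particular clinical effect size.
Artifact injection (asymmetric frontal blink-like transients, high-power
channels, 50x spikes) exists to exercise the cleanup rules, with every
insertion position recorded for recovery testing.

## Statistics

The group contrast is a Welch two-sample t-test on the per-subject top-3
ISC sums, reported with Cohen's d in the pooled-SD convention (the
conventional pairing even alongside Welch's unequal-variance statistic).
Covariate control is a one-covariate ANCOVA: Type-II sums of squares for
the group effect (`y ~ group + cov`), the group x covariate interaction
tested separately in the moderated model, and covariate-adjusted group
means at the grand covariate mean with Bonferroni-adjusted pairwise
p-values. Generalized eta-squared is reported as
`SS_effect / (SS_effect + SS_error)`, i.e. with the covariate treated as
part of the manipulated design — in a two-group between-subjects layout
with one covariate this equals partial eta-squared, and it is the form
consistent with the effect sizes reported in the literature this package
follows. Rank association uses tie-corrected Kendall tau-b (exact
permutation p for n <= 8, normal approximation above); within-group
synchrony uses the one-tailed one-sample Wilcoxon signed-rank test (exact
signed-rank distribution for n <= 25 without ties, otherwise normal
approximation with continuity and tie correction) with effect size
`r = |Z|/sqrt(n)`.

The windowed-ISC mixed model is assembled here (one row per patient per
window: ISC, movement label, clinical/cognitive scores; fixed effects
movement + scores + score x movement; random intercepts for subject and
subject x movement) and fitted by `lme4::lmer` under REML — the REML
machinery is deliberately not reimplemented. `lme4` reports no
finite-sample p-values; per-coefficient p-values use the normal
approximation on t, which is adequate at the window counts involved
(hundreds per subject) and is flagged as approximate in the output. For
the same reason the suite validates the mixed model by parameter recovery
(a known movement effect lands within 2 SEs) rather than by a
rejection-rate calibration that the approximation could not honestly meet
to tight tolerance.

## Configuration surface and formats

All thresholds live in plain R objects (`preprocess_config()`,
`movement_config()`, `pipeline_config()`) and serialize to JSON; YAML is
not supported in the target environment. EEG comes in and out as either a
tab-delimited channels x samples matrix with a JSON sidecar, or minimal
continuous 16-bit EDF (1 s records), which bounds round-trip accuracy at
about 1/65000 of a channel's range — immaterial next to the quantities
analyzed. Readers reject silently inconsistent inputs (mixed sampling
rates, missing montage channels) rather than coercing. A thin CLI wrapper
is installed under `inst/cli/corrisc.R`; the exported functions are the
primary interface.

## Known limitations

* The bad-channel rule's self-inclusive SD makes "mean + k SD" flagging
  mathematically impossible for small channel counts (see above); with
  19 channels only near-maximal outliers are caught.
* The leading in-sample component carries a small positive ISC bias on
  null data; absolute null levels need held-out projections.
* The ICA stage identifies ocular components by a frontal proxy
  correlation; artifacts with no frontal expression are out of its scope.
* Sliding-window ISC at sub-second windows is noisy by nature; the window
  grid supports 0.2–5 s, but interpretation at the short end should lean
  on the across-window aggregate, not single windows.
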