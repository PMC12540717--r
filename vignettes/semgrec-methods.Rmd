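---
title: "Methods: windowed sEMG features, tree ensembles and L-SHADE tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed sEMG features, tree ensembles and L-SHADE tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its scientific choices: the
signal model, the feature definitions and their quirks, the evaluation
protocol, the optimizer, and what the synthetic data does and does not
establish.

## Signal model and preprocessing

Surface EMG is modeled here as band-limited stochastic activity
(roughly 20–450 Hz) whose envelope follows muscle activation,
contaminated by 50 Hz power-line interference and low-frequency motion
artifacts. The denoising chain applies, per channel and in this order:

1. a second-order IIR notch at 50 Hz. The design places unit zeros on
   the unit circle at the notch frequency, so the interference tone is
   rejected exactly while DC passes untouched. The quality factor
   defaults to `Q = 30` (a −3 dB width of about `f0/Q` ≈ 1.7 Hz at
   50 Hz): narrow enough to leave neighboring EMG content intact,
   wide enough to be robust to small mains-frequency drift.
2. a Butterworth band-pass with cutoffs 10 and 500 Hz and analog
   prototype order 4 (the digital band-pass realization has eight
   poles). The 10 Hz edge removes motion artifact; 500 Hz is the upper
   edge of useful surface-EMG content at a 2 kHz sampling rate.

Filtering is **causal single-pass by default**, matching on-line
prosthetic use where future samples are unavailable; a zero-phase
forward–backward option exists for off-line analysis. Tests that
measure attenuation do so on the steady-state half of a 2 s tone so
filter transients do not contaminate the measurement. Both stages are
verified stable (poles strictly inside the unit circle) at design time.

## Windowing

Windows are 256 ms with 25 % overlap, read as *overlap equal to a
quarter of the window* (64 ms): at 2 kHz this gives `W = 512` samples
and step `384`. The window count over `n` samples is
`floor((n − W)/step) + 1`; a trailing remainder shorter than one
window is discarded rather than padded, keeping every feature row a
statistic of exactly `W` samples. The alternative reading
(step = 25 % of the window) is available by setting
`overlap_frac = 0.75`. Features are computed on the *preprocessed*
signal, following the pipeline ordering denoise → segment → extract.

## The 17 features

Eleven time-domain features are computed per window and channel: MAV,
RMS, VAR, AAC, DASDV, ZC, WL, WAMP, iEMG, MYOP and the log detector.
Six frequency-domain features (TP, PKF, FR, MNF, MDF, MNP) come from a
one-sided periodogram. Several definitional choices deserve record:

* **VAR** is the *uncentered* second moment `Σx² / (N−1)`, as commonly
  printed in the sEMG feature literature (the window is approximately
  zero-mean after band-passing, so centering changes little).
* **WL** as often printed (`Σ|x|²/(N−1)`) is algebraically identical
  to that VAR, which would duplicate a column; the default is the
  conventional waveform length `Σ|x_{p+1} − x_p|`, with the printed
  form available via `wl_convention = "as-printed"`.
* **PKF** follows the same pattern: the printed half-total-power form
  duplicates the median-frequency defining expression, so the default
  is the frequency of maximum power, with `pkf_convention =
  "as-printed"` available.
* **MDF** is the first frequency bin whose cumulative power reaches
  half the total, without interpolation — the simplest deterministic
  tie-break, exercised explicitly in the tests (two equal point masses
  give the lower frequency).
* **ZC** uses the strict sign-product test with no noise threshold; a
  sample exactly at zero ends no crossing.
* **WAMP** counts successive-difference magnitudes `≥` threshold;
  **MYOP** counts samples with `|x| ≥` threshold. Both thresholds
  default to 0.01 signal units — amplitude units are treated as opaque
  throughout, so the thresholds are plain configuration, not volts.
* **LOG** computes `exp(mean(log(|x| + ε)))` with `ε = 1e-12`, since
  the bare formula diverges at any zero sample.
* **FR** is low-band over high-band power with default bands
  10–250 / 250–500 Hz: the passband split at its midpoint, in the
  absence of a stated convention.

The periodogram uses a rectangular taper on the mean-detrended window
and is normalized so spectral powers sum to the detrended mean square
(Parseval consistency, asserted to 1e-6 in tests). Every feature is
checked against an independently coded naive-summation oracle to 1e-10
(time domain) / 1e-8 (frequency domain) relative tolerance on random
windows.

## Split protocol and metrics

The train/test split is temporal: the first 70 % of each gesture's
windows (in recording order) train, the rest test, with no shuffling —
overlapping windows make shuffled splits leak heavily, so this is the
conservative protocol. A global single-cut variant exists for
completeness. Precision, recall and F1 are **support-weighted**
averages of per-class values; under that averaging the weighted recall
is identically the accuracy, an invariant asserted on every report. A
class never predicted contributes zero precision rather than NaN.

The split-quality diagnostic `2I/(H_split + H_class)` (mutual
information of split side and class, normalized by the two entropies)
is computed in bits; the normalization makes the score base-invariant,
and base 2 keeps the intermediate entropies on the conventional scale.
It is a diagnostic of extremely-randomized-tree node scoring, not a
reimplementation of the forest.

## Classifier backends

The featured backend is extremely randomized trees via
`ranger(splitrule = "extratrees", num.random.splits = 1)`, grown on
the full learning sample. Two mapping caveats, both deliberate:

* ranger's extratrees splitrule scores candidate splits with Gini
  impurity only; the `criterion` dimension ({gini, entropy}) is kept
  in the search space for interface fidelity but both levels realize
  Gini impurity in this backend.
* `min_samples_split` maps to ranger's `min.node.size`, the closest
  available control of when a node stops splitting.

Additional backends (`rf`, and `dt` when rpart is installed) are
registered behind the same name registry; the registry validates
hyperparameters against each backend's declared space and lists valid
names on a lookup miss. ranger interprets a literal seed of 0 as
"seed from the clock", so the package shifts user seeds by one
internally to keep the documented default seed deterministic. No
feature normalization layer is applied: tree ensembles are invariant
to monotone per-feature transforms, so standardization would be a
no-op for the featured backend.

## L-SHADE

The optimizer maximizes a scalar objective over the unit box; integer
dimensions decode by affine rounding and categoricals by equal-width
binning, so the evolution operates on a purely continuous
representation. Per generation and individual:

* a memory cell `k` is drawn uniformly from `H` cells (default 6);
  `SF ~ Cauchy(M_SF,k, 0.1)`, resampled while ≤ 0 and clipped to 1;
  `CR ~ N(M_CR,k, 0.1)` clipped to [0, 1]. All cells start at 0.5.
* the trial is current-to-pbest/1 with external archive — the strategy
  of the canonical L-SHADE family; the pbest pool is the top
  `max(2, ceil(0.11·NP))` individuals, the archive holds up to
  `1.4·NP` replaced parents with uniform-random eviction. Out-of-box
  coordinates are repaired to the midpoint between parent and violated
  bound, which keeps repaired coordinates strictly interior whenever
  the parent is.
* selection keeps a trial that does not degrade fitness; *strict*
  improvements record `(SF, CR, Δf)` and push the parent to the
  archive. After the generation, the weighted Lehmer mean
  (`Σw S²/Σw S`, `w ∝ Δf`) of the successes is blended into the cell
  at the cycling write index: `M ← c·M + (1−c)·mean_wl`, with
  `c = 0.5`. The blend (rather than an overwrite) is implemented
  exactly as specified; `c = 1` freezes the memory, a degenerate case
  used in the engine-vs-reference equivalence test. An empty success
  set leaves both memory and write index unchanged.
* the population follows linear size reduction,
  `NP = round((NP_min − NP_max)/NF_max · NF + NP_max)`, dropping the
  worst-fitness members with ties resolved toward keeping older
  indices (stable ordering).

**Budget semantics.** The size schedule is written in objective
evaluations, while tuning budgets are naturally stated in generations;
both modes are exposed. With only a generation cap, the evaluation
budget is derived from the linear schedule as
`np_init + round(max_gen·(np_init + np_min)/2)`. Candidates whose
objective returns a non-finite value are treated as worst-possible
(with a warning); the fitness improvement recorded when such a
candidate is replaced is capped at a large finite value so the Lehmer
weights stay well-defined.

**Tuning objective.** The default fitness is mean accuracy under
3-fold cross-validation with *contiguous per-class blocks* inside the
training set — no leakage from the held-out test data. A holdout
protocol that scores directly on a supplied evaluation set is also
available for mirroring setups that tune against the reserved 30 %.
Every classifier fit inside the objective uses one fixed seed, so the
objective is deterministic per candidate and whole runs replay exactly
from the optimizer seed. A random-search baseline at identical budget
shares the interface, and further optimizers can be plugged in behind
the same `objective(genome) → fitness` contract.

## Synthetic sEMG

The generator emulates a six-gesture, two-channel, 2 kHz acquisition
with 40 s per task: white Gaussian noise shaped by the package's own
20–450 Hz Butterworth design (an EMG-like spectrum), amplitude-
modulated by a per-gesture envelope (constant baseline 0.35 plus
periodic bursts at a class-specific rate and duty cycle), plus a 50 Hz
interference sinusoid with random phase and a small white noise floor
(sd 0.05). Class identity is carried by the per-channel amplitude pair
and the burst pattern; the default profiles were chosen once so the
default-parameter classifier lands in the 0.85–0.99 accuracy band —
clearly learnable yet below ceiling, leaving visible headroom — and
were frozen (measured 0.89–0.92 across generation seeds).

**Sessions** differ by a multiplicative amplitude gain: the first
session is the nominal (enrollment) recording at gain 1, and each
later session draws a gain uniformly within ±`session_jitter` of
nominal. Under this reading, a jitter of 0.1 bounds the train-vs-test
amplitude drift of a cross-session protocol at exactly 10 %, which is
what the parameter's name promises; jittering every session
independently would allow twice that between two sessions. This is a
gain-drift surrogate for electrode shift and fatigue, not a
physiological model.

What passing tests on this data do **not** show: real sEMG has
motor-unit structure, non-stationarity within a task, inter-subject
variability and electrode-configuration effects that the generator
deliberately omits (no MUAP trains, no fatigue dynamics, no amputee
signals). Results here validate the pipeline's mechanics and the
optimizer's behavior, not clinical-grade recognition accuracy.

## Problem sizes and numerical choices

The test suite runs the full study geometry where it matters (40 s
tasks, 1248 windows × 34 features for the end-to-end experiment; three
sessions for the cross-session protocol) and 8 s tasks for unit-level
checks. Tuning tests use a reduced budget (population 20, 20
generations, ≈ 260 evaluations, three optimizer seeds); the optimizer
benchmark uses the 10-D sphere on [−100, 100] with a 50 000-evaluation
budget, where the engine reaches the optimum to below 1e-8 in every
seeded run and dominates random search. Feature round-trips serialize
at full double precision (`%.17g`), making CSV read-after-write
bit-exact. The t-test guards against constant-shift inputs whose
difference variance is floating-point residue (relative tolerance
1e-10) and reports the exact zero-variance failure instead of an
unstable statistic.

## Known limitations

* The extratrees backend cannot realize entropy-based impurity; the
  `criterion` dimension is effectively inert there (see above).
* Causal filtering leaves group delay in the features; the zero-phase
  option changes feature values, so models should not be mixed across
  the two modes.
* The synthetic classes are separable mainly by amplitude and burst
  statistics; frequency-domain features contribute less than they
  would on real recordings with class-dependent spectral shifts.
* Archive eviction and tie-breaks follow common practice where the
  algorithm family leaves them open; they are seed-controlled and
  documented rather than canonical.
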