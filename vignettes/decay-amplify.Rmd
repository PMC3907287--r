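---
title: "Storing an analog variable by decay and re-amplification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing an analog variable by decay and re-amplification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavemem)
```

## The problem

In delayed-discrimination tasks a transient analog stimulus (here: the
frequency of a tactile vibration, `f1`) must be held in working memory
across a delay of a few seconds and then compared against a second stimulus
`f2`. Recordings from frontal cortex during such tasks show monotonic
encoding — firing rates that increase with the remembered frequency — but
with three awkward features for the textbook model of analog memory, the
line attractor:

1. cells split into **early**, **persistent** and **late** classes by when
   during the delay they are tuned to the stimulus;
2. the **number** of tuned cells falls during roughly the first half of the
   delay and rises again afterwards (a U-shaped count);
3. the firing rate of persistent cells is not constant: a common pattern is
   a decline followed by a recovery around the middle of the delay.

A perfect line attractor would hold every tuned cell at a constant rate and
keep the tuned count constant. It also requires synaptic coupling tuned to
machine-precision unity, and even then diffuses under noise.

`wavemem` implements an alternative mechanism in which all three features
are part of the solution rather than noise: the stimulus is carried by a
travelling activity pulse in an *imperfectly* tuned network; the activity
decays slowly because the tuning is imperfect; and an externally timed
**executive input** arriving near mid-delay un-gates a block of late cells
whose feedback re-amplifies the decayed activity back to the
stimulus-indicative level.

## The model

Cell activities `x_i(t)` follow the stochastic rate equation (Euler–Maruyama
integrated)

    dx_i = ( -x_i + F( sum_j W_ij x_j + feedback_i ) ) dt + sigma dB_i

with the membrane time constant fixed at 1 (it defines the time unit) and
`W` a feed-forward nearest-neighbour chain, `W[i, i-1] = g`
(`build_chain_weights()`). The gain `F` (`gain_spec()`) is rectified
piecewise-linear — zero below threshold, never negative, optionally
saturated — and is the handle through which task events act on the network:

| configuration | phase portrait of `x = F(g x)` | role |
|---|---|---|
| loading     | stable fixed point at the stimulus level | drive activity to `load_level(f1)` |
| maintenance | line attractor when `s g = 1` | hold the level across the delay |
| comparison  | unstable fixed point (separatrix) at `load_level(f2)` | report `f1 > f2` or `f1 < f2` |
| quiescent   | `F == 0` | make late cells ignore their input |

The stimulus enters through a strictly monotone map from frequency to
loaded level (`stimulus_map()`; default linear, `f` in [10, 34] onto
activity [0.4, 1.2]). Loading is performed by direct initialisation of the
stimulated block at `load_level(f1)`: the loading fixed point is the
dynamical route to the same state, and starting at the loaded level is what
the raster figures of the underlying theory depict. With maintenance gain
`theta = 0`, `s = 1`, the rectification sits at zero so that summed noise
can propagate — which is essential for the trailing-front freeze discussed
below.

### Decay, gating, amplification

With `g` slightly below 1 the pulse amplitude decays as
`x0 * exp(-(1 - g) t)` (`persistent_envelope()`). At `t_exec` the executive
input switches the late block from quiescent to maintenance; the leading
wavefront then advances into the late cells at about one cell per time
constant, recruiting them into stimulus tuning. Simultaneously a single
designated late cell (`feedback_source`, by default the first late cell)
begins to feed back with strength `c` onto every stimulated cell. For a
deep persistent cell `y` and the feedback cell `z` this gives the linear
pair `y' = (g - 1) y + c z`, `z' = -z + g y`, whose dominant eigenvalue

    lambda(g, c) = ( -(2 - g) + sqrt( (2 - g)^2 - 4 (1 - g - c g) ) ) / 2

is the realised amplification rate `a` (`amplification_rate()`); to first
order in the small rates it is the familiar `a = g + c - 1`. The package
works with the exact expression in both directions:
`feedback_strength(g, a) = (a + d)(1 + a)/(1 - d)` (with `d = 1 - g`)
returns the feedback that realises a requested rate. This calibration is
what makes "matched `(d, a)`" configurations have noiseless endpoints equal
to a line attractor's, as the noise-comparison experiment requires.

**What the executive input does to the feedback cell.** Upon gating, a late
cell joins the travelling wave and assumes the persistent-cell solution. On
the amplifying mode the feedback cell's share of that solution is
`z = g y / (1 + a)`. The default `feedback_init = "wave"` therefore sets
the feedback source onto exactly that level at `t_exec`, so amplification
starts at the executive input with no charging transient and the realised
trajectory follows the analytic piecewise-exponential envelope. A
`"zero"` (cold-start) option is provided; it delays effective amplification
by about one time constant, which matters only when the delay is short
relative to the time constant.

### Tuning theory

The piecewise envelope (`decay_amplify_envelope()`)

    x(t) = x0 exp(-d t),                    t <= t_s
    x(t) = x0 exp(-d t_s) exp(a (t - t_s)), t >  t_s

must end the delay inside the resolution band `x0 [1 - eps, 1 + eps]`.
`eps` is interpreted throughout as a *relative* tolerance — the printed
form of the success band in the source theory is ambiguous on this point,
and the relative form makes every bound dimensionless. Solving the band
condition for `t_s` gives the admissible timing interval
(`timing_interval()`):

    lo = (a T - log(1 + eps)) / (a + d)
    hi = (a T - log(1 - eps)) / (a + d)

clipped to `[0, T]`, with algebraic length
`log((1+eps)/(1-eps)) / (a + d)`, approximately `2 eps / (a + d)`
(`interval_length_approx()`). Because the printed closed form in the source
is illegible, these expressions were derived from the envelope and are
validated in the test suite against a bisection oracle on
`decay_amplify_envelope()` itself. For contrast, a bare line attractor
needs `g >= 1 + log(1 - eps)/T` (`line_attractor_min_coupling()`): for
`eps = 0.1` and `T = 3` that is `g = 0.96488`, i.e. per-synapse tuning to a
few percent, whereas the decay-amplify network tolerates order-one decay
over the delay as long as one *scalar* — the executive-input time — lands
in an interval of length `~2 eps/(a + d)`.

## The two stated worlds

The theory assumes the membrane time constant is much shorter than the
delay, and the raster phenomenology requires wavefronts to traverse a
150-cell chain within one delay. No single delay length serves both
purposes well at reasonable cost, so the package fixes two documented
parameter worlds (both exposed as constructors, all values overridable):

* **`sweep_world()`** (`T = 6`, `d = a` in {0.02, 0.05, 0.1}, `eps = 0.1`,
  `f1 = 22`, readout = last 10 persistent cells): the quantitative timing
  world used for success-rate sweeps, noise comparison and the comparison
  readout. `T = 6` is the shortest round delay for which the analytic
  timing interval of *all three* stand-in rate sets lies strictly inside
  the delay (for `d = a = 0.02`, `hi < T` requires `T > -log(0.9)/0.02 =
  5.3`). The three rate sets and the noise grid
  {0, 0.005, 0.01, 0.02} are stand-ins: the corresponding values in the
  source theory are symbolic in the available text.
* **`raster_world()`** (`T = 150`, `t_exec = 75`, `d = a = 0.005`,
  `sigma = 0.005`): the phenomenology world. Reading the 3 s delay as 150
  membrane time constants (tau = 20 ms) lets the leading front recruit the
  full 50-cell late block between mid-delay and the last tenth of the
  delay, and the trailing front erode the first cells early — the geometry
  the raster figures show. The decay `exp(-0.375) = 0.69` at mid-delay is a
  visible but recoverable dip.

The noiseless stretch experiment (`run_stretch_experiment()`) uses a
shorter delay (`T = 30` doubled to 60): with `sigma = 0` there is no
noise floor to prop the trailing front, which would otherwise sweep the
entire persistent block during a doubled 150-long delay. The measured
quantity — the ratio of late-cell onset times — is scale-free.

## What the trial analysis measures

**Encoding** (`encoding_criterion()`, `encoding_matrix()`): a cell encodes
the stimulus at time `t` if, across an ensemble of `reps = 20` trials at
each of 5 stimulus values, the trial means are *strictly increasing* in the
stimulus and their range exceeds `k_sd = 2` pooled within-stimulus standard
deviations. The underlying study never operationalises "monotonically
tuned"; this criterion is the package's definition. Under label permutation
its false-positive rate is at most `1/5! = 0.83%` (strict ordering of
exchangeable means), which the pure-noise test verifies empirically.

**Classification** (`classify_cells()`): early/late windows are the first
and last 10% of the delay; a cell "encodes in a window" if it encodes at
more than half of the window's recorded time points (majority rule —
robust to single-point noise). Early = first window only, late = last
only, persistent = both, unresponsive = neither. In the raster world this
labels the un-gated block (cells 101–150) late *exactly*, a handful of
leading cells early, and the bulk of the stimulated block persistent; the
first two or three chain cells decay within a couple of time constants and
are labelled unresponsive under the majority rule, which is faithful to
their behaviour.

**Front tracking** (`track_front()`, `front_position()`): level crossings
of half the loaded activity, linearly interpolated between recorded steps
(earliest step at ties); speeds are least-squares slopes. In the plain
pulse the leading and trailing fronts share speed (~1 cell per time
constant). After the executive input, the trailing front freezes: the
rectified summed noise of the early cells — rectification converts
zero-mean input noise into a positive activity floor — plus the tuned
feedback `c z` prop up the rear of the pulse ("summed noise plus a small
amount of feedback"). The prop accumulates through the chain at about one
stage per time constant, so it needs roughly `0.4 x0 / (c z)` time units
to reach the half-maximum contour. The freeze demonstration therefore
gates at `t_exec = 40` rather than mid-delay, at which point the prop
catches and pins the half-maximum front (fitted post-gate speed ~0.02
cells per time constant versus ~1 before) with most of the delay still to
run. With the gate at mid-delay the *encoding*-level trailing edge still
freezes — the classification shows most of the stimulated block
re-encoding by the late window — but the half-maximum activity contour is
only caught near the end of the delay.

**Success and decision** (`trial_success()`, `readout_decision()`): success
means the readout mean (last 10 persistent cells; a single-cell option
matches the noise-comparison protocol of the source, cell #100) ends the
delay inside `load_level(f1) [1 - eps, 1 + eps]`. The comparison phase
switches the stimulated block to a slope-2 gain whose unstable point sits
at `load_level(f2)`; the sign of the readout change across a 1-time-unit
comparison window is the decision, with changes below `1e-6` reported
`undecided`. The feedback gate closes when the comparison starts (the
executive episode belongs to the delay period).

## Numerical choices

* **Integrator**: Euler–Maruyama, `dt = 0.01` time constants, noise
  increment `sigma * sqrt(dt)` per step. The drift is linear and
  non-stiff; halving `dt` moves noiseless readout endpoints by under
  `1e-4`. The state is *not* clipped at zero — only the gain is rectified —
  so noise enters outside `F` as the model prescribes.
* **Noise is phase-independent**: injected during every phase including
  the comparison window and into gated-off late cells.
* **Event timing**: the late gate opens at the first integration step
  starting at or after `t_exec` (closed-interval convention); comparison
  dynamics start strictly after `T`, so the recorded state at `T` is the
  end-of-delay readout.
* **Seeds**: every ensemble/sweep trial gets a distinct seed via the
  counter-based rule `derive_seed()` (multiplicative congruential step of
  the base seed plus a multiple of the trial index, mod `2^31 - 1`).
  Noiseless runs are bit-identical across seeds.
* **Ties**: the U-shape minimum reports the earliest minimiser; front
  crossings take the earliest step.

## What a green test does and does not establish

The synthetic worlds above are the *stated* conditions of the mechanism,
not fits to data: sample sizes (200 trials per sweep point), rate sets,
noise grids and the stimulus map are declared once and the analytic theory
is then required to predict the Monte-Carlo behaviour (0.5 success at the
interval boundaries, width halving when `a + d` doubles, onset stretch
factor 2). A green suite establishes internal consistency of mechanism and
theory — it does not establish that cortical networks use this mechanism,
nor that the specific parameter values are physiological. Known
limitations, inherited from the model class: no inhibition, no negatively
monotonic encoders, no spiking, a single designated feedback cell (any
late-cell configuration that assumes the persistent level would do), and a
quiescence mechanism left abstract (shunting or tonic inhibition are
plausible implementations but are not modelled).
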