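---
title: "Methods: ripple-gated assembly analysis in dCA1-BLA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple-gated assembly analysis in dCA1-BLA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`swrassembly` analyzes dual-site recordings from hippocampal dorsal CA1
(dCA1) and the basolateral amygdala (BLA) across a fear-conditioning
protocol: pre-training sleep, training with foot shocks, post-training
sleep, and a recall test.  The underlying model is a *many-to-one weighted
mapping*: during post-training slow-wave sleep, dCA1 sharp-wave ripples
gate the reactivation of one selective BLA cell assembly, with dCA1
population activity leading BLA activity by roughly 35 ms and with graded
contributions from many dCA1 neurons rather than a few.

The package implements the full chain: ripple detection, ICA assembly
extraction, peri-ripple modulation statistics, a memory/non-memory ripple
taxonomy, Poisson GLM population decoding, and place-cell spatial
information, plus a ground-truth synthetic-session generator so every
stage can be validated against planted structure.

# Ripple detection

The LFP is band-passed 100-250 Hz with a zero-phase frequency-domain
filter (raised-cosine band edges, 10 Hz transition).  The envelope is the
magnitude of the analytic (Hilbert) signal, smoothed with a 4-ms Gaussian
kernel; rectification is available as an alternative
(`ripple_envelope(method = "rectify")`), since published descriptions
rarely disambiguate the two.  Events are contiguous regions where the
z-scored envelope exceeds 1 s.d., promoted to ripples when their peak
exceeds 5 s.d. (3 s.d. for content analyses), with onset/offset at the
1-s.d. crossings and a 20-ms minimum duration.  Because an event *is* a
1-s.d. region, overlapping candidates merge by construction and raising
the peak threshold can only remove events — both are asserted as tests.
Normalization statistics are computed per continuous epoch, over
slow-wave-sleep intervals when available.

The closed-loop simulation (`streaming_trigger`) uses a causal 81-tap
windowed-sinc FIR, a rectified causally smoothed envelope, normalization
from a leading 60-s calibration segment, an 8-s.d. trigger with a
refractory period, and an optional 150-ms delay mimicking a
delayed-stimulation control.  A causal linear-phase FIR was chosen over an
IIR design because it meets the same contract (no future samples) with
simpler, fully reproducible numerics.

**Slow-wave sleep** has no published algorithm in this setting, so
`detect_sws` is a declared heuristic: 1-s bins are slow-wave sleep when
1-4 Hz delta power dominates broadband power (ratio > 0.5) and the
stretch contains at least one ripple and lasts 10 s or more.  A dominance
ratio is used instead of a median split because a within-segment median
split marks ~50% of bins by construction and can never say "this whole
epoch is SWS" or "there is no SWS here".

# Assembly extraction

Spike counts are binned at 25 ms and z-scored per unit (zero-variance
units are dropped with a warning — their z-score is undefined).  The
number of significant co-activation patterns is the number of
correlation-matrix eigenvalues above the Marchenko-Pastur bound
`(1 + sqrt(n_units / n_bins))^2`.  FastICA (symmetric decorrelation,
tanh contrast, fixed seed, re-seeded up to 3 times on non-convergence) is
run on the whitened projection onto those components; unmixing rows are
mapped back to unit space, normalized to unit length with the
largest-magnitude entry positive, and ordered by explained variance.
Members are units whose weight exceeds the pattern mean + 2 s.d.

The null calibration of the Marchenko-Pastur count deserves a note: the
bound is the *asymptotic* edge of the eigenvalue distribution, and the
largest sample eigenvalue fluctuates around it, so for independent data
at 58 units x 10^4 bins a single eigenvalue exceeds the bound in roughly
5-10% of draws.  Green tests therefore assert a high — not perfect —
zero-count rate.

**Activation strength** defaults to the quadratic form `z' (w w') z` with
the diagonal zeroed, which is insensitive to any single unit firing alone;
the plain linear projection `w . z` is exposed as `mode = "linear"`.
Activation events exceed the trace mean + 5 s.d.  Surrogate significance
circularly shifts each unit's bin series (preserving autocorrelation,
destroying co-activation) and counts crossings of the *real* trace's
threshold: holding the statistic fixed while permuting the data is the
standard permutation logic, and re-deriving a 5-s.d. cut per surrogate
would let the planted events inflate the real trace's own cut.

# Peri-ripple modulation and memory classification

Peri-event histograms use 5-ms bins in a +/-500 ms window, smoothed with a
15-ms Gaussian.  The baseline band is |lag| in [300, 500] ms — outside the
+/-150 ms test window, symmetric.  The baseline s.d. of the smoothed trace
is obtained by variance propagation from the raw bins
(`sd(raw) * ||kernel||_2`): the raw baseline bins are nearly independent,
giving ~10x more effective samples than the smoothed bins themselves, which
keeps the 3.3-z rule calibrated instead of inflating its false-positive
rate several-fold.

A unit or assembly is *ripple-modulated* when its smoothed z deviates from
baseline by at least 3.3 for three or more consecutive bins within
+/-150 ms of onset (upward modulation takes precedence).  Two indices
summarize memory involvement:

* RMI = (peak_post − peak_pre) / baseline, peaks on the smoothed rate in
  (0, 150] ms after ripple onset, baseline the mean SWS rate;
* MAI = mean rate after the first shock (3-30 min of training) / mean rate
  before it (0-3 min).

A *memory* assembly/neuron satisfies RMI > 1, MAI > 2, post-training
upward ripple modulation, and no pre-training upward modulation.
Assemblies are evaluated through their activation-event times and single
neurons through their spikes — one code path.

The permutation test redraws ripple onsets uniformly within the SWS
intervals (100 shuffles) and compares the modulated proportion by an
uncorrected chi-squared test.  Two calibration facts matter.  First,
because smoothing correlates neighbouring bins, "three consecutive bins at
z >= 3.3" is not a p^3 event: the per-assembly null modulation rate is
~2-3%, which the type-I calibration test confirms is compatible with a
properly sized test.  Second, that same null rate means a *single*
modulated assembly among twelve (real proportion 8%) is genuinely hard to
distinguish from a ~2.5% shuffle proportion — the power to detect one
yoked assembly out of twelve is limited by arithmetic, not implementation.
In the source setting, sessions typically had several ripple-modulated
assemblies, which is where the reported significance comes from.

# Ripple taxonomy and content

Post-training ripples are *memory-associated* when the memory assembly's
activation exceeds its median + 2 s.d. in any 25-ms bin intersecting
(onset, onset + 150 ms]; the rest are non-memory.  Properties (amplitude,
duration) are compared by two-sided rank-sum tests.  Content difference
scores per dCA1 unit use pooled rates in +/-100 ms windows:
`M|N = |M − N| / (M + N)`, with split-half controls `M1|M2` and `N1|N2`
computed from seeded random equal halves within a class (odd classes drop
one ripple so the halves stay comparable).  Units are grouped
up/none/down by applying the same 3.3-z / 3-bin rule to the z of the
(memory − non-memory) smoothed rate difference — the published grouping
criterion is not spelled out, so this is a declared choice.  The
selectivity index at an amplitude threshold is `S = M / (M + N)` over the
within-class percentages of supra-threshold ripples.

One statistical subtlety: with unequal class sizes (say 200 memory vs
2000 non-memory ripples), `M|N` has *smaller* sampling noise than the
100-vs-100 split-half control `M1|M2`, so under exchangeable labels
`E[M|N] < E[M1|M2]`.  The meaningful calibration is therefore one-sided —
a content difference is `M|N` *exceeding* its split-half noise floor —
and that is what the tests assert.

# GLM decoding

Window schedule: dCA1 predictor windows [-300,-200), [-200,-100),
[-100,0), [0,100) ms and BLA target windows [-65,35), [35,135),
[135,235), [235,335) ms relative to ripple onset, paired elementwise as
printed in the protocol.  The BLA grid is the 100-ms grid shifted by the
35-ms dCA1-to-BLA latency; the assertable invariant is that all windows
are 100 ms wide, the within-pair offset is constant, and it equals the lag
modulo the window width.

Per pair, a Poisson GLM with log link (IRLS, small L2 ridge 1e-4 on the
slopes for separability; escalated tenfold up to three times on
non-convergence) is trained on a random half of the ripples and scored by
the Pearson correlation between predicted and observed counts on the
other half.  The shuffle control permutes the held-out target counts
across ripples and recomputes the correlation (100 shuffles).  The
weight-split analysis ranks dCA1 units by their peri-target
cross-correlogram peak (search window +/-350 ms, wide enough to cover
every schedule pair) and decodes the top and bottom halves separately.

# Spatial information

Rate maps use 1 x 1 cm bins (bin *i* covers [i-1, i) cm from the arena
corner), occupancy from the position sampling interval, and Gaussian
smoothing with "filter width 5 bins" read as a full width of ~5 bins
(sigma = 5/2.355).  Count and occupancy maps are smoothed separately
before division — the numerically stable order; smoothing the raw ratio
is exposed as an option.  Spatial information is
`SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` over visited
bins with `0 log 0 = 0`, and the place-cell filter keeps units whose peak
smoothed rate exceeds 0.4 Hz (strict).

# The synthetic session: what it emulates, and what it does not

`simulate_session()` generates: 1/f LFP with a delta component in sleep
epochs and sinusoidal ripple bursts (uniform 100-250 Hz carrier, Gaussian
envelope) whose peak amplitude is expressed in s.d. of the baseline
ripple-band envelope, so detection thresholds are directly interpretable;
Poisson BLA background with planted co-activating assemblies (25-ms event
windows aligned to the analysis grid, members at `gain` x baseline);
a yoked "memory" assembly following a fraction of post-training ripples at
a 35-ms lag, with its recruitment probability scaled by the dCA1
population count in the schedule-matched window (the many-to-one mapping)
and its event rate multiplied after the first shock; dCA1 units with
log-normal ripple gains; a GLM-coupled BLA target unit whose window
counts are Poisson in `exp(b0 + w . x)`; and a reflected random-walk
trajectory with Gaussian place fields.

Chosen constants, and why: epoch durations default to the protocol's
stated scale (3600 s sleeps, 1800 s training, 300 s test) — at a 20-min
desk scale the pre-sleep peri-ripple histograms become shot-noise sparse
and the 3.3-z rule loses calibration, which is a property of the data
regime, not of the code.  BLA baseline is 5 Hz, the rate regime used in
standard assembly-detection benchmark simulations, putting a gain-8,
4-member assembly's correlation eigenvalue clearly above the
Marchenko-Pastur edge at 25-ms bins; dCA1 baseline is 2 Hz with mean
ripple gain 3.  The yoked fraction (0.3) is a free parameter: the source
does not report what fraction of ripples recruit the memory assembly.
Shocks fall every 3 minutes from 3 min after training onset, at most ten.

Not emulated: spike waveforms, biophysics, theta/REM structure, the
empirical enlargement of memory-associated ripples (property-comparison
tests plant that enlargement directly), and behavioral video.  A green
end-to-end test therefore establishes that the pipeline recovers planted
reactivation structure of realistic magnitude — not that it would handle
every pathology of real tetrode data.

# Degenerate inputs and numerical choices

Zero-variance units are dropped before z-scoring; an all-zero GLM target
returns the capped-intercept fit; zero-variance test counts give r = NA;
a zero SWS baseline makes RMI undefined (unit excluded with a warning);
sessions without shocks yield no memory labels, with a warning.  FFT
filtering subtracts the mean and pads to a 2-3-5-smooth length;
Gaussian smoothing uses direct convolution with edge renormalization.
All randomness flows from one master seed split per stage
(`run_config(seed = )`), and the pipeline writes a deterministic manifest
so a run can be reproduced bit for bit.

# Known limitations

The session format stores LFP as plain CSV rather than HDF5 (no HDF5 R
binding is assumed available).  The importer for externally deposited
datasets is a stub by design: their internal layout is not described in
the protocol.  detect_sws is a heuristic, not a sleep-scoring method.
The permutation test's power for a single modulated assembly among many
is limited (see above); reported proportions should be read per session,
as in the source setting.
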