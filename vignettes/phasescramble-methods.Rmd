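---
title: "Phase-scrambled gratings: stimulus design and tuning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-scrambled gratings: stimulus design and tuning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasescramble)
library(dplyr)
```

## The problem

Developing visual cortex becomes selective for smoothly drifting oriented
gratings. To ask whether the *specific pattern* of experienced motion
sculpts that selectivity (instructive plasticity) or whether experience
merely enables maturation of pre-seeded selectivity (permissive
plasticity), one needs stimuli that drive cortex at a fixed orientation but
vary their spatiotemporal pattern. This package implements the full
computational chain for such experiments: designing a family of
phase-scrambled gratings, modelling ideal responses with linear kernels,
scoring single-cell selectivity, and drawing population-level inferences —
together with a synthetic-data generator so the chain can be validated
end-to-end.

## Stimulus design

One temporal cycle of a 2 Hz grating is discretized into 8 spatial-phase
steps, each shown for $1/(2\,\mathrm{Hz} \times 8) = 0.0625$ s. Smooth
forward motion steps through phases $[1\,2\,\dots\,8]$; any other
permutation is scrambled motion. Because the sequence repeats (10 cycles
give a 5 s stimulus), sequences that are circular rotations of one another
are physically identical; the canonical representative is the rotation
starting at phase 1, and the $8! = 40320$ permutations collapse to 5040
circular-unique sequences.

```{r}
nrow(enumerate_sequences(8))
nrow(enumerate_sequences(4))  # with 4 steps only 6 stimuli exist
```

Three irregularity metrics score each sequence:

* **Best-aligned correlation.** Frame $i$ of sequence $s$ is the spatial
  sinusoid $\sin(2\pi(x + (s_i - 1)/8))$ on the grid
  $x = [0, 1, \dots, 10]/10$. The correlation between two sequences is the
  sum over frames of the product of their sinusoids, maximized over all
  circular rotations of one sequence (a repeating stimulus has no
  privileged start frame), and normalized by the geometric mean of the
  self-products so self-correlation is 1. The package also retains an
  `as_printed` rendering mode, $\sin(2\pi((s_i-1)/8)\,x)$, in which the
  step scales spatial frequency rather than phase; its first frame is
  identically zero, so the phase-offset form is the default and the
  literal form is kept purely for auditability.
* **Summed total phase interval.** The sum, over consecutive frames
  treated circularly (including the wrap from last to first — the stimulus
  repeats), of the circular phase distance
  $\min(|\Delta|, 8 - |\Delta|) \cdot 2\pi/8$. Smooth motion takes unit
  steps everywhere and attains the minimum, $2\pi$.
* **Motion energy.** One cycle is rendered as an $8 \times 16$ X-T array
  (16 spatial samples per cycle: the smallest power-of-two grid on which
  all 8 phase offsets land exactly, avoiding aliasing), 2-D
  Fourier-transformed, and the absolute coefficients summed over all
  nonzero temporal frequencies. Every frame is a unit sinusoid, so total
  spectral power is the same for all sequences; smooth motion concentrates
  it at one spatiotemporal frequency and therefore minimizes this L1
  measure, while scrambling spreads it to higher temporal frequencies.

```{r}
metrics <- sequence_metrics(enumerate_sequences(8))
summary(metrics$corr_smooth_avg)
```

The 10-stimulus family comprises F, B, six scrambled sequences S1–S6, and
two counterphase stimuli CP1/CP2 (frame-wise means of F and B, i.e.
contrast-reversing standing gratings) at spatial phases 0 and $\pi/2$ —
quadrature covers both families of null positions, since only "two spatial
phases" is specified by the protocol. S6 is fixed at `[8 3 6 2 7 4 1 5]`.
S1–S5 are not pinned down by the protocol, so the package ships a
deterministic documented selection (`select_scrambled_sequences()`): after
excluding F, B, S6 and anything with average smooth-motion correlation
above 0.8, the two least smooth-correlated sequences become S4 and S5, and
S1–S3 are the sequences closest to intermediate correlation targets 0.45,
0.35 and 0.25 — giving the intended mix of strongly and intermediately
irregular stimuli while deliberately avoiding near-smooth sequences, whose
training effects would be confounded with smooth-motion experience. Ties
break by enumeration order; no randomness is involved. Users can override
the whole family via `build_family()` or a YAML config
(`read_family_config()`).

## The ideal-kernel model

The ideal kernel for stimulus X is its one-cycle X-T profile reversed in
time — the matched filter, which as a linear receptive field responds
maximally to X under convolution. The response of kernel KX to stimulus Y
is the correlation between the kernel and one cycle of Y at the optimal
circular *temporal* alignment (for drifting sequence stimuli a spatial
shift is equivalent to a temporal rotation, so the search is over temporal
shifts only), normalized so each kernel's response to its own stimulus is
1. Negative responses are rectified to 0 by default, consistent with
firing-rate semantics; a signed mode exists for diagnostics. Whether the
original analysis rectified before forming RPI referents is not stated;
rectification is the package's choice and barely matters here because the
default family's ideal responses are almost all nonnegative.

```{r}
M <- kernel_response_matrix(build_family())
round(unclass(M)[c("KF", "KB", "KS6"), ], 2)
```

Two structural facts are worth noting. First, the counterphase kernels tie
their diagonal: a drifting grating drives a standing-grating kernel at
full amplitude under this normalization, so KCP rows are 1 at F, B and
their own stimulus — the "row maximum on the diagonal" property holds with
ties. Second, the KB kernel's response to any stimulus equals the KF
kernel's response to that stimulus reversed in time; this, rather than a
simple F/B column swap, is the exact forward/backward symmetry (a column
swap would additionally require every scrambled sequence to be
rotation-equivalent to its own reversal, which is false for, e.g., S2).

## Single-cell statistics

With $R$ a cell's vector of mean $\Delta F/F$ responses to the 10 stimuli:

* **Selectivity index**: $\mathrm{SI}(n) = R(S_n) / \sum_m R(S_m)$.
  Negative means are clamped to 0 by default before the ratio (firing-rate
  semantics; a raw mode exists — the original definition is silent on
  negatives). Defined SI vectors sum to 1; because family stimuli are
  mutually correlated, even ideal kernel cells peak near 0.2–0.3.
* **Response projection index**: with $u_1, u_2$ the unit-normalized
  referent rows of the kernel matrix,
  $D_k = \lVert R - (R \cdot u_k) u_k \rVert$ and
  $\mathrm{RPI} = (D_1 - D_2)/(D_1 + D_2) \in [-1, 1]$. The statistic is
  invariant to positive rescaling of $R$ (both distances scale linearly)
  but not to shifts, so the package feeds it raw (not blank-subtracted)
  mean $\Delta F/F$ by default, documented as a switchable choice.
* **Orientation selectivity**:
  $1 - \mathrm{CirVar} = |\sum_k R(\theta_k) e^{2 i \theta_k} / \sum_k
  R(\theta_k)|$ on blank-subtracted responses, with angles doubled so
  opposite directions reinforce.
* **Hotelling gate**: each trial is collapsed to the complex point
  $\sum_k R_t(\theta_k) e^{2 i \theta_k}$; a one-sample Hotelling $T^2$
  test of the mean of (Re, Im) against the origin gives the tuning
  p-value ($F$ approximation with $p = 2$).
* **Double-Gaussian fit**: least squares of
  $R(\theta) = C + R_p e^{-\mathrm{ang}(\theta-\theta_p)^2/2\sigma^2} +
  R_n e^{-\mathrm{ang}(\theta+180-\theta_p)^2/2\sigma^2}$ to per-angle
  means, where $\mathrm{ang}(x)$ wraps differences onto $[0, 180]$ — the
  printed form $\min(x, x-360, x+360)$ lacks absolute values and is
  implemented as $\min(|x|, |x-360|, |x+360|)$, the only reading that
  wraps onto $0°\!-\!180°$. Half-width at half-height is
  $\sqrt{\log 4}\,\sigma$ and $\mathrm{DI} = (R_p - \max(R_n, 0))/R_p$.

No fitting protocol is prescribed by the original analysis, so the package
documents its own: $\theta_p$ initialized at the peak-response angle,
$C$ at the minimum, $\sigma \in [5°, 90°]$ bounded, Levenberg–Marquardt
least squares restarted from widths $\{30, 15, 45, 60, 10\}°$. Restarts
guard against local minima; once two starts agree on the optimum (relative
difference below $10^{-10}$) remaining starts are skipped, since agreement
of independent starts is the evidence the restarts exist to provide. The
direction sweep defaults to 8 directions × 45° (the angle count is not
specified by the protocol; 8 is the field's standard sweep and the
smallest that comfortably constrains the 5-parameter fit).

## Response extraction

$\Delta F/F = (F_\mathrm{stim} - F_\mathrm{base})/F_\mathrm{base}$, with
$F_\mathrm{base}$ the mean over the final 3 s of the preceding
interstimulus interval and $F_\mathrm{stim}$ the mean over the response
window — $[0, 5]$ s by default, with a $[0, 7]$ s mode for cells whose
responses outlast the stimulus. Frames (period ≈ 1.5 s, coarse relative to
the windows) are assigned by their acquisition midpoint falling in the
half-open window. Trials with non-positive baseline are dropped and
flagged, never imputed. The full stimulus window is averaged (no
sub-window is specified by the protocol). Cells pass the responsiveness
gate when a classical one-way fixed-effects ANOVA over all stimulus
conditions plus blank rejects at 0.05, on untransformed $\Delta F/F$.

## Population inference

`bootstrap_delta()` draws, in each of 10,000 replicates, $N$ cells from
the before population and $M$ from the after population (both with
replacement) and records the difference of means; the 5th and 95th
percentiles of the resulting distribution (type-7 interpolation — the
interpolation rule is not specified and type 7 is R's default) bound the
reported interval, and the change is significant when the low bound
exceeds 0. That stated rule is one-sided; the package additionally flags
significant *decreases* (high bound below 0) with `direction = -1`, since
the corresponding figures do mark decreases, but `rpi_significant` in the
pipeline follows the stated positive-bound rule. Whether the 5%/95%
interval was meant as a 90% two-sided CI or a one-sided 95% rule is left
as stated; the symmetric extension is only a flag.

Covariate relations use the Pearson correlation with its t-based p-value
on $n - 2$ degrees of freedom; group comparisons use the classical
pooled-variance two-sample t-test. `pca_project()` unit-normalizes
population mean vectors together with the kernel rows, centers them
jointly, and projects onto the top two principal components (signs fixed
by making each component's largest-magnitude loading positive, so the
plot is deterministic); a fit-on-kernels-only mode is available.

## The synthetic-data generator

The generator produces what the analysis consumes, with the statistical
structure the experimental protocol describes — not a biophysical
simulation.

* **Cells** are noisy kernel mixtures: expected response to stimulus $j$
  is $g \sum_k w_k M_{kj}$ with additive Gaussian trial noise (the
  simplest defensible noise model; nothing more specific is stated).
  Defaults: gain $g = 0.5$ $\Delta F/F$, noise SD $0.05$ (10% of gain),
  8 trials per stimulus — matching the recorded 8 repetitions and typical
  GCaMP6s response magnitudes.
* **Populations**: mixture weights are Dirichlet draws with concentration
  2 on F and B and 0.25 elsewhere — an immature population dominated by
  smooth-motion preference with heterogeneous tails.
* **Regimes**: *instructive* training pulls after-epoch weights toward the
  trained kernel, $w' = (1-e)w + e\,\mathbf{1}_{ST}$ (default $e = 0.5$),
  and leaves the DI distribution unchanged; *permissive* training leaves
  the weight distribution untouched (after cells are fresh exchangeable
  draws) and matures DI from Uniform(0.1, 0.5) to Uniform(0.4, 0.8).
* **Direction sweeps** invert the double-Gaussian model with
  $R_n = R_p(1 - \mathrm{DI})$; a target initial orientation selectivity
  can be hit exactly by solving the noiseless curve's $1-\mathrm{CirVar}$
  for $\sigma$ (`calibrate_sigma_for_osi()`).
* **Traces**: 5 s stimuli with 10 s interstimulus interval (within the
  protocol's 5–10 s range; 10 s keeps the 3 s baseline window essentially
  free of the preceding trial's decay at the default $\tau_\mathrm{decay}
  = 1$ s, so extraction bias is dominated by the brief rise), frame period
  1.5 s, transients rising with $\tau_\mathrm{rise} = 0.2$ s and decaying
  exponentially after offset, on a multiplicative baseline.

What the generator does *not* emulate: correlated noise across cells or
stimuli, response adaptation over trials, neuropil contamination, slow
drift, or cell-matching ambiguity between epochs. Passing tests therefore
demonstrate that the statistics recover the structure they are designed
for — not that they are robust to every artifact of real recordings.

## Validation and problem sizes

The test suite validates every vectorized computation against brute-force
oracles written as explicit loops over the defining formulas (correlation
alignment, DFT-by-definition motion energy, kernel alignment), and
exercises the stochastic machinery at these sizes, chosen to make the
Monte-Carlo error small relative to each acceptance band:

* bootstrap coverage: 500 simulated population pairs ($N = M = 40$,
  1000 resamples) — the 5th–95th interval covers the true difference
  ~90% of the time;
* Hotelling gate: 1000 isotropic 8-trial sweeps — type-I error ~5%;
* tuning recovery: 100 seeded sweeps at 10% noise across
  $\mathrm{DI} \in \{0, 0.5, 1\}$ — median DI error ≤ 0.05, median
  preferred-direction error ≤ 5°;
* regime recovery: 100 seeded animals per regime, 100 cells per epoch,
  2000 bootstrap resamples — instructive animals show significant-positive
  ΔRPI(F vs ST) in ≥ 95% of seeds, permissive animals significant-positive
  ΔDI with non-significant ΔRPI in ≥ 90%.

Note the permissive ΔRPI check runs against an exact null, so its
non-significance rate is pinned at the one-sided rule's specificity
(~95%), not at 100%.

## Known limitations

* The identities of S1–S5 in the original experiments are unknown; the
  shipped defaults are the package's documented selection, and any
  analysis tied to specific published scrambles should supply them
  explicitly.
* The correlation-metric scale depends on normalization choices that are
  not pinned down externally; comparisons should use one mode
  consistently.
* `fit_double_gaussian()` fits per-angle means, not trial-level data, so
  its `sse` is not a trial-noise estimate.
* Animal-level findings from real recordings (correlations with age or
  initial selectivity) cannot be reproduced without those recordings;
  `covariate_correlation()` and `group_ttest()` are validated on synthetic
  data only.
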