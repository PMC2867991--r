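---
title: "Nonlinear dynamics features and SOM classification of multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear dynamics features and SOM classification of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaosEEG)
```

## The problem

Scalp EEG is the macroscopic output of a strongly nonlinear dynamical
system. A long line of work treats short EEG segments as observations of an
underlying attractor and characterises them with invariants from chaos
theory — dimension, divergence rates, entropy rates, determinism tests —
rather than with second-order statistics alone. `chaosEEG` implements one
such analysis chain end to end: six chaos/spectral features are extracted
per multichannel recording and a self-organizing map (SOM) classifies
mental-task states from them. Because public mental-task corpora of the
exact layout studied here are not bundled, the package ships a synthetic
generator that emulates the recording format (7 leads named C3, C4, P3, P4,
O1, O2, EOG at 250 Hz, 10 s segments) with class-dependent spectral and
dynamical structure; every statistic is validated against analytic values
and independent oracles on canonical systems (logistic map, Henon map,
Lorenz flow, AR processes).

## Phase-space reconstruction

All nonlinear statistics operate on a trajectory reconstructed from the
scalar series by the method of delays,
\[
X_i = (x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau}), \qquad
M = N - (m-1)\tau ,
\]
(`delayEmbed()`), or on the spatial *multi-lead* embedding where each lead
is one coordinate of the state vector (`multileadEmbed()`). The package
fixes forward indexing throughout; the backward-window convention found in
parts of the literature differs only by an index shift. The defaults
$\tau = 3$ and $m = 16$ (250 Hz) are the values established by repeated
trial for this type of recording; the theoretical lower bound
$m \ge 2\delta + 1$ is unusable in practice because the number of degrees of
freedom $\delta$ of cortical dynamics is unknown. No automatic
$\tau$/$m$ selection (mutual information, false nearest neighbours) is
attempted. For map-type signals (logistic, Henon) the appropriate embedding
is $\tau = 1$ with small $m$; tests use those.

A *mean period* is needed in several places (temporal exclusion windows).
"Average cycle" is not a well-defined quantity for broadband signals; the
package defines it as the sampling rate divided by the power-weighted mean
frequency of the periodogram (DC excluded), rounded up (`meanPeriod()`).

## Determinism: CTM of the tangent-angle SODP versus IAAFT surrogates

For a trajectory, the tangent vectors are $T_n = X_{n+1} - X_n$ and
$A(n) = \cos\angle(T_n, T_{n+1})$ is their angle cosine (more
noise-tolerant than the angle itself). The second-order difference plot
(SODP) of $A$ plots $A(n+2)-A(n+1)$ against $A(n+1)-A(n)$; the central
tendency measure (CTM) is the fraction of SODP points with norm strictly
inside a radius. A smooth trajectory turns slowly and steadily, so its SODP
concentrates at the origin and its CTM is *large*. (Some descriptions state
the opposite orientation while writing the same counting formula; this
package fixes CTM = fraction inside, larger = smoother, and defines the
determinism ratio on $1 - \mathrm{CTM}$ so the conventional thresholds keep
their meaning.)

The null hypothesis "linear stochastic process with this spectrum and this
amplitude distribution" is represented by IAAFT surrogates
(`iaaftSurrogate()`): iterated alternation of spectral-amplitude imposition
and rank-remapping onto the original sorted amplitudes, starting from a
seeded permutation. Ending on the rank-remap step makes the amplitude
multiset exact; the spectral error after 100 iterations is well below 1%
for AR-like series of length 1024. The determinism ratio is
\[
S = \frac{1 - \mathrm{CTM}_{\text{data}}}{1 - \overline{\mathrm{CTM}}_{\text{surr}}},
\]
clipped at zero, with the conventional reading $S < 0.3$ deterministic,
$S > 0.7$ random, in between partly deterministic. Defaults: 19 surrogates
(the one-sided rank-test convention), radius = 1 SD of the data's SODP
norms (no canonical value exists; the radius is applied unchanged to the
surrogates so the comparison is at fixed scale).

Two properties of this statistic are worth knowing. First, because the
radius is data-adaptive, CTM differences between a signal and its
surrogates are driven by the *shape* of the SODP norm distribution, not its
scale; discrimination is therefore modest in absolute terms, and ordering
statements (chaotic map scores below matched noise) are the robust way to
use $S$. Second, a *pure* sinusoid is a single spectral line whose IAAFT
surrogate is essentially a time-shifted copy, so $S \approx 1$ there by
construction; the smoothness contrast requires cross-frequency phase
structure (harmonic-rich waveforms, chaotic flows), and the tests use such
signals.

## Approximate entropy

`apen()` follows the standard Pincus definition with Chebyshev distance:
match fractions $C_i^m(r)$ of length-$m$ templates within $r$, then
$\mathrm{ApEn} = \phi^m - \phi^{m+1}$ with $\phi^m = \overline{\ln C_i^m}$.
The package default includes the self-match with denominator $N-m+1$. The
bias-corrected variant (exclude self, denominator $N-m$) is available as
`selfMatches = FALSE`, with an explicit "r too small" error naming the
first template left without a match: on weakly correlated data at
$r = 0.2\,\mathrm{SD}$ and $N \sim 1000$, the $m+1$ stage has an expected
match count of order one per template, so zero-count templates occur with
probability near one and the variant is undefined exactly where the
statistic is most often applied — which is why it is not the default. The
two differ at order $1/N$. Comparison is non-strict ($d \le r$) by default,
with a `strict` toggle (irrelevant for continuous data). Defaults
$m = 2$, $r = 0.2\,\mathrm{SD}$ sit inside the conventional
$0.1$–$0.25\,\mathrm{SD}$ band; $0.5$ and $1.0\,\mathrm{SD}$ are common
experiment presets (`apenScaled()`). Note the finite-sample behaviour:
below roughly $0.3\,\mathrm{SD}$ at $N \le 1000$ the estimator saturates,
so tolerance comparisons ("larger $r$, smaller ApEn") are only meaningful
in the valid regime.

## Correlation dimension

`correlationDimension()` implements the Grassberger–Procaccia estimator:
the correlation integral $C(r)$ counts point pairs closer than $r$ whose
temporal separation exceeds a Theiler window $w$ (excluding
autocorrelation-inflated pairs), and $D_2$ is the slope of
$\ln C(r)$ vs $\ln r$ over the scale-free region. Choices:

* **Metric** — Euclidean by default (the counting kernel also supports
  Chebyshev); the norm inside the Heaviside argument is not canonical.
* **Radius grid** — 24 geometric points between the 1st and 50th
  percentile of deterministically sampled inter-point distances, avoiding
  the empty-count tail below and the saturation shoulder above; the grid is
  widened downward if needed so it always spans 1.5 decades.
* **Scale-free region** — the longest contiguous window whose
  centred-difference local slopes stay within a relative tolerance of their
  window mean (ties: smaller slope variance), with the reported slope from
  a least-squares fit over the window. The classical prescription demands
  fluctuation below 1%; at desk-scale $N$ (about 2000 points) that rule
  almost never admits a region, because local slopes of an empirical
  $\ln C$ curve fluctuate by several percent even for clean attractors. The
  default tolerance is therefore 5%, with `tol = 0.01` available as the
  strict preset. Centred differencing halves point-to-point jitter, so very
  short windows can pass by luck; meaningful use sets `minLen` of at least
  5 curve points (the default).
* **Theiler window** — the mean period for delay embeddings, 0 for
  multi-lead embeddings.

Validation: 2000 points on a line segment give $D_2 = 1.0 \pm 0.05$, on the
unit square $2.0 \pm 0.1$; the Henon attractor at $N = 10^4$ matches an
independent $N = 5\times10^4$ brute-force pair-count oracle ($D_2 \approx
1.20$) within $\pm 0.15$ and is stable across $m = 2..4$, while i.i.d.
noise keeps climbing with $m$ — the saturation signature that
distinguishes low-dimensional structure from stochasticity.

## Largest Lyapunov exponent (small-data-sets method)

`lyapunovExponent()` follows Rosenstein: each point is paired with its
nearest neighbour at temporal separation beyond the mean period, the pairs
are advanced step by step, and
$y(i) = \langle \ln d_j(i) \rangle$ grows linearly with slope
$\lambda_1 \Delta t$ while divergence is exponential. Pairs that reach
exactly zero distance at a step are dropped from that step's mean rather
than floored at an arbitrary epsilon (they carry no divergence
information); the count is reported. The fit window can be given
explicitly; `autoFitWindow()` selects the longest early run of steps whose
local slopes are positive and stable within 20% — a curve that saturates
immediately (i.i.d. noise) has no such run and raises a typed error, which
the pipeline records as a flag rather than a number.

For multichannel recordings (`lyapunovFromRecording()`), the selected leads
are *spliced*: z-scored per lead (preventing amplitude offsets from
creating artificial jumps) and concatenated. Embedding windows that
straddle a splice joint would create spurious neighbours, so they are
masked from the neighbour search and from advanced pairs. Validation:
logistic map $\lambda_1 = \ln 2$ recovered within $\pm 0.1$; Henon within
20% of a Benettin tangent-map oracle; a Lorenz trace packaged as a
recording within 25% of the variational-equation oracle
($\lambda_1 \approx 0.906$ per time unit).

## Power spectra

`burgFit()` implements Burg's maximum-entropy AR estimation (reflection
coefficients minimising summed forward/backward prediction-error energy
under the Levinson recursion; $|\kappa_k| < 1$ guarantees stability), with
the coefficient convention $x_n = \sum_k a_k x_{n-k} + w_n$. `aicOrder()`
selects $\arg\min_p N \ln \hat\sigma^2(p) + 2p$ from a single recursion to
`pMax`; ties go to the smaller order. Plain AIC is not a consistent order
selector — each spurious extra order is preferred with probability
$P(\chi^2_1 > 2) \approx 0.16$, so over a 0..10 search the true AR(2) order
is selected in only about 72% of realisations even at $N = 4000$; the
package reports what AIC yields rather than papering over this. The
default search bound is $\min(N/4, 64)$; an order-320 preset mirrors usage
on 6000-sample clinical segments but is over-parameterised at desk scale.

`arPSD()` evaluates $P(f) = \sigma^2 \Delta t / |1 - \sum_k a_k
e^{-i 2\pi f k \Delta t}|^2$ on the uniform grid $k \cdot f_s /
n_\mathrm{fft}$ (default 1024). This is the two-sided density evaluated on
non-negative frequencies — unit-variance white noise gives the constant
$1/f_s$, and variance is recovered by integrating over the full band
$[-f_s/2, f_s/2]$ (checked in the tests as twice the one-sided integral).
`bandEnergy()` integrates the PSD by the trapezoid rule with interpolated
band edges, so disjoint bands tile exactly; the pipeline uses the alpha
(8–13 Hz) and beta (14–30 Hz) bands.

## Self-organizing map

`trainSOM()` is a from-scratch classical Kohonen map: seeded uniform
initialisation within per-dimension data ranges; best-matching unit by
Euclidean distance (ties to the smallest row-major index); Gaussian
neighbourhood on grid coordinates; learning rate decaying exponentially
0.5 → 0.01 and radius $\max(\text{rows},\text{cols})/2 \to 0.5$ over the
epochs; per-epoch seeded reshuffling. No canonical schedule exists for the
classical SOM, so the schedule is fully exposed; 500 epochs is the default.
Training is bit-deterministic given (data, seed, hyperparameters), weights
remain in the convex hull of the data ranges, and features are z-scored
with training-set statistics stored in the model — without this the
Euclidean metric is dominated by the band-energy scales and accuracy
collapses (a guard test demonstrates the degradation). Node labelling is
majority vote with nearest-node inheritance for empty nodes; the default
8 × 6 competitive layer is the shape this pipeline was designed around. Prediction is the BMU's
label; `resolutionReport()` returns per-class and overall correct
resolution plus the confusion matrix.

## The synthetic generator

`syntheticRecording()` composes each EEG lead as
\[
a \left[ (1 - c)\,\text{shaped noise} + c\,\text{Lorenz}_x \right]
+ \text{EOG leakage},
\]
where the shaped noise has class-specific relative weights on the alpha and
beta bands, a $1/f$ power baseline elsewhere, and a 4th-order low-pass
rolloff at the class smoothness cutoff; the chaotic ingredient is the
z-scored $x$-trace of a Lorenz flow sampled at $1/f_s$ (a flow sampled at
250 Hz is a closer EEG analogue than a map), phase-offset per lead. The
EOG lead is sub-4 Hz noise leaking into the EEG leads with a coefficient
decreasing toward the occipital leads, giving the EOG-correlation ranking
real structure. All streams are seeded per lead: generators are pure
functions of their arguments.

The five default classes encode the intended task phenomenology through
exactly the features the pipeline measures: `relax` is alpha-dominant;
`math` and `count` are low-complexity and high-amplitude (strong
narrowband weights, low smoothness cutoffs of 20–25 Hz, small chaotic
weight, amplitude scales 1.8–2.0); `rotate` is the highest-complexity class
(broadest bandwidth, 80 Hz cutoff, largest chaotic weight); `letter` sits
between. One composition subtlety fixed at design time: because the
sampled Lorenz flow is *smooth*, pattern novelty (ApEn) is governed chiefly
by noise bandwidth, not by the chaotic weight — a near-pure chaotic lead
would be the *least* complex by ApEn. The chaotic weight for `rotate` is
therefore moderate (0.5) while its bandwidth is the widest, which realises
the intended complexity ordering (ApEn: rotate highest, math/count
lowest).

What passing tests on these data do and do not show: the generator
reproduces the *format* and the *feature-level contrasts* of mental-task
EEG, so end-to-end results demonstrate that the implemented statistics
carry class information through the SOM correctly. They do not demonstrate
classification of real EEG: real recordings add non-stationarity, eye-blink
transients, inter-subject variability and volume-conduction correlations
that the generator deliberately omits.

## The pipeline

`extractFeatures()` ranks leads by absolute Pearson correlation with the
EOG channel (the aggregation the literature leaves open) and averages
per-lead features over the 3 least-contaminated leads: alpha/beta band
energies from the AIC-order Burg PSD, CTM and $S$, ApEn
($m = 2, r = 0.2\,\mathrm{SD}$), $D_2$ (single-lead delay embedding;
series truncated to 2000 samples for pair counting), and $\lambda_1$ from
the spliced leads. Individual feature failures (no scaling region, no
stable divergence window) become `NA` plus a flag, never a fatal error;
`runExperiment()` imputes them with training-split means. The experiment
makes a seeded stratified 70/30 split, trains and labels the SOM on the
training split, reports per-class resolution, overall accuracy and the
confusion matrix, and computes the mixed-task curve by re-splitting and
re-training on the first $k$ classes (canonical order) for $k = 1..K$.
Because a single-lead D2 at $m = 16$ on noise-dominated recordings often
has no admissible scaling region, the `d2` column is flagged/imputed for a
fraction of recordings; classification rests on the remaining features for
those rows.

Problem sizes used by the tests and the acceptance script — 5000/10000
points for the map exponents, 2000 for analytic dimensions, 100-seed
ensembles for ordering statements, 20 recordings per class end to end —
were chosen as the smallest sizes at which each statistic is in its
asymptotic regime on the canonical fixtures.

## Known limitations

* The determinism ratio discriminates by ordering, not by wide margins;
  with 19 surrogates the resolution of $S$ is limited and single-recording
  classifications near the 0.3/0.7 thresholds should not be over-read.
* Plain AIC overfits the AR order in roughly a quarter of realisations by
  construction; downstream band energies are robust to this (extra orders
  refine, not distort, the spectral shape).
* The 1% scale-free-region rule is honoured as a preset but is unusable at
  desk-scale $N$; dimension estimates carry the 5% tolerance.
* Splice masking removes spurious *embedding windows*, but splicing still
  concatenates dynamically unrelated segments; $\lambda_1$ from spliced
  noise-like leads is a feature, not a certified exponent (the auto-window
  rule refuses genuinely saturating curves).
* The SOM is the classical algorithm: no growing/hierarchical variants, no
  supervised refinement.
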