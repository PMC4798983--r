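---
title: "The stochastic switch model of C. elegans random search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic switch model of C. elegans random search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochswitch)
```

## The model

*C. elegans* random search alternates forward runs, briefer reverse runs
and sub-second pauses. The package models the locomotory state as a
four-state continuous-time Markov chain driven by two binary,
stochastically switching units representing the forward (F) and reverse
(R) command-neuron pools: state F (forward unit on), state R (reverse
unit on), pause state X (both off) and pause state Y (both on). Because
the units flip independently, direct F&harr;R and X&harr;Y transitions
have probability zero, leaving eight rate constants `a_ij`.

Each unit flips like a thermally activated bistable element: with summed
synaptic input $S$, it switches on at rate $A e^{S}$ and off at rate
$A e^{-S}$, where $A$ (Hz) is the fundamental switching rate at zero
input. Writing the inputs in terms of six weights — external drives
$h_F, h_R$, self-connections $w_{FF}, w_{RR}$ and cross-connections
$w_{FR}, w_{RF}$ — expresses all eight rates through six parameters
(`rates_from_weights()`), which imposes two exact product constraints on
the rates: $a_{FX}a_{XF} = a_{RY}a_{YR}$ and
$a_{FY}a_{YF} = a_{RX}a_{XR}$. The inverse map
(`weights_from_rates()`) requires a value of $A$; the cross-connection
weights are the only ones independent of it.

The chain is hidden: the observable is the signed tangential velocity
$v(t)$ of a tracked body point, sampled at the video frame rate
(~30 Hz). Each state emits $v$ from a state-specific density: both pause
states share a central Cauchy with half-width $b$ (default 18 µm/s;
heavy tails because the worm decelerates smoothly into a pause), the
forward state emits on $v > 0$ and the reverse state on $v < 0$.

## Fitting procedure

`fit_rates()` maximizes the filtered likelihood
$\ln L = \sum_{t,w} \ln(P_w(t) \cdot G(v_w(t)))$, where each worm's state
probability vector starts at the steady state $P_\infty$ and is updated
each frame by the per-frame transition matrix and Bayes' rule with
normalization (so 18,000-frame traces cannot underflow). The per-frame
matrix is $M = (\varepsilon Q + I)^{K}$ with $K = 2^{30}$ and
$\varepsilon = \Delta t/K \approx 31$ ps, evaluated by 30 serial
squarings. Numerically we square the deviation $E = M - I$
($E \leftarrow 2E + E^2$), which preserves the tiny off-diagonal entries
of the early squarings; the result matches a scaled Taylor-series matrix
exponential to better than $10^{-9}$ element-wise and rows sum to one to
machine precision.

The optimizer is the stated random search: six free rates (the two
Y-exit rates are recomputed from the constraints at every step, chosen
as the dependent pair so the six free rates stay strictly positive),
log-uniform initial guesses in [0.01, 10] Hz, Cauchy proposal steps of
width `b_random` (initially 0.01 Hz; any proposal with a rate below
0.01 Hz is redrawn), growth by 3% on improvement and shrinkage by 0.5%
otherwise, stopping below 0.001 Hz; ten replicate starts, then a
refinement pass of the best replicate with stop threshold $10^{-5}$ Hz
and a hard rate floor of $10^{-4}$ Hz. All randomness flows from
`run_config()$rng_seed`, so fits are bit-reproducible. Because the two
pause states share an emission density the likelihood is invariant under
exchanging their labels (the exchange also swaps the two constraints);
after fitting, X is defined as the pause state with the higher
steady-state probability.

`viterbi()` and `forward_backward()` decode hard paths and smoothed
posteriors; Viterbi ties break toward the earlier state in the fixed
(F, R, X, Y) order. Model variants for comparison: B pins the two rates
into Y at $10^{-10}$ s⁻¹ (one effective pause state, 4 free
parameters); C is the general three-state forward/reverse/pause chain
with six unconstrained rates. `likelihood_ratio_test()` refers
$D = 2\,\Delta\ln L$ to a chi-squared distribution.

## Emission estimation

`fit_emissions()` pools all of a cohort's velocities. The Cauchy peak is
fit on the histogram bins within ±50 µm/s by weighted least squares of
$c\,\mathrm{Cauchy}(0,b)$ plus a non-negative background linear in
$|v|$ — the background absorbs the movement-density tails that reach
into the window. We chose this over a plain maximum-likelihood fit of a
Cauchy to the windowed samples because the latter is biased by both
truncation and contamination (about −20% in our recovery experiments),
and the bias propagates into the fitted rates. The scaled Cauchy is then
subtracted from the full histogram and the residual splits at $v = 0$
into the forward and reverse densities, renormalized to unit area. Two
guards matter in practice. First, a significance check on the locally
smoothed residual (two Poisson standard errors) makes a pure-pause
sample fail loudly with "no movement state present" rather than yield a
noise-built movement density. Second, each movement density is floored
at 2% of the observed pooled density on its side: the state densities
genuinely overlap, so assigning a movement state a hard zero at a
velocity the cohort actually visited is overconfident — and, we found,
fragments decoded reverse runs and badly biases the fitted exit rates
whenever subtraction noise or a slightly overestimated half-width zeroes
the slow-velocity bins. Densities are
carried on a 2 µm/s grid over ±600 µm/s with linear interpolation,
exponential tail extensions fitted to the outermost occupied bins, and a
$10^{-12}$ floor so that no finite velocity yields $-\infty$
log-likelihood.

## Synthetic data: the stated world

`simulate_cohort()` draws state sequences from the chain (initial state
from $P_\infty$, then the rows of $M$) and velocities independently per
frame from the state's density. The generating defaults mirror the
reference recordings: 10-minute traces at ~30 Hz (~18,000 frames),
cohorts of a few to a few tens of worms, reference wild-type rates
(`ss_reference_rates()`), Cauchy pauses with $b = 18$ µm/s, and
movement densities peaking near +200 and −300 µm/s (truncated normals
with widths 80 and 100 µm/s — chosen once as realistic for the broad
single-mode velocity distributions of crawling worms and not revisited).

`simulate_track()` is the point-worm: constant speeds of 200 µm/s
forward and 300 µm/s backward, stationary pauses, a uniformly random new
heading at every reverse→pause→forward transition (the random
reorientation that ends a pirouette), and per-frame Gaussian heading
jitter with standard deviation 0.001°. That printed jitter value is
retained verbatim although it produces negligibly curved runs; it is
configurable, and tests of heading statistics rely on the reorientation
events, not the jitter. `simulate_chemotaxis()` couples the input
weights to the concentration change along the track
($h_F \mathrel{+}= \kappa\, dC/dt$, $h_R \mathrel{-}= \kappa\, dC/dt$),
rebuilding the transition matrix every frame; the coupling strength
$\kappa$ has no reference value and is a free argument.

What a green simulation test does establish: the generator and the
closed forms agree (occupancies vs $P_\infty$, dwell means vs
$1/\!\sum a_{i\cdot}$, run lengths vs the run-length formulas), and the
fitting machinery recovers generating rates at the stated data sizes.
What it does not establish: fidelity to real worm tracks — the
generator has no posture, no tracking noise, no velocity
autocorrelation within states, and per-frame-independent emissions.

## Descriptive statistics and posture

`kinematics_summary()` implements the lag statistics (mean heading
change, speed autocovariance, velocity and heading autocorrelation, mean
squared displacement) with sums over frames $k = 1..N-j-1$ and per-worm
averaging; zero-speed frames carry the last defined heading and are
flagged. `undulation_frequency()` is half the reciprocal of the lag of
the first local minimum of the heading autocorrelation, `NA` when the
curve is monotone. Curvature analysis resamples the track to uniform
10 µm arclength steps and differentiates the unwrapped tangent angle (no
reference discretization exists; 10 µm resolves worm-scale bends while
averaging tracker noise). The phase of a pause entry is
$2\pi z_1/(z_2 - z_1)$ from the two preceding downward zero crossings of
curvature; ventral/dorsal mirroring is a per-worm flag supplied by the
caller. The Rayleigh test uses the standard finite-$n$ corrected
exponential approximation.

## Run-length analytics and search modes

`run_lengths()` evaluates the reversal frequency from the steady state
and exit fates, and the mean forward run length both exactly and in the
approximation that ignores the rare direct F→Y transitions (the two
coincide exactly when $a_{FY} = 0$). The mean reverse run length uses
the mirror-image expression $\bar v_R\, p_R / f_{FPR}$, which the
reference analysis uses implicitly but never prints. Search modes follow
the stated cutoff boxes on (mF, fFPR, mR); "cropping" and "dwelling"
are treated as synonyms of the smallest-scale mode. `scan_subspace()`
scans up to three weights over [−6, 6] in steps of 0.4 with the others
held at the wild-type operating point; coverage is the occupancy of a
30×30 binning of the $(\log_{10} m_F, f_{FPR})$ plane over
$[-1.5, 1.5] \times [0, 12\,\mathrm{min^{-1}}]$ (the reference figures
show but never quantify coverage). Escape motifs: exciting the reverse
unit (Push) leaves $p_R = a_{YR}/(a_{YR}+a_{RY})$, inhibiting the
forward unit (Pull) leaves $p_R = a_{XR}/(a_{XR}+a_{RX})$, and both
together make R absorbing. Expected escape latency is computed by
first-passage algebra on the stimulated chain at a finite stimulus
strength (exponentials saturate at $e^{\pm 700}$); the latency ratio
between motifs depends on how the two limits are coupled, so no single
reference ratio is asserted.

## Numerical choices and degenerate inputs

* Rates are validated non-negative; user-supplied rate sets must satisfy
  the synaptic constraints to a relative $10^{-6}$ before weight
  inversion (the bundled cohort-mean reference rates satisfy them only
  to ~1–6%, so reference-table code passes an explicit wider tolerance).
* Steady states solve the normal-equations form with the generator
  rescaled by its largest entry; an SVD null-space solve is the fallback,
  and reducible chains return the absorbing-state distribution with a
  warning.
* Summed synaptic inputs are capped at ±700 before exponentiation;
  saturated scan points classify as indeterminate when their statistics
  are not finite.
* Tracks must have strictly increasing, uniform frame times (tolerance
  1 µs); unknown direction signs (0) are legal on input but refused by
  `tangential_velocity()`, since the likelihood needs resolved signs.
* A constrained cohort comparison (`cohort_compare()`) shares one
  derived quantity across two cohorts (11 vs 12 free parameters): the
  shared value is a free parameter and one designated rate per cohort is
  solved to reproduce it (closed form for dwell times, a root solve for
  the mean pause dwell). How the reference analysis parameterized this
  equality is not documented; this is one consistent reading.

## Interface notes

The package is function-first: tibbles in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for result types. No shell
entry point is shipped — `scripts/acceptance.R` and small user scripts
compose the exported functions directly, which replaces a CLI for an
analysis package of this kind.

## Known limitations

* Emissions are conditionally independent across frames given states;
  real velocity has within-state autocorrelation (worms decelerate into
  pauses), which the reference analysis also ignores.
* Viterbi-decoded dwell histograms are only approximately exponential:
  decoding smooths over the briefest visits, biasing short-dwell states
  long. Tests compare decoded dwell means at loose (20%) tolerance for
  this reason.
* Fitted rates inherit error from the estimated emission densities; at
  the reference data size (5 worms × 18,000 frames) the well-identified
  rates recover to within ~10–15% per experiment and a few percent in
  the median over experiments, but weakly identified small rates
  ($a_{RX}$, $a_{FY}$, of order 0.01–0.03 s⁻¹) can be off severalfold
  in a single cohort.
* The point-worm has no body; posture analyses only apply to real or
  synthetically drawn sinuous tracks.
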