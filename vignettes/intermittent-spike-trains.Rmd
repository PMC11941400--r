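---
title: "Spike trains from coupled intermittent maps: model, estimation, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike trains from coupled intermittent maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spikemap` produces spike trains by alternating two one-dimensional
intermittent maps through threshold switching.

The *critical (type-I) intermittency map*

$$\phi_{n+1} = \phi_n + u_1\,\phi_n^{z_1} + \epsilon_n,
\qquad \epsilon_n \sim U(-\epsilon_1, +\epsilon_1),$$

has a marginally unstable fixed point at $\phi = 0$: the derivative of the
noise-free map at the origin is exactly 1, so a trajectory near zero
performs a noise-dominated random walk with a weak upward nonlinear drift.
It models the fluctuations of an order parameter at a second-order
critical point; its exponent is tied to the isothermal critical exponent
$\delta$ by $z_1 = \delta + 1$. The *tricritical intermittency map*

$$\phi_{n+1} = \phi_n - u_2\,\phi_n^{-z_2} + \epsilon_n$$

is marginally unstable at (theoretically) infinite $\phi$ and drives
trajectories downward; it models order-parameter fluctuations near a
Griffiths tricritical point and is defined only for $\phi > 0$. The two
maps are *complementary repellors*: each one's burst points into the
other's laminar region.

The coupling (`generate_spike_train()`): the system starts in the critical
map at $\phi_{init}$. When a computed critical-map value exceeds the
firing threshold $\phi_{Th1}$, that value is suppressed — it never reaches
the output — and the state jumps to the tricritical entry value $\phi_k$,
which is emitted and is the visible spike peak. The tricritical map then
falls; when a computed value drops below $\phi_{Th2}$ it is suppressed in
turn and the critical map resumes at $\phi_m$. For biological-neuron-type
trains $\phi_{Th1}$ is the end of the critical laminar region and
$\phi_{Th2}$ its fixed point, so after each spike the trajectory re-enters
below the firing threshold (hyperpolarization). There is deliberately no
external-field term anywhere: imposing a stimulus would destroy the
internal self-organization that produces the statistics below.

At criticality the laminar lengths $L$ (maximal runs inside a value band)
obey $P(L) \sim L^{-p}$ with

$$p = \frac{z_1}{z_1 - 1} = 1 + \frac{1}{\delta} \in [1, 2)
\quad\text{(critical)},\qquad
p = \frac{z_2}{z_2 + 1} \in [2/3, 1) \quad\text{(tricritical)} .$$

These relations are exposed as `p_from_z1()`, `p_from_delta()`,
`p_from_z2()`, `z1_from_delta()`.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `u1`, `z1` | critical-map drift coefficient and exponent | 0.011, 4 | $z_1 = 4 \Leftrightarrow \delta = 3$, the mean-field universality class; $u_1$ small so the laminar walk is noise-dominated |
| `eps1` | critical-map noise half-width | 0.0175 | reference experiment |
| `u2`, `z2` | tricritical drift and exponent | 17, 5 | gives a spike fall of ~9 samples from the peak |
| `eps2` | tricritical noise half-width | 0.07 | reference experiment |
| `th1`, `th2` | switching thresholds | 0.31, 0 | end of the critical laminar region, and its fixed point |
| `phi_k`, `phi_m` | entry values after each switch | 3, 0 | spike peak; re-entry at the fixed point |
| `n_samples` | series length | 3e6 | enough laminar episodes (~17,000 in the reference band) for tight exponent confidence intervals |
| `p3_tol` | MCF qualification tolerance on \|p3\| | 0.001 | "p3 ≈ 0" made operational; applied two-sidedly since the estimate can be a small negative number |

All quantities are dimensionless; time is the map iteration index $n$.

## Estimation: the method of critical fluctuations

`mcf_scan()` treats the upper band edge $\phi_{blue}$ as a free parameter:
candidates on progressively denser equally spaced grids (20, 50, 100, 200,
500 interior points) over $(\phi_{red}, \phi_{Th1})$ are each fitted with
the truncated power law

$$g(L) = A\,L^{-p_2}\,e^{-p_3 L},$$

and a candidate qualifies when $|p_3| \le 0.001$ while $p_2 \in [1, 2)$.
The scan stops at the first density with a qualifier and picks the
qualifier with maximal $R^2$, breaking ties by smaller $|p_3|$, then
smaller $\phi_{blue}$ — a deterministic rule, so a given series always
yields the same band. Different simulation seeds may select different
$\phi_{blue}$; the fitted $p_2$ is what is stable.

Two $\phi_{red}$ conventions are used. For a spike train the default is
the series minimum: the laminar band must reach below the
hyperpolarization excursions, and the minimum is the natural data-driven
lower edge. For a *bare* intermittent map run
(`run_uncoupled_intermittent()`) the laminar region is known by
construction and $\phi_{red}$ is best set to the map's own laminar start
(0 for the critical map): with the series minimum instead, the scan can
select a band lying entirely below zero, where the dynamics are pure
noise.

### Why the fit is in linear space

The fit (`fit_truncated_power_law()`) is nonlinear least squares
(Levenberg–Marquardt, via `minpack.lm::nlsLM`) of $g(L)$ against the raw
unit-bin relative frequencies. A log-space variant
(`fit_space = "log"`) is provided, fitting
$\log_{10} P = \log_{10} A - p_2 \log_{10} L - p_3 L/\ln 10$.
Linear space is the default for an empirical reason: the unit-binned
distribution of a finite sample has a long tail of lengths observed once,
all at frequency $1/n$. In log space those singleton cells form a flat
cloud that dominates the residual sum and drags $p_2$ toward zero (on the
reference run: $p_2 \approx 0.99$, $R^2 \approx 0.81$). In linear space
the fit is weighted toward the well-populated head cells, recovers
synthetic exponents to well under 1%, and on the reference run gives
$p_2 \approx 1.37$–$1.38$ with $R^2 > 0.999$ — the regime the analysis is
designed for. $R^2$ always refers to the fit space used, recorded in the
result.

Numerical details: the amplitude start is taken from the first cell of
the distribution with $p_2 = 1.3$, $p_3 = 0.01$; box constraints
$p_2 \in [0, 5]$, $p_3 \in [-1, 1]$; 95% confidence intervals use the
Jacobian covariance with a Student-t quantile at (points − 3) degrees of
freedom. Fits are refused (a classed error) below 10 distinct lengths or
100 events — below that the three-parameter model is not identifiable in
any meaningful way. A scan that finds no qualifying band signals a
classed error carrying the full candidate ledger.

## Semantics pinned down

Several micro-decisions in the coupling are easy to get wrong and are
fixed as follows:

* **Suppression**: the threshold-crossing computed value is discarded,
  never emitted. This also keeps the tricritical overshoot (which can be
  hundreds of units negative, e.g. $0.5 - 17\cdot 0.5^{-5} = -543.5$) out
  of the series.
* **Entry samples consume one time step** and are emitted (`ENTRY2` = the
  spike peak, `ENTRY1` = the re-entry), so the output has exactly
  `n_samples` values and labels.
* **Strict inequalities** for crossings (`> th1`, `< th2`); equality does
  not switch — a measure-zero event under continuous noise.
* **Non-integer exponents** use $|\phi|^z$ as the nonlinear-term base, the
  only reading that keeps the term real for $\phi < 0$; integer exponents
  use the plain power.
* **Noise**: both maps draw from R's RNG (Mersenne–Twister by default) in
  emission order, so one seed fixes the entire experiment bit-for-bit.
  Entry values are fixed by default; a uniform-random entry mode exists
  (drawing on the laminar regions) and does not change the laminar
  statistics.

## What the generator does and does not emulate

The simulator *is* the data generator: it reproduces the morphology of
biological spikes (sharp thresholded peak, fast fall, hyperpolarization)
and the critical statistics of the relaxation fluctuations. It does not
model membrane biophysics (no conductances, no refractory period beyond
the fall itself, no stimulus), uses dimensionless algorithmic time, and
draws noise i.i.d. — real recordings have colored noise, drift and
measurement artifacts. Tests passing on this generator therefore validate
the mechanism and the estimators, not the claim that any particular
biological recording is critical.

## Known limitations

* **MCF bias at finite noise.** On an uncoupled critical-map run with
  $z_1 = 4$ (500,000 samples), the scan-selected fit gives
  $p_2 \approx 1.34$ with a CI of half-width ~0.008 sitting just above
  the asymptotic $4/3$; the coupled reference run gives
  $p_2 \approx 1.37$. The excess over $1 + 1/\delta$ is a finite-noise,
  finite-band correction, and the Jacobian CI — which measures fit
  uncertainty only — does not cover it. Comparisons with the theoretical
  exponent should allow a few percent of bias.
* **The inter-spike-interval distribution is not a clean power law under
  fixed re-entry.** With re-entry pinned at the fixed point, ISIs are
  first-passage times of a noise-driven escape from a marginal fixed
  point: the reference run produces only ~830 spikes in $3\times 10^6$
  samples, with no intervals shorter than ~100 steps, and the unit-binned
  ISI distribution is almost entirely singleton cells. The truncated
  power-law fit on such data returns an exponent near zero rather than
  the laminar exponent; `fit_isi_distribution()` is reliable when
  intervals are dense near their minimum (as in the sampled-power-law
  test at 50,000 events), not at a few hundred events spread over three
  decades. The laminar (MCF) exponent is the robust route to $p$ for this
  mechanism.
* The scan's grid schedule and tie-break rule are implementation choices;
  any deterministic refinement with the same qualification rule should
  select statistically equivalent bands.

## Problem sizes used by the test suite

The shipped tests run the reference analysis at the full
$3\times 10^6$ samples (the simulation core is compiled, so this takes
seconds), property checks on runs of $10^5$–$5\times 10^5$ samples, and
oracle comparisons on thousands of short random series.
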