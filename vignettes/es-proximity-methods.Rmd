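---
title: "Estimating proximity to explosive synchronization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating proximity to explosive synchronization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Coupled-oscillator networks cross from incoherence to synchrony either
gradually (a second-order transition) or abruptly, with hysteresis (a
first-order, "explosive" transition, ES). Where a network sits on that
spectrum — its *ES proximity* — shapes how it responds to a crisis: networks
close to the explosive limit lose their critical operating point quickly
under perturbation and, because the synchronized state is self-reinforcing,
recover slowly once the perturbation ends. `esprox` provides (i) a
mechanistic oscillator-network model in which ES proximity is a single
dial, (ii) a signal-level statistic that estimates ES proximity from time
series alone, and (iii) pipelines applying that statistic to multichannel
band-limited recordings (EEG-like) and to daily stock-index panels.

## The model

Each node is a Stuart–Landau oscillator (the normal form of a Hopf
bifurcation) carrying amplitude and phase, $z_j = r_j e^{i\theta_j}$:

$$\dot z_j = (\lambda_j + i\omega_j - |z_j|^2)\,z_j
  + S\,G(t)^{Z} \sum_k A_{jk}\, z_k(t-\tau_{jk})
  + \beta\,\xi_j(t) + u(t),$$

with structural connectivity $A_{jk}$, global coupling $S$, link delays
$\tau_{jk}$, complex white noise $\xi_j$, and a global square pulse $u(t)$.
The adaptive feedback gain $G(t)^Z$ multiplies the coupling by a power of
the instantaneous Kuramoto order parameter $R(t)$: while the network is
incoherent the effective coupling $k_j S R^Z$ is suppressed, and once
synchrony builds it is reinforced. $Z = 0$ is a conventionally coupled
network; raising $Z$ makes the transition steeper and hysteretic — the ES
dial.

Design choices that required a decision, and why:

- **Coupling form.** The package couples through the delayed neighbour
  states ("direct" mode) rather than the diffusive difference
  $z_k(t-\tau)-z_j(t)$. With mean degree 8, $\lambda = 1$, $\tau = 10$ ms
  and alpha-band frequencies, strong diffusive coupling adds a damping
  $-S G^Z k_j z_j$ that quenches the oscillations entirely (amplitude
  death: mean $|z|$ falls below $0.05$ for $S \gtrsim 1$) before any
  synchronized branch forms; direct coupling supports the full
  incoherent-to-synchronized transition. Both modes are available
  (`coupling_mode`).
- **Feedback gain.** $G = R(t)$, the global order parameter computed from
  the current phases and shared by all nodes. The per-node alternative
  $G_j = |z_j|$ is implemented (`feedback_mode = "amplitude"`) but is
  structurally divergent for $Z \ge 2$ under direct coupling (the drive
  grows as $|z|^{Z+1}$, outrunning the cubic damping), so it is reserved
  for small-$Z$ exploration.
- **A finite-N consequence.** With $G = R$, the incoherent state has
  $R \approx N^{-1/2}$, so the fluctuation-driven jump to synchrony moves
  to larger $S$ roughly geometrically in $Z$ (at $N = 100$: $S^* \approx
  1, 2.5, 10, 30$ for $Z = 0, 1, 2, 3$). Coupling grids must therefore be
  geometric in the coarse stage; `locate_critical_coupling()` automates
  the bracket-then-refine search.
- **Noise.** "$\beta = 0.05$" is implemented as a variance rate: each of
  the real and imaginary parts receives independent Gaussian increments of
  variance $\beta\,dt$ per step. At this noise level the finite-size
  critical flickering that the ES-proximity statistic feeds on is well
  resolved.
- **Frequencies, decay, delays.** $\omega_j \sim \mathcal N(2\pi\cdot 10,
  (2\pi)^2)$ rad/s — an alpha-band-like population, so simulated node
  signals can stand in for EEG channels; $\lambda_j = 1$ (self-oscillatory,
  unit limit cycle); homogeneous $\tau = 10$ ms. All configurable per node
  or link.
- **Integrator.** Euler–Maruyama at $dt = 1$ ms with a ring-buffer delay
  history (initial history = initial state), with one refinement: the
  per-node rotation $e^{i\omega_j dt}$ is applied exactly by operator
  splitting. A naive Euler rotation at $\omega dt \approx 0.06$ inflates
  the limit-cycle amplitude by $\approx \omega^2 dt/2$ (about +70% at
  10 Hz), which would distort every amplitude-dependent quantity; with
  splitting, an uncoupled noiseless node settles at $\sqrt\lambda$ to
  machine-level accuracy. A guard aborts if any $|z_j| > 10^3$.

## Critical points and the ES-proximity statistic

The instantaneous order parameter $r(t) = |N^{-1}\sum_j e^{i\theta_j(t)}|$
summarizes the network state. Two statistics sit on top of it:

- **PCF** (pair correlation function): $N\,\mathrm{Var}_t\,r(t)$, the
  N-scaled variance of synchronization fluctuations. It peaks at the
  critical coupling; `find_critical_point()` takes the argmax over a sweep
  (ties toward smaller $S$, endpoint peaks flagged as "sweep too narrow",
  optional 3-point smoothing off by default).
- **Windowed-ACF kurtosis.** Within 10-s windows advanced by 5 s, the
  lagged autocorrelation of $r(t)$ is computed (biased divide-by-$n$
  estimator, so every value lies in $[-1, 1]$; zero-variance windows are
  recorded missing and excluded). The default lag is
  `round(sampling_rate/10)` samples — one cycle of a 10 Hz rhythm at any
  rate (50 samples at 500 Hz, 100 at the solver's 1 kHz). Near the
  critical point of a high-$Z$ network, $r(t)$ flickers between coherent
  and incoherent episodes, producing occasional extreme window-ACFs; the
  Pearson kurtosis $m_4/m_2^2$ of the across-window distribution is
  therefore the ES-proximity estimate: $\approx 3$ far from ES, $> 3$
  close to it. The Pearson (non-excess) convention is used precisely so
  that the Gaussian reference value is 3; no small-sample bias correction.
  Reports with fewer than 30 windows carry a low-confidence flag.

Comparators: `hurst_dfa()` (DFA-1, boxes log-spaced from 10 to $n/4$
samples) and `rank_correlation()` (Spearman via `stats::cor.test`) support
the negative-control analyses — long-range correlation indexes distance
from criticality but not transition type.

## Perturbation protocol

`run_es_experiment()` reproduces the loss/recovery protocol: at each $Z$'s
own critical coupling, simulate a 120-s baseline, apply a global pulse
($u = 10$ for 5 s by default), and follow the windowed ACF through a
post-offset horizon (default 300 s; the desk-scale runs in the packaged
tests use 80–120 s and state so). The baseline zone is the
baseline ACF mean $\pm$ 3 SD; *loss time* is the first post-onset window
centre outside the zone, referenced to onset; *recovery time* is the first
post-offset window starting `dwell = 3` consecutive in-zone windows,
referenced to offset (dwell 1 reproduces the literal crossing rule; 3
suppresses single-window false recoveries). A run that never leaves the
zone has censored loss and, by convention, recovery time 0.

The 120-s default baseline gives 23 windows, enough for stable zone and
kurtosis estimates per realization; baseline kurtosis is computed
per-realization (each realization draws a fresh frequency configuration,
so it is a genuine per-network estimate). In the summary correlations,
censored times are scored at the horizon by default
(`censored = "horizon"`): they are rank-preserving right-censored
observations, and the slowest responses are exactly the informative ones —
dropping them would discard the resilient tail. `censored = "exclude"` is
available.

## Signal and market pipelines

`es_proximity()` chains band-pass (4th-order Butterworth applied forward
and backward, so zero phase in the pass band; edges of two low-cutoff
cycles per side are trimmed), Hilbert instantaneous phases (analytic
signal via the one-sided FFT spectrum, implemented in-package), the
across-channel order parameter (channels as nodes), the windowed ACF, and
its kurtosis. Defaults mirror the EEG recipe: 8–13 Hz, lag 50 at 500 Hz,
10-s windows, 5-s step, 3-minute minimum duration (shorter input is
flagged, not refused). Artifact handling is reduced to nonfinite-channel
rejection and per-channel demeaning; full EEG artifact pipelines are out
of scope.

`market_timing()` implements the collapse/recovery rates over an
$\alpha$-trading-day span (row counts, so closures are skipped):
$R_1 = \frac{P(t_1)-P(t_1+\alpha)}{P(t_1)-P(t_2)}$,
$R_2 = \frac{P(t_2+\alpha)-P(t_2)}{P(t_1)-P(t_2)}$, response/recovery
times $\ln(1/R_1)$, $\ln(1/R_2)$; $t_1, t_2$ are the in-recession argmax /
argmin (ties earliest; recession windows are user input). Non-positive
rates keep their value but leave the time missing rather than clamped.
`market_es_proximity()` estimates baseline ES proximity either from
constituent stocks (per-day cross-sectional sign coherence of log-returns
as an order-parameter proxy — preferred) or from the index alone (windowed
ACF of log-returns), at lag 2 trading days, 60-day windows, 5-day step.
Both constructions are labelled in the output because the choice between
them is a genuine open question for index-only data.

## Synthetic data: what it emulates and what it does not

`make_surrogate_recording()` reuses the mechanistic simulator (nodes →
channels, solver output decimated to 500 Hz, white sensor noise at a
chosen SNR), so estimator validation is a round trip through the model
itself. It does *not* emulate volume conduction, electrode geometry,
non-stationary artifacts, or 1/f background — passing round-trip tests
shows the estimator recovers the model's ES proximity, not that real EEG
is this clean. `make_market_panel()` produces geometric random walks with
a rising baseline, a crash of controlled speed, a trough plateau, and a
rebound of controlled speed, plus constituent stocks whose cross-sectional
coherence switches between regimes via a two-state Markov chain (mean
dwell 20 days); the regime separation scales with the ground-truth
bistability parameter. It does not emulate heavy-tailed return
distributions, volatility clustering, or cross-market contagion.

## Numerical choices and degenerate inputs

Ties in the PCF argmax break toward smaller $S$; endpoint peaks are
flagged. Zero-variance ACF windows are missing values, excluded listwise
from kurtosis with a reported count, and declared degenerate only below a
$10^{-20}$ variance floor so that roundoff on an exactly-coherent channel
set does not masquerade as signal. Kurtosis requires $\ge 4$ finite values
and positive spread; `baseline_zone()` requires $\ge 10$ windows and
nonzero SD. Delays must be integer multiples of $dt$. Blow-ups abort with
a diagnostic rather than returning garbage. All stochastic entry points
take a seed and are bit-reproducible given it (the solver's noise stream
is drawn from a xoshiro256++ generator seeded from R's RNG, so
`set.seed()` controls everything).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the qualitative claims are stable: networks of
$N = 100$ (mean degree 8), 15–30 realizations per condition, 120-s
baselines, 120–150-s horizons, and coupling sweeps of 13 fine grid points
with 2–3 realizations each. The same code scales to $N = 1000$ and 100
realizations via function arguments.

## Known limitations

- The fluctuation-driven critical coupling of high-$Z$ networks depends on
  $N$ through $R_{\rm inc} \sim N^{-1/2}$; critical couplings found at one
  size do not transfer to another.
- The perturbation is uniform across nodes by construction; targeted or
  patterned perturbations are out of scope.
- Window-centre timing quantizes loss/recovery times to the window step
  (5 s by default).
- The market sign-coherence proxy ignores magnitude information; markets
  with few constituents give a coarse-grained order parameter.
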