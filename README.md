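# esprox

Proximity to explosive synchronization (ES) from mechanistic models and
from time series — and what it predicts about collapse and recovery.

## The problem

Networks of coupled oscillators cross from incoherence to synchrony either
gradually (second-order) or abruptly and hysteretically (first-order,
"explosive"). Where a given network sits between those limits — its **ES
proximity** — turns out to govern how it behaves in a crisis: networks
close to the explosive limit are hypersensitive at their critical point
(fast collapse) and self-trapping once pushed (slow recovery). `esprox` is
for researchers who want to (a) simulate that spectrum mechanistically,
(b) estimate ES proximity from recorded signals alone, and (c) relate the
estimate to response and recovery timing — in neural-style multichannel
recordings and in daily stock-market panels.

## The model and the statistic

The mechanistic core is a feedback-modified Stuart–Landau network,

$$\dot z_j = (\lambda_j + i\omega_j - |z_j|^2) z_j
 + S\,R(t)^{Z}\sum_k A_{jk}\,z_k(t-\tau_{jk}) + \beta\,\xi_j(t) + u(t),$$

where $R(t)$ is the instantaneous Kuramoto order parameter fed back into
the coupling. The exponent $Z \ge 0$ is the ES dial: $Z = 0$ gives a
gradual transition, larger $Z$ an increasingly abrupt, hysteretic one.
Critical points are located at the peak of the **pair correlation
function** $\mathrm{PCF} = N\,\mathrm{Var}_t\,r(t)$.

The signal-level estimate of ES proximity is the **Pearson kurtosis of
moving-window lagged autocorrelations** of the order parameter
($m_4/m_2^2$ over 10-s windows, 5-s step, lag ≈ one oscillation cycle):
≈ 3 far from ES, > 3 (heavy tails, from critical flickering) close to it.

## Worked example

```r
library(esprox)

topo <- generate_topology("random", n_nodes = 100, n_links = 400, seed = 42)
cp <- locate_critical_coupling(topo, feedback_exponent = 2.5, seed = 1)
cp
#> # A tibble: 1 x 4
#>   s_star pcf_peak endpoint flat
#>    <dbl>    <dbl> <lgl>    <lgl>
#> 1   13.5     12.5 FALSE    FALSE

tr <- simulate_network(topo,
  sl_config(coupling = cp$s_star, feedback_exponent = 2.5,
            duration = 300, transient = 10), seed = 3)
glance(windowed_acf(tr))
#> # A tibble: 1 x 7
#>   kurtosis n_windows n_missing   lag window_length  step low_confidence
#>      <dbl>     <int>     <int> <dbl>         <dbl> <dbl> <lgl>
#> 1     9.70        59         0   100            10     5 FALSE
```

The near-explosive network ($Z = 2.5$) at its own critical coupling
($S^* = 13.5$) produces a heavy-tailed window-ACF distribution (kurtosis
9.7 here): its order parameter flickers between coherent and incoherent
episodes. The same protocol on the conventionally coupled network
($Z = 0$, $S^* = 1.1$) gives kurtosis 3.24 — Gaussian-like fluctuations.
Single-realization kurtosis is noisy near criticality; conclusions in the
package's own checks always aggregate 20–30 seeded realizations.

The same statistic runs on recordings — here a surrogate 32-channel
alpha-band recording generated by the model itself:

```r
x <- make_surrogate_recording(n_channels = 32, duration = 180,
                              z_truth = 2.5, noise_snr = 20, seed = 5)
es_proximity(x)
#> <es_proximity_report> kurtosis 2.481 over 34 windows (band 8-13 Hz, lag 50)
```

and on markets, where collapse/recovery rates over an α-trading-day span
turn into response and recovery times:

```r
px <- tibble::tibble(date = as.Date("2008-01-01") + 0:3,
                     price = c(100, 60, 50, 90))
collapse_recovery_rates(px, px$date[1], px$date[3], alpha = 1)
#> # A tibble: 1 x 5
#>      r1    r2 response_time recovery_time alpha
#>   <dbl> <dbl>         <dbl>         <dbl> <dbl>
#> 1   0.8   0.8         0.223         0.223     1
```

`run_es_experiment()` ties it together: at each $Z$'s critical coupling it
applies a global pulse and measures the time to lose and to regain the
baseline ACF zone (mean ± 3 SD); across realizations, baseline kurtosis
correlates negatively with loss time and positively with recovery time —
ES proximity predicts fast collapse and slow recovery.

A command-line wrapper over the same functions is in
`inst/cli/esprox.R` (subcommands `simulate`, `sweep`, `experiment`,
`eeg`, `market`, `synth`).

## Scope notes

Recession windows for market analyses are user input; no data are
downloaded. Real EEG/stock data are not bundled: the synthetic generators
(`make_surrogate_recording()`, `make_market_panel()`) produce seeded
fixtures with known ground truth, and the methods vignette
(`vignettes/es-proximity-methods.Rmd`) documents what they do and do not
emulate.
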