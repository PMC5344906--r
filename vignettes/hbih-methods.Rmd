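---
title: "Methods: simulating and quantifying chaos in the HB+Ih model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying chaos in the HB+Ih model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the numerical methods behind the package: the model
equations, the integration protocol, and the three chaos quantifiers
(trajectory Lyapunov exponents, interval-series Lyapunov exponents, and
Lempel-Ziv complexity), together with the design decisions and their
rationale. Chunks are not evaluated at build time because several of them
run for minutes; every number quoted below is reproduced by the package's
test suite.

## The model

The HB+Ih model is a Huber & Braun-type cold thermoreceptor neuron: a fast
spike-generating pair (instantaneous depolarizing current $I_d$ and delayed
rectifier $I_r$), a slow oscillator pair (persistent depolarizing $I_{sd}$
and calcium-activated repolarizing $I_{sr}$), a hyperpolarization-activated
cation current $I_h$, and a temperature-scaled leak:

$$C_m \frac{dV}{dt} = -I_{sd} - I_{sr} - I_h - I_d - I_r - I_l,$$

with $I_i = \rho(T)\, g_i\, a_i\, (V - E_i)$ for $i \in \{d, r, sd, h, l\}$
($a_l \equiv 1$, $a_d = a_{d\infty}(V)$ instantaneous) and the saturable
calcium-binding form

$$I_{sr} = \rho(T)\, g_{sr}\, \frac{a_{sr}^2}{a_{sr}^2 + K_{sr}}\, (V - E_{sr}),
  \qquad K_{sr} = 0.4^2.$$

$a_{sr}$ is a calcium concentration proxy, driven by the $I_{sd}$ influx:

$$\frac{da_{sr}}{dt} = \phi(T)\,\frac{-\eta I_{sd} - \kappa a_{sr}}{\tau_{sr}},$$

while $a_r$, $a_{sd}$, $a_h$ relax toward Boltzmann steady states with
$\tau_r = 2$, $\tau_{sd} = 10$, $\tau_h = 125$ ms. The two temperature
factors are $\rho(T) = 1.3^{(T-25)/10}$ (conductances) and $\phi(T) =
3^{(T-25)/10}$ (kinetics).

A note on $K_{sr}$: the constant is $0.4^2 = 0.16$, i.e. a Hill-type binding
term whose half-activation sits at $a_{sr} = 0.4$, matching the squared
numerator. This value is what reproduces the model's reference firing
patterns across temperature (bursting at 10-26 °C, regular tonic at 33 °C,
skipping at ~3 spikes/s at 36.3 °C); reading the constant as a plain 0.42
makes the model roughly eight times too excitable and destroys the slow
oscillation of the full system. `K_sr` remains a user-settable parameter.

```{r}
library(hbih)
p <- hb_params(temperature = 36.3)
tr <- simulate_hb(p, duration = 60000)   # ms
autoplot(tr)
```

## Integration protocol

`simulate_hb()` uses classic fixed-step fourth-order Runge-Kutta in compiled
code. The default step of 0.025 ms resolves the fastest time constant
($\tau_r = 2$ ms, further shortened by $\phi(T) \approx 3.3$ at 36 °C to
~0.6 ms) with ~25 steps; the test suite verifies clean fourth-order
convergence against the closed-form leak solution. Each run discards a 30 s
equilibration segment before recording, long enough for the slowest variable
($\tau_h/\phi \approx 37$ ms, but with relaxation oscillations an order of
magnitude slower) to forget the initial condition.

Spike times (upward crossings of -15 mV) and optional monitor-level
crossings are detected inside the integrator at full step resolution with
linear interpolation, so they are independent of the trace recording stride.
The default initial state places every gating variable on its nullcline at
V = -60 mV, which makes runs deterministic and parameter sweeps independent
of the direction of parameter change.

## Firing-pattern classification

`classify_pattern()` maps a trajectory to the seven codes used throughout
the package: 0 silent, 1 subthreshold oscillations, 2 skipping/polymodal,
3 regular tonic, 4 bursting, 5 tonic above 20 spikes/s, 6 above 50 spikes/s.
The slow regimes are separated by the ISI coefficient of variation (< 0.05
is tonic) and, for candidate bursters, by splitting intervals at the
geometric mean of the extreme ISIs: bursting requires short intra-burst
intervals (median < 100 ms), at least two spikes per burst on average, and a
near-constant burst size (>= 90% of bursts within ±1 of the mode). Irregular
structure falls back to skipping.

## Trajectory Lyapunov exponents

`mle_ode()` implements the classic two-trajectory method: integrate a
reference and a companion offset by $d_0 = 10^{-6}$ in scaled coordinates
(100 mV for voltage, 1 for gates, so the metric weighs all variables
comparably), renormalize the separation every 1 ms, and average the log
stretch after discarding the first 10% (alignment with the most unstable
direction). The estimator is validated three ways in the test suite:

* exactly against linear systems ($\dot x = \lambda x$) to $10^{-3}$;
* against an independent tangent-linear (variational) integration of the
  Lorenz system to ±0.02, itself within 0.03 of the literature value 0.906;
* sign checks on the model: positive at the chaotic slow-subsystem reference
  point ($g_{sd} = 0.222$, $g_h = 0.4$), negative past the limit point.

If the separation spends more than 20% of its renormalization intervals at
the saturation bound the estimate is flagged `saturated` and should not be
trusted (it is then an attractor-size bound, not an exponent).

## Interval-series Lyapunov exponents

`isi_lyapunov()` estimates an exponent directly from an inter-spike interval
(or return-interval) series: delay-1 embeddings at $m = 7, 9, 11$, nearest
neighbours capped at 0.05% of the embedded points (with a Theiler window of
$m$ samples to exclude temporal neighbours), and the stretching statistic

$$S(s) = \left\langle \log \overline{d_s} \right\rangle_{\text{reference points}},
  \qquad s = 0, \dots, 6,$$

whose OLS slope is the exponent for that $m$; dimensions with slope p-value
below 0.05 are averaged.

Three design decisions deserve justification:

* **Divergence is measured on the following points.** Neighbourhoods are
  defined by Euclidean distance in the $m$-dimensional embedding, but $d_s$
  is the scalar distance between the series values $s$ steps after each
  window's reference time (its last coordinate). Taking the distance between
  whole $s$-advanced windows instead smears the divergence over the window
  and underestimates the slope, increasingly so at larger $m$.
* **Average of logs, not log of averages.** The log of the mean neighbour
  distance is taken per reference point *before* averaging across reference
  points, so a few large-distance outliers cannot dominate the profile.
* **Practical-significance floor.** Statistical significance of the slope
  alone cannot separate chaos from near-periodic firing: a near-periodic
  series (e.g. the model at $\tau_h = 190$ ms) yields an almost flat profile
  whose tiny slope is nonetheless significant because thousands of reference
  points enter the fit. The `chaotic` flag therefore also requires the
  exponent to exceed 0.005 per step. The floor sits in a ~1000-fold gap
  between the classes (the model's chaotic interval series ~0.3 per step;
  its near-periodic series below $3\times10^{-4}$), so the classification is
  insensitive to its exact value.

One validation caveat: with one e-fold of stretching per step (the logistic
map, $\lambda = \ln 2$), neighbour separations grow by $e^{m-1+s}$ across a
window plus the fit horizon, so a clean scaling region needs $n \gg
e^{m-1+r}$ points — attainable at $m = 7$ (0.69 ± 10% on surrogates of
length 8000) but not at $m = 11$ ($\sim 4\times10^5$ points), where the
profile saturates at the attractor diameter and biases the averaged estimate
low. The model's own interval series stretch by well under 0.1 per step,
comfortably inside the data requirement at the default dimensions.

Exactly periodic series embed onto finitely many points, all neighbour
distances vanish, and the fit is skipped: the value is reported as 0 with
`significant = FALSE`.

## Lempel-Ziv complexity

`lz_complexity()` binarizes a spike train with bins of half the minimum ISI
(guaranteeing at most one spike per bin) and counts Kaspar-Schuster
production steps $c(n)$, normalized by $n/\log_2 n$. The implementation is
pinned by hand-traced identities ($c = 2$ for a constant word, $c = 3$ for
an alternating word, $c = 6$ for the canonical 16-digit example) and
approaches 1 on random words.

## Slow subsystem and bifurcation analysis

Setting $g_d = g_r = 0$ (and $a_r \equiv 0$) removes the spike generator and
leaves a 4-variable slow oscillator. Its equilibria reduce to a scalar
root-finding problem in V (every gate on its nullcline, $a_{sr} = -\eta
I_{sd}/\kappa$), solved by a 0.01 mV grid scan plus `uniroot()` polish;
stability comes from the eigenvalues of the numerical Jacobian.
`equilibrium_branch()` re-solves from scratch at every parameter value and
brackets two event types by bisection: Hopf points (the leading complex pair
crosses the imaginary axis) and limit points (the root count changes).

Return intervals through the equilibrium voltage (`return_intervals()`,
upward crossings of $V_{eq}$) feed `count_distinct_intervals()`, a greedy
grouping with width 2% of the median interval that reports the number of
distinct interval values - the period-doubling readout (1 → 2 → 4 → many).
With the default parameters and $g_h = 0.4$ the transect along $g_{sd}$
shows the full route: Hopf near 0.17, first doubling near 0.21, chaos around
0.222 (positive trajectory MLE, unstable focus), a reverse cascade, and a
limit point near 0.32 where the oscillation dies against a stable
equilibrium. At $g_h = 0$ the doublings are absent everywhere - the
hyperpolarization-activated current is what introduces chaos.

```{r}
br <- equilibrium_branch(hb_params(g_h = 0.4), "g_sd",
                         from = 0.14, to = 0.34, step = 0.005)
branch_events(br)
```

### Limitation: interval counts near the limit point

One distinct-interval count caveat matters when interpreting the transect:
for $g_{sd}$ between roughly 0.30 and the limit point, the single surviving
periodic orbit keeps a small subthreshold wiggle around the focus (local
maximum -62.3 mV, local minimum -66.4 mV at $g_{sd} = 0.31$) and $V_{eq}
\approx -63.7$ mV lies inside it. The orbit therefore crosses $V_{eq}$
upward twice per cycle and the interval series alternates between two values
(92/336 ms at 0.31) even though only one orbit exists. A distinct-interval
count of 2 is thus *necessary but not sufficient* evidence of a period
doubling; near folds it should be cross-checked against the trajectory MLE
(here ~0, not chaotic) or the waveform itself.

## Parameter sweeps

`sweep_grid()`/`run_sweep()` evaluate measures on 1- or 2-axis grids, one
independent simulation per point (fresh deterministic initial state, no
carry-over), with per-point seeds derived from the grid seed and point index
so results do not depend on worker count. Default per-point durations are
150 s (rates, patterns, interval counts) and 1000 s when interval-series
exponents or complexity are requested; both can be overridden for faster
scans. `isi_bifurcation()` emits every ISI at every parameter value in long
format for scatter-style bifurcation plots (`plot_isi_bifurcation()`).

```{r}
g <- sweep_grid(list(g_sd = seq(0.15, 0.30, by = 0.005)),
                fixed = list(g_h = 0.2), duration = 150000)
bd <- isi_bifurcation(g)
plot_isi_bifurcation(bd)
```

## Problem sizes and runtimes

The compiled integrator advances ~3.5 million steps per second on one CPU:
a 1000 s full-model simulation at dt = 0.025 ms takes ~13 s, a 200 s
slow-subsystem run ~2.5 s. The acceptance-scale computations (a 101-point
slow transect at 200 s per point, a 21-point tau_h sweep at 300 s per point,
a 51-point fine ISI-doubling scan at 150 s per point) each complete in a few
minutes. Memory is bounded by the trace recording stride; spike and monitor
crossings are always full-resolution.
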