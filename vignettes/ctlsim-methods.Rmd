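---
title: "Spatial surveillance by cytotoxic T cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial surveillance by cytotoxic T cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlsim)
```

## The scientific question

How many cytotoxic T lymphocytes (CTL) does a tissue need so that a newly
seeded infection is eliminated rather than established? The canonical
within-host answer comes from mass-action kinetics: if infected cells grow
at net rate $r$ without control, and one CTL surveys $k$ cells per minute,
then killing balances growth at the critical CTL density

$$C^* = \frac{r}{k},$$

with $C$ measured as a fraction of all surveyable cells. This estimate
rests on three assumptions: infected cells and CTL are well mixed; CTL
search by undirected random walks; and the handling time $h$ a CTL spends
conjugated to a target while killing it is negligible next to the search
time $S = 1/(kI)$ needed to find the next target at infected fraction $I$.
`ctlsim` implements a spatially explicit stochastic simulation in which
each of these assumptions can be broken separately — by letting the
infection spread in clusters, by giving CTL a chemotactic bias, and by
making CTL fast enough that handling dominates — together with the
deterministic comparators needed to interpret the results. The organising
quantity throughout is the search-to-handling ratio $S\!:\!H$, not the
effector-to-target ratio.

## The agent-based tissue

The tissue is a lattice of immobile cells (default $320 \times 320$ sites
of 10 µm, a ~10 mm² patch) with toroidal boundaries, so the simulated
patch behaves as if surrounded by statistically similar tissue. Sites are
`susceptible`, `infected`, `dead`, or `non_susceptible` (the last used for
surveillance measurements on inert tissue). Sites are never created or
destroyed, only relabelled. CTL and virions move off-lattice with
floating-point positions; contact detection coarse-grains positions to
1 µm. All agents update at fixed steps (default $\delta t = 1$ s) with
event probabilities $1 - e^{-\text{rate}\,\delta t}$, the exact
exponential waiting-time conversion at any step size; construction fails
if any per-step probability reaches 0.1.

Infected cells die cytopathically with a 1.4-day half-life and, in
clustered mode, produce virions that travel in straight lines at constant
speed (default 10 µm/min) until cleared (4-h half-life) or until they
enter a susceptible site, which they infect instantly. This virion rule is
a device to generate focal spread, not a transport model. In diffuse mode
no virions exist: each infected cell converts a uniformly random
susceptible site with per-step probability derived from rate $r +
\ln 2/1.4$ d⁻¹, with cytopathic death retained so the realised net growth
is $r$; a `diffuse_literal` flag instead applies the bare rate $r$ with
death disabled. Both defaults reproduce $r = 1$ d⁻¹ (doubling time
$\ln 2/r \simeq 16.6$ h); the clustered production rate (default 1.548
virions cell⁻¹ day⁻¹) was calibrated once by sweeping production ±15%,
regressing the mean fitted growth rate of CTL-free runs on production, and
solving for $r = 1$ d⁻¹, then frozen.

CTL cycle through three behaviours:

* **searching** — a persistent random walk: straight segments of 25 µm
  punctuated by turns through angles uniform on ±45°;
* **scanning** — on contact with a living uninfected cell the CTL pauses
  for a fixed scan time (5 s), then turns and moves on;
* **conjugated** — on contact with an infected cell the CTL binds and
  remains attached for a fixed handling time $h = 30$ min, after which the
  target dies. Multiple CTL may bind one target without changing its death
  time, which is set by the first-attached CTL's clock; when the target
  dies (by lysis or cytopathy) every attached CTL is released with a fresh
  turn. A CTL can kill any number of times.

Chemotaxis is implemented at turn events only: with probability
`chemotaxis_prob` (0, 1%, 5% or 20% in the study design) the new heading
points exactly at the nearest living infected cell — conjugated targets
included — instead of being drawn from ±45°. Speed is never altered, so
the surveillance rate of an uninfected tissue is independent of the
chemotaxis setting.

### Contact detection and the surveillance rate

A cell is "in contact" when its centre lies within `contact_radius` of the
CTL's coarse-grained position. A scan or conjugation is triggered only
when a site *newly enters* the CTL's contact set. We chose set-entry
semantics over remembering a single last-scanned site deliberately: with
any radius large enough to give realistic surveillance rates, two cells
can be in simultaneous contact, and a one-site memory lets a CTL
alternately re-scan two neighbours without moving — an unbounded,
velocity-dependent artefact. Entry-triggered scanning has the same intent
(no re-scan while contact persists) with none of the pathology.

The contact radius is the one free geometric parameter. It is fixed by
calibration: bisect the radius until the *measured* surveillance rate —
distinct-cell scans per CTL per minute for 100 CTL on inert tissue —
matches 1.1 cells/min at 7.5 µm/min and a 5-s scan. The frozen default is
6.6875 µm, roughly a cell radius plus a T-cell radius. Two caveats are
worth recording. First, because positions are coarse-grained to 1 µm, the
measured rate is a step function of the radius (whole families of lattice
offsets become reachable at once), so calibration settles on the nearest
shelf within its 5% tolerance rather than an exact match. Second, for any
contact process of this kind the rate obeys $k(v) = 1/(g/v + t_{scan})$
where $g$ is the mean path length between distinct cell contacts — a
purely geometric, speed-independent quantity. Consequently one geometry
cannot yield both $k(7.5) = 1.1$ and $k(0.18) = 0.022$ cells/min: matching
the fast rate forces $k(0.18) \approx 0.029$. We calibrate to the fast
regime and report the slow regime as measured; the package's slow-regime
critical densities are therefore always expressed relative to the
*measured* $k$ of the same geometry (the `k_ref` entry of the presets),
which keeps every relative quantity internally consistent.

### Update order, randomness, reproducibility

Each step advances (1) virions, (2) infected-cell production, death and
diffuse spread, (3) CTL, with CTL order reshuffled every step; the paper
trail for this choice is simply that a fixed phase order with within-class
shuffling avoids systematic bias without the cost of full event-driven
scheduling. Per-cell Bernoulli events with small probabilities are drawn
as per-step binomial counts assigned to uniformly chosen cells, which is
distributionally equivalent and removes one RNG call per cell per step.
All randomness comes from R's generator, so a single `seed` makes a whole
run — growth phase, placement, dynamics — bit-reproducible; replicate
ensembles derive per-replicate seeds from a base seed. Runs end at
extinction, at `t_max` (default 10–15 days) or, on small lattices, when
the cumulative epidemic (infected plus dead) reaches half the tissue; the
last rule stops target-cell burnout — exhaustion of susceptibles, which is
no part of the modelled biology — from masquerading as CTL control.

## Deterministic comparators

The simple model is $dT/dt = (r - kC_0)\,T$ with the closed form used
directly. The extended model follows conjugates by age $\tau$ since
binding, $X(t, \tau)$:

$$\frac{dT}{dt} = rT - kC_f T, \qquad X(t, 0) = kC_f T,$$
$$\frac{\partial X}{\partial t} + \frac{\partial X}{\partial \tau} = 0,
\qquad \frac{dC_f}{dt} = -kC_f T + X(t, h),$$

where $C_f$ is the free-CTL density; at age $h$ the target dies and the
CTL returns to the free pool. Conjugated targets neither replicate nor are
re-attacked. Numerically, age transport uses first-order upwind on a
uniform $\tau$ grid with the time step equal to $\Delta\tau$ (default
$h/30$), which advects age exactly with no numerical diffusion; within
each step the free-target equation is integrated exactly at frozen $C_f$,
and the bound mass is computed from the same integral, so CTL conservation
$C_f + \int X\,d\tau = C_0$ holds to machine precision while the per-step
bias of plain Euler is avoided. A CFL-style guard rejects
$k\,\max(T_0, C_0)\,\Delta\tau \ge 1$.

The critical density of the extended model has no closed form; it is
found by bisection on $C_0$ against the sign of the log-linear slope of
$T(t)$ over the final 20% of a 20-day horizon, to $10^{-4}$ relative
tolerance. With $h = 0$ the function returns $r/k$ exactly. A useful
analytic cross-check is the quasi-steady-state result
$C^* \approx r(1 + kT_0h)/k$, accurate when $T$ varies slowly; it shows
why the extended $C^*$ always exceeds $r/k$ and grows with $h$ and $T_0$.

Two limit behaviours deserve a note because they are easy to misread.
When CTL vastly outnumber targets, the *free-target* trajectory collapses
onto the simple model, but the *total* infected count (free plus
conjugated) lags it by up to one handling time — conjugated cells are
alive until lysed. Model-to-model agreement of total counts therefore
requires the doomed-cell standing stock $kC_0h$ to be negligible, which at
fixed $h$ bounds the CTL density for which "mass action holds" in the
strict <2% sense.

## Estimating the critical density stochastically

In the stochastic setting $C^*$ is the density at which half of the
simulated infections go extinct. A run whose infected count reaches zero
is extinct; otherwise the ordinary least-squares gradient of the infected
count over the final 12 simulated hours decides (negative → extinct),
which resolves runs still fluctuating near zero at `t_max`. The extinction
probability at density $C$ is the proportion of replicate runs (200 in the
full design; desk presets use 20–50) that go extinct, reported with a
Wilson interval. An adaptive search bisects on "estimated proportion minus
one half" from broadly spaced guesses, keeping every evaluated point;
estimates exactly at 0.5 are treated as the high side so ties move toward
smaller densities. All evaluated points then feed a sigmoid fit

$$p(C) = \frac{C^\alpha}{C^\alpha + (C^*)^\alpha},$$

a two-parameter Hill curve that is zero at $C = 0$, one half at
$C = C^*$ by construction, and saturates at one; $\alpha$ measures how
sharply demographic stochasticity blurs the deterministic threshold. The
fit minimises replicate-weighted least squares (binomial likelihood is
available as an option — the loss is not dictated by the design) over
$(\log C^*, \log\alpha)$ by Nelder–Mead from three starts. Critical
densities are reported in units of $r/k$ with $k$ the measured
surveillance rate of the matching regime.

## Desk-scale presets

The full study conditions (320×320 lattice, 1-s steps, 200 replicates per
density, many densities) are hours-to-days of computation. The package's
own tests and examples therefore run documented scaled-down presets,
chosen once: a 64×64 lattice for the slow-surveillance regime
(0.18 µm/min) and 128×128 for the fast regime (7.5 µm/min), both with
10-s steps (every per-step probability stays far below the 0.1 cap),
infected counts at CTL introduction scaled in proportion to lattice area,
12-day horizons and 20–50 replicates per density. Directional claims
(clustering raises $C^*$ when handling limits; any chemotaxis lowers it)
are tested as one-sided comparisons of extinction counts at matched
densities and matched seed streams, which is far cheaper than estimating
two full sigmoids and statistically sharper at small replicate counts.

What the scaled-down generator reproduces faithfully: the relative
geometry (cell size, contact radius, persistence length and speeds are
unscaled, so per-CTL search and handling kinetics are identical to the
full scale); growth-rate calibration; the competition between killing and
growth near threshold. What it does not: with tens rather than hundreds
of CTL, density is quantised (one CTL on a 128×128 grid is
$6\times10^{-5}$ in density), so fitted $C^*$ values carry a
discreteness error of order one CTL; small lattices reach the
cumulative-epidemic stop earlier, truncating late dynamics; and
demographic noise is relatively larger, broadening the sigmoid (smaller
$\alpha$) compared with the full tissue. Passing desk-scale tests
therefore demonstrates the mechanisms and their directions, not the
paper-scale numerical surfaces.

## Numerical and design choices in brief

* "At random from the directions ±45°" is read as a continuous uniform
  deviate on $[-45°, +45°]$ (a persistent random walk); the two-point
  $\{-45°, +45°\}$ alternative is available via `discrete_turns`.
* Recognition of an infected cell on contact is immediate and certain
  (100% killing efficiency after contact); there is no separate
  recognition delay before conjugation.
* Dead cells persist as sites but are excluded from contact sets: they
  are neither scannable nor infectable nor chemotactic targets.
* Conjugated infected cells keep producing virions and seeding diffuse
  infections by default (they are alive until lysed); `conjugates_produce
  = FALSE` switches this off.
* A CTL released by its target's death re-enters search with a fresh turn
  event; its stale contact set prevents instantly re-scanning cells it
  was already touching.
* Handling time and scan time are fixed constants, not exponential draws.
* A directed turn aims at the nearest infected cell at the moment of the
  turn and does not re-aim mid-segment; nearest-site ties break on the
  smaller (row, column) index for determinism.
* The growth-rate estimator is log-linear OLS opening when the count
  first reaches 50 cells; runs that never reach the threshold carry no
  growth information and are excluded (they would otherwise bias
  calibration toward zero).
* Infections that fizzle before reaching the CTL-introduction count are
  restarted on a fresh substream with the attempt count reported.

## Limitations

Targets are immobile and the tissue is planar; both favour focal spread,
and the return-probability utility (`lattice_return_probability`) exists
precisely to illustrate why three-dimensional search is qualitatively
harder for undirected walkers (the 3-D simple-cubic return probability is
only ≈0.34, against 1 in 2-D). There is no eclipse phase between infection
and virion production, no epitope-expression dynamics, no non-lytic
suppression, and no CTL exhaustion; the virion rule is phenomenological.
The chemotaxis rule is deliberately extreme — an unbounded-range cue —
which is why the study design caps the directed-turn probability at 20%.
Finally, the published fast/slow surveillance-rate pair is not jointly
reachable by any single contact geometry of this class (see above); all
densities in units of $r/k$ use the geometry's measured rate, so
conclusions about *relative* critical densities are unaffected.
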