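---
title: "Methods: direction-dependent collective movement on a ring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-dependent collective movement on a ring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ringswarm` simulates $N$ individuals on a one-dimensional ring $[0, L)$
with periodic boundary conditions. Individual $i$ has position $x_i(t)$
and heading $v_i(t) \in \{+1, -1\}$ and, in the constant-speed model,
moves at speed $\gamma$ in its heading. Headings reverse stochastically:
a right- or left-moving individual turns with rate

$$\lambda_i^\pm = \lambda_1 + \lambda_2\, f\!\big(\alpha\,(y_{r,i}^\pm - y_{a,i}^\pm + y_{al,i}^\pm)\big),
\qquad f(x) = \tfrac12 + \tfrac12 \tanh(x - y_0),$$

where $\lambda_1$ is a baseline (random) turning rate, $\lambda_2$ the
maximum additional bias, and $y_{r}, y_{al}, y_{a}$ are the repulsion,
alignment and attraction social forces felt for the individual's own
heading. Attraction enters with opposite sign: crowding ahead of an
attractive group should suppress turning, not promote it. With the
default shift $y_0 = 2$, $f(0) \approx 0.018$, so an unstimulated
individual turns at essentially $\lambda_1$: movement without neighbours
is a discrete-time telegraph process with per-step flip probability
$(\lambda_1 + \lambda_2 f(0))\,\Delta t$. This zero-interaction limit is
verified by Monte Carlo in the test suite.

Each timestep is synchronous: turning rates are evaluated on the current
state, every individual advances $\gamma v_i \Delta t$ (wrapped onto the
ring), and each heading flips iff $\lambda_i \Delta t \ge X_i$ with
$X_i \sim U[0,1]$ drawn fresh per individual per step. Probabilities
above one simply flip with certainty; they are not clamped.

### Social forces and interaction zones

Neighbours are weighted by truncated Gaussian kernels of the pairwise
ring distance,

$$K_j(s) = \frac{1}{\sqrt{2\pi m_j^2}} \exp\!\Big(-\frac{(s - s_j)^2}{2 m_j^2}\Big),
\qquad j \in \{r, al, a\},$$

with zone centres $s_r = 0.25$, $s_{al} = 0.5$, $s_a = 1$, widths
$m_j = s_j / 8$, and support truncated at $2 s_j$ (a distance exactly at
the cutoff is inside the support; the choice is measure-zero and fixed
for reproducibility). A revised repulsion kernel centred on the
individual itself ($\tilde m_r = s_r / 2$, kernel maximal at distance 0)
is available as `kernel_variant = "revised_repulsion"`; it weights the
nearest neighbours most strongly, which removes the short-range "valley"
of the zonal form in which tight subgroups can otherwise sit without
repelling each other. Its truncation is kept at $2 s_r$ so the
interaction range matches the zonal form.

Which neighbours count is set by one of five direction-dependent
interaction rules. Writing $R$/$L$ for a neighbour's side of the
reference individual and "toward" for a right-zone left-mover or a
left-zone right-mover:

| rule | repulsion & attraction          | alignment                        |
|------|---------------------------------|----------------------------------|
| M1   | all neighbours, $R - L$         | toward neighbours only           |
| M2   | all neighbours, $R - L$         | all neighbours, opposite-heading minus same-heading |
| M3   | ahead only                      | ahead only, opposite minus same  |
| M4   | toward neighbours on both sides | toward neighbours on both sides  |
| M5   | ahead and toward only           | ahead and toward only            |

The sums exclude the individual itself (a self-term would inject a
spurious constant repulsion under the centred revised kernel), use
minimal-image displacements for both distance and side, assign the exact
antipode (distance $L/2$) to the right zone by convention, and leave a
neighbour at exactly zero distance on neither side. With the default
kernels ($2 s_a = 2 \ll L/2$) none of these conventions is ever exercised
by the physics; they only pin down degenerate configurations so that runs
are bit-reproducible.

The scaling $\alpha = A L / N$ (with total mass $A = 2$, so
$\alpha = 0.04$ at the standard $N = 500$, $L = 10$) converts per-capita
force sums onto a density scale, making the turning-rate parameters
independent of how many individuals discretise the same population.

### Density-dependent speed

In the density-dependent-speed variant individuals turn only in response
to alignment, $\lambda_i^\pm = \lambda_1 + \lambda_2 f(y_{al,i}^\pm)$
(the printed form of this rate carries no $\alpha$; the constructor
exposes `apply_alpha_dds` for consistency experiments, default off), and
move at

$$\Gamma_i^\pm = \gamma\,\big(1 + \tanh(y_{a,i}^\pm - y_{r,i}^\pm)\big) \in (0, 2\gamma):$$

an individual speeds up toward a distant group and slows down in a
crowd. The update order matters here: headings flip first, then the
forces are **recomputed with the new headings at the pre-move
positions**, and only then do individuals move at the recomputed speed —
otherwise an individual that has just turned would respond to signals
evaluated for its old heading. The bounds on $\Gamma$ are open
mathematically but close at double precision: once
$|y_a - y_r| \gtrsim 19$, `tanh` saturates to $\pm 1$ exactly, and the
dense cores of splitting-merging runs do reach such force differences,
momentarily stalling (or maxing out) the affected individuals.

## Simulation engine and reproducibility

The inner loop is compiled (Rcpp). It visits each unordered pair once,
accumulates four directional sums per zone per individual (side
$\times$ neighbour heading), and applies the per-rule sign structure
afterwards, so the O($N^2$) loop is free of rule logic. Kernel
evaluation uses the same floating-point association order as the R
formula, and the RNG discipline is fixed — initial positions, then
initial headings, then one uniform per individual per step in index
order, all from R's stream — so the compiled engine and the pure-R
reference steppers (`step_constant_speed()`, `step_density_dependent()`)
produce **bit-identical** trajectories from the same seed. The test
suite asserts this for all five interaction rules and both speed modes.

Two invariances are also tested at trajectory level: translating the
initial condition translates the trajectory, and mirroring it
($x \to L - x$, $v \to -v$) mirrors the trajectory under matched draws.
These tests use a dyadic geometry ($L = 8$, $\gamma \Delta t = 2^{-7}$,
initial positions on a $2^{-7}$ grid) in which reflection and every
displacement are exact binary fractions, so the expected equalities are
exact rather than approximate.

## Pattern analysis

Space-time rasters are kernel density estimates per recorded frame,

$$\rho(x, t) = \frac{1}{N h} \sum_{i=1}^N K\!\Big(\frac{x - x_i(t)}{h}\Big),$$

with standard-normal $K$ and bandwidth $h = 0.1$. The displacement is
taken minimal-image, which makes the estimate periodic; with
$h \ll L$ this only removes the seam artifact of the line version. The
raster integrates to one over the ring each frame (tested to $10^{-6}$
on a 2000-point grid), and `normalize_max()` applies the separate
unit-maximum colour normalization used for heat maps. The default raster
uses 500 grid points (an output-resolution choice only; no model
quantity depends on it).

Per-frame order parameters (`diagnostics()`): polarization
$|\sum_i v_i| / N$; circular-mean centroid; windowed drift speed of the
unwrapped centroid (default window 20 time units — long against the
$\approx 1/(2\lambda) \approx 2.3$ time-unit heading correlation time,
short against the pattern lifetime); and aggregation width, the circular
(angular) standard deviation mapped to space units. Two raster-level
statistics complete the set: `count_density_peaks()` counts contiguous
regions above half the frame maximum (with ring wrap), and
`pattern_speed()` estimates the signed translation velocity of the
density pattern by summed circular cross-correlation between frames a
fixed lag apart. The pattern speed is essential for multi-band states:
counter-moving trains hold the global polarization and centroid near
zero while the bands themselves move ballistically.

### Diagnostic signatures for the preset patterns

The documented evidence for the nine constant-speed patterns and four
density-dependent-speed behaviours is visual. To make them testable, the
package fixes one quantitative signature per pattern family, scored on
the final third of a run (final two thirds for oscillation counts), with
$\gamma = 0.1$ the baseline speed:

* **Stationary aggregation** (stationary pulses 1 and 2, feathers,
  density-dependent-speed presets a and b):
  $|$`pattern_speed`$| < 0.1\gamma$ and mean per-frame maximum of
  $\rho L \ge 2.5$ (the uniform state has $\rho L = 1$; an aggregation
  concentrates several times that). Neither a width bound nor the
  centroid drift is used: random initial conditions regularly produce
  two or more coexisting stationary pulses — the same pattern class —
  and a multi-pulse state inflates any global dispersion measure, while
  its circular-mean centroid jitters at around $0.1\gamma$ as pulses
  exchange individuals even though the density raster stands still.
  Raster translation measures stationarity directly.
* **Traveling pulse**: median $|$drift$| \in (0.3\gamma, 1.3\gamma)$ and
  mean polarization $> 0.3$. A stochastic pulse cannot move at $\gamma$:
  its speed is $\gamma$ times the mean heading, and with $y_0 = 2$
  turning noise the sustained polarization sits near 0.6, so the group
  travels at roughly $0.6\gamma$. The 0.3 floors are an order of
  magnitude above the $1/\sqrt{N} \approx 0.045$ polarization noise of
  an unordered population and three times the stationary drift
  ceiling.
* **Traveling train**: at least three density peaks in at least half
  of the scored frames, mean local polarization
  (`local_polarization()`, radius $s_{al}$) $\ge 0.2$ — several times
  the disordered-population level — and band motion: the larger
  direction-conditional raster speed (`pattern_speed()` of
  `direction_density()`) in $(0.25\gamma, 1.5\gamma)$. Global order
  parameters are deliberately avoided: trains of both directions can
  coexist on the ring for hundreds of time units, cancelling the global
  polarization and freezing the full-population raster, while each
  heading's own raster still translates at the band speed
  (approximately the local polarization times $\gamma$).
* **Ripples**: at least two density peaks in at least half of the
  scored frames plus at least two sign reversals of the drift between
  sustained episodes ($|$drift$| > 0.3\gamma$), the centroid signature
  of bands repeatedly crossing.
* **Zigzag pulse**: at least two sign reversals between sustained
  drift episodes after the formation transient ($t > 100$).
* **Breathers** (stationary or traveling): relative oscillation of the
  dominant-peak width (`dominant_peak_width()`, the extent of the
  widest above-half-max region), sd/mean $\ge 0.1$, with at least four
  crossings of its mean — expansion and contraction, not monotone
  spreading; the stationary breather preset must additionally stay in
  place (median $|$drift$| < 0.3\gamma$). The dominant-peak width is
  used instead of the global
  circular dispersion because random initial conditions regularly
  produce several coexisting breathing groups, whose joint dispersion
  is nearly constant even while each group visibly breathes.
* **Fission-fusion** (density-dependent speed, presets c and d): the
  half-max peak count varies over time (range $\ge 2$ with at least
  eight changes), capturing repeated splitting and merging.

These thresholds are this package's own operational definitions; the
signatures are intentionally not mutually exclusive (a zigzag pulse also
breathes while it turns) because the goal is verification of each preset
against its documented description, not automatic nine-way
classification, which is out of scope.

### The traveling-train parameter row

One reference preset is internally inconsistent with the printed
equations, and the package documents rather than hides this. The
traveling-train row prescribes rule M3 with $q_r = 0$, $q_{al} = 2$,
$q_a = 6$. M3 is the only rule whose zone sums are one-sided (ahead
only, no right-minus-left cancellation), so at the standard conditions
the attraction stimulus alone is
$\alpha\, q_a \sum_j K_a \approx 0.04 \cdot 6 \cdot 50 = 12 \gg y_0$:
the turning function is pinned at $f \approx e^{-28}$ for **every**
individual and **both** headings, all turning bias vanishes, and the
population remains a fast telegraph gas indefinitely (measured local
polarization $\approx 0.10$, the disorder level, out to thousands of
steps). No train can form — for comparison, the feathers row (also M3)
works precisely because its $q_r = 6.4$ and $q_a = 6$ nearly cancel.
The row's turning rates factor as $\lambda_1 = 0.2/0.03$ and
$\lambda_2 = 0.9/0.03$, identifying the alignment-only sweep regime
(case b) at $\alpha = 0.03$ — a regime in which M3 does form traveling
trains, and the documented source of this pattern. The catalog
therefore keeps the reference row verbatim under `traveling_train`
(its signature checks fail, by design honesty) and adds
`traveling_train_alignment_only` — the same turning rates, $q_{al} = 2$,
$q_r = q_a = 0$, $\alpha = 0.03$. Every realization of the
reconstruction forms the train lattice (15–20 small, locally aligned
bands); pattern selection within the regime is stochastic: in most
realizations the lattice travels at about the local polarization times
$\gamma$, while occasionally the two heading populations balance and
the same lattice stands still. The test suite accordingly requires the
lattice and local order of every seed but ballistic band motion only of
the majority. Incidentally, only the "divide" reading of the case-(b)
rate scaling reproduces this regime, which corroborates the
`rate_scaling = "divide"` default.

## Study conditions and problem sizes

The preset catalog reproduces the reference parameter rows exactly, with
the shared constants $N = 500$, $L = 10$, $A = 2$, $\Delta t = 0.05$,
$\gamma = 0.1$ and the default 20,000-step horizon (1,000 time units,
recorded every 20 steps) matching the time spans of the reference
space-time plots. The acceptance script runs representative presets at
exactly these conditions. The test suite scores every preset in the
catalog, three seeds each for the constant-speed ones, at a
12,000-step horizon
(600 time units): the patterns form within the first 200–300 time units,
so the scored final third is comfortably post-transient, and the shorter
horizon keeps the full suite within a desktop-scale run. Force-oracle
and invariance tests use populations of up to 30 individuals, where the
naive double-loop reference is fast.

## Parameter sweeps

`sweep_spec()`/`sweep_configs()` enumerate the three canonical regimes:
(a) repulsion-attraction only ($q_{al} = 0$, $q_r, q_a \in [0.5, 9]$),
(b) alignment only ($q_r = q_a = 0$, $\alpha \in [0.006, 1]$,
$q_{al} \in [0.5, 10]$), and (c) all interactions
($q_r, q_{al}, q_a \in [1, 10]$), crossed with any subset of M1–M5 and
replicate seeds, at a default resolution of 8 points per axis (the
reference ranges come without grids; 8 points per axis keeps a full
five-rule sweep near $10^3$ runs). In regime (b) the turning rates are
tied to $\alpha$; the printed fraction is typographically ambiguous
between $\lambda = 0.2\alpha$ and $\lambda = 0.2/\alpha$, so the
generator exposes `rate_scaling = c("divide", "multiply")` rather than
silently picking one. The default is `"divide"`: regime (b) varies
$\alpha$ precisely to probe turning-rate magnitude, and division makes
small $\alpha$ mean fast turning, consistent with the traveling-train
preset whose $\lambda_1 = 6.67 = 0.2/0.03$ matches the division reading.
Both behaviours are tested.

## What the simulations do and do not show

The synthetic runs demonstrate that the interaction rules generate the
documented pattern families under the stated conditions; they are not
evidence about any particular species. Real aggregations are not
one-dimensional, interact through senses with occlusion and latency
rather than clean zonal kernels, and have heterogeneous individuals.
Within the model itself, known limitations: patterns at these noise
levels are quasi-stationary, so any finite-horizon diagnostic is a
snapshot of a stochastic process (the test signatures were chosen to be
robust to single rare events, e.g. medians over windows rather than
means of signed quantities); global symmetry breaking on the ring can
be slow at high baseline turning rates, which is why multi-band states
are scored by band motion instead of global polarization; and the
O($N^2$) force pass, while compiled, makes populations beyond a few
thousand individuals expensive — the reference conditions ($N = 500$)
run in about a minute per thousand time units on one core.
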