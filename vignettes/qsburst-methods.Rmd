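---
title: "Quorum-sensing induction bursts in growing colonies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quorum-sensing induction bursts in growing colonies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsburst)
```

## The model

`qsburst` simulates the onset of quorum sensing (QS) in an early, effectively
two-dimensional bacterial colony — the stage at which cells growing as a
monolayer on a surface decide, via secreted autoinducer (AI) molecules,
whether to switch to the communal biofilm-forming mode. The model is
individual-based and lattice-free: every cell is a point-like disk of radius
$r_c$ tracked explicitly, cells do not interact mechanically (overlaps are
allowed and read as cells growing on top of one another), and the plane is
unbounded — the seeding disk of radius $R$ constrains only the initial
condition.

Three processes drive the dynamics:

**Growth.** Each division step picks a mother uniformly at random among the
$n$ current cells, leaves one daughter on the mother's exact position, and
displaces the second daughter either by a fixed distance $d_\mathrm{new}$ at
a uniform random angle, or by independent Gaussian offsets with standard
deviation $\sigma_\mathrm{str}$ along each axis. The clock advances by
$t_\mathrm{gap} = 1/(\gamma n)$ per step, so the population grows
exponentially at the per-capita division rate $\gamma$. Daughters inherit the
mother's lineage label, which identifies the "genetic family" descending
from each seed cell.

**Signalling.** Every cell emits AI molecules that diffuse (coefficient $D$)
and degrade (rate $\delta$). Because the field relaxes much faster than the
division time, only its steady state matters; around a single cell it is

$$c_\mathrm{st}(r) \;=\; \frac{K_0(r\sqrt{\alpha})}{K_0(2 r_c \sqrt{\alpha})},
\qquad \alpha = \delta / D ,$$

with $K_0$ the modified Bessel function of the second kind. The
normalisation makes the contribution of one basal-rate cell equal to exactly
1 at the touching distance $2 r_c$, and for $r \le 2 r_c$ the profile is
truncated to that value. $1/\sqrt{\alpha}$ is the signal range: the typical
distance an AI molecule travels before degradation. A cell perceives the
superposition $\sum_j w_j\, c_\mathrm{st}(d_{ij})$ over all cells $j$, with
weight $w_j = 1+\eta$ for induced emitters and $1$ otherwise.

**Induction.** A cell whose perceived concentration reaches the threshold
$\beta_\mathrm{thr}$ switches irreversibly to the induced state and raises
its production by the factor $(1+\eta)$. Because that raises every other
cell's perceived field, one induction can trigger more: after every division
the threshold rule is re-applied until nothing changes. All cells induced
within one division step form a *burst* of size $k_t$.

## Units

Lengths are in micrometres and times in minutes. Concentrations are
dimensionless *threshold units*: the touching-distance contribution of one
basal-rate cell is the unit, so $\beta_\mathrm{thr} = 30$ reads "thirty
touching-cell contributions". This is the only convention under which the
profile normalisation and the stated threshold values are mutually
consistent, and it removes the basal rate $\varphi$ from the numerics
entirely ($\varphi$ merely renormalises time and is kept as a bookkeeping
field fixed at 1/s). No conversion to physical (nanomolar) concentrations is
attempted.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `r_c` | 2.5 um | cell radius |
| `R` | 100 um | seeding-disk radius |
| `rho` | 0.0025 /um^2 | seed density; mean seed count $\rho\pi R^2 \approx 78.5$ |
| `gamma` | 1/60 /min | division rate |
| `beta_thr` | 30 | induction threshold (threshold units) |
| `eta` | 0 | surplus production of induced cells |
| `alpha` | — (required) | inverse squared signal range, 1/um^2 |
| `max_time` | 240 min | clock cap |

The biologically motivated constants ($r_c$, $R$, $\rho$, $\gamma$,
$\beta_\mathrm{thr}$) are treated as fixed; the scientifically interesting
dials are $\alpha$, the spatial-disorder parameter ($d_\mathrm{new}$ or
$\sigma_\mathrm{str}$) and $\eta$. `alpha` spans $10^{-3}$–$10^{3}$ /um^2
(signal ranges of roughly 30 um down to 0.03 um).

## Initial conditions

`seeding = "disk"` draws the seed count from a Poisson distribution with
mean $\rho \pi R^2$ and scatters the cells area-uniformly in the disk.
`seeding = "grid"` places a deterministic square lattice (default 10 × 10 at
200 um spacing — wide enough that lineages grow as effectively isolated
clusters even at long signal range). `seeding = "single"` starts from one
cell at the origin, the setup for the burst phase-transition analysis. A
cell-table CSV can also be supplied directly.

Induction is evaluated once at $t = 0$: a sufficiently dense seed
configuration may be super-threshold before any division. For the default
parameters this evaluation never fires, but it makes dense hand-built
configurations behave consistently.

## Numerical choices

* **Self term.** The truncation rule makes a cell's own contribution exactly
  $w_i$ at $r = 0$; it is included by default (`include_self`). Relative to
  $\beta_\mathrm{thr} = 30$ the self term is minor, and the switch allows
  reporting either convention.
* **Inclusive threshold.** Induction fires at `conc >= beta_thr`. For
  continuous fields the difference from a strict inequality has measure
  zero, and inclusivity makes integer-arithmetic fixtures (touching cells
  contributing exactly 1) exact.
* **Cascade resolution.** Synchronous sweeps; induced weights update
  incrementally ($O(kn)$ per step). Since inducing a cell never lowers any
  perceived concentration, the update operator is monotone and the fixed
  point is unique — the asynchronous resolver (`order = "random"`) reaches
  the same set, which the test suite verifies against brute-force closure
  enumeration on small colonies. Sweep counts, unlike the final set, are
  implementation-defined. Cells induced mid-cascade all receive the step's
  clock time: sweeps are instantaneous within a division step.
* **Deterministic clock.** $t_\mathrm{gap} = 1/(\gamma n)$ is applied
  deterministically (mean-field event stepping), which keeps single
  trajectories exactly reproducible while preserving per-capita exponential
  growth; `step_mode = "exponential"` draws the gaps from the corresponding
  exponential distribution for sensitivity checks.
* **Maintained fields.** Perceived concentrations are maintained
  incrementally across steps (one Bessel evaluation vector per division or
  induction). The final state stores the maintained values; the suite checks
  them against a from-scratch recomputation (drift is at the
  $10^{-12}$ level on full runs).
* **Far-field cutoff.** `field_cutoff` drops single-cell contributions below
  the given value (default 0, i.e. exact). Ensemble runs use $10^{-12}$,
  bounding the error per perceived concentration by $n \cdot 10^{-12}$ —
  negligible against a threshold of order 10 — while avoiding Bessel
  evaluations for distant pairs.
* **Decay distances.** `qs_percent_decay_distance` brackets the root by
  doubling and refines with `uniroot` to a relative tolerance of $10^{-10}$.
* **Burst detector.** A step is flagged when $k_t$ exceeds the running mean
  by more than 8 running standard deviations, the sample being all steps
  since the last flagged burst. Two regularisations make the rule well
  defined on degenerate samples: the SD is floored at `s_min = 1` cell and
  at least 5 steps must accumulate before flagging; flagging resets the
  sample.
* **Censoring.** Replicates that never reach the event of interest (first
  induction, a target induced fraction) are excluded from ensemble means and
  reported as censored; nothing is imputed.

## Reproducibility

Each replicate uses a single RNG stream with a documented draw order
(seed count; per-seed radius and angle; per step: mother, clock gap where
stochastic, placement draws). Replicate $i$ of an ensemble uses seed
`seed_base + i - 1`, and sweep runs derive their seed as a pure function of
(base seed, grid-point index, replicate index) — any single run of a sweep
can be reproduced in isolation. Identical parameters and seed give
bit-identical event logs. A useful consequence of the draw order: the
cascade consumes no randomness, so the first-induction time of a fixed seed
is bit-identical for any $\eta$ — only the subsequent dynamics differ.

## Design choices where the model is open

* **Daughters of induced mothers are born non-induced** and evaluated
  against the local field immediately; the induced state is not inherited.
  At the location of an induced mother the field almost always exceeds
  threshold anyway, so this choice is conservative and rarely visible.
* **The order parameter $\zeta$** (relative burst size) uses the *first*
  cascade of a single-seed colony: the cells induced at the first-induction
  step divided by the colony size at that step. Later bursts are not
  averaged in.
* **Mean concentration at first induction** is measured after the cascade of
  that step has resolved (induced cells already carry weight $1+\eta$).
* **Event-based stopping.** Besides the clock, cell-count and
  full-induction termination rules, runs can stop at the first induction
  event; first-passage ensembles use this, which is exact because nothing
  after the first induction feeds back into it.

## Problem sizes and what the ensembles show

The packaged analyses use the ensemble sizes natural for this model: 20
replicates for first-passage and cluster statistics, 15 per point for the
$\zeta(\eta)$ transition, and 100 for induced-fraction histograms. Long
first-passage runs carry a clock cap of 480 min and a cell-count cap of
12,000 cells; ordering statements across parameter points use
censoring-aware comparisons (a censored run enters as the time its colony
stopped, a strict lower bound on its first-induction time). With these
settings the characteristic behaviours are well resolved: first induction
around 150–190 min under the reference regime ($\alpha = 0.05$ /um^2,
$d_\mathrm{new} = 10$ um, $\eta = 1$), earlier induction for longer signal
range and stronger spatial heterogeneity, and the sigmoidal rise of
$\langle\zeta\rangle$ with $\eta$.

The simulator *is* the data-generating model, so what the test ensembles
demonstrate is internal consistency and the qualitative physics — threshold
cascades, locality, disorder effects — not agreement with any particular
organism. Mapping to real biofilms requires rescaling time (different
division rates), and the model deliberately omits features real colonies
have: three-dimensional growth, mechanical exclusion, nutrient limitation
and death, advective flows, density-dependent AI diffusion, multiple AI
species, and active motility. Within those limits the geometry-driven
conclusions (where and when induction starts, how bursts spread) are the
quantities the package is designed to measure.

## A worked micro-example

The canonical cascade fixture: three collinear cells at 0, 5 and 10 um with
$\alpha = 0.04$ /um^2 and threshold 3. The centre cell perceives
$1 + 1 + 1 = 3$ (self, two touching neighbours) and tips first; with
$\eta = 4$ its weight becomes 5 and the outer cells then perceive
$1 + 5 + K_0(2)/K_0(1) \approx 6.27 \ge 3$:

```{r cascade}
tri <- qs_fixture("collinear_triple")
p <- qs_params(alpha = 0.04, beta_thr = 3, eta = 4, d_new = 1)
qs_resolve_cascade(tri, p)
qs_resolve_cascade(tri, qs_params(alpha = 0.04, beta_thr = 3, eta = 0, d_new = 1))
```

Without feedback ($\eta = 0$) only the centre is induced — the minimal
illustration of why the surplus production $\eta$ is the burst-forming
ingredient.
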