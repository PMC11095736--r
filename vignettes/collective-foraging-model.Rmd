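---
title: "A mechanistic model of visual social information use in collective foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of visual social information use in collective foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`swarmforage` simulates groups of disk-shaped agents foraging for resources
in a 2D arena. Its purpose is to connect *individual-level* perception and
evidence accumulation to *collective* search performance: rather than
assigning agents a fixed probability of responding to social cues, every
agent continuously accumulates personal and visual social evidence in two
leaky integrators and switches behavioral state when an integrator crosses
its threshold. This vignette describes the model, the choices made where the
design was genuinely open, and what the simulated experiments can and cannot
show.

## The world

The arena is a rectangle (default 500 x 500 px) with reflective walls.
`n_patches` circular resource patches (radius `patch_radius`, default 15 px)
divide a fixed budget of `total_units = 2400` resource units equally, so the
*environment axis* runs from patchy (3 patches of 800 units) to uniform (50
patches of 48 units) at constant total richness. A patch is discovered when
an agent's *centre* enters the patch disk; the agent's body radius plays no
role in patch overlap. An exploiting agent consumes `quality = 0.25` units
per timestep; when fewer units remain than the demand, the remainder is
consumed. A depleted patch disappears and a full copy appears at a uniform
random location not overlapping any survivor, so the number of live patches
and the long-run resource budget are conserved. Patch centres are sampled
fully inside the arena (at least one radius from every wall) to avoid edge
clipping; placement uses rejection sampling with a cap of 10,000 attempts,
after which an environment-too-dense error is raised.

## Perception

Social information is purely visual. The model projects every *currently
exploiting* agent onto a focal agent's 1D retina: a binary field over
relative bearing (default `resolution = 2000` bins covering 2&pi;). A body
of radius $R_A$ at centre distance $d$ subtends a half-angle
$\alpha = \arcsin(R_A/d)$ — the laws of optics, so nearer agents cast wider
projections. Perception range is unlimited. Three rules restrict the field:

* agents exploiting the *same* patch as the focal agent are not targets;
* bins outside the symmetric field-of-view window $[-L, L]$
  (`fov_half_angle`) are dark; $L = 0$ is a blind agent;
* with `occlusion = TRUE`, *any* nearer body (exploiting or not, including
  same-patch co-exploiters) blocks farther exploiting agents along a bin's
  ray; the nearest hit wins.

Internally a bin is set when the ray at its centre angle intersects the
disk. This single rule reproduces the $\arcsin$ interval for $d \ge R_A$
and a half-angle of $\pi/2$ for overlapping bodies, and it makes the
implementation directly comparable to an independent per-bin ray-casting
oracle, which the test suite holds it to bit for bit.

The collision sensor is the same construction with a vision range of 2 px:
a 360-degree binary proximity field (the field of view does not apply)
marking bodies whose surface comes within `prox_range = 2` px of the focal
surface.

## Cognition

Each agent carries two independent leaky integrators, updated by one Euler
step per timestep (dt = 1, matching the px/ts units of the movement rules):

$$u \leftarrow u + \epsilon_u I^{per} - g_u (u - B_u) - S_{wu}\,[w]_+$$
$$w \leftarrow w + \epsilon_w \overline{V^{soc}} - g_w (w - B_w) - S_{uw}\,[u]_+$$

with decay $g_u = g_w = 0.085$, baselines 0, cross-inhibition
$S_{uw} = S_{wu} = 0$ (an independent race) and saturation at 1. The
personal drive is $I^{per} = (N + Q)/2$: a binary novelty component $N$,
active for `novelty_length = 10` steps after the first discovery of a patch
(once per patch lifetime — a regenerated patch is a fresh discovery), plus
the units $Q$ consumed in the current step. The social drive
$\overline{V^{soc}}$ is the mean of the projection field over the **full**
angular domain (bins outside the field of view count as zero), so narrowing
the field of view strictly reduces social input. The gain $\epsilon_w$ is
the *social excitability* — the single parameter varied in the headline
experiments.

States follow threshold logic with strict comparisons at
$T_u = T_w = 0.5$: exploitation whenever $u > T_u$ (priority over
relocation), social relocation when only $w > T_w$, exploration otherwise.
Exactly one state is active for any $(u, w)$.

Two choices here were genuinely open:

* **Saturation semantics.** Freezing the derivative at the ceiling would
  trap a saturated integrator forever, so exploiting agents could never
  disengage after patch depletion. We instead clamp into $[0, u_{max}]$
  with decay always active; a saturated integrator relaxes as soon as input
  stops, which is what lets agents resume exploration.
* **Consumption timing.** Discovery (novelty) precedes the state switch:
  on the discovery step itself $Q = 0$, the novelty alone drives
  $u$ to $0.5$ (not yet above threshold), and exploitation plus consumption
  begin on the following step when $u = 0.9575$ crosses $T_u$. Under
  sustained consumption the unclamped fixed point
  $\epsilon_u \cdot 0.125 / g_u \approx 1.47$ exceeds $u_{max} = 1$, so $u$
  saturates and agents hold the patch until depletion.

## Movement

Motion integrates in the co-moving frame: heading first
($\theta \leftarrow \theta + T_\theta$, wrapped), then speed
($v \leftarrow \max(v + F_v, 0)$), then displacement. Per state:

* **Exploration** — persistent random walk: $F_v = v_{exp} - v$ and a fresh
  uniform turn from $[-0.5, 0.5]$ rad each step.
* **Exploitation** — braking at rate $r_{stop} = 0.175$ while turning toward
  the patch centre at rate $r_{turn} = 0.02$ (angular difference wrapped to
  $(-\pi, \pi]$, so turns take the short way).
* **Social relocation** — $F_v = v_{soc} - v$ and
  $T_\theta = 1.8 \cdot D$, where $D$ is the left-minus-right hemisphere
  mean of the social field: a minimal left/right steering rule.

Walls reflect: positions mirror back inside and the corresponding heading
component flips. With `collisions = TRUE`, an agent whose proximity field is
non-empty *and* whose central 10% window is blocked stops ($F_v = -v$) and
turns toward the hemisphere with lower mean proximity until the window
clears; at exact symmetry it turns left (an arbitrary but deterministic
tie-break). The avoidance turn reuses the relocation cap of 1.8 rad/ts,
which is not numerically pinned down by the behavioral description; it is
exposed in the configuration. This avoidance is deliberately *soft*:
grazing approaches that never block the central window can produce shallow
transient overlaps, particularly near walls — the test suite bounds their
depth and frequency rather than forbidding them.

## The simulation step

All agents perceive the *same* start-of-step snapshot (synchronous update);
the alternative — in-place sequential updates — would make outcomes depend
on agent ids throughout, whereas here id order enters only through one
explicitly sequential rule: when a patch's final units cannot satisfy all
demands, agents consume in ascending id. Each step runs: (1) discovery,
novelty and personal information; (2) visual and proximity fields;
(3) integrator update, state selection, forces, motion, walls, avoidance;
(4) consumption; (5) regeneration of depleted patches; (6) recording.

A single R random stream seeds everything (`set.seed` at run start; the
compiled core draws from the same stream), so a run is bit-reproducible
from `(config, seed)`.

## Metrics and experiments

Per run the engine reports collective search efficiency
$E = \sum_t \sum_i Q_i(t) / (N_A T)$ (units per agent per timestep, at most
`quality`), the mean inter-individual distance $\hat D$ (computed every
step), and $T_{soc}$, the fraction of agent-timesteps in social relocation,
plus per-step ledgers (consumption, remaining units, regenerations, state
counts) that make resource conservation assertable exactly.

`sweep_grid()`/`run_sweep()` run factorial designs over
$\epsilon_w \times N_R \times N_A$ (and the occlusion/collision/field-of-view
toggles), with disjoint per-replicate seeds, per-cell mean and sd, min-max
normalization of $E$ per environment (`normalize_per_environment()`), and
paired contrasts with pooled standard errors (`compare_conditions()`).

**Problem sizes.** The reference experiments behind the model use runs of
$T = 25000$ steps with up to 80 replicates; that scale is supported (it is
only a configuration), but the package's own tests and the bundled
acceptance script work at desk scale: $T = 3000$–$5000$ steps, 5–10
replicates, $N_A \le 50$. At this scale the qualitative findings are stable
across seeds: the optimal $\epsilon_w$ is high ($\ge 1$) in patchy and low
($\le 0.5$) in uniform environments; $\hat D$ decreases monotonically in
$\epsilon_w$; occlusion *raises* the efficiency of large, highly social
groups in uniform environments; collisions depress efficiency on small
patches and occlusion recovers part of it.

## What the synthetic environments do not capture

Everything the generator produces is an idealization: patches are identical
disks of constant quality with no depletion over time beyond consumption,
no diminishing returns and no stochastic yields; agents are homogeneous,
tireless and energetically free; vision is noiseless and infinite-range;
the arena is featureless. Passing tests therefore certify the internal
consistency of the mechanism and the direction of its comparative effects —
not quantitative predictions for any real foraging system. Known further
limitations: the avoidance rule is heuristic (no momentum exchange), the
integrator parameters are shared by all agents, and cross-inhibition,
though wired, is untested at nonzero values.
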