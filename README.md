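# swarmforage

Mechanistic, spatially explicit agent-based simulation of **visual social
information use in collective foraging**.

Groups of disk-shaped agents search a rectangular arena for resource units
concentrated in circular, depletable, regenerating patches. Instead of fixed
switching probabilities, every agent runs a minimal evidence-accumulation
circuit: a personal integrator $u$ pools patch discovery and consumption,
and a social integrator $w$ pools a binary 1D visual projection of other
agents currently exploiting patches (optics-true: a body at distance $d$
subtends a half-angle $\arcsin(R_A/d)$). One Euler step per timestep:

$$u \leftarrow u + \epsilon_u I^{per} - g_u(u - B_u), \qquad
  w \leftarrow w + \epsilon_w\,\overline{V^{soc}} - g_w(w - B_w),$$

clamped into $[0, 1]$. Threshold logic with exploitation priority maps
$(u, w)$ onto three movement states — exploration (persistent random walk),
social relocation (left/right steering toward visible exploiters at
$T_\theta = \theta_{soc}^{max} D$, where $D$ is the left-minus-right
hemisphere mean of the visual field), and exploitation (brake and centre on
the patch). The single parameter $\epsilon_w$ (*social excitability*)
controls how strongly agents respond to social cues. Optional real-world
constraints: visual occlusion (nearer bodies block farther exploiters), a
limited field of view, and proximity-based collision avoidance.

The package is for researchers in collective behavior, behavioral ecology
and swarm robotics who want to study when social information use pays off —
e.g. how the optimal $\epsilon_w$ shifts between patchy and uniform resource
landscapes, and how perceptual/physical constraints reshape it.

## Worked example

```r
library(swarmforage)

cfg <- sim_config(n_agents = 10, n_patches = 3, eps_w = 1, n_steps = 5000)
run <- sim_run(cfg, seed = 1)
run
#> <forage_run>
#>   N_A = 10, N_R = 3, eps_w = 1, T = 5000, seed = 1
#>   E = 0.14352 R/agent/ts, D_hat = 191.6 px, T_soc = 0.0333
#>   consumed = 7175.75 units, regenerations = 8
```

Ten agents in a patchy arena (3 patches of 800 units) collect on average
0.144 resource units per agent per timestep (the ceiling is the patch
quality, 0.25), keep a mean inter-individual distance of ~192 px, and spend
3.3% of their time relocating toward successful others. Sweeping social
excitability across environments:

```r
g <- sweep_grid(eps_w = c(0, 0.25, 0.5, 1, 2, 5), n_patches = c(3, 50),
                n_agents = 10, replicates = 10, n_steps = 5000)
res <- run_sweep(g)
subset(res$summary, n_patches == 3, c(eps_w, E_mean, D_hat_mean))
#>   eps_w E_mean D_hat_mean
#>    0.00 0.1091      231.8
#>    0.25 0.1116      228.8
#>    0.50 0.1334      215.3
#>    1.00 0.1448      190.6
#>    2.00 0.1553      157.6
#>    5.00 0.1501      100.7
```

In the patchy environment efficiency peaks at high excitability
($\epsilon_w = 2$); with 50 poor patches the same sweep peaks at
$\epsilon_w = 0$ — social information helps only where patches are rare and
rich. `normalize_per_environment()` rescales each environment column to
[0, 1] and `compare_conditions()` contrasts paired sweeps (e.g. occlusion on
vs off) with pooled standard errors.

A thin command-line wrapper lives at `inst/cli/forage.R`
(`Rscript inst/cli/forage.R run --n-agents 10 --eps-w 2 ...`).

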