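# rdgep

Coupled reaction–diffusion modelling of mRNA–siRNA dynamics with
cluster-based gene-expression profiling.

## What it is for

Small interfering RNA (siRNA) silences genes by binding messenger RNA
and driving its degradation. `rdgep` is for researchers who want to ask
which *kinetic regime* — which combination of transcription,
self-degradation, coupled degradation, and intercellular mobility —
best explains an observed gene-expression trajectory. It simulates a
two-species reaction–diffusion system over a tissue-like 2D domain,
reduces each simulation to a discrete four-cluster abundance pattern,
and matches observed gene patterns (for example microarray-derived
cluster memberships of non-small-cell lung cancer oncogenes under
non-thermal plasma treatment) against a library of fifteen candidate
kinetic models.

## The model

mRNA concentration $m(x,y,t)$ and siRNA concentration $n(x,y,t)$ evolve
on $\Omega = [0,1]^2$ as

$$
\partial_t m = D_m \Delta m + \alpha_m - \beta_m m - \theta\, m n,
\qquad
\partial_t n = D_n \Delta n + \alpha_{ns} - \beta_{ns} n - \theta\, m n,
$$

with homogeneous Dirichlet or Neumann boundary conditions, Gaussian-
mixture initial states (made boundary-consistent by a multiplicative
window), and $D_m = D_n = 10^{-3}$ by default. The five rate
coefficients may be constants or time/space-dependent functions from a
built-in library; fifteen preset combinations form the model registry.
Simulated total mRNA abundance at $t = 0,1,2,3,4$ is min–max normalised
onto a 0–12 scale, discretised into clusters C1–C4, and matched against
gene patterns by minimal L1 distance (distance 0 = "complete fit").

Numerics: method of lines, 5-point Laplacian, fixed-step classical RK4
(forward Euler available) with an automatic CFL-safe step. See the
vignette in `vignettes/coupled-reaction-diffusion.Rmd` for the
modelling decisions and their rationale.

## Worked example

Simulate registry model 1 under the default reference setup and match
its own pattern, then profile an observed oncogene pattern:

```r
library(rdgep)

g    <- make_grid(dim = 2, n = 51)
w    <- consistency_window(g)
m0   <- apply_window(gaussian_mixture_ic(g, seed = 1), w)
n0   <- apply_window(gaussian_mixture_ic(g, seed = 2), w)
traj <- simulate_pde(get_model(1), state_pair(m0, n0, g),
                     bc_spec("dirichlet"), integrator_config())
traj
#> <rd_trajectory> model 1 on 51x51 grid, dirichlet BC, rk4 (dt = 0.01, 400 steps)
#>  time abundance_m abundance_n
#>     0   0.5652301   0.3238963
#>     1   6.0132359   0.1513459
#>     2   6.8011421   0.3896679
#>     3   5.1437521   1.1596356
#>     4   2.8478255   3.6734849
```

Total mRNA abundance rises from 0.57 to a peak of 6.80 at $t = 2$ as
production outpaces degradation, then falls as the growing siRNA
population (driven by its $e^t$ production term) accelerates coupled
degradation. Discretising and matching:

```r
pat <- cluster_pattern(traj, gene_label = "model_1")
pat
#> <rd_pattern> model_1: NT=1 LE1h=4 LE2h=4 LE4h=3

lib <- pattern_library(seed = 1)   # all 15 models, same seed
match_models(pat, lib)
#> <rd_match> model_1 -> model 1 (complete fit, distance 0)
#>   runner-ups: 2, 5, 7, 8, 9, 14
```

The pattern reads: lowest abundance cluster before treatment, highest
at 1–2 h, third cluster at 4 h. Model 1 recovers itself (distance 0);
the runner-ups include model 7, whose registry definition is identical
to model 1's, and other models whose patterns happen to coincide under
this seed.

Matching an observed oncogene pattern from the packaged reference
table:

```r
rec <- as_pattern_records(table7_patterns())[[27]]  # SMEK1
rec
#> <rd_pattern> SMEK1: NT=4 LE1h=2 LE2h=2 LE4h=2
match_models(rec, lib)
#> <rd_match> SMEK1 -> model 4 (best fit, distance 3)
#>   runner-ups: 10
```

SMEK1 — the one suppressed gene in the reference table — gets a best
(not complete) fit at distance 3 here: with this seed no synthetic
pattern starts in C4, so the match is driven by the three treatment
conditions.

A full run (simulation + profiling + artifact bundle on disk) is one
call: `run_pipeline(run_config(model_id = 1), out_dir = "out")`. A thin
command-line wrapper over the same functions ships at
`system.file("cli", "rdgep", package = "rdgep")` with subcommands
`run`, `profile`, `match`, `models`, and `validate`.

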