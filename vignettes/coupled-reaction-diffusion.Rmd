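---
title: "Modelling coupled mRNA–siRNA dynamics and cluster-based expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled mRNA–siRNA dynamics and cluster-based expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdgep)
```

## The model

`rdgep` simulates the interaction of a messenger RNA population
$m(x, y, t)$ with a small interfering RNA population $n(x, y, t)$ on a
rectangular tissue domain $\Omega = [0, L]^d$ (default the unit square).
Each species is produced at a rate $\alpha$, degrades spontaneously at a
rate $\beta$, and the two co-degrade through the bilinear coupling that
models siRNA-mediated mRNA silencing.  With both species mobile between
cells the governing system is

$$
\frac{\partial m}{\partial t}
  = D_m \Delta m + \alpha_m(t,x,y) - \beta_m(t,x,y)\, m - \theta(t,x,y)\, m n,
\qquad
\frac{\partial n}{\partial t}
  = D_n \Delta n + \alpha_{ns}(t,x,y) - \beta_{ns}(t,x,y)\, n - \theta(t,x,y)\, m n,
$$

with homogeneous Dirichlet (absorbing) or Neumann (zero-flux) boundary
conditions.  Four *mobility modes* drop the diffusion term from one or
both equations (`none`, `ns_only`, `mi_only`, `both`), which recovers
the reaction-only system and the single-mobile-species variants.
Setting the spatial dimension to 1 or 3 uses the same kinetics with the
dimension-generic Laplacian.  A single coupling coefficient $\theta$
multiplies the $mn$ loss in both equations: the model's notation table
lists one coupled-degradation symbol, so we do not introduce separate
coefficients per species.

Key assumptions worth keeping in mind:

* concentrations are treated as continuous, deterministic fields — no
  molecular noise, no delay terms (microRNA-style delayed silencing is
  out of scope);
* rates may depend on time *or* on space, not both (the spatial
  "experimental" tanh rates are stationary, the temporal rates are
  spatially uniform); user-supplied closures may combine both;
* the coupling removes one molecule of each species per silencing
  event, hence the same $\theta mn$ term in both equations.

## The rate library and the fifteen models

The rate library (`rate_spec()`) provides the constant, exponential,
logarithmic, epigenetic, and spatial forms used by the fifteen built-in
models (`get_model()`, `model_registry()`).  Three tabulated forms are
typographically ambiguous, and the package fixes one reading for each —
these are documented choices, not facts inherited from a source:

* the rectified oscillation is read as $e^{t/2}\lvert\sin \pi t\rvert$
  (`exp_sin`).  The alternative reading $e^{t^2}\lvert\sin \pi t\rvert$
  would reach $\sim 10^7$ by $t = 4$ and dwarf every other rate in the
  library; it remains available as `exp_t2_sin` for sensitivity checks;
* the logarithmic form is read as $1 / (\log 5 - \log(1+t))$
  (`log_pole`), with natural logarithms.  It has a pole at $t = 4$ —
  exactly the end of the default horizon — so the registry assigns it a
  default cap equal to its value at $t = 4 - 10^{-2}$ ($\approx 499.5$);
  capped evaluation returns $\mathrm{sign}(v)\min(\lvert v\rvert, c)$.
  `validate_rate()` reports the singularity when asked to scan the rate;
* the epigenetic rate is read as $1 + 1/(2 - 0.1 t)$.  No built-in model
  uses it; it ships for completeness.

In the spatial tanh rates, `xy` is the *product* of the coordinates, so
the transition front runs along the hyperbola $xy = 0.5$.  In 1D the
unused coordinate evaluates to 0.

Five pairs of registry rows are identical
(`model_equivalence_classes()` returns 1/7, 2/9, 4/10, 8/14, 12/15).
The registry reproduces the rows verbatim rather than de-duplicating:
the duplication is part of the reference table, and pattern matching
(below) treats the resulting ties explicitly.

## Space and time discretisation

No discretisation is prescribed by the source model, so the package
makes the standard choices and treats them as tunables:

* **method of lines** on a uniform node-centred grid including the
  boundaries (default $51 \times 51$ over the unit square), with the
  central 5-point (2D) stencil.  Dirichlet conditions pin the boundary
  nodes — their time-derivative is zeroed, so every snapshot satisfies
  the condition exactly; Neumann conditions mirror the first interior
  node into a ghost node, a second-order zero-flux closure that
  conserves the *trapezoidal* total abundance exactly under pure
  diffusion.  (The plain nodal sum is not the conserved functional for
  this closure; the quadrature-weighted sum is.)
* **fixed-step explicit integration.**  `dt = "auto"` resolves to
  $\min(0.9\, h^2/(2 d D_{\max}),\ 10^{-2})$ — the diffusive CFL limit
  with a 10% safety margin, capped by a reaction-resolution step of
  $10^{-2}$.  The default scheme is classical RK4 rather than forward
  Euler: the registry's reaction terms are moderately stiff (production
  rates reach $e^4 \approx 55$ while $\beta_{ns} = 10$ relaxes the
  siRNA field on a 0.1 time scale), and the package's step-halving
  convergence tests show first-order Euler at the capped step changes
  snapshots by far more than the $10^{-3}$ tolerance we hold snapshots
  to, while RK4 at the same step is orders of magnitude inside it at
  four times the cost per step.  Euler remains available
  (`integrator_config(scheme = "euler")`) and refuses steps beyond the
  CFL limit before stepping.
* snapshots are recorded at the steps nearest the requested output
  times (offset at most $dt/2$, and zero for the default step, which
  divides the integer output times); integration aborts with a
  diagnostic if any state magnitude exceeds $10^{12}$ or turns
  non-finite, and warns if any node drops below $-10^{-6}$ (negative
  overshoot signals a too-coarse step — concentrations are not
  clamped).

## Initial states and the consistency window

The initial condition for each species is a mixture of isotropic
Gaussian bumps (`gaussian_mixture_ic()`).  The mixture parameters are
package choices: 3 components, standard deviation $0.1 L$, means drawn
uniformly from the central subdomain $[0.2, 0.8]^d$, positive component
amplitudes, and the field rescaled to a maximum of 6 — the midpoint of
the 0–12 profiling scale; since the profiling layer min–max normalises
the abundance series, the absolute amplitude does not affect cluster
patterns.  The siRNA field uses its own seed (default `seed_m + 1`):
nothing in the source setup ties the two initial states together.

A Gaussian mixture does not vanish on the boundary, which is
inconsistent with homogeneous Dirichlet data.  The package resolves
this with a *consistency window* (`consistency_window()`): a tunable
per-axis profile on $z \in [0,1]$,

$$
w(z) = \frac{(1 - b^{-z})(1 - b^{-(1-z)})}{(1 - b^{-1/2})^2},
\qquad b = 1.01,
$$

combined **multiplicatively** across axes.  Two remarks on why this
exact form: the window expression as originally tabulated diverges at the boundary
instead of vanishing, contradicting its stated purpose, so the package
keeps its building blocks ($b^{\pm z}$ terms with the 1% base) but
arranges them to be exactly 0 at both ends, maximal (normalised to 1)
at the centre, symmetric, and strictly increasing toward the centre;
and an additive cross-axis combination only vanishes at corners, while
the multiplicative product vanishes on the whole boundary, which is
what consistency with Dirichlet data requires.  The window multiplies
the initial state (`apply_window()`); for extra safety `simulate_pde()`
additionally pins boundary nodes under Dirichlet conditions, so an
unwindowed initial state is truncated rather than rejected.

## Profiling: abundance, clusters, matching

The profiling layer turns a trajectory into the discrete object used
for model matching:

1. **total abundance** — the trapezoidal domain integral of the mRNA
   field at each snapshot time (`total_abundance()`).  We read the
   clustered quantity as this integral rather than a pointwise summary;
   that reading is flagged here because the source description admits
   either.
2. **normalisation** — the abundance series is mapped affinely so its
   minimum is 0 and its maximum 12 (`normalize_series(mode =
   "minmax12")`).  How raw abundance maps onto the reference 0–12 scale
   is not stated anywhere; min–max over the trajectory's own snapshot
   times is the weakest assumption that lands every trajectory on the
   scale.  An `identity` mode passes pre-scaled series through, and a
   constant series is a degenerate-input error rather than a silent
   division by zero.
3. **cluster assignment** — the reference scale partitions $[0, 12]$
   into four intervals with small gaps between them (C1 up to 2.265458,
   C2 from 2.267602, and so on).  `assign_cluster()` makes the
   assignment total by cutting each gap at its midpoint, with the
   midpoint itself belonging to the upper cluster; assignment is
   monotone, idempotent, and clamps values marginally outside the scale
   (warning beyond $10^{-6}$).
4. **condition mapping** — observed patterns have four conditions
   (non-treatment, then 1 h, 2 h, 4 h post long-exposure treatment)
   against five snapshot times; the default map is NT→$t=0$,
   LE1h→$t=1$, LE2h→$t=2$, LE4h→$t=4$, leaving $t = 3$ unused.  The
   map is configurable.
5. **matching** — the distance between two patterns is the L1 sum of
   absolute cluster-index differences over conditions
   (`match_models()`).  Distance 0 is a *complete* fit, any positive
   minimum a *best* fit; ties break to the lowest model id, and models
   within distance $+1$ of the winner are reported as runner-ups.  The
   best/complete distinction is given without a distance; L1 on ordinal cluster indices is the simplest choice that
   reproduces that distinction.

Because duplicated registry rows (and, under some seeds, dynamically
distinct models) can produce identical patterns, "recovering" a model
from its own simulated pattern is only defined up to pattern identity:
the matcher returns the smallest id among pattern-identical models and
lists the rest as runner-ups.  The test suite asserts exactly this.

## What the synthetic generator does and does not emulate

The Gaussian-mixture generator and the forward simulator reproduce the
*structure* of the reference experiments: heterogeneous initial
expression, smoothing and redistribution by diffusion, and
abundance trajectories whose discretised patterns distinguish the
kinetic models.  They do **not** emulate microarray measurement:
probe-level noise, background correction, or the fusion clustering that
produced the reference gene patterns.  The packaged oncogene table
(`table7_patterns()`) is therefore reference data for qualitative
comparison — matching those 31 patterns against a synthetic library
exercises the pipeline end-to-end, but reproducing the reference
gene-to-model assignments exactly would require the original microarray
normalisation, which is out of scope.  Passing tests demonstrate
numerical correctness of the solver and the discrete profiling
contracts, not biological validity of any particular model fit.

## Problem sizes and numerical tolerances used in validation

The test suite validates on sizes chosen to make each property sharp
but quick: the analytic eigenmode decay on a $101 \times 101$ grid
(trapezoid and stencil errors $O(h^2)$ keep the decay ratio within 1%
of $e^{-2\pi^2 D t}$), conservation and model recovery at the default
$51 \times 51$, and nodewise agreement with the fine-step RK4 reference
(`reference_ode()`, $dt = 10^{-4}$) on a $7 \times 7$ grid, where the
immobile-species solver matches the reference to better than $10^{-6}$.
An independent adaptive integrator (deSolve's LSODA at
$10^{-10}$ relative tolerance) cross-checks the well-mixed kinetics in
the test suite, so the package's fixed-step integrators are validated
against code they share nothing with.

## Known limitations

* Explicit stepping only: strongly stiff user-defined rates would need
  an implicit scheme, which the package deliberately does not provide.
* Homogeneous boundary data only (a constant Dirichlet value is
  accepted; inhomogeneous Neumann flux is not).
* Uniform tensor grids on rectangles; no adaptive or curved meshes.
* The delay-type microRNA interaction mentioned alongside the siRNA
  model comes with no explicit equations and is excluded.
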