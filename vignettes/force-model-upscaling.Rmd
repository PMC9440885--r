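---
title: "Upscaling cellular traction forces: smoothed particles versus cell densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upscaling cellular traction forces: smoothed particles versus cell densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(woundfem)
library(ggplot2)
```

## The problem

During dermal wound healing, fibroblasts and myofibroblasts pull on the
extracellular matrix (ECM) and contract the wound. Two force descriptions
are in use at different scales:

* **Smoothed-particle (SP) model** — agent-based. Each cell at position
  $s_i$ contributes a regularised point-force *dipole*: the spatial
  derivative (gradient) of a Gaussian mollifier
  $\delta_\varepsilon$ of width $\varepsilon$. The body force is
  $f = P \sum_{i=1}^{N_s} \delta_\varepsilon'(x - s_i)$ in 1D, and
  $P \sum_i \nabla \delta_\varepsilon(\mathbf x - \mathbf s_i)$ in 2D.
  A dipole is self-equilibrated (zero net force) and models a cell pulling
  its surroundings inward.
* **Cell-density model** — continuum. The cells are summarised by a
  density field $n_c$, and the body force is $P \, \mathrm d n_c/\mathrm d x$
  (1D) or $P\, \nabla \cdot (n_c \mathbf I)$ (2D).

The ECM is linearly elastic: in 1D the balance of momentum with $E = 1$
reduces to the Poisson problem $-u'' = f$ on $(0, L)$ with $u(0)=u(L)=0$;
in 2D it is the static Navier–Cauchy equation with the plane-strain
isotropic Hooke law
$\sigma = \tfrac{E}{1+\nu}\!\left[\epsilon +
\mathrm{tr}(\epsilon)\tfrac{\nu}{1-2\nu} I\right]$ and zero displacement on
the outer boundary.

The package implements both force models with P1 (piecewise-linear) finite
elements, the closed-form 1D solutions, the upscaling algorithms that
convert between cell positions and piecewise-constant densities, and the
diagnostics that quantify when and how fast the two models agree.

## Closed forms in 1D

For $N_s$ cells equispaced in a wound region $(a, b) \subset (0, L)$ with
spacing $\Delta s = (b-a)/N_s$, the dipole sum has an exact solution as a
superposition of error functions (`sp_solution_1d()`). Its
$\Delta s \to 0$ limit coincides with the Green's-function solution of the
density model with the uniform density $n_c = N_s/(b-a)$,
$$u_2(x) = \bar n\, P\,[G(x, a) - G(x, b)], \qquad
G(x, x') = (1 - x'/L)\,x - \max(x - x', 0),$$
a continuous piecewise-linear tent (`continuum_solution_1d()`,
`limit_solution_1d()`). The package's property tests verify the monotone
convergence of the dipole sum to this limit over six halvings of
$\Delta s$.

```{r dipole-limit, fig.height = 3}
xs <- seq(0, 7, by = 0.01)
df <- do.call(rbind, lapply(c(8, 32, 128), function(n) {
  cells <- uniform_cells_1d(2, 5, n, P = 0.01)
  data.frame(x = xs, n = factor(n),
             u = sp_solution_1d(xs, cells, 7, attr(cells, "ds"),
                                mode = "analytic"))
}))
ggplot(df, aes(xs, u, colour = n)) +
  geom_line() +
  geom_line(data = data.frame(xs, u = continuum_solution_1d(xs, 0.01, 2, 5, 7)),
            aes(colour = NULL), linetype = 2) +
  labs(x = "x", y = "u(x)", colour = expression(N[s])) +
  theme_minimal()
```

## Discretisation and load assembly

Both 1D problems are discretised with P1 elements on a uniform mesh of
size $h$. The loads are assembled in integrated-by-parts form, i.e. the
mollifier (not its derivative) is integrated against the piecewise-constant
derivatives of the hat functions. Because Gaussian interval masses are
error functions, the 1D SP load is **exact** — no quadrature error — and
the classical nodal-exactness property of 1D P1 elements then makes the
discrete SP solution coincide with the erf closed form at every node to
machine precision. The density load is exact as well (piecewise-constant
density against piecewise-constant test derivatives).

In 2D the same assembly needs Gaussian masses of triangles, which have no
closed form; they are computed by a symmetric degree-5 quadrature rule with
adaptive triangle subdivision to an absolute tolerance of $10^{-10}$
(rectangles are separable and exact). Triangles farther than
$8\varepsilon$ from a cell are skipped; the neglected mass is below
$10^{-13}$.

The sign convention deserves a note: integrating either force by parts
gives the same form $-P\int(\,\cdot\,)\,\phi'$ for both models, so both
load routines carry the minus sign. Only with that sign does the discrete
density solution reproduce the Green's-function solution — a check the
test suite performs against independent adaptive quadrature of the
non-integrated forcing.

## Upscaling algorithms

* **Positions → density** (`density_from_positions_1d()`,
  `density_from_positions_2d()`): count the cells in each element and
  divide by its measure. A cell exactly on an interior node contributes
  half a unit to each neighbour; in 2D a cell on a shared edge contributes
  one half to each triangle and a cell on a vertex contributes the incident
  angle over $2\pi$. Under these conventions the total assigned weight is
  exactly the number of cells, on any mesh.
* **Density → positions** (`positions_from_density_1d()`,
  `positions_from_density_2d()`): tile the domain with bins of length `d`
  (squares of side `cell_side` in 2D), set the bin count to the integral of
  the density over the bin rounded half away from zero, and place that many
  cells — equispaced by default in 1D (so benchmark tables are reproducible
  bit for bit), uniformly at random under a seed otherwise.

`density_from_positions_1d()` also offers `node_rule = "drop"`, in which a
node-coincident cell contributes nothing. This mimics counting codes that
bin with strict inequalities and lose cells that sit exactly on element
boundaries. It matters for the standard benchmark below, where the cell
spacing (0.06) and the mesh size (0.07) conspire to put every seventh cell
exactly on a node.

## The 1D benchmark and a counting subtlety

The standard configuration is $L = 7$, wound $(2, 5)$, $N_s = 50$ uniform
cells, $P = 0.01$, $h = 0.07$ and $\varepsilon = h/3$. The SP solution
agrees with its closed form at quadrature-noise level, and its reduction
ratio of the wound matches the analytic continuum value
$100\,(u_2(a) - u_2(b))/(b-a) = 9.52\%$ closely.

For the density route this benchmark is degenerate in an instructive way:
8 of the 50 cells sit exactly on mesh nodes. With the half-weight rule the
counted density keeps all 50 cells and the discrete solution tracks the
continuum tent to an RMS of about $1.4 \times 10^{-3}$; with the drop rule
the density loses those 8 cells (16% of the force), the solution amplitude
drops accordingly, and the RMS against the continuum solution rises to
about $1.2 \times 10^{-2}$ while the reduction ratio falls to 8.0%.
Tabulated reference values for this benchmark are consistent with the *drop*
behaviour for the RMS and reduction rows and with the *half* behaviour for
the norm rows, so the package exposes the rule as configuration
(default `"half"`, the convention under which cell weight is conserved)
and the acceptance script reports the drop-rule RMS for the tabulated
benchmark. The per-level $L^2$ norms of both discrete solutions converge
from below to the interpolant norm of the continuum tent, $0.21822$.

```{r bench}
res <- run_case(case_config(dim = 1))
glance(res)[, c("sp_l2", "density_l2", "sp_reduction_percent",
                "density_reduction_percent", "gap_sup")]
```

## Consistency between the models

If the density is built from the same cells by counting, the SP and
density loads differ only through the difference between per-element
Gaussian masses and per-element counts, which vanishes as
$\varepsilon \to 0$. The package measures this *consistency gap*
(`consistency_gap()`: $L^2$, sup and $H^1$ norms of the difference field)
and the tests verify its monotone decay over
$\varepsilon \in \{h/3, h/6, h/12\}$ in 1D and on a $40\times40$ structured
mesh of $(-10,10)^2$ in 2D.

## Convergence-rate conventions

`convergence_rate()` implements the standard estimate
$\log_2(\|u^h - u^{h/2}\| / \|u^{h/2} - u^{h/4}\|)$ from three nested
solutions interpolated to the finest mesh. For pipelines in which
$\varepsilon$ is rescaled with $h$ at every level this quantity is **not**
a mesh-convergence rate: the continuous problem changes with the level and
its $\varepsilon \to 0$ limit is discontinuous at every cell, so the
differences of solutions need not shrink. For such sweeps
`converge_sweep()` additionally reports `rate_norms`,
$\log_2$ of the ratio of successive increments of the per-level norms,
which is the convention under which the 1D SP benchmark shows a rate of
about 1.6 (between first and second order). Both numbers are reported;
neither is asserted as a reproduction of published rate values, which are
not mutually consistent with the published per-level norms.

## The 2D configuration

The 2D benchmark uses $\Omega = (-10, 10)^2$, wound
$\Omega_w = (-5, 5)^2$, $E = 1$, $\nu = 0.49$, $P = 10$ and 196 cells
placed uniformly at random in the wound with a minimum separation of 0.2
(the non-overlap radius is not standardised; 0.2 is recorded in the
output). Structured meshes with a fixed lower-left-to-upper-right diagonal
are used throughout (the alternative diagonal is available for sensitivity
checks); such meshes are invariant under a half-turn but not under a single
mirror, so equivariance tests use the half-turn.

Two caveats are documented deliberately:

* $\nu = 0.49$ with plain P1 displacement elements is prone to volumetric
  locking; the combination is retained because it is the standard
  parameterisation for this problem, and all cross-checks (patch test,
  energy identities, dipole virtual work) hold exactly.
* With these parameters the computed contraction is strong (wound-area
  reductions above 50%, nominal strains well outside the small-strain
  regime). Linear elasticity is retained by construction; the absolute
  percentages should be read as model output, not physiology.

Mesh resolution plays two opposing roles. The mollified SP forces need a
fine mesh (the tests use $40\times40$, $\varepsilon = h/3$) to resolve the
ring-like structure around each cell; at that resolution the deformed
wound edges bow inward — pointwise for the SP model, in the mean over the
four edges for the density model, whose raw counted density fluctuates
element by element. The *comparison* of the two models' reduction ratios,
by contrast, is meaningful where a piecewise-constant density is
statistically sensible, i.e. when triangles hold at least a couple of
cells on average. With 196 cells in a $10\times10$ wound this gives
element areas of about 1 ($14\times14$ squares on the outer domain); there
the two models' wound-area reductions agree within about one percentage
point across seeds, while on the $40\times40$ mesh the counted density is
atomised (one cell per ~8 triangles) and the models can differ by ten
points. The acceptance tests encode exactly this split.

```{r twod, eval = FALSE}
res2 <- run_case(case_config(dim = 2, cells = list(source = "random", n = 196),
                             nx = 14, ny = 14, seed = 1))
glance(res2)
autoplot(res2, model = "sp")
```

## What the synthetic configurations do and do not show

All inputs are generated in code: equispaced or seeded-random cells,
analytic densities (`40|sin 2x|`, narrow and standard Gaussians), and the
parameter sets above. They exercise the numerics — assembly, upscaling,
convergence, consistency — under exactly the published study conditions.
They do not model cell migration, proliferation or death, time-dependent
contraction, viscoelasticity or morphoelasticity, spatially varying
stiffness, or realistic wound geometries; passing tests therefore
establish the correctness and internal consistency of the two force
models, not predictive accuracy for real wounds.

## Numerical choices (summary)

* $\varepsilon = h/3$ by default (`eps_factor = 3`): the largest width for
  which per-element Gaussian masses are still close to indicator counts.
* Dirichlet conditions by row/column elimination: boundary values are
  exact zeros.
* Norms by exact element-wise integration of the P1 interpolant; no
  quadrature error in any reported norm.
* Triangle Gaussian masses: adaptive subdivision, absolute tolerance
  $10^{-10}$, far-field cutoff at $8\varepsilon$.
* Bin counts round half away from zero; in-bin placement deterministic
  equispaced by default.
* Cells exactly on the outer boundary are rejected (forces must be
  interior, matching the Dirichlet assumption).
* One master seed per case; all randomness (cell placement) derives from
  it, so a fixed configuration and seed reproduce byte-identical reports.

## Problem sizes

The test suite and the acceptance script run 1D problems with 100–400
elements and 2D problems on $14\times14$ to $40\times40$ structured grids
(up to ~3,200 triangles, ~3,400 constrained degrees of freedom) with 196
cells, three mollifier widths and three seeds — sizes chosen so the full
suite completes in well under a minute while every property is exercised
at the published parameter values.
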