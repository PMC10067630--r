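---
title: "The killisim model: self-propelled cells confined to a spherical shell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The killisim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killisim)
```

## The biological setting

Early annual-killifish embryogenesis separates epiboly from embryo
formation: undifferentiated embryonic cells first disperse at low density
over the egg surface, migrating in the thin gap between the enveloping
layer (EVL) and the yolk syncytial layer (YSL), and only later congregate
at one pole into a single aggregate that becomes the embryo proper.
`killisim` implements an agent-based biophysical model of this process:
what combinations of motility, adhesion, contact inhibition of locomotion
(CIL) and external guidance keep cells dispersed, and which drive them
into one aggregate?

## The model

Cells are identical spheres of radius $R$ (the length unit) whose centers
live near a spherical shell of radius $R_E$. Each cell $i$ carries a unit
polarity vector $\hat p_i$ constrained to the local tangent plane of the
shell; a constant motile force $F_m \hat p_i$ drives it forward. The
dynamics are overdamped: the substrate drag $\gamma_s \dot x_i$ balances
the motile force plus all contact forces,

$$\gamma_s \dot x_i = F_m \hat p_i + \sum_j F^{cc}_{ij}\, \hat n_{ij} + F^{conf}_i,$$

with $\hat n_{ij} = (x_i - x_j)/d_{ij}$ the contact normal.

**Pairwise force.** Cells in contact ($d_{ij} < 2R$) interact through a
linear overlap law parameterised by the cell–substrate adhesion energy
$W_s$ and the cell–cell adhesion energy $W_c$:

$$F^{cc}_{ij} = 2R\left[W_s - \frac{W_s + W_c}{R}\,(d_{ij} - R)\right],
\qquad d_{ij} < 2R,$$

and zero beyond. The force is repulsive below the zero crossing
$d^\ast = R\,(1 + W_s/(W_s+W_c))$, adhesive between $d^\ast$ and $2R$, and
there is no inner cut-off: overlaps deep below $R$ meet a finite (bounded)
repulsion, which is what lets aggregates become multilayered under
pressure. Because only the ratio of the energies matters, $W_s = 1$
throughout and $W_c$ is the dial.

**Confinement.** The EVL and YSL are modelled as two virtual spherical
cells of radius $R_E$ centred at the origin. The YSL branch pushes a cell
outward whenever $\lVert x_i\rVert - R_E < R$ and the EVL branch pushes it
inward whenever $R_E - \lVert x_i\rVert < R$, each with the same linear
law evaluated against the giant sphere. Taken literally, the two
activation conditions overlap in the band
$\lvert\,\lVert x\rVert - R_E\rvert < R$ and extend beyond it on either
side, which yields a globally restoring radial field: in the band the net
force is $4\,(W_s + W_c)\,(R_E - \lVert x\rVert)$, zero exactly on the
shell. We keep both branches exactly as printed; the field is then
restoring everywhere, and after a short burn-in every cell satisfies
$\lvert\,\lVert x_i\rVert - R_E \rvert < R$.

**Polarity dynamics.** The polarity angle relaxes toward guidance
directions and diffuses:

$$\dot\theta_i = -f_{cil}\,\alpha_{cil}
               \;-\; f_{tax}\,\alpha_{tax}
               \;+\; \sqrt{2 D_r}\,\xi(t),$$

where $\alpha_{cil}$ is the signed tangent-plane angle from the CIL target
direction to $\hat p_i$, and likewise for taxis. The CIL target points
*away* from the mean position of the cell's contacting neighbours
(projected to the tangent plane); the taxis target points toward a fixed
organizing center $x_{org}$ on the shell, at a rate independent of the
distance to it. CIL strength is summarised by the dimensionless
$\Psi = f_{cil} / (2 D_r)$, with $D_r = 1$ the time-scale convention.

Two formulation details are deliberate design choices. First, angles are
*signed*: a relaxation written with an unsigned arc-cosine cannot encode
which way to turn, so we implement the standard signed-angle relaxation,
which reduces to the same magnitude and realises the intended behaviour
(turn away from contacts, turn toward the organizer). Second, polarity is
stored as a 3-D unit vector kept in the local tangent plane rather than as
an angle in a per-cell chart: all angular updates are rotations about the
local outward normal, and after each position update the vector is
re-projected onto the new tangent plane and renormalised (projection
transport). This is chart-free and has no pole singularities; no transport
rule for a scalar angle chart needs to be invented.

## Numerical scheme

Positions advance by implicit Euler with step $\Delta t = 0.1$:
$x(t+\Delta t)$ solves
$x(t+\Delta t) = x(t) + \tfrac{\Delta t}{\gamma_s}\,[F_m \hat p +
F(x(t+\Delta t))]$. Within one step the contact *set* and every force-law
*branch* are frozen at time $t$ (per-step motion is well below $R$, so
branch changes are rare events of the step size's order). With frozen
branches the step force field is the exact gradient of a piecewise
quadratic potential $U$, so the implicit relation is the stationarity
condition of the proximal objective

$$\Phi(y) = \tfrac12\,\lVert y - x(t)\rVert^2
          + \tfrac{\Delta t}{\gamma_s}\,U(y),$$

which the core minimises with L-BFGS (memory 8, Armijo backtracking).
This choice is deliberate: in taxis-compressed aggregates contact degrees
exceed 20 and the naive fixed-point (Picard) map has spectral radius far
above 1, where no amount of damping converges, while descent on $\Phi$ is
unconditionally stable and selects the stable implicit solution. The run
loop warm-starts each solve from the previous step's displacement.

Numerical tolerances: the solver accepts when the implicit residual (the
gradient of $\Phi$, measured as the largest per-cell norm) falls below
`fp_tol`, default $10^{-5} R$. $\Phi$ is an extensive sum of hundreds of
$O(1)$ terms, so its double-precision floor limits the reachable residual
to roughly $\sqrt{\varepsilon\,\lvert\Phi\rvert}$; a stalled line search
with residual below $10^{-4} R$ (still three orders below the per-step
motion) is therefore accepted as convergence to machine precision. If the
solver fails outright, the step falls back to 20 explicit Euler sub-steps
on the frozen contact set, the event is counted, and a run aborts if more
than 1% of steps need the fallback. In the regimes exercised by the tests
the fallback count is zero.

Polarity angles advance by Euler–Maruyama: one rotation by
$-\Delta t\,f_{cil}\,\alpha_{cil} - \Delta t\,f_{tax}\,\alpha_{tax} +
\sqrt{2 D_r \Delta t}\, z$ with $z \sim \mathcal N(0,1)$, so the free
angular displacement has variance $2 D_r t$ (verified by a statistical
test). Exactly one Gaussian draw is consumed per cell per step regardless
of guidance, so the random stream is configuration-independent and
trajectories are bit-reproducible given a seed. The update order within a
step is: contact detection at time $t$ → polarity update (using time-$t$
positions) → position update → re-projection of polarities.

Degenerate cases: a vanishing tangential component of a guidance vector
(cell at the organizer or its antipode, or neighbour centroid along the
normal) simply drops that term for the step; a polarity that degenerates
under projection is re-seeded along an arbitrary tangent; coincident cell
centers are an error, prevented by the initial minimum separation.

## What the generator produces

Initial conditions are the model's own: `init_state()` places `n_cells`
uniformly at random on the shell (rejecting any placement closer than
$0.5R$ to an existing cell, so the contact singularity cannot occur) and
draws independent uniformly random tangential unit polarities. The
reference conditions are those of the study system: $\Phi = 0.2$
(500 cells, $R_E = 25$), the in-vivo-like density, and $\Phi = 0.56$
(500 cells, $R_E = 15$) as the dense contrast, with $\Delta t = 0.1$ and a
horizon of 500 dimensionless time units. Figure-style captions count
"time steps", but a frame labelled time 72.5 is not an integer step count,
so we read those numbers as dimensionless *time*; `t_end = 500` therefore
means 5000 integration steps (`max_steps` caps steps directly if wanted).

This generator emulates the post-epiboly dispersed state: uniformly
scattered, independently oriented motile cells. It does not emulate cell
division or death, cell-size variability, EVL/YSL deformation, gradual
developmental changes in adhesion, or any spatial pre-pattern; passing
tests demonstrate the model's internal consistency and its agreement with
the published simulation behaviour, not fidelity to real embryos.

## Parameters at a glance

| parameter | meaning | default | units |
|---|---|---|---|
| `R` | cell radius | 1 | length unit |
| `RE` | shell radius | — | lengths of `R` |
| `Ws` | cell–substrate adhesion energy | 1 | energy unit |
| `Wc` | cell–cell adhesion energy | 0 | relative to `Ws` |
| `psi` | CIL strength $f_{cil}/(2D_r)$ | 0 | dimensionless |
| `Dr` | rotational diffusion rate | 1 | 1/time |
| `Fm` | motile force | 1 | force unit |
| `gamma_s` | substrate viscosity | 1 | force·time/length |
| `ftax` | taxis repolarization rate | 0 | 1/time |
| `x_org` | organizing center | north pole when `ftax > 0` | on the shell |
| `dt` | time step | 0.1 | time |
| `t_end` | horizon | 500 | time |
| `record_every` | frame interval | 0.5 | time |

`Fm` and `gamma_s` are never given explicitly by the source model; both
default to 1 in its dimensionless unit system and are exposed in the
configuration. The organizing center's position is arbitrary by symmetry;
the north pole is the configurable default.

## Quantification

A *cluster* is a connected component of the contact graph with edges at
$d < 2R$ — the same criterion used for CIL neighbours (strict at $2R$,
matching the force cutoff). The headline statistic is the maximum cluster
size per frame; ensembles are summarised by pointwise means and standard
deviations over replicates (50 by convention for time curves, 25 for
phase-diagram grids), and late-time plateaus by the mean over the final
20% of recorded frames — a simple, monotone-robust estimator adequate for
factor-level comparisons.

One known sensitivity deserves emphasis: with $W_c = 0$ the pair force
vanishes continuously at $d = 2R$, so a taxis-compressed crowd of
non-adhesive cells equilibrates with nearest-neighbour spacings just
below the contact threshold. There the $d < 2R$ graph sits at its own
percolation edge and the maximum cluster size responds sharply to the
capture radius; implementations that resolve overlaps by hard constraints
(keeping $d \ge 2R$) will report much smaller clusters for the same
physical configuration. Comparisons of absolute cluster sizes in that
regime should be read with this in mind.

## Problem sizes used by the test suite

The package's tests run the full reference conditions (500 cells,
$R_E = 25$, horizon 500) for the taxis experiments, with 5 replicates for
the full-aggregation ensemble and 10 for the plateau ensembles. The
cell-autonomous checks use reduced sizes chosen to keep the suite quick
while leaving the phenomena unambiguous: 200 cells for the
dispersed-state and adhesion-monotonicity checks (20 and 10 replicates),
and a horizon of 100 time units for the monotonicity scan, by which time
the ranking of final cluster sizes across $W_c \in \{0, 0.5, 1\}$ at
$\Phi = 0.56$ is already far outside replicate noise.

## Known limitations

- Cells are identical, non-deformable, and conserved: no division, death,
  differentiation, or size variation.
- Exactly one organizing center; taxis rate is distance-independent, and
  it keeps acting on cells inside an aggregate (no exemption is modelled).
- Only the sphere is supported as a substrate; the confinement layers are
  rigid.
- The two supplementary taxis variants (directional-speed adjustment along
  the gradient, slowing at the source) are not implemented; the polarity
  step's guidance interface is the extension point where they would plug
  in.
- Absolute maximum-cluster sizes for non-adhesive crowded states carry the
  capture-radius sensitivity discussed above.

## A worked example

```{r example, eval = FALSE}
library(killisim)

cfg <- sim_config(
  n_cells = 500, RE = 25,      # packing density 0.2
  Wc = 1, psi = 0,             # adhesive, no CIL
  ftax = 1,                    # strong taxis toward the north pole
  stop_on_single_cluster = TRUE,
  seed = 1
)
traj <- simulate_cells(cfg)
glance(traj)

cs <- cluster_timeseries(traj)
autoplot(cs)                    # aggregation kinetics, log-log
plot_shell_snapshot(traj)       # final configuration on the shell
```
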