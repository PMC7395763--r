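---
title: "Simulating 3D scaffold cell cultures: model, numerics and calibration"
author: "scaffoldsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating 3D scaffold cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldsim)
```

## The model

`scaffoldsim` implements a hybrid discrete/continuous cellular automaton for
cell populations cultured in three-dimensional polymeric scaffolds. The
scaffold is a cubic lattice of voxels (default: a 1 cm cube at 10 voxels per
edge, i.e. 1 mm resolution). Each voxel holds at most one *virtual cell* --
an integer identifier in the occupancy grid -- and three continuous
quantities: glucose concentration (g/L), dissolved oxygen concentration
(g/L) and the local compressive Young's modulus of the extracellular matrix
(kPa).

Because a wet-lab experiment seeds millions of biological cells while the
lattice holds at most `n_layers`^3 virtual cells, populations are scaled by
occupancy: the fraction of scaffold volume occupied in vitro
(`n_vitro * cell_volume / scaffold_volume`, with the average eukaryotic cell
volume 4.2e-6 mm^3) is multiplied by the lattice capacity to give the
virtual population, and the *aggregation ratio* `n_vitro / n_virtual`
(~2.4e5 biological cells per virtual cell at the default 5 M seeding)
scales every per-cell uptake so that total consumption matches the in-vitro
experiment exactly.

Each iteration (default 1 h) executes four phases in a fixed order:

1. **Transport.** Both concentration fields advance by Fick's second law,
   dC/dt = D * Laplacian(C).
2. **Media change**, when due (default every 24 h): the glucose field is
   reset to the fresh-medium concentration at every voxel and the external
   reservoir is refilled. Oxygen is untouched -- gas exchange keeps the
   medium saturated regardless.
3. **Environmental rules.** Every living cell consumes glucose and oxygen
   from its own voxel (quiescent cells consume the fraction `s` of the
   proliferant amounts; concentrations floor at zero), and every
   proliferant cell stiffens its voxel and its entire 6-neighbourhood.
4. **Behavioural rules.** Every cell executes at most one stochastic
   transition -- duplication, migration, state change, death or (for dead
   cells) degradation -- chosen according to context-dependent
   probabilities. Cells are processed in a freshly shuffled random order
   each iteration, so no lattice direction or cell age is systematically
   favoured.

### The rule grammar

Cell behaviour is fully configuration-driven. A rule is one line,

```
id: A -> B [+ C], D
```

where `A` is the source cell type, `B` (and optionally `C`) are products and
`D` is either an arithmetic probability expression or an environment tag
(`environment (Glc)`, `environment (O2)`, `environment (YM)`).
`B + C` with two cell types is duplication; `empty + C` is migration;
a bare `B` different from `A` is a state change; `empty` alone is
degradation of a dead cell. Probability expressions may use the operators
`+ - * /`, parentheses, the functions `min`, `max`, `exp`, numeric
literals, and the context variables

| variable | meaning |
|----------|---------|
| `TIME`   | current iteration / total iterations |
| `TD`     | death iteration / total iterations (0 for living cells) |
| `Glc`    | local glucose / fresh-medium concentration |
| `O2`     | local oxygen / incubator concentration |
| `#T`     | cells of type `T` / lattice capacity |
| `AGE`    | (iteration - birth) / iteration |
| `TLD`    | (iteration - last division) / iteration |
| `YM`     | local stiffness / initial scaffold stiffness |

Expression values are clamped into [0, 1] after evaluation rather than
raising an error, so calibration sweeps over coefficient ranges cannot
crash a batch. If the clamped probabilities of a cell's candidate rules sum
above 1 they are renormalized and a warning is emitted once per run -- this
always indicates a mis-calibrated rule set, but aborting mid-sweep would be
worse. Names from the `[parameters]` section appearing in rule expressions
are substituted with their numeric values when the configuration is loaded,
which keeps every tunable coefficient in one place while the parsed rules
contain only context variables and literals.

Two conventions resolve corner cases the grammar itself leaves open: at
iteration 0 the `AGE`/`TLD` denominators are undefined and both variables
are defined as 0 (a warning is signalled), and the `#T` denominator is the
lattice capacity (`n_layers^3 * capacity_per_site`), the only global
maximum the model defines.

### Default rule set and parameters

The shipped rule set uses these forms (coefficients in `[parameters]`):

* duplication `P -> P + P` with `a * min(Glc, O2)`
* quiescence `P -> Q` with `d * (1 - Glc)`
* reactivation `Q -> P` with `b * Glc`
* death `P|Q -> D` with `c * (1 - Glc) * (1 - min(O2, 1))`
* migration `P -> empty + P` with `e`
* degradation `D -> empty` with `a`
* uptake rules for P and Q (`U` = reference uptakes: glucose
  16.7e-12 g/cell/h, oxygen 2.93e-15 g/cell/h) and a stiffening rule for P.

The two shipped cell-line presets differ only in the published coefficients:
duplication/degradation `a` (MCF7 0.38, MDA-MB-231 0.44), quiescent-to-
proliferant `b` (0.005 vs 0.02), migration `e` (0.008 vs 0.01) and LOX
expression `lox` (3e-6 vs 3e-3, the ~1000-fold differential expression of
lysyl oxidase that drives matrix stiffening in the aggressive line).

The remaining coefficients are not experimentally constrained and were
calibrated once, against population-level anchors, and then frozen:

* `c = 0.1`, `d = 0.15` -- chosen so the simulated density time courses
  reproduce the qualitative course of the two lines (MDA-MB-231 roughly
  constant-rate growth early, returning to ~1.0 of the initial population
  at day 10; MCF7 a brief proliferative phase followed by decline to ~0.5);
* `s = 0.5` -- quiescent cells consume half of the proliferant uptake, a
  standard order of magnitude for metabolically shut-down cells;
* `u_ym = 1050` kPa/h -- the per-virtual-cell remodeling rate, calibrated so
  that 50 replicates of the MDA-MB-231 protocol stiffen the scaffold from
  47 kPa to a grand mean of ~58 kPa at day 10, matching compressive
  testing of collagen scaffolds seeded with this line. The value is per
  *virtual* cell: it absorbs the ~2.4e5-fold aggregation, i.e. ~4.4e-3
  kPa/h per biological cell before the `lox` coefficient.

## Numerical choices

**Transport.** The solver is explicit central-difference (FTCS),
sub-stepped so that lambda = D dt_sub / h^2 <= 1/12. The classical 3D
stability bound is 1/6, but exactly at that bound the stencil's self-weight
1 - 6 lambda vanishes and point-like disturbances excite a parity
(checkerboard) mode; halving the bound keeps the self-weight >= 1/2 and
restores smooth kernels at negligible cost (the default protocol runs ~130
oxygen sub-steps per hour on a 10^3 grid, still well under two seconds per
simulated 10-day run). FTCS is first-order in dt_sub; the test suite checks
convergence under sub-step refinement rather than asserting exact
invariance.

**Boundaries.** Three modes are available per species. Glucose defaults to
`reservoir`: face voxels exchange mass with a finite well-mixed external
medium (default 1 mL) whose concentration is tracked and refilled at media
changes. Oxygen defaults to `dirichlet` at the incubator concentration,
because gas exchange keeps the medium saturated. `zero-flux` (mirrored
ghost voxels) is provided for closed-system analyses and conserves mass to
round-off.

**Diffusivities and concentrations.** Free-diffusion values in water are
used, since the open scaffold pore structure does not measurably hinder
small-molecule transport: glucose 6.7e-10 m^2/s = 2.412 mm^2/h and oxygen
3.0e-9 m^2/s = 10.8 mm^2/h (more than fourfold faster). Fresh medium is
high-glucose DMEM (4.5 g/L); air-saturated medium at 37 C holds 7.2e-3 g/L
oxygen. All four are configuration keys.

**Stiffening at the boundary.** A proliferant cell deposits
`lox * u_ym * dt` kPa over its 7-voxel neighbourhood (self + 6 faces). At
the scaffold surface the neighbourhood is clipped; the shares that would
fall outside are redistributed over the in-bounds voxels so that the cell's
total remodeling effect is conserved. Without this, surface voxels would be
structurally under-stiffened by up to ~45% purely because boundary voxels
have fewer neighbouring lattice sites -- a lattice artifact with no
biological reading.

**Blocked moves.** Duplication or migration drawn when all six
face-neighbours are occupied is a silent no-op: the cell neither dies nor
queues. Dead cells keep occupying their site -- and blocking their
neighbours -- until a degradation rule removes them.

**Determinism.** One seeded RNG stream drives a run; replicate k of a batch
uses seed `(base_seed + 99991 k) mod (2^31 - 1)`. Identical configuration
and seed reproduce a run bit for bit, and the per-cell event log replays
exactly to the recorded per-iteration counts.

## Analysis layer

Cell density is living cells (proliferant + quiescent) normalised to the
initial population. Spatial structure is summarised along the *Manhattan*
distance from the scaffold center -- the cubic lattice is not radially
symmetric, so the L1 metric respects its geometry better than the Euclidean
radius. Voxels are binned at 1 mm (left-closed bins labelled by their left
edge); the engine records per-iteration shell means of every field during
the run, so radial profiles over all 240 iterations cost no extra storage.
In profiles, cell counts are normalised to the summed initial count of the
same bin across replicates (bins that start empty are reported as missing,
not zero) and fields to their initial spatial average.

Stiffness variability is reported from two deliberately different views:
*pooled* (every voxel of every replicate is one observation -- the spread of
the full stiffness distribution, the honest description of an intrinsically
heterogeneous material) and *per-scaffold* (each replicate's mean is one
observation -- what mechanical testing of whole scaffolds measures). Their
ratio quantifies how much intra-scaffold heterogeneity exceeds
between-scaffold variation; under the default MDA-MB-231 protocol it is
about fifteenfold. Confidence intervals are normal-approximation mean +/-
1.96 SE by default (the construction used for reported means elsewhere),
with a percentile bootstrap on request; a Shapiro-Wilk p-value is attached
as a diagnostic because stiffness distributions under active remodeling are
strongly right-skewed, and two-group comparisons therefore use the
Kruskal-Wallis test.

## Sensitivity analysis

Global sensitivity uses uniform ranges of +/- 40% around the reference
values, with the behavioural (`a`..`e`) and environmental (`u_glu`, `u_o2`,
`u_ym`, `s`) groups analysable separately. First-order and total Sobol
indices are estimated with the Monte-Carlo Saltelli design (radial A/B/AB_i
matrices; centred estimators, Jansen form for the totals; percentile
bootstrap intervals) rather than a polynomial-chaos expansion: the
estimands are identical, the estimator is self-contained and its error is
controlled by the base sample size. Model outputs per parameter row average
a small fixed number of replicate seeds (default 3) to tame run-to-run
stochasticity, with seeds derived from the row index for reproducibility.
The suite verifies the estimator against the analytic variance
decompositions of an additive model and of the Ishigami function at base
sample 1024.

## What the simulator reproduces, and what it does not

The default configurations are calibrated to population-level anchors:
density time courses of the two lines, the day-10 stiffening of
MDA-MB-231-seeded scaffolds (47 -> ~58 kPa grand mean) and the ~15-fold
pooled/per-scaffold dispersion ratio. These are emergent: none of them is
assigned anywhere in the code, and the test suite recomputes them from
fresh replicate batches.

A known limitation concerns *radial* structure. With diffusivities at their
water values, the stationary center-to-surface glucose deficit for the
default consumption is of order q L^2 / 6D, roughly 10% of the medium
concentration -- so the simulated microenvironment is only mildly
radius-dependent, and the emergent outer-shell vs core stiffness contrast
is weak (a few percent, with large replicate-to-replicate spread). Deep
core depletion, and the strong radial stratification some 3D-culture
experiments show, would require either an order-of-magnitude lower
effective diffusivity (e.g. dense cell-laden matrices), seeding
heterogeneity, or transport limits not in this model. Related caveats: the
uniform random seeding ignores the edge-biased cell penetration of real
scaffold seeding; virtual cells aggregate ~2.4e5 biological cells, so
uptake is spatially lumpy at the voxel scale; and there is no cell-cell
signalling, ECM degradation, or mechanotransduction feedback from the
stiffness field unless a rule references `YM`.

Problem sizes in the test suite are chosen to keep the full run fast while
leaving the estimators honest: unit tests use 3^3-5^3 lattices over 6-48 h,
the acceptance-level checks use the full 10^3 x 240 h protocol at 50
replicates (the batch the dispersion statistics are defined on) and 30
paired seeds for the cell-line contrast.

## A worked example

```{r example, eval = FALSE}
cfg <- defaultConfig("mdamb231")
res <- runSimulation(cfg, seed = 1)
res

d <- densitySeries(res)
d[d$hour %in% c(0, 24, 72, 168, 240), ]

rs <- runReplicates(cfg, 50, baseSeed = 2026)
stiffnessSummary(rs, "pooled")$mean          # ~58 kPa at day 10
stiffnessSummary(rs, "pooled")$dispersionRatio
```
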