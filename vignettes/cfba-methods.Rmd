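---
title: "Conditional flux balance analysis: model, discretization and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional flux balance analysis: model, discretization and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfba)
```

## The problem cFBA solves

Most constraint-based metabolic models assume an environment that never
changes. Many microbial habitats are instead *cyclic*: day–night light
cycles, feast–famine feeding regimes in bioreactors, alternating
aerobic–anaerobic phases. Conditional flux balance analysis (cFBA) asks:
given a stoichiometric network, enzyme capacities and a repeating
environment, what is the largest factor `mu` by which a cell can multiply
its composition over one full cycle, and what intracellular strategy —
flux schedules, enzyme investment, storage-polymer accumulation —
achieves it?

The species of the network are partitioned:

* **balanced** metabolites are assumed at quasi-steady state (their
  turnover is much faster than the cycle), so their net production is zero
  at every instant;
* **imbalanced** species — enzymes, storage polymers, biomass
  constituents, internal substrate pools — have explicit time-resolved
  amounts `M(t)` (mmol per gram initial dry weight).

Biomass is not a reaction: it is the weighted sum `w'M(t)` of the
imbalanced amounts, with `w` the molecular weights (g/mmol) of the species
flagged as contributing to weight. Two boundary conditions close the
problem:

* normalization, `w' M(t0) = B0` with `B0 = 1` g_DW by default, and
* cyclicity, `M(t_end) = mu * M(t0)` — the cell ends the cycle as a
  scaled copy of itself (balanced growth over cycles).

For a *fixed* `mu` every constraint is linear, so the feasible-`mu`
frontier is found by bisection over linear feasibility programs. This is
the reason the engine never needs a nonlinear solver.

## Discretization

The cycle `[t0, t_end]` is split into `N` intervals (uniform by default;
`time_grid()` accepts explicit nodes). Fluxes `v[r,k]` are piecewise
constant on intervals; amounts `M[i,k]` live on the `N+1` nodes and evolve
by an explicit Euler step,

```
M[i,k+1] = M[i,k] + dt_k * sum_r S[i,r] v[r,k].
```

Explicit Euler with piecewise-constant fluxes is the choice that keeps the
program exactly linear in `(M, v)` for fixed `mu`; higher-order schemes
would couple fluxes across intervals. Refining `N` tightens the
discretization: for the analytic self-replicator below the discrete
optimum is `(1 + kcat*dt)^N`, which converges to the continuous
`exp(kcat*t)` from above as `N` grows.

The full constraint set, with the provenance tags used throughout the
package (`build_lp()` attaches one to every row):

| tag    | constraint                                             |
|--------|--------------------------------------------------------|
| EQ1    | `sum_i w_i M[i,0] = B0` (initial normalization)        |
| EQ2    | `M[i,N] = mu * M[i,0]` per cycle-subject species       |
| QSS    | `sum_r S[m,r] v[r,k] = 0` per balanced metabolite      |
| DYN    | explicit Euler dynamics                                |
| CAP    | `v[r,k] <= kcat_r * M[catalyst(r),k]`                  |
| QUOTA  | `w_i M[i,k] {=,>=,<=} value * sum_j w_j M[j,k]`        |
| BOUND  | environment bounds at the interval start               |
| NONNEG | `M[i,k] >= 0`                                          |

Choices a reader should know about:

* **Capacity anchoring.** The capacity inequality holds at a continuous
  `t` in the underlying model; on the grid the engine anchors it at the
  start of each interval (the permissive reading). `capacity_anchor =
  "both"` in `solve_options()` also enforces it at the interval end, which
  is tighter; the default is `"start"`.
* **Environment bounds** are piecewise-constant segments, half-open
  `[t_start, t_end)`: a flux is attributed the bounds of the segment in
  which its interval starts, and a query at the exact segment end already
  sees the next regime. `bounds_at()` is total on `[t0, t_end)`.
* **Quotas** constrain a species' share of *current* total weight,
  `w_i M_i(t_k)` vs `value * sum_j w_j M_j(t_k)` — a linear constraint —
  with kind `exact`, `min` or `max`, at all nodes or a chosen 0-based
  subset (`t_0 … t_N`).
* **Reversible catalysed reactions** are split into `_fwd`/`_rev`
  irreversible pairs (negated stoichiometry, bounds `[0, |bound|]`, the
  capacity rule duplicated), because a one-sided capacity ceiling cannot
  bound a signed flux. Uncatalysed reversibles are left signed. The
  operation is idempotent and `maximize_mu()` applies it automatically.
* **Storage and lean biomass.** Storage polymers are flagged
  `is_storage`. By default they obey the cyclic constraint like everything
  else; `exempt_storage_from_cycle = TRUE` frees their end-of-cycle
  amounts, decoupling storage from the biomass recipe entirely. Keeping
  the strict-cyclic default makes the baseline reproducible: exemption is
  a modelling decision, not a numerical one. Lean-biomass accounting —
  storage carrying mass that does *not* count toward the biomass vector —
  is expressed per species with `contributes_to_weight`.

## The mu search

`maximize_mu()` brackets and bisects:

1. check `mu_lo` (default 1 — the cell can at least maintain itself); if
   infeasible, scan downward geometrically (mandatory-decay models);
2. double `mu_hi` (default 4) until infeasible, up to
   `max_bracket_doublings` (30) — exhaustion is reported as unbounded
   growth, which in practice means an uncapped synthesis path;
3. bisect to `mu_tol` (default 1e-6) and return the trajectory of the last
   feasible program.

Bisection presumes the feasible `mu` set is an interval. This is not
proved here for arbitrary models; the property suite checks it on
randomized fixtures (interior points between two feasible values stay
feasible), and pathological disconnected sets would be silently truncated
— a documented limitation inherited from the method itself.

## Solving the feasibility programs

No general-purpose LP library is part of this package's dependency
footprint; instead two self-contained backends implement a minimal solver
contract (`register_solver()` lets users plug in their own — status
tokens `optimal` / `infeasible` / `unbounded` / `numerical_error`):

* **quadprog** — minimum-norm feasibility: minimize `||x||^2` subject to
  the constraint rows, via the dual active-set method of Goldfarb and
  Idnani. Equality rows are eliminated first by a QR null-space reduction,
  which both shrinks the problem and avoids a documented fragility of
  active-set methods (degenerate equality sets misreported as
  inconsistent). The minimum-norm point is unique, making trajectories
  deterministic for this backend.
* **simplex** — a dense two-phase primal simplex on the split-variable
  standard form, with row equilibration, Dantzig pricing falling back to
  Bland's rule on degenerate stalls, periodic QR refactorization of the
  basis, a dual-style feasibility repair near the feasibility boundary,
  and final self-certification of the returned point.

The default backend, **auto**, runs quadprog and accepts its feasible
points immediately, but confirms every *infeasible* verdict with the
simplex before believing it. A false infeasible would silently truncate
the bisection — the one failure mode the outer loop cannot detect on its
own — so the two algorithms act as mutual witnesses. Points are accepted
only if they satisfy every constraint row within `feas_tol` (default
1e-9, scaled by the right-hand side); anything else is raised as an
explicit solver error, never returned as a trajectory.

Within about `mu_tol` of the feasibility boundary the programs become
degenerate slivers; both backends map uncertifiable near-boundary points
to "infeasible", which can bias `mu*` low by at most the bisection
resolution. Trajectory uniqueness is *not* promised across backends —
alternative optima are resolved arbitrarily (min-norm for quadprog, a
vertex for simplex); only `mu*` is comparable.

## Fixtures: what the generators emulate

`self_replicator()` is the analytic oracle: one species `E` (w = 1) made
from nothing by a reaction it catalyses itself. Greedy growth is optimal,
so the discrete optimum has the closed form `mu* = prod_k (1 + kcat
dt_k)`, computed independently of the LP machinery by
`self_replicator_mu()`. The engine must reproduce it to `mu_tol` across
grids and kcats.

`minimal_cell_model()` is a four-species feast–famine toy: balanced
`intermediate`; imbalanced `storage`, `enzymes`, `biomass`. Uptake
(substrate → intermediate) and biomass synthesis are both catalysed by
`enzymes` (kcat 2 and 1 h⁻¹); `store`/`mobilize` shuttle intermediate to
and from storage; the feed is open (`ub` 10 mmol g_DW0⁻¹ h⁻¹) only during
`[0, feed_end)`. Only `biomass` contributes to the weight vector — with
all three species weighted, optimization would pour everything into the
self-catalytic enzyme loop and neither biomass nor storage would ever be
made; pinning the weight to biomass is what makes enzyme investment and
storage instruments of the optimum rather than goals. The kcats, unit
weights, unit stoichiometry and the 10 mmol g_DW0⁻¹ h⁻¹ feed ceiling are
fixture parameters chosen once so that the characteristic behaviour
emerges (they are not fitted quantities), and the tests assert only
ordinal claims: enzymes rise early, a capacity saturates within the first
half-cycle, storage accumulates during the feed and is spent after it.
Two presets ship (`feed_end = 2 h` of a 4 h cycle, N = 8; and `feed_end =
10` of a 20-unit cycle, N = 10) because both cycle descriptions are in
circulation for this toy; neither is ground truth.

`random_model()` generates deterministic, always-valid models for
property tests: a catalysed uptake backbone through every balanced
metabolite into a weight-contributing species, plus random extra
reactions (possibly reversible, possibly catalysed), kcats in
[0.1, 10] h⁻¹, weights in [0.01, 1] g/mmol, all bounds containing zero
(so `mu = 1` is always feasible under zero flux) and all upper bounds
finite (so `mu*` is bounded). What these generators do *not* emulate:
genome-scale sparsity patterns, ill-conditioned kcat spreads over many
orders of magnitude, maintenance/decay reactions, or thermodynamic
infeasibilities — passing the suite says the engine is correct on
well-posed small models, not that every genome-scale model is tractable
at default tolerances.

## Numerical choices and edge cases

* `mu_tol = 1e-6`, `feas_tol = 1e-9`; trajectory invariants are asserted
  at `10 * feas_tol` on extraction, so a solver tolerance problem raises
  an error instead of silently returning a bad trajectory.
* Capacity *ratios* in `capacity_report()` divide two solved quantities;
  where the capacity itself is numerically zero the quotient is noise, so
  denominators are floored at `denom_floor` (1e-6) — the ceiling
  constraint itself is enforced in absolute terms by the LP regardless.
  Saturation is flagged at ratio ≥ `1 - epsilon` (default 1e-6).
* Weight rescaling (`w → c w`) is an exact symmetry of the program — `mu*`
  invariant, amounts scaled `1/c` — only when no finite nonzero flux bound
  pins an absolute scale; environment bounds deliberately break it (they
  are per gram initial dry weight).
* The problem sizes exercised by the test-suite and the acceptance script
  — 50-model random batteries on a 3-interval grid, the minimal cell at
  N = 8–10, self-replicators to N = 16, 100-model round-trip batteries —
  were chosen as the smallest sizes at which every claimed property is
  non-trivially exercised.
* Degenerate inputs: `N = 0` grids, non-positive `mu`, unvalidated models
  and catalysed-reversible inputs to `build_lp()` are rejected with
  specific errors; a model with no reactions is feasible exactly at
  `mu = 1`.

## Interchange formats

SBML Level 3 Version 1 carries the core network (species, reactions,
reversibility, stoichiometry); everything SBML core has no vocabulary for
— roles, weights, kcat/catalyst links, quotas, environment segments, the
initial weight and the storage-cycle flag — rides in a dedicated
annotation namespace (`https://cfba-r.invalid/ns/cfba/v1`), with explicit
units attributes. The FBC package was deliberately not used: it has no
notion of time-varying bounds, catalyst amounts or composition quotas.
Balanced species are ordinary SBML species annotated `role="balanced"`
(not `boundaryCondition`): quasi-steady state is an engine concern, not
an SBML semantics concern. Numbers serialize with 17 significant digits,
so `write_sbml()` → `read_sbml()` is bit-exact; `INF`/`-INF` follow SBML
double syntax. Files missing role annotations fail with every offending
species named; foreign annotation namespaces are skipped with a warning.
A CSV form (`write_model_csv()`/`read_model_csv()`, one file per entity)
serves spreadsheet-based model curation.

## Worked example

```{r}
mc <- minimal_cell_model()
traj <- maximize_mu(mc$model, mc$grid)
traj$mu_star
round(traj$amounts, 3)
capacity_report(traj)$saturation_node
storage_dynamics(traj, feed_end = 2)
```

The uptake reaction saturates its enzyme capacity immediately (node 0),
enzymes double per interval until the absolute feed ceiling takes over,
storage fills while substrate is available and is spent afterwards to
keep biomass synthesis running — the feast–famine strategy emerging from
optimization alone, with no scripted behaviour.

## Known limitations

* One catalyst per reaction; isozymes and enzyme complexes are out of
  scope, as are reactions sharing one catalyst pool through a summed
  constraint (the per-reaction form is implemented).
* Feasible-`mu` sets are assumed to be intervals (see above).
* The LP backends are dense and intended for models up to a few hundred
  variables; genome-scale cFBA needs an external sparse solver, which the
  solver contract accommodates but this package does not bundle.
* No flux-variability analysis at `mu*`: the reported trajectory is one
  optimum among possibly many.
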