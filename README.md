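# cellspring

A coarse-grained bead-spring simulator of single-cell mechanics, built to
study how cortical membrane–actin tension gates neurite-like protrusion.
During neuronal differentiation the actomyosin cortex weakens and
finger-like projections emerge; `cellspring` models the mechanical side
of that observation: a 2D cell of 700 beads — a plasma-membrane ring, a
nuclear-envelope ring, and 19 radial actin filaments whose terminal
*head* beads adhere to the membrane — evolved by overdamped Langevin
dynamics while one protrusive filament elongates by bead insertion.

Two parameters carry the biology, both in reduced units (bead diameter
σ = length, kT = energy, drag γ = 1):

* **u3** — the depth (kT) of the truncated-shifted Lennard-Jones well
  between actin-head and membrane beads; cortical tension.
* **κ₀₀** — the spring constant of the membrane–membrane bonds;
  membrane tension.

The rest of the force field is standard for bead-spring membranes:
harmonic stretch, `κ_b (1 − cos(θ − θ₀))` bending, WCA excluded volume
between structures, a quadratic area constraint per ring, and a soft
compression core within each structure. Forces are analytic throughout
and validated against finite differences of an independently coded
energy; a velocity-Verlet constant-energy mode exists purely for that
validation. See `vignettes/cellspring-model.Rmd` for the full model
account.

## A worked example

Build the default 700-bead cell, let the protrusive filament grow for
4 τ at intermediate cortical tension, and measure the contour:

```r
library(cellspring)

cfg <- sim_config(u3 = 10, kappa00 = 10, dt = 1e-4, n_steps = 40000L,
                  save_every = 2500L, grow_interval = 0.07, grow_max = 45L,
                  seed = 1L)
build_cell(cfg)$state
#> <cell_state> 700 beads at t = 0 tau (MEMBRANE:240, NUCLEUS:80, ACTIN:361, ACTIN_HEAD:19)

traj <- run_simulation(cfg)
traj
#> <cell_trajectory> 17 frames over 4 tau; 726 beads in last frame; 26 growth events

m <- measure_trajectory(traj)
tail(m, 3)
#>    frame_time projection_length n_protrusions cell_area circularity
#> 15       3.50              6.18             1       461       0.385
#> 16       3.75              6.00             1       458       0.388
#> 17       4.00              6.04             1       457       0.374
attr(m, "persistence_fraction")
#> [1] 1
```

A stable protrusion about 6 σ long (half a cell radius) has formed and
persists through the final half of the run: `projection_length` is the
radial excursion of the protrusion tip above the median cell-body
radius, and a persistence fraction of 1 means every late frame holds a
protrusion longer than 2 σ. Raising `u3` to 30–50 clamps the membrane
onto the cortex and restricts the same growth schedule to ~3 σ; dropping
it below 1 removes the membrane–tip coupling and the protrusion stays
short and slip-prone. `render_contour(traj$frames[[17]], "cell.svg",
traj$topology)` draws the resulting morphology.

The sweep pipeline packages these comparisons: `preset_adhesion_scan()`
(u3 grid at κ₀₀ = 10) and `preset_tension_contrast()` (u3 = 3 vs 30 at
κ₀₀ = 500), each with five replicate seeds, summarised as mean ± SEM by
`summarize_sweep()`.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/cellspring simulate --config cell.yaml --seed 5 --out run
Rscript inst/cli/cellspring sweep --preset adhesion_scan --out scan
Rscript inst/cli/cellspring measure --traj run.xyz --out metrics.csv
Rscript inst/cli/cellspring plot --traj run.xyz --frame last --out cell.svg
```

Trajectories are extended-XYZ (roles encoded as species M/N/A/H, z = 0),
so standard molecular viewers open them; metrics and sweep tables are
CSV with provenance headers; configs and sweep specs are YAML/JSON.

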