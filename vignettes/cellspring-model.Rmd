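---
title: "The cellspring model: cortical tension as a mechanical barrier to protrusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cellspring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellspring)
```

## The question the model addresses

During neuronal differentiation the actomyosin cortex under the plasma
membrane weakens, and neurite-like protrusions appear. cellspring asks the
corresponding mechanical question in the simplest setting that can answer
it: in a single cell whose membrane adheres to its actin cortex, how does
the strength of that adhesion (cortical tension) gate the ability of a
growing cytoskeletal element to push out a stable, finger-like protrusion?

## The cell

The cell is two-dimensional: a planar cross-section through the cell body,
which is also how simulated morphologies are compared with micrograph
contours. Four bead species make up `r 240 + 80 + 19 * 20` beads under the
default architecture:

* 240 **membrane** beads on a ring of radius 12 sigma,
* 80 **nuclear-envelope** beads on a concentric ring of radius 4 sigma,
* 19 radial **actin filaments** of 20 beads each, anchored to the nearest
  nuclear bead at the base, ending in an **actin head** bead just inside
  the membrane.

All lengths are in bead diameters sigma, energies in kT, and the drag
coefficient gamma is 1, so time is measured in tau = gamma sigma^2 / kT.
The bead budget (240/80/19 x 20) is a package choice: it gives even
angular spacing and a realistic membrane-to-nucleus perimeter ratio, and
every count is configurable through `sim_config()`.

## The force field

`compute_forces()` is the single source of truth; every term has an
analytic gradient, and the test suite checks all of them against central
finite differences of an independently coded energy sum.

* **Stretch**: harmonic springs E = 1/2 kappa (r - r0)^2 on both rings,
  along filaments, and on the filament-nucleus anchors. The
  membrane-membrane spring constant is `kappa00`, the model's membrane
  tension. Rest lengths come from the as-built geometry.
* **Bend**: E = kappa_b (1 - cos(theta - theta0)) at consecutive triples
  of the membrane ring (theta0 = the regular-polygon interior angle, so
  the built ring is unstrained) and of each filament (theta0 = pi).
* **Adhesion**: a Lennard-Jones well of depth `u3`, truncated and shifted
  to zero at 2.5 sigma, acting only between actin-head and membrane
  beads. Its depth is the model's cortical tension: it sets the energy
  per contact holding the membrane onto the cortex.
* **Excluded volume**: WCA repulsion between beads of different
  structures.
* **Area constraint**: E = 1/2 kappa_area (A - A0)^2 / A0 on the shoelace
  area of each ring, preventing collapse under cortical adhesion and
  giving the cytoplasm an effective compressibility.
* **Intra-structure soft core**: within one ring or filament, a harmonic
  repulsion (k = 1000 kT/sigma^2) switches on when two beads approach
  closer than the native bead spacing. The spec-level geometry places
  ring neighbours at 0.31 sigma, so a sigma-sized WCA core cannot act
  within a structure; without any core, strong adhesion compresses the
  soft membrane ring locally until bond lengths collapse and bending
  forces diverge. The soft core supplies the in-plane incompressibility
  of a lipid bilayer at bounded stiffness. It is zero in the as-built
  state, so the relaxed-start property is preserved.

Functional forms are deliberately standard for bead-spring membrane
models, and each lives behind its own exported function
(`stretch_energy()`, `bend_energy()`, `attraction_energy()`,
`repulsion_energy()`, `area_energy()`) so alternatives can be swapped.

## Dynamics

Production dynamics are overdamped Langevin (Euler-Maruyama): cells at
this scale are inertialess. Noise comes from R's Mersenne-Twister RNG via
inversion, drawn in bead index order (x before y), so a configuration and
seed reproduce a trajectory bit for bit. A velocity-Verlet NVE mode
exists solely to validate the force field: energy conservation over 10^4
steps and closed-form oscillator periods are part of the test suite.

Two numerical guards matter in practice:

* The explicit update must resolve the stiffest local mode. The adhesion
  well has curvature ~57 u3 per contact, so sweeps scale the timestep as
  dt = min(dt_base, 1e-3 / max(u3, 1), 0.5 / (3 (kappa00 + 1000))),
  keeping the simulated time and frame cadence fixed across grid points.
* A per-step displacement cap of 0.25 sigma acts as a safety valve
  against rare overshoot into the steep LJ core. Engagements are counted
  and reported per trajectory (`n_clamped`); in the shipped sweeps the
  count is zero in essentially all runs.

The production integrator keeps a Verlet neighbor list (skin 0.4 sigma,
rebuilt when any bead has moved half a skin); single-point force
evaluations and the NVE validator use an exhaustive O(n^2) pair loop, and
the tests assert both paths agree to machine precision.

## The protrusion engine

The observation the model targets is that protrusions appear when
cortical tension drops; what microscopically drives a nascent protrusion
is left open by that observation, so the engine below is this package's
design, calibrated once against the two qualitative target behaviours
and then frozen.

One filament (configurable: `protrusive_count`) is designated
protrusive, standing in for the microtubule-rich core of a nascent
neurite. It differs from the actin filaments in three ways:

1. **Growth.** Every `grow_interval` tau, one bead is inserted at the
   midpoint between the head and its neighbour, and the two new bonds
   keep the replaced bond's rest length: each insertion adds one segment
   of natural contour, a polymerization proxy. At most `grow_max` beads
   are added.
2. **An end-to-end strut.** A base-to-head spring whose rest length grows
   with each insertion transmits the polymerization push along the
   filament axis, the way a crosslinked microtubule bundle transmits
   compression. A chain with only bending stiffness either buckles (at
   any affordable bending constant) or forces a prohibitively small
   timestep through its transverse modes; the strut decouples axial
   push from transverse flexibility.
3. **Stall.** No insertion happens while the strut is compressed by more
   than 0.15 sigma, i.e. while the push force exceeds
   kappa_fil x 0.15 = 15 kT/sigma. Real polymerization stalls under
   load; numerically, the stall bounds the push so that a clamped
   membrane is not eventually pierced by unbounded spring loading.

With this engine the two regimes of interest emerge rather than being
scripted. At intermediate adhesion the membrane wraps the advancing tip,
the wrap both guides the tip and adds an adhesive contribution to the
driving force, and a long protrusion extends. At high adhesion the
membrane is clamped onto the 18 static cortex heads; freeing membrane
material costs more than the stall force supplies, and extension is
restricted. At very low adhesion nothing couples the membrane to the
tip: the bare tent resistance is close to the stall force and the
protrusion stays short and slip-prone.

## Morphometrics

The membrane contour is measured per frame. The radial profile is the
distance of each membrane bead from the membrane centroid; the baseline
radius R0 is its median (median, not mean, so a long protrusion does not
inflate its own baseline). A protrusion is a maximal circularly
contiguous arc more than delta = 2 sigma beyond R0 with at least
min_arc = 2 beads; the thresholds ignore single-bead thermal spikes and
are configurable. Projection length is the tip excursion of the largest
protrusion above R0 - the headline readout. Persistence is the fraction
of frames in the final half of a trajectory whose projection length
exceeds 2 sigma, the proxy for a stable rather than flickering neurite.
Circularity (4 pi A / P^2) and cell area complete the per-frame table.
All metrics are invariant under rigid rotation and translation, which
the tests check directly.

## The sweeps and what passing them shows

Two presets ship with the package (as functions and as YAML under
`inst/presets/`):

* `preset_adhesion_scan()`: u3 in {0.5, 1, 3, 10, 30, 50} kT at
  kappa00 = 10, five replicate seeds. The calibration property is an
  interior maximum of mean projection length: some interior u3 exceeds
  both endpoint means by at least twice the pooled SEM.
* `preset_tension_contrast()`: u3 in {3, 30} kT at kappa00 = 500, five
  replicate seeds. The calibration property is that mean persistence at
  u3 = 3 strictly exceeds that at u3 = 30.

Each replicate runs 4 tau of dynamics with a frame every 0.25 tau and a
growth event every 0.07 tau up to 45 insertions - the shortest schedule
at which both properties held with five replicates when the presets were
calibrated; the u3-scaled timestep keeps the longest replicate at 2 x
10^5 steps. Replicate r uses seed root_seed + r - 1.

What passing shows: the model reproduces, from its own mechanics, the
qualitative phase behaviour of interest - protrusion gated by a balance
of cortical adhesion against membrane tension. What it does not show:
agreement with any measured neurite length (the model is 2D, reduced
units, one protrusive element, no myosin motors, no filament turnover),
nor anything about the biochemical pathway that lowers cortical tension
in real differentiating neurons.

## Degenerate inputs and tie-breaks

Configurations are validated before use (ring spacings below 0.1 sigma,
inverted radii, or an infeasible filament span are rejected naming the
offending component). `validate_cell()` reports all violated invariants
without raising. Growth insertions that would land within 0.1 sigma of an
unrelated bead are skipped with a warning and logged. When several
protrusions tie in length, the first arc in ring order is reported first;
`which.max` resolves tips within an arc. A sweep grid point that fails
aborts the whole sweep with its (u3, kappa00, replicate) coordinates in
the message, since a silent hole in a grid is worse than a loud stop.

## Known limitations

* 2D: no membrane tubes, no torsion, no out-of-plane buckling.
* One protrusive element with a deterministic growth clock; no stochastic
  polymerization, severing, or retraction.
* Cortical tension enters only through the adhesion well depth; there are
  no explicit myosin motors.
* The Euler-Maruyama integrator is first order; the timestep rule is
  calibrated for the shipped parameter ranges, and configurations far
  outside them (e.g. u3 well above 50) should scale dt down accordingly.
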