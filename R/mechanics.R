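#' Harmonic stretch energy
#'
#' `E = 1/2 kappa (r - r0)^2` for a spring of constant `kappa` and rest
#' length `r0`. This is the form used for every bond in the model; the
#' membrane--membrane bonds carry `kappa00` and so encode membrane tension.
#'
#' @param r Bead separation (sigma). Must be `>= 0`.
#' @param kappa Spring constant (kT/sigma^2).
#' @param r0 Rest length (sigma).
#' @return Energy in kT.
#' @examples
#' stretch_energy(2, 10, 1) # 5
#' @export
stretch_energy <- function(r, kappa, r0) {
  stopifnot(all(r >= 0))
  0.5 * kappa * (r - r0)^2
}

#' Discrete bending energy
#'
#' `E = kappa_b (1 - cos(theta - theta0))`: zero at the rest angle
#' `theta0`, which is `pi` for straight chains (filaments) and the
#' regular-polygon interior angle for the membrane ring, so rings are not
#' penalised for their built-in curvature.
#'
#' @param theta Interior angle at the middle bead, in radians, in `[0, pi]`.
#' @param kappa_b Bending stiffness (kT).
#' @param theta0 Rest angle (radians); default `pi` gives the classic
#'   `kappa_b (1 + cos theta)` chain-stiffness term.
#' @return Energy in kT.
#' @examples
#' bend_energy(pi, 5)     # 0
#' bend_energy(pi / 2, 5) # 5
#' @export
bend_energy <- function(theta, kappa_b, theta0 = pi) {
  stopifnot(all(theta >= -1e-12), all(theta <= pi + 1e-12))
  kappa_b * (1 - cos(theta - theta0))
}

#' Membrane--actin-head attraction energy
#'
#' Lennard-Jones well `4 u3 [(sigma/r)^12 - (sigma/r)^6]`, truncated and
#' shifted to zero at `2.5 sigma`. Applied only between ACTIN_HEAD and
#' MEMBRANE beads; its well depth `u3` is the model's cortical-tension
#' parameter: it sets how strongly the actin cortex adheres to the
#' membrane.
#'
#' @param r Bead separation (sigma). Must be `> 0`.
#' @param u3 Well depth (kT).
#' @param sigma Bead diameter (length unit).
#' @return Energy in kT; minimum `-u3` plus the cutoff shift at
#'   `r = 2^(1/6) sigma`; identically 0 for `r >= 2.5 sigma`.
#' @examples
#' attraction_energy(2.5, 3) # 0
#' @export
attraction_energy <- function(r, u3, sigma = 1) {
  stopifnot(all(r > 0))
  sr6c <- (1 / 2.5)^6
  shift <- 4 * u3 * (sr6c^2 - sr6c)
  sr6 <- (sigma / r)^6
  ifelse(r < 2.5 * sigma, 4 * u3 * (sr6^2 - sr6) - shift, 0)
}

#' Excluded-volume (WCA) repulsion energy
#'
#' Purely repulsive truncated-shifted Lennard-Jones:
#' `4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`,
#' zero beyond; continuous at the cutoff. Applied to all nonbonded pairs
#' of different structures that are not attraction pairs.
#'
#' @param r Bead separation (sigma). Must be `> 0`.
#' @param eps_rep Repulsion strength (kT).
#' @param sigma Bead diameter.
#' @return Energy in kT.
#' @examples
#' repulsion_energy(1, 1)       # 1
#' repulsion_energy(2^(1 / 6), 1) # 0
#' @export
repulsion_energy <- function(r, eps_rep, sigma = 1) {
  stopifnot(all(r > 0))
  sr6 <- (sigma / r)^6
  ifelse(r < 2^(1 / 6) * sigma, 4 * eps_rep * (sr6^2 - sr6) + eps_rep, 0)
}

#' Ring area-constraint energy
#'
#' `E = 1/2 kappa_area (A - A0)^2 / A0` with `A` the signed shoelace
#' polygon area of the ordered ring. Penalises deviation of the enclosed
#' area from its target, preventing ring collapse under cortical adhesion;
#' invariant under rigid rotation and translation.
#'
#' @param ring_positions Ordered cycle of 2D points (matrix, one row per
#'   vertex, at least 3 rows).
#' @param kappa_area Area modulus (kT/sigma^2... per relative area).
#' @param a0 Target area (sigma^2).
#' @return Energy in kT.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' area_energy(sq, 4, 0.5) # 1
#' @export
area_energy <- function(ring_positions, kappa_area, a0) {
  p <- as.matrix(ring_positions)
  if (nrow(p) < 3L) stop("ring must have at least 3 points", call. = FALSE)
  nxt <- c(seq_len(nrow(p))[-1], 1L)
  a <- 0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])
  if (abs(a) < 1e-12) stop("degenerate ring: zero area", call. = FALSE)
  0.5 * kappa_area * (a - a0)^2 / a0
}

#' Forces and energy breakdown for a cell state
#'
#' Evaluates the full force field (stretch, bend, attraction, repulsion,
#' area) and returns analytic forces `-grad E` per bead together with the
#' energy decomposition. Pairwise terms obey Newton's third law, so the
#' net force and torque vanish; bonded pairs and same-structure pairs are
#' excluded from the nonbonded terms.
#'
#' @param state A `cell_state` (see [build_cell()]).
#' @param topology The matching `cell_topology`.
#' @param cfg The generating [sim_config()].
#' @return List with `forces` (n x 2 matrix, kT/sigma) and `energies`
#'   (an `energy_breakdown`: stretch, bend, attraction, repulsion, area,
#'   total, in kT).
#' @export
compute_forces <- function(state, topology, cfg) {
  core <- topo_to_core(topology)
  core$role <- role_int(state$role)
  res <- cg_eval(state$positions, core, core_par(cfg))
  list(forces = res$forces,
       energies = energy_breakdown(res$stretch, res$bend, res$attraction,
                                   res$repulsion, res$area))
}

energy_breakdown <- function(stretch, bend, attraction, repulsion, area) {
  structure(list(stretch = stretch, bend = bend, attraction = attraction,
                 repulsion = repulsion, area = area,
                 total = stretch + bend + attraction + repulsion + area),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> [kT]\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  invisible(x)
}
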