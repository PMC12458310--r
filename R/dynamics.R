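#' One overdamped Langevin (Euler--Maruyama) step
#'
#' `dx = F dt / gamma + sqrt(2 kT dt / gamma) xi` with `xi` standard
#' normal per coordinate. Noise is drawn from R's global RNG (Mersenne
#' Twister with inversion sampling) in bead index order, x before y, so a
#' trajectory is bit-reproducible after `set.seed()`. Velocities are left
#' untouched (the production dynamics are inertialess).
#'
#' @param state A `cell_state`.
#' @param forces n x 2 force matrix (e.g. from [compute_forces()]).
#' @param dt Timestep (tau).
#' @param gamma Drag coefficient.
#' @param kT Thermal energy; 0 gives pure gradient descent.
#' @return The advanced `cell_state` (time incremented by `dt`).
#' @export
step_overdamped <- function(state, forces, dt, gamma = 1, kT = 1) {
  stopifnot(dt > 0, gamma > 0, kT >= 0)
  n <- nrow(state$positions)
  noise <- if (kT > 0) {
    matrix(rnorm(2L * n), ncol = 2L, byrow = TRUE)
  } else {
    matrix(0, n, 2L)
  }
  disp <- forces * dt / gamma + sqrt(2 * kT * dt / gamma) * noise
  if (!all(is.finite(disp))) {
    bad <- which(!is.finite(disp[, 1]) | !is.finite(disp[, 2]))[1]
    stop("non-finite displacement for bead ", bad, " at t = ",
         format(state$time), call. = FALSE)
  }
  state$positions <- state$positions + disp
  state$time <- state$time + dt
  state
}

#' One velocity-Verlet step (validation mode)
#'
#' Symplectic constant-energy update at unit bead mass; used only to
#' validate the force field (energy conservation, oscillator periods),
#' never for production runs.
#'
#' @param state A `cell_state` carrying velocities.
#' @param topology The matching `cell_topology`.
#' @param cfg The generating [sim_config()].
#' @param dt Timestep (tau).
#' @return The advanced `cell_state` (positions, velocities, time).
#' @export
step_nve <- function(state, topology, cfg, dt) {
  res <- run_nve(state, topology, cfg, n_steps = 1L, dt = dt,
                 save_every = 1L)
  res$state
}

#' Velocity-Verlet integration of a cell
#'
#' @inheritParams step_nve
#' @param n_steps Number of steps.
#' @param save_every Energy-sampling interval (steps).
#' @return List with `state` (final) and `energy`, a data.frame of
#'   sampled `time`, `kinetic`, `potential` and `total` energy.
#' @export
run_nve <- function(state, topology, cfg, n_steps, dt = cfg$dt,
                    save_every = 100L) {
  core <- topo_to_core(topology)
  core$role <- role_int(state$role)
  res <- cg_run_nve(state$positions, state$velocities, core, core_par(cfg),
                    dt, as.integer(n_steps), as.integer(save_every))
  state$positions <- res$pos
  state$velocities <- res$vel
  state$time <- state$time + n_steps * dt
  list(state = state,
       energy = data.frame(time = res$time, kinetic = res$kinetic,
                           potential = res$potential, total = res$total))
}

#' Elongate the protrusive filament(s) by one bead each
#'
#' The polymerization proxy driving protrusion: for each protrusive
#' filament that has not reached `grow_max`, one bead is inserted at the
#' midpoint between the head bead and its bonded neighbour. The replaced
#' bond is rewired into two bonds that keep the original segment rest
#' length, so every insertion adds one segment of contour at its natural
#' length and the filament pushes its tip outward as it relaxes. Bend
#' triples are rewired accordingly (straight rest angle at the new bead).
#'
#' An insertion that would land within `0.1 sigma` of a non-bonded bead is
#' skipped with a warning and logged as such. Growth also stalls (the
#' event is skipped silently, logged with `skipped = TRUE`) while the
#' filament's end-to-end strut is compressed beyond the stall threshold:
#' the polymerization push is bounded, as for real filaments growing
#' against a load.
#'
#' @param state A `cell_state`.
#' @param topology The matching `cell_topology`.
#' @param cfg The generating [sim_config()].
#' @param time Simulation time of the event (tau), recorded in the log.
#' @return List with updated `state`, `topology`, and `events` (data.frame
#'   `time`, `filament_id`, `bead_index`, `skipped`).
#' @export
grow_protrusive_filament <- function(state, topology, cfg, time = state$time) {
  events <- list()
  for (f in seq_len(cfg$protrusive_count)) {
    added <- sum(state$filament_id == f) - cfg$beads_per_filament
    if (added >= cfg$grow_max) next
    h <- which(state$role == "ACTIN_HEAD" & state$filament_id == f)
    stopifnot(length(h) == 1L)
    bd <- topology$bonds
    srow <- integer(0)
    if (!is.null(topology$struts) && f %in% topology$struts$filament) {
      su <- topology$struts[topology$struts$filament == f, ]
      srow <- which((bd$i == su$i & bd$j == su$j) |
                      (bd$i == su$j & bd$j == su$i))
      # stall: no insertion while the strut is loaded beyond the threshold
      ree <- sqrt(sum((state$positions[su$i, ] - state$positions[su$j, ])^2))
      if (bd$r0[srow] - ree > STALL_COMPRESSION * cfg$sigma) {
        events[[length(events) + 1L]] <-
          data.frame(time = time, filament_id = f, bead_index = NA_integer_,
                     skipped = TRUE)
        next
      }
    }
    brow <- which((bd$i == h | bd$j == h) &
                    state$filament_id[bd$i] == f &
                    state$filament_id[bd$j] == f &
                    !(seq_len(nrow(bd)) %in% srow))
    stopifnot(length(brow) == 1L)
    nb <- if (bd$i[brow] == h) bd$j[brow] else bd$i[brow]
    newpos <- (state$positions[h, ] + state$positions[nb, ]) / 2

    d2 <- (state$positions[, 1] - newpos[1])^2 +
      (state$positions[, 2] - newpos[2])^2
    d2[c(h, nb)] <- Inf
    if (min(d2) < (0.1 * cfg$sigma)^2) {
      warning("growth event skipped on filament ", f, " at t = ",
              format(time), ": insertion would overlap bead ",
              which.min(d2), call. = FALSE)
      events[[length(events) + 1L]] <-
        data.frame(time = time, filament_id = f, bead_index = NA_integer_,
                   skipped = TRUE)
      next
    }

    new <- nrow(state$positions) + 1L
    state$positions <- rbind(state$positions, newpos, deparse.level = 0)
    state$velocities <- rbind(state$velocities, c(0, 0), deparse.level = 0)
    state$role <- c(state$role, "ACTIN")
    state$filament_id <- c(state$filament_id, f)
    topology$group <- c(topology$group, topology$group[h])

    r0 <- bd$r0[brow]
    kap <- bd$kappa[brow]
    # each insertion adds one segment of contour at its natural length, and
    # lengthens the strut rest span to match, so the filament pushes its
    # tip outward as it relaxes
    if (length(srow) == 1L) bd$r0[srow] <- bd$r0[srow] + r0
    topology$bonds <- rbind(
      bd[-brow, ],
      data.frame(i = c(nb, new), j = c(new, h), kappa = kap, r0 = r0)
    )
    rownames(topology$bonds) <- NULL

    ang <- topology$angles
    hit <- ang$j == nb & ang$k == h
    ang$k[hit] <- new
    hit2 <- ang$j == nb & ang$i == h
    ang$i[hit2] <- new
    kb <- cfg$kappa_bend_fil *
      if (f <= cfg$protrusive_count) PROTRUSIVE_BEND_FACTOR else 1.0
    topology$angles <- rbind(
      ang,
      data.frame(i = nb, j = new, k = h, kb = kb, theta0 = pi)
    )
    rownames(topology$angles) <- NULL
    events[[length(events) + 1L]] <-
      data.frame(time = time, filament_id = f, bead_index = new,
                 skipped = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), filament_id = integer(),
               bead_index = integer(), skipped = logical())
  list(state = state, topology = topology, events = events)
}

#' Run a full overdamped Langevin simulation
#'
#' Builds the cell from `cfg`, integrates `n_steps` of overdamped Langevin
#' dynamics with forces recomputed every step, applies the deterministic
#' growth schedule (one insertion per protrusive filament every
#' `grow_interval` tau until `grow_max` beads are added), and records a
#' frame plus its energy breakdown every `save_every` steps. The first
#' frame is the as-built cell. Identical `(cfg, seed)` give bit-identical
#' trajectories.
#'
#' @param cfg A [sim_config()].
#' @param verbose Print a progress line per saved frame.
#' @return A `cell_trajectory`: `frames` (list of `cell_state`), `times`,
#'   `energies` (data.frame per frame), `events` (growth log), `config`.
#' @export
run_simulation <- function(cfg, verbose = FALSE) {
  validate_config(cfg)
  cell <- build_cell(cfg)
  state <- cell$state
  topology <- cell$topology
  set.seed(cfg$seed)

  grow_steps <- integer()
  if (cfg$grow_max > 0L && cfg$protrusive_count > 0L) {
    m <- seq_len(cfg$grow_max)
    s <- as.integer(round(m * cfg$grow_interval / cfg$dt))
    grow_steps <- sort(unique(s[s >= 1L & s <= cfg$n_steps]))
  }

  e0 <- compute_forces(state, topology, cfg)$energies
  frames <- list(state)
  times <- 0
  energies <- list(as.data.frame(unclass(e0)))
  events <- list()
  n_clamped <- 0

  boundaries <- sort(unique(c(grow_steps, cfg$n_steps)))
  cur <- 0L
  for (b in boundaries) {
    if (b > cur) {
      core <- topo_to_core(topology)
      core$role <- role_int(state$role)
      res <- cg_run_od(state$positions, core, core_par(cfg),
                       cfg$dt, cfg$gamma, cfg$kT,
                       as.integer(b - cur), cfg$save_every, cur)
      state$positions <- res$pos
      state$time <- b * cfg$dt
      n_clamped <- n_clamped + res$n_clamped
      for (q in seq_along(res$frames)) {
        fr <- state
        fr$positions <- res$frames[[q]]
        fr$time <- res$frame_steps[q] * cfg$dt
        frames[[length(frames) + 1L]] <- fr
        times <- c(times, fr$time)
        energies[[length(energies) + 1L]] <-
          as.data.frame(as.list(res$energies[q, ]))
        if (verbose) {
          np <- length(detect_protrusions(fr))
          message(sprintf("t = %8.3f  E = %10.4f  protrusions = %d",
                          fr$time, res$energies[q, "total"], np))
        }
      }
      cur <- b
    }
    if (b %in% grow_steps) {
      g <- grow_protrusive_filament(state, topology, cfg, time = b * cfg$dt)
      state <- g$state
      topology <- g$topology
      if (nrow(g$events)) events[[length(events) + 1L]] <- g$events
    }
  }

  energies <- do.call(rbind, energies)
  energies <- cbind(time = times, energies)
  rownames(energies) <- NULL
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), filament_id = integer(),
               bead_index = integer(), skipped = logical())
  rownames(events) <- NULL
  structure(list(frames = frames, times = times, energies = energies,
                 events = events, config = cfg, topology = topology,
                 n_clamped = n_clamped),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("<cell_trajectory> ", length(x$frames), " frames over ",
      format(max(x$times)), " tau; ",
      nrow(x$frames[[length(x$frames)]]$positions), " beads in last frame; ",
      sum(!x$events$skipped), " growth events\n", sep = "")
  invisible(x)
}
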