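#' Define a (u3 x kappa00) parameter sweep
#'
#' @param base_config The [sim_config()] shared by every grid point; `u3`,
#'   `kappa00` and `seed` are overridden per run.
#' @param u3_values Cortical-adhesion well depths to sweep (kT).
#' @param kappa00_values Membrane spring constants to sweep.
#' @param replicates Replicate simulations per grid point.
#' @param root_seed Root RNG seed; replicate r runs with
#'   `root_seed + r - 1`.
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(base_config, u3_values, kappa00_values,
                       replicates = 5L, root_seed = 1L) {
  validate_config(base_config)
  stopifnot(length(u3_values) >= 1L, length(kappa00_values) >= 1L,
            replicates >= 1L)
  structure(list(base_config = base_config,
                 u3_values = as.numeric(u3_values),
                 kappa00_values = as.numeric(kappa00_values),
                 replicates = as.integer(replicates),
                 root_seed = as.integer(root_seed)),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("<sweep_spec> u3 in {", paste(x$u3_values, collapse = ", "),
      "} x kappa00 in {", paste(x$kappa00_values, collapse = ", "),
      "} x ", x$replicates, " replicates (root seed ", x$root_seed, ")\n",
      sep = "")
  invisible(x)
}

#' Run a parameter sweep
#'
#' Runs one simulation per `(u3, kappa00, replicate)` combination and
#' summarises each into a row of projection-length statistics. Rows are
#' produced in a deterministic order (u3 outer, kappa00 middle, replicate
#' inner); replicate `r` uses seed `root_seed + r - 1`, so identical specs
#' give identical tables.
#'
#' The headline statistic `proj_mean` is the time-mean projection length
#' over the final half of saved frames; the final-frame and maximal values
#' are recorded alongside, as is the persistence fraction.
#'
#' Each grid point keeps the base configuration's total simulated time and
#' frame cadence but runs at a timestep capped by the stability limits of
#' its own stiffness scale: the adhesion-well curvature grows with `u3`
#' and the membrane spring stiffness with `kappa00`, so
#' `dt = min(dt_base, 1e-3 / max(u3, 1), 0.5 / (3 (kappa00 + k_core)))`.
#'
#' @param spec A [sweep_spec()].
#' @param delta,min_arc Protrusion detection parameters (see
#'   [detect_protrusions()]).
#' @param l_min Persistence threshold (sigma).
#' @param verbose Print one line per completed run.
#' @return A data.frame with columns `u3`, `kappa00`, `seed`, `proj_mean`,
#'   `proj_final`, `proj_max`, `persistence`.
#' @export
run_sweep <- function(spec, delta = 2.0, min_arc = 2L, l_min = 2.0,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (u3 in spec$u3_values) {
    for (k00 in spec$kappa00_values) {
      for (r in seq_len(spec$replicates)) {
        cfg <- spec$base_config
        cfg$u3 <- u3
        cfg$kappa00 <- k00
        cfg$seed <- spec$root_seed + r - 1L
        t_total <- cfg$n_steps * cfg$dt
        t_save <- cfg$save_every * cfg$dt
        cfg$dt <- stable_dt(cfg$dt, u3, k00)
        cfg$n_steps <- as.integer(round(t_total / cfg$dt))
        cfg$save_every <- as.integer(round(t_save / cfg$dt))
        traj <- tryCatch(
          run_simulation(cfg),
          error = function(e) stop("sweep failed at u3 = ", u3,
                                   ", kappa00 = ", k00, ", replicate ", r,
                                   ": ", conditionMessage(e), call. = FALSE))
        lens <- vapply(traj$frames, projection_length, numeric(1),
                       delta = delta, min_arc = min_arc)
        nf <- length(lens)
        win <- lens[(nf - ceiling(nf / 2) + 1L):nf]
        rows[[length(rows) + 1L]] <- data.frame(
          u3 = u3, kappa00 = k00, seed = cfg$seed,
          proj_mean = mean(win),
          proj_final = lens[nf],
          proj_max = max(lens),
          persistence = persistence(traj, 0.5, l_min, delta, min_arc))
        if (verbose)
          message(sprintf(
            "u3 = %6.2f kappa00 = %6.1f seed = %d : proj_mean = %.3f",
            u3, k00, cfg$seed, rows[[length(rows)]]$proj_mean))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a sweep into mean +/- SEM per grid point
#'
#' @param rows Output of [run_sweep()].
#' @param value Column to summarise (default the headline `proj_mean`).
#' @return A data.frame with columns `u3`, `kappa00`, `n`, `mean`, `sem`
#'   (sample SD / sqrt(n); 0 by convention, with a message, for a single
#'   replicate), ordered by `kappa00` then `u3`.
#' @export
summarize_sweep <- function(rows, value = "proj_mean") {
  stopifnot(value %in% names(rows))
  key <- interaction(rows$u3, rows$kappa00, drop = TRUE)
  parts <- split(rows, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    n <- nrow(p)
    data.frame(u3 = p$u3[1], kappa00 = p$kappa00[1], n = n,
               mean = mean(p[[value]]),
               sem = if (n > 1L) sd(p[[value]]) / sqrt(n) else 0)
  }))
  if (any(out$n == 1L))
    message("single-replicate grid point(s): SEM reported as 0 by convention")
  out <- out[order(out$kappa00, out$u3), ]
  rownames(out) <- NULL
  out
}

# per-grid-point timestep: the explicit Euler-Maruyama update must resolve
# the stiffest local mode -- the adhesion well curvature (~ 57 u3 per
# contact) and the membrane stretch + compression core
stable_dt <- function(dt_base, u3, kappa00) {
  min(dt_base, 1e-3 / max(u3, 1), 0.5 / (3 * (kappa00 + INTRA_CORE_K)))
}

# base_config shared by the two shipped presets: 4 tau of dynamics, one
# frame every 0.25 tau, one growth event per 0.1 tau up to 30 inserted
# beads; calibrated once so the sweeps resolve the phase behaviour at
# modest cost (see the methods vignette)
preset_base <- function() {
  sim_config(dt = 2e-4, n_steps = 20000L, save_every = 1250L,
             protrusive_count = 1L,
             grow_interval = 0.07, grow_max = 45L)
}

#' Shipped sweep presets
#'
#' `preset_adhesion_scan()` sweeps the cortical-adhesion well depth `u3`
#' over a log-spaced grid (0.5 to 50 kT, bracketing the low = 3.0 and
#' high = 30.0 reference values) at a soft membrane, `kappa00 = 10`: the
#' mean projection-length curve exhibits an interior maximum, i.e.
#' intermediate cortical tension permits the longest neurite-like
#' protrusion while very low or very high adhesion restricts it.
#'
#' `preset_tension_contrast()` contrasts low (3.0) versus high (30.0)
#' `u3` at a stiff membrane, `kappa00 = 500`: low cortical adhesion
#' permits dynamic protrusions (higher persistence) while high adhesion
#' clamps the membrane to the cortical shell.
#'
#' The same preset specs ship as YAML under
#' `system.file("presets", package = "cellspring")`.
#'
#' @param replicates Replicate seeds per grid point.
#' @param root_seed Root RNG seed.
#' @return A [sweep_spec()].
#' @export
preset_adhesion_scan <- function(replicates = 5L, root_seed = 1L) {
  sweep_spec(preset_base(),
             u3_values = c(0.5, 1, 3.0, 10, 30.0, 50),
             kappa00_values = 10,
             replicates = replicates, root_seed = root_seed)
}

#' @rdname preset_adhesion_scan
#' @export
preset_tension_contrast <- function(replicates = 5L, root_seed = 1L) {
  sweep_spec(preset_base(),
             u3_values = c(3.0, 30.0),
             kappa00_values = 500,
             replicates = replicates, root_seed = root_seed)
}
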