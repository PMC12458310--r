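#' Simulation configuration
#'
#' Collects every model and run parameter of the bead-spring cell in reduced
#' units (bead diameter `sigma` = length unit, `kT` = energy unit, drag
#' `gamma` = 1, so time is measured in tau = gamma * sigma^2 / kT).
#'
#' The two biophysical control parameters are `u3`, the well depth of the
#' short-range attraction between actin-filament head beads and membrane
#' beads (cortical membrane--actin tension, in kT), and `kappa00`, the
#' stretching constant of the membrane--membrane springs (membrane tension,
#' in kT / sigma^2). Under the default architecture the cell has
#' 240 + 80 + 19 x 20 = 700 beads.
#'
#' @param n_membrane Number of plasma-membrane beads.
#' @param n_nucleus Number of nuclear-envelope beads.
#' @param n_filaments Number of radial actin filaments.
#' @param beads_per_filament Beads per filament, head bead included.
#' @param r_cell Initial membrane ring radius (sigma).
#' @param r_nucleus Initial nuclear ring radius (sigma).
#' @param u3 Membrane--actin-head attraction well depth (kT).
#' @param kappa00 Membrane--membrane stretching spring constant (kT/sigma^2).
#' @param kappa_nuc Nuclear-ring spring constant.
#' @param kappa_fil Intra-filament and anchor spring constant.
#' @param kappa_bend_mem Membrane bending stiffness (kT).
#' @param kappa_bend_fil Filament bending stiffness (kT); protrusive
#'   filaments are stiffer by a fixed factor of 5.
#' @param kappa_area Quadratic area-constraint modulus for both rings.
#' @param sigma Bead diameter, the length unit.
#' @param eps_rep Excluded-volume (WCA) repulsion strength (kT).
#' @param kT Thermal energy, the energy unit.
#' @param gamma Drag coefficient.
#' @param dt Integration timestep (tau).
#' @param n_steps Total number of integration steps.
#' @param save_every Frame interval (steps).
#' @param seed Integer RNG seed.
#' @param protrusive_count Number of filaments designated protrusive.
#' @param grow_interval Simulation time (tau) between growth events on
#'   protrusive filaments. The default (50 tau) exceeds the default run
#'   length, so growth is effectively off unless set.
#' @param grow_max Maximum beads added per protrusive filament (0 = no
#'   growth).
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config()
#' total_beads(cfg) # 700
#' @export
sim_config <- function(n_membrane = 240L,
                       n_nucleus = 80L,
                       n_filaments = 19L,
                       beads_per_filament = 20L,
                       r_cell = 12.0,
                       r_nucleus = 4.0,
                       u3 = 3.0,
                       kappa00 = 10.0,
                       kappa_nuc = 100.0,
                       kappa_fil = 100.0,
                       kappa_bend_mem = 5.0,
                       kappa_bend_fil = 20.0,
                       kappa_area = 50.0,
                       sigma = 1.0,
                       eps_rep = 1.0,
                       kT = 1.0,
                       gamma = 1.0,
                       dt = 1e-3,
                       n_steps = 20000L,
                       save_every = 200L,
                       seed = 1L,
                       protrusive_count = 1L,
                       grow_interval = 50.0,
                       grow_max = 0L) {
  cfg <- list(
    n_membrane = as.integer(n_membrane),
    n_nucleus = as.integer(n_nucleus),
    n_filaments = as.integer(n_filaments),
    beads_per_filament = as.integer(beads_per_filament),
    r_cell = as.numeric(r_cell),
    r_nucleus = as.numeric(r_nucleus),
    u3 = as.numeric(u3),
    kappa00 = as.numeric(kappa00),
    kappa_nuc = as.numeric(kappa_nuc),
    kappa_fil = as.numeric(kappa_fil),
    kappa_bend_mem = as.numeric(kappa_bend_mem),
    kappa_bend_fil = as.numeric(kappa_bend_fil),
    kappa_area = as.numeric(kappa_area),
    sigma = as.numeric(sigma),
    eps_rep = as.numeric(eps_rep),
    kT = as.numeric(kT),
    gamma = as.numeric(gamma),
    dt = as.numeric(dt),
    n_steps = as.integer(n_steps),
    save_every = as.integer(save_every),
    seed = as.integer(seed),
    protrusive_count = as.integer(protrusive_count),
    grow_interval = as.numeric(grow_interval),
    grow_max = as.integer(grow_max)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$n_membrane >= 3L, "n_membrane must be >= 3")
  chk(cfg$n_nucleus >= 3L, "n_nucleus must be >= 3")
  chk(cfg$n_filaments >= 0L, "n_filaments must be >= 0")
  chk(cfg$beads_per_filament >= 2L, "beads_per_filament must be >= 2")
  chk(cfg$r_nucleus < cfg$r_cell, "r_nucleus must be < r_cell")
  chk(cfg$r_nucleus > 0 && cfg$r_cell > 0, "radii must be positive")
  chk(cfg$u3 >= 0, "u3 must be >= 0")
  chk(cfg$kappa00 > 0, "kappa00 must be > 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$sigma > 0, "sigma must be > 0")
  chk(cfg$gamma > 0, "gamma must be > 0")
  chk(cfg$kT >= 0, "kT must be >= 0")
  chk(cfg$n_steps >= 0L, "n_steps must be >= 0")
  chk(cfg$save_every >= 1L, "save_every must be >= 1")
  chk(cfg$protrusive_count >= 0L &&
        cfg$protrusive_count <= cfg$n_filaments,
      "protrusive_count must be between 0 and n_filaments")
  chk(cfg$grow_interval > 0, "grow_interval must be > 0")
  chk(cfg$grow_max >= 0L, "grow_max must be >= 0")
  invisible(cfg)
}

#' Total bead count of a configuration
#'
#' @param cfg A [sim_config()].
#' @return Integer: `n_membrane + n_nucleus + n_filaments * beads_per_filament`.
#' @export
total_beads <- function(cfg) {
  validate_config(cfg)
  cfg$n_membrane + cfg$n_nucleus + cfg$n_filaments * cfg$beads_per_filament
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", total_beads(x), " beads (",
      x$n_membrane, " membrane + ", x$n_nucleus, " nucleus + ",
      x$n_filaments, " x ", x$beads_per_filament, " filament)\n", sep = "")
  cat("  u3 = ", x$u3, " kT, kappa00 = ", x$kappa00,
      ", dt = ", x$dt, ", n_steps = ", x$n_steps,
      ", seed = ", x$seed, "\n", sep = "")
  if (x$grow_max > 0L)
    cat("  growth: ", x$protrusive_count, " protrusive filament(s), +",
        x$grow_max, " beads max, every ", x$grow_interval, " tau\n", sep = "")
  invisible(x)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file must be a flat key-value document whose keys are exactly the
#' field names of [sim_config()]; unknown keys are an error. Missing keys
#' take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a simulation configuration to a YAML or JSON file
#'
#' @param cfg A [sim_config()].
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

# Hash of the configuration used in provenance headers.
config_hash <- function(cfg) {
  txt <- paste(names(unclass(cfg)),
               vapply(unclass(cfg), function(v) format(v, digits = 17), ""),
               sep = "=", collapse = ";")
  # small multiplicative hash; avoids a digest dependency
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
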