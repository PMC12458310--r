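#' Radial profile of the membrane ring
#'
#' Distance of every membrane bead from the membrane centroid (arithmetic
#' mean of membrane bead positions), in ring order. Translation invariant.
#'
#' @param state A `cell_state` with at least 3 membrane beads.
#' @return Numeric vector of distances (sigma), one per membrane bead.
#' @export
radial_profile <- function(state) {
  mem <- which(state$role == "MEMBRANE")
  if (length(mem) < 3L) stop("need at least 3 membrane beads", call. = FALSE)
  p <- state$positions[mem, , drop = FALSE]
  ctr <- colMeans(p)
  sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
}

#' Detect membrane protrusions
#'
#' A protrusion is a maximal circularly-contiguous arc of membrane beads
#' whose radial distance exceeds the baseline radius `R0 + delta`, where
#' `R0` is the median of the radial profile (the median keeps the baseline
#' stable when a long protrusion is present), with at least `min_arc`
#' beads. Arcs wrapping past the ring origin are handled; records never
#' overlap.
#'
#' @param state A `cell_state`.
#' @param delta Radial excursion threshold (sigma).
#' @param min_arc Minimum number of beads in an arc.
#' @return List of protrusion records, each with `arc` (membrane-bead ring
#'   indices), `tip_index` (ring index of maximal excursion), `length`
#'   (tip distance minus `R0`, sigma) and `base_width` (chord across the
#'   arc ends, sigma). Empty list when none found.
#' @export
detect_protrusions <- function(state, delta = 2.0, min_arc = 2L) {
  stopifnot(delta > 0, min_arc >= 1L)
  r <- radial_profile(state)
  n <- length(r)
  r0 <- median(r)
  above <- r > r0 + delta
  if (!any(above)) return(list())

  # maximal circular runs of TRUE
  if (all(above)) {
    runs <- list(seq_len(n))
  } else {
    # rotate so position 1 is below threshold, then find ordinary runs
    start <- which(!above)[1]
    idx <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
    rl <- rle(above[idx])
    ends <- cumsum(rl$lengths)
    begins <- c(1L, head(ends, -1L) + 1L)
    runs <- lapply(which(rl$values), function(q) idx[begins[q]:ends[q]])
  }

  mem <- which(state$role == "MEMBRANE")
  p <- state$positions[mem, , drop = FALSE]
  out <- list()
  for (arc in runs) {
    if (length(arc) < min_arc) next
    tip <- arc[which.max(r[arc])]
    a <- arc[1]
    b <- arc[length(arc)]
    out[[length(out) + 1L]] <- list(
      arc = arc,
      tip_index = tip,
      length = r[tip] - r0,
      base_width = sqrt(sum((p[a, ] - p[b, ])^2))
    )
  }
  out
}

#' Projection length of a frame
#'
#' The maximal protrusion length (tip radial excursion above the median
#' baseline radius), or 0 when no protrusion is detected. This is the
#' model's neurite-projection-length readout. Invariant under rigid
#' rotation and translation.
#'
#' @inheritParams detect_protrusions
#' @return Length in sigma (`>= 0`).
#' @export
projection_length <- function(state, delta = 2.0, min_arc = 2L) {
  pr <- detect_protrusions(state, delta, min_arc)
  if (length(pr) == 0L) return(0.0)
  max(vapply(pr, `[[`, numeric(1), "length"))
}

#' Protrusion persistence over a trajectory
#'
#' The fraction of frames in the final `window_fraction` of a trajectory
#' whose projection length exceeds `l_min`; the proxy for how stably a
#' protrusion is maintained.
#'
#' @param trajectory A `cell_trajectory`.
#' @param window_fraction Fraction of final frames considered, in (0, 1].
#' @param l_min Projection-length threshold (sigma).
#' @param delta,min_arc Passed to [projection_length()].
#' @return Fraction in `[0, 1]`.
#' @export
persistence <- function(trajectory, window_fraction = 0.5, l_min = 2.0,
                        delta = 2.0, min_arc = 2L) {
  stopifnot(window_fraction > 0, window_fraction <= 1, l_min > 0)
  nf <- length(trajectory$frames)
  from <- nf - ceiling(window_fraction * nf) + 1L
  win <- trajectory$frames[from:nf]
  if (length(win) < 2L)
    stop("persistence window holds fewer than 2 frames", call. = FALSE)
  lens <- vapply(win, projection_length, numeric(1),
                 delta = delta, min_arc = min_arc)
  mean(lens > l_min)
}

#' Cell area of the membrane polygon
#'
#' Absolute shoelace area of the membrane ring polygon.
#'
#' @param state A `cell_state`.
#' @return Area in sigma^2.
#' @export
cell_area <- function(state) {
  mem <- which(state$role == "MEMBRANE")
  p <- state$positions[mem, , drop = FALSE]
  if (nrow(p) < 3L) stop("need at least 3 membrane beads", call. = FALSE)
  nxt <- c(seq_len(nrow(p))[-1], 1L)
  abs(0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]))
}

#' Circularity of the membrane polygon
#'
#' `4 pi A / P^2` with `A` the shoelace area and `P` the perimeter of the
#' membrane ring polygon; 1 for a continuous circle, smaller for any
#' other shape (a regular n-gon approaches 1 from below as n grows).
#'
#' @param state A `cell_state`.
#' @return Dimensionless circularity in (0, 1].
#' @export
circularity <- function(state) {
  mem <- which(state$role == "MEMBRANE")
  p <- state$positions[mem, , drop = FALSE]
  if (nrow(p) < 3L) stop("need at least 3 membrane beads", call. = FALSE)
  nxt <- c(seq_len(nrow(p))[-1], 1L)
  a <- abs(0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]))
  per <- sum(sqrt((p[nxt, 1] - p[, 1])^2 + (p[nxt, 2] - p[, 2])^2))
  if (a < 1e-12 || per < 1e-12) stop("degenerate membrane polygon",
                                     call. = FALSE)
  4 * pi * a / per^2
}

#' Per-frame morphometrics of a trajectory
#'
#' @param trajectory A `cell_trajectory`.
#' @param delta,min_arc Protrusion detection parameters.
#' @param window_fraction,l_min Persistence parameters.
#' @return A data.frame with one row per frame (`frame_time`,
#'   `projection_length`, `n_protrusions`, `cell_area`, `circularity`);
#'   the trajectory-level `persistence_fraction` is attached as an
#'   attribute of the same name.
#' @export
measure_trajectory <- function(trajectory, delta = 2.0, min_arc = 2L,
                               window_fraction = 0.5, l_min = 2.0) {
  rows <- lapply(trajectory$frames, function(fr) {
    pr <- detect_protrusions(fr, delta, min_arc)
    data.frame(
      frame_time = fr$time,
      projection_length = if (length(pr)) {
        max(vapply(pr, `[[`, numeric(1), "length"))
      } else 0.0,
      n_protrusions = length(pr),
      cell_area = cell_area(fr),
      circularity = circularity(fr)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "persistence_fraction") <-
    persistence(trajectory, window_fraction, l_min, delta, min_arc)
  out
}
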