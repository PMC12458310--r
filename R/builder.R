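#' @useDynLib cellspring, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm sd setNames
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

ROLE_LEVELS <- c("MEMBRANE", "NUCLEUS", "ACTIN", "ACTIN_HEAD")

# offset of the filament base ring above the nuclear ring; keeps filament
# base beads outside the WCA range (2^(1/6) sigma) of nuclear beads
FILAMENT_BASE_OFFSET <- 1.15
# head beads start at the adhesion minimum, 2^(1/6) sigma inside the
# membrane ring, so the as-built head-membrane contacts carry no net force
HEAD_INSET <- 2^(1 / 6)
# protrusive filaments are stiffer than ordinary actin by this factor
PROTRUSIVE_BEND_FACTOR <- 5.0
# growth on a protrusive filament stalls while its end-to-end strut is
# compressed by more than this (sigma); bounds the polymerization push
# at kappa_fil * STALL_COMPRESSION, a stall-force analogue
STALL_COMPRESSION <- 0.12
# minimum as-built bead spacing on a ring or filament
MIN_SPACING <- 0.1
# stiffness of the intra-structure soft compression core (kT/sigma^2)
INTRA_CORE_K <- 1000

#' Assemble the initial bead-spring cell
#'
#' Places membrane and nuclear beads on concentric rings, and
#' `n_filaments` radial actin filaments (base just outside the nuclear
#' ring, head bead about one bead diameter inside the membrane ring) at
#' equal angular spacing. All spring rest lengths, bend rest angles, and
#' ring target areas are taken from the as-built geometry, so the bonded
#' and area terms of the initial state are mechanically relaxed.
#'
#' The first `protrusive_count` filaments are designated protrusive: they
#' carry a five-fold higher bending stiffness and are the ones elongated by
#' the growth schedule during a simulation (see [run_simulation()]).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `state` (a `cell_state`: positions,
#'   velocities, roles, filament ids, time) and `topology` (a
#'   `cell_topology`: stretch bonds, bend triples, nonbonded rules,
#'   exclusions, area groups).
#' @examples
#' cell <- build_cell(sim_config())
#' nrow(cell$state$positions) # 700
#' @export
build_cell <- function(cfg) {
  validate_config(cfg)
  n_mem <- cfg$n_membrane
  n_nuc <- cfg$n_nucleus
  n_fil <- cfg$n_filaments
  bpf <- cfg$beads_per_filament
  n <- total_beads(cfg)

  ring_xy <- function(nn, r) {
    th <- 2 * pi * (seq_len(nn) - 1) / nn
    cbind(r * cos(th), r * sin(th))
  }
  spacing_mem <- 2 * cfg$r_cell * sin(pi / n_mem)
  spacing_nuc <- 2 * cfg$r_nucleus * sin(pi / n_nuc)
  if (spacing_mem < MIN_SPACING * cfg$sigma)
    stop("membrane ring infeasible: bead spacing ", signif(spacing_mem, 3),
         " sigma below ", MIN_SPACING, " sigma", call. = FALSE)
  if (spacing_nuc < MIN_SPACING * cfg$sigma)
    stop("nuclear ring infeasible: bead spacing ", signif(spacing_nuc, 3),
         " sigma below ", MIN_SPACING, " sigma", call. = FALSE)

  pos <- matrix(0, n, 2)
  role <- character(n)
  fil_id <- rep(-1L, n)
  pos[seq_len(n_mem), ] <- ring_xy(n_mem, cfg$r_cell)
  role[seq_len(n_mem)] <- "MEMBRANE"
  nuc_idx <- n_mem + seq_len(n_nuc)
  pos[nuc_idx, ] <- ring_xy(n_nuc, cfg$r_nucleus)
  role[nuc_idx] <- "NUCLEUS"

  r_base <- cfg$r_nucleus + FILAMENT_BASE_OFFSET * cfg$sigma
  r_head <- cfg$r_cell - HEAD_INSET * cfg$sigma
  if (n_fil > 0L) {
    if (r_base >= r_head)
      stop("filaments infeasible: base radius ", signif(r_base, 3),
           " not inside head radius ", signif(r_head, 3), call. = FALSE)
    fil_spacing <- (r_head - r_base) / (bpf - 1)
    if (fil_spacing < MIN_SPACING * cfg$sigma)
      stop("filament infeasible: bead spacing ", signif(fil_spacing, 3),
           " sigma below ", MIN_SPACING, " sigma", call. = FALSE)
  }

  bonds <- list()
  angles <- list()
  excl <- list()
  struts <- list()
  add_bond <- function(i, j, k, r0) bonds[[length(bonds) + 1L]] <<- c(i, j, k, r0)
  add_angle <- function(i, j, k, kb, th0) {
    angles[[length(angles) + 1L]] <<- c(i, j, k, kb, th0)
  }

  # membrane ring: closed chain of stretch bonds + bend triples with the
  # regular-polygon interior angle as rest angle
  th0_mem <- pi - 2 * pi / n_mem
  for (i in seq_len(n_mem)) {
    j <- i %% n_mem + 1L
    add_bond(i, j, cfg$kappa00, spacing_mem)
    k <- j %% n_mem + 1L
    add_angle(i, j, k, cfg$kappa_bend_mem, th0_mem)
  }
  # nuclear ring: stretch bonds only (shape held by the area constraint)
  for (i in seq_len(n_nuc)) {
    j <- i %% n_nuc + 1L
    add_bond(nuc_idx[i], nuc_idx[j], cfg$kappa_nuc, spacing_nuc)
  }

  group <- integer(n)
  group[seq_len(n_mem)] <- 0L
  group[nuc_idx] <- 1L

  ofs <- n_mem + n_nuc
  for (f in seq_len(n_fil)) {
    phi <- 2 * pi * (f - 1) / n_fil
    radii <- seq(r_base, r_head, length.out = bpf)
    idx <- ofs + (f - 1L) * bpf + seq_len(bpf)
    pos[idx, ] <- cbind(radii * cos(phi), radii * sin(phi))
    role[idx] <- c(rep("ACTIN", bpf - 1L), "ACTIN_HEAD")
    fil_id[idx] <- f
    group[idx] <- 1L + f
    kb <- cfg$kappa_bend_fil *
      if (f <= cfg$protrusive_count) PROTRUSIVE_BEND_FACTOR else 1.0
    for (b in seq_len(bpf - 1L)) {
      add_bond(idx[b], idx[b + 1L], cfg$kappa_fil, fil_spacing)
      if (b < bpf - 1L) add_angle(idx[b], idx[b + 1L], idx[b + 2L], kb, pi)
    }
    # anchor: filament base to its nearest nuclear bead
    d2 <- (pos[nuc_idx, 1] - pos[idx[1], 1])^2 +
      (pos[nuc_idx, 2] - pos[idx[1], 2])^2
    anchor <- nuc_idx[which.min(d2)]
    add_bond(idx[1], anchor, cfg$kappa_fil, sqrt(min(d2)))
    excl[[length(excl) + 1L]] <- c(idx[1], anchor)
    # protrusive filaments carry an end-to-end strut: a base-to-head spring
    # at the as-built span that transmits the polymerization push along the
    # filament axis without the stiff transverse modes a very large bending
    # constant would need; growth extends its rest length
    if (f <= cfg$protrusive_count && bpf >= 3L) {
      add_bond(idx[1], idx[bpf], cfg$kappa_fil, r_head - r_base)
      struts[[length(struts) + 1L]] <- c(f, idx[1], idx[bpf])
    }
  }

  bonds <- do.call(rbind, bonds)
  bonds <- data.frame(i = as.integer(bonds[, 1]), j = as.integer(bonds[, 2]),
                      kappa = bonds[, 3], r0 = bonds[, 4])
  angles <- if (length(angles)) {
    a <- do.call(rbind, angles)
    data.frame(i = as.integer(a[, 1]), j = as.integer(a[, 2]),
               k = as.integer(a[, 3]), kb = a[, 4], theta0 = a[, 5])
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               kb = numeric(), theta0 = numeric())
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    matrix(integer(), 0, 2)
  struts <- if (length(struts)) {
    st <- do.call(rbind, struts)
    data.frame(filament = st[, 1], i = st[, 2], j = st[, 3])
  } else {
    data.frame(filament = integer(), i = integer(), j = integer())
  }

  shoelace <- function(p) {
    nn <- nrow(p)
    nxt <- c(seq_len(nn)[-1], 1L)
    0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])
  }
  topology <- structure(list(
    bonds = bonds,
    angles = angles,
    attraction = list(roles = c("ACTIN_HEAD", "MEMBRANE"),
                      u3 = cfg$u3, cutoff = 2.5 * cfg$sigma),
    exclusions = exclusions,
    struts = struts,
    group = group,
    # intra-structure soft-core range: a harmonic repulsion below the
    # native bead spacing resists local compression (bunching) that the
    # soft stretch springs alone cannot prevent
    group_core = c(spacing_mem, spacing_nuc,
                   if (n_fil > 0L) rep(fil_spacing, n_fil)),
    rings = list(membrane = seq_len(n_mem), nucleus = nuc_idx),
    ring_k = c(cfg$kappa_area, cfg$kappa_area),
    ring_a0 = c(shoelace(pos[seq_len(n_mem), , drop = FALSE]),
                shoelace(pos[nuc_idx, , drop = FALSE]))
  ), class = "cell_topology")

  state <- structure(list(
    positions = pos,
    velocities = matrix(0, n, 2),
    role = role,
    filament_id = fil_id,
    time = 0.0
  ), class = "cell_state")

  rep <- validate_cell(cfg, state, topology)
  if (length(rep) > 0L)
    stop("build_cell produced an invalid cell: ",
         paste(rep, collapse = "; "), call. = FALSE)
  list(state = state, topology = topology)
}

#' @export
print.cell_state <- function(x, ...) {
  tab <- table(factor(x$role, levels = ROLE_LEVELS))
  cat("<cell_state> ", nrow(x$positions), " beads at t = ",
      format(x$time), " tau (", paste(names(tab), tab, sep = ":",
      collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
print.cell_topology <- function(x, ...) {
  cat("<cell_topology> ", nrow(x$bonds), " stretch bonds, ",
      nrow(x$angles), " bend triples, ", length(x$rings),
      " area groups, u3 = ", x$attraction$u3, "\n", sep = "")
  invisible(x)
}

#' Check a cell state and topology against the model invariants
#'
#' Collects all violated invariants instead of raising on the first:
#' role-count closure against the configuration, finite coordinates,
#' bonded-bead separation, closed rings, per-filament bond counts,
#' duplicate bonds and index validity. Never mutates its inputs.
#'
#' @param cfg The generating [sim_config()].
#' @param state A `cell_state`.
#' @param topology A `cell_topology`.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_cell <- function(cfg, state, topology) {
  out <- character()
  say <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  n <- nrow(state$positions)

  bad <- which(!is.finite(state$positions[, 1]) |
                 !is.finite(state$positions[, 2]))
  for (b in bad) say("non-finite coordinate at bead ", b)

  counts <- table(factor(state$role, levels = ROLE_LEVELS))
  if (counts[["MEMBRANE"]] != cfg$n_membrane)
    say("membrane bead count ", counts[["MEMBRANE"]],
        " != n_membrane ", cfg$n_membrane)
  if (counts[["NUCLEUS"]] != cfg$n_nucleus)
    say("nucleus bead count ", counts[["NUCLEUS"]],
        " != n_nucleus ", cfg$n_nucleus)
  if (counts[["ACTIN_HEAD"]] != cfg$n_filaments)
    say("head bead count ", counts[["ACTIN_HEAD"]],
        " != n_filaments ", cfg$n_filaments)
  n_grown <- sum(state$filament_id > 0L) - cfg$n_filaments * cfg$beads_per_filament
  if (n_grown < 0L)
    say("filament bead count below n_filaments * beads_per_filament")

  bd <- topology$bonds
  if (any(bd$i < 1L | bd$i > n | bd$j < 1L | bd$j > n)) {
    say("bond with out-of-range bead index")
  } else {
    key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
    dup <- unique(key[duplicated(key)])
    for (d in dup) say("duplicate bond (", sub(" ", ",", d), ")")
    d2 <- (state$positions[bd$i, 1] - state$positions[bd$j, 1])^2 +
      (state$positions[bd$i, 2] - state$positions[bd$j, 2])^2
    coincident <- which(is.finite(d2) & d2 < 1e-24)
    for (b in coincident)
      say("bonded beads ", bd$i[b], " and ", bd$j[b], " at identical position")

    # ring closure: count bonds internal to each ring
    is_mem <- state$role == "MEMBRANE"
    is_nuc <- state$role == "NUCLEUS"
    n_mm <- sum(is_mem[bd$i] & is_mem[bd$j])
    n_nn <- sum(is_nuc[bd$i] & is_nuc[bd$j])
    if (n_mm != cfg$n_membrane)
      say("membrane ring not closed: ", n_mm, " membrane-membrane bonds, ",
          "expected ", cfg$n_membrane)
    if (n_nn != cfg$n_nucleus)
      say("nuclear ring not closed: ", n_nn, " nucleus-nucleus bonds, ",
          "expected ", cfg$n_nucleus)

    # per-filament: (size - 1) chain bonds (plus the end-to-end strut on
    # protrusive filaments) plus one anchor to the nucleus
    struts <- topology$struts
    for (f in seq_len(cfg$n_filaments)) {
      memb <- which(state$filament_id == f)
      on_f <- state$filament_id[bd$i] == f | state$filament_id[bd$j] == f
      internal <- sum(on_f & state$filament_id[bd$i] == state$filament_id[bd$j])
      anchor <- sum(on_f & (is_nuc[bd$i] | is_nuc[bd$j]))
      expected <- length(memb) - 1L +
        (!is.null(struts) && f %in% struts$filament)
      if (internal != expected)
        say("filament ", f, ": ", internal, " internal bonds, expected ",
            expected)
      if (anchor != 1L)
        say("filament ", f, ": ", anchor, " anchor bonds, expected 1")
      if (sum(state$role[memb] == "ACTIN_HEAD") != 1L)
        say("filament ", f, ": must carry exactly one head bead")
    }
  }

  ang <- topology$angles
  if (nrow(ang) > 0L &&
      any(ang$i < 1L | ang$i > n | ang$j < 1L | ang$j > n |
            ang$k < 1L | ang$k > n))
    say("bend triple with out-of-range bead index")

  out
}

# --- bridge to the compiled core --------------------------------------------

role_int <- function(role) {
  match(role, ROLE_LEVELS) - 1L
}

topo_to_core <- function(topology) {
  # all bonded pairs are excluded from the nonbonded terms, alongside any
  # explicit exclusions (anchors)
  excl <- rbind(topology$exclusions,
                cbind(topology$bonds$i, topology$bonds$j))
  list(
    bond_i = topology$bonds$i - 1L, bond_j = topology$bonds$j - 1L,
    bond_k = topology$bonds$kappa, bond_r0 = topology$bonds$r0,
    ang_i = topology$angles$i - 1L, ang_j = topology$angles$j - 1L,
    ang_k = topology$angles$k - 1L,
    ang_kb = topology$angles$kb, ang_th0 = topology$angles$theta0,
    group = as.integer(topology$group),
    group_core = as.numeric(if (is.null(topology$group_core)) 0 else
      topology$group_core),
    role = NULL,  # filled per call from the state
    excl_i = as.integer(excl[, 1]) - 1L, excl_j = as.integer(excl[, 2]) - 1L,
    rings = lapply(topology$rings, function(ix) as.integer(ix) - 1L),
    ring_k = topology$ring_k, ring_a0 = topology$ring_a0
  )
}

core_par <- function(cfg) {
  list(u3 = cfg$u3, eps_rep = cfg$eps_rep, sigma = cfg$sigma,
       k_core = INTRA_CORE_K)
}
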