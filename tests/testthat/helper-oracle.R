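# Test scaffolding: an independent brute-force energy oracle (pure R,
# closed forms, O(n^2) pair loop), small hand-built systems, and
# constructed membrane contours with known morphometrics.

# total potential energy computed from the exported closed-form energy
# functions; independent of the compiled force path it is used to check
oracle_energy <- function(state, topology, cfg) {
  p <- state$positions
  n <- nrow(p)
  dist_ij <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  e <- 0

  bd <- topology$bonds
  for (b in seq_len(nrow(bd)))
    e <- e + stretch_energy(dist_ij(bd$i[b], bd$j[b]), bd$kappa[b], bd$r0[b])

  ang <- topology$angles
  for (t in seq_len(nrow(ang))) {
    a <- p[ang$i[t], ] - p[ang$j[t], ]
    b2 <- p[ang$k[t], ] - p[ang$j[t], ]
    th <- atan2(abs(a[1] * b2[2] - a[2] * b2[1]), sum(a * b2))
    e <- e + bend_energy(th, ang$kb[t], ang$theta0[t])
  }

  excl <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  if (nrow(topology$exclusions) > 0L)
    excl <- c(excl, paste(pmin(topology$exclusions[, 1], topology$exclusions[, 2]),
                          pmax(topology$exclusions[, 1], topology$exclusions[, 2])))
  grp <- topology$group
  gcore <- topology$group_core
  k_core <- cellspring:::INTRA_CORE_K
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- dist_ij(i, j)
      if (grp[i] >= 0 && grp[i] == grp[j]) {
        rc <- gcore[grp[i] + 1L]
        if (rc > 0 && r < rc) e <- e + 0.5 * k_core * (r - rc)^2
        next
      }
      if (paste(min(i, j), max(i, j)) %in% excl) next
      pair <- c(state$role[i], state$role[j])
      if (cfg$u3 > 0 && "ACTIN_HEAD" %in% pair && "MEMBRANE" %in% pair) {
        e <- e + attraction_energy(r, cfg$u3, cfg$sigma)
      } else {
        e <- e + repulsion_energy(r, cfg$eps_rep, cfg$sigma)
      }
    }
  }

  for (q in seq_along(topology$rings))
    e <- e + area_energy(p[topology$rings[[q]], , drop = FALSE],
                         topology$ring_k[q], topology$ring_a0[q])
  e
}

# minimal hand-built state + topology (no build_cell involved)
make_state <- function(positions, role, velocities = NULL,
                       filament_id = NULL) {
  n <- nrow(positions)
  structure(list(
    positions = positions,
    velocities = if (is.null(velocities)) matrix(0, n, 2) else velocities,
    role = role,
    filament_id = if (is.null(filament_id)) rep(-1L, n) else filament_id,
    time = 0.0
  ), class = "cell_state")
}

make_topology <- function(n, bonds = NULL, angles = NULL, group = NULL,
                          group_core = numeric(0), rings = list(),
                          ring_k = numeric(0), ring_a0 = numeric(0),
                          exclusions = NULL, u3 = 0) {
  structure(list(
    bonds = if (is.null(bonds)) {
      data.frame(i = integer(), j = integer(), kappa = numeric(),
                 r0 = numeric())
    } else bonds,
    angles = if (is.null(angles)) {
      data.frame(i = integer(), j = integer(), k = integer(),
                 kb = numeric(), theta0 = numeric())
    } else angles,
    attraction = list(roles = c("ACTIN_HEAD", "MEMBRANE"), u3 = u3,
                      cutoff = 2.5),
    exclusions = if (is.null(exclusions)) matrix(integer(), 0, 2) else
      exclusions,
    struts = data.frame(filament = integer(), i = integer(), j = integer()),
    group = if (is.null(group)) rep(-1L, n) else group,
    group_core = group_core,
    rings = rings,
    ring_k = ring_k,
    ring_a0 = ring_a0
  ), class = "cell_topology")
}

# random small system exercising every potential term: a ring (stretch +
# bend + area + soft core), a chain ending in an adhesion head near the
# ring, and a few free beads feeling WCA
random_system <- function(seed) {
  set.seed(seed)
  nr <- sample(6:10, 1)
  spacing <- runif(1, 1.0, 1.4)
  R <- spacing / (2 * sin(pi / nr))
  th <- 2 * pi * (0:(nr - 1)) / nr
  ring <- cbind(R * cos(th), R * sin(th))

  nc <- sample(3:6, 1)
  ang <- runif(1, 0, 2 * pi)
  rr <- R + 1.2 + 0.9 * (0:(nc - 1))
  chain <- cbind(rr * cos(ang), rr * sin(ang))

  nfree <- sample(2:4, 1)
  rf <- R + 1.3 + 1.1 * (0:(nfree - 1))
  free <- cbind(rf * cos(ang + pi), rf * sin(ang + pi))

  pos <- rbind(ring, chain, free)
  n <- nrow(pos)
  pos <- pos + matrix(runif(2 * n, -0.08, 0.08), n, 2)
  role <- c(rep("MEMBRANE", nr),
            "ACTIN_HEAD", rep("ACTIN", nc - 1),  # head nearest the ring
            rep("NUCLEUS", nfree))
  group <- c(rep(0L, nr), rep(1L, nc), rep(-1L, nfree))

  bonds <- rbind(
    data.frame(i = 1:nr, j = c(2:nr, 1L),
               kappa = runif(nr, 5, 50), r0 = spacing),
    data.frame(i = nr + 1:(nc - 1), j = nr + 2:nc,
               kappa = runif(nc - 1, 5, 50), r0 = 0.9),
    # tether the chain to the ring, like a filament anchor
    data.frame(i = nr + 1L, j = 1L, kappa = 20, r0 = 1.2)
  )
  angles <- rbind(
    data.frame(i = 1:nr, j = c(2:nr, 1L), k = c(3:nr, 1L, 2L),
               kb = runif(nr, 1, 10), theta0 = pi - 2 * pi / nr),
    if (nc >= 3) data.frame(i = nr + 1:(nc - 2), j = nr + 2:(nc - 1),
                            k = nr + 3:nc,
                            kb = runif(nc - 2, 1, 10), theta0 = pi)
  )
  shoe <- function(p) {
    nn <- nrow(p); nxt <- c(seq_len(nn)[-1], 1L)
    0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])
  }
  topo <- make_topology(
    n, bonds = bonds, angles = angles, group = group,
    group_core = c(spacing, 0.9),
    rings = list(1:nr), ring_k = runif(1, 5, 50),
    ring_a0 = shoe(pos[1:nr, , drop = FALSE]) * runif(1, 0.9, 1.1),
    u3 = runif(1, 0.5, 5))
  cfg <- sim_config(u3 = topo$attraction$u3)
  list(state = make_state(pos, role), topology = topo, cfg = cfg)
}

# circular membrane contour, optionally with radial "fingers"
circle_state <- function(n = 40, radius = 10, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1)) / n
  make_state(cbind(center[1] + radius * cos(th),
                   center[2] + radius * sin(th)),
             role = rep("MEMBRANE", n))
}

# push beads `which` of a circle contour radially out to `r_out`
add_finger <- function(state, which, r_out, center = c(0, 0)) {
  p <- state$positions
  for (b in which) {
    d <- p[b, ] - center
    p[b, ] <- center + d / sqrt(sum(d^2)) * r_out
  }
  state$positions <- p
  state
}

rotate_state <- function(state, phi) {
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  state$positions <- state$positions %*% rot
  state
}

# trajectory stub from a list of frames (for morphometrics-level tests)
traj_stub <- function(frames) {
  structure(list(frames = frames,
                 times = seq_along(frames) - 1,
                 energies = NULL, events = NULL, config = NULL),
            class = "cell_trajectory")
}

# finite-difference force check against the oracle; returns worst
# relative deviation over `n_beads` sampled beads
fd_worst <- function(sys, n_beads = 8, h = 1e-6) {
  f <- compute_forces(sys$state, sys$topology, sys$cfg)$forces
  n <- nrow(sys$state$positions)
  beads <- if (n <= n_beads) seq_len(n) else sort(sample(n, n_beads))
  worst <- 0
  for (b in beads) {
    for (d in 1:2) {
      s1 <- sys$state; s1$positions[b, d] <- s1$positions[b, d] + h
      s2 <- sys$state; s2$positions[b, d] <- s2$positions[b, d] - h
      fd <- -(oracle_energy(s1, sys$topology, sys$cfg) -
                oracle_energy(s2, sys$topology, sys$cfg)) / (2 * h)
      worst <- max(worst, abs(fd - f[b, d]) / max(1, abs(fd)))
    }
  }
  worst
}
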