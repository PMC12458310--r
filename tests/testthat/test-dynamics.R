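small_cfg <- function(...) {
  sim_config(n_membrane = 40, n_nucleus = 12, n_filaments = 4,
             beads_per_filament = 5, r_cell = 6, r_nucleus = 1.8, ...)
}

test_that("overdamped step is deterministic drift at zero temperature", {
  st <- make_state(rbind(c(0, 0)), role = "ACTIN")
  adv <- step_overdamped(st, matrix(c(1, 0), 1, 2), dt = 1e-3, kT = 0)
  expect_equal(adv$positions[1, ], c(1e-3, 0))
  expect_equal(adv$time, 1e-3)
  same <- step_overdamped(st, matrix(0, 1, 2), dt = 1e-3, kT = 0)
  expect_equal(same$positions, st$positions)
})

test_that("free diffusion recovers the 2D Einstein relation", {
  # 1000 independent force-free beads; MSD slope should be 4 kT / gamma
  set.seed(20240917)
  n <- 1000L
  st <- make_state(matrix(0, n, 2), role = rep("ACTIN", n))
  zero_f <- matrix(0, n, 2)
  nstep <- 10000L
  keep <- seq(100L, nstep, by = 100L)
  msd <- numeric(length(keep))
  k <- 1L
  for (s in seq_len(nstep)) {
    st <- step_overdamped(st, zero_f, dt = 1e-3, gamma = 1, kT = 1)
    if (s == keep[k]) {
      msd[k] <- mean(rowSums(st$positions^2))
      if (k < length(keep)) k <- k + 1L
    }
  }
  tt <- keep * 1e-3
  slope <- sum(msd * tt) / sum(tt * tt)  # regression through the origin
  expect_lt(abs(slope - 4) / 4, 0.05)
})

test_that("velocity Verlet reproduces the harmonic oscillator period", {
  # two unit-mass beads, kappa = 0.5 => reduced mass 1/2, omega = 1
  st <- make_state(rbind(c(0, 0), c(2.4, 0)), role = c("ACTIN", "ACTIN"))
  topo <- make_topology(2, bonds = data.frame(i = 1, j = 2, kappa = 0.5,
                                              r0 = 2))
  cfg <- sim_config()
  dt <- 1e-3
  # measure the period from zero crossings of (separation - r0)
  core_traj <- numeric(0)
  s <- st
  for (chunk in 1:200) {
    res <- run_nve(s, topo, cfg, n_steps = 100L, dt = dt, save_every = 10L)
    s <- res$state
    core_traj <- c(core_traj, sqrt(sum((s$positions[1, ] - s$positions[2, ])^2)))
  }
  tt <- (1:200) * 100 * dt
  x <- core_traj - 2
  cross <- which(x[-1] * x[-length(x)] < 0)
  t_cross <- tt[cross] - x[cross] * (tt[cross + 1] - tt[cross]) /
    (x[cross + 1] - x[cross])
  period <- 2 * mean(diff(t_cross))
  expect_lt(abs(period - 2 * pi) / (2 * pi), 1e-3)
})

test_that("NVE conserves total energy and leaves a relaxed cell static", {
  cfg <- sim_config(n_membrane = 40, n_nucleus = 12, n_filaments = 0,
                    protrusive_count = 0L, r_cell = 6, r_nucleus = 1.8)
  cell <- build_cell(cfg)
  # no filaments: the as-built state is a true mechanical equilibrium
  res <- run_nve(cell$state, cell$topology, cfg, n_steps = 50L, dt = 1e-3)
  expect_equal(res$state$positions, cell$state$positions, tolerance = 1e-12)

  # thermalized full cell drifts by less than 1e-4 relative energy
  cfg2 <- small_cfg()
  cell2 <- build_cell(cfg2)
  set.seed(5)
  cell2$state$velocities <- matrix(rnorm(2 * nrow(cell2$state$positions)),
                                   ncol = 2)
  res2 <- run_nve(cell2$state, cell2$topology, cfg2, n_steps = 10000L,
                  dt = 1e-4, save_every = 100L)
  e <- res2$energy$total
  e0 <- sum(0.5 * rowSums(cell2$state$velocities^2)) +
    compute_forces(cell2$state, cell2$topology, cfg2)$energies$total
  expect_lt(max(abs(e - e0)) / abs(e0), 1e-4)
})

test_that("growth inserts a midpoint bead, rewires bonds and extends the strut", {
  cfg <- small_cfg(protrusive_count = 1L, grow_max = 10L)
  cell <- build_cell(cfg)
  st <- cell$state
  topo <- cell$topology
  n0 <- nrow(st$positions)
  b0 <- nrow(topo$bonds)
  srow <- which(topo$bonds$i == topo$struts$i[1] &
                  topo$bonds$j == topo$struts$j[1])
  strut_r0 <- topo$bonds$r0[srow]
  h <- which(st$role == "ACTIN_HEAD" & st$filament_id == 1L)
  fil <- which(st$filament_id == 1L & st$role == "ACTIN")
  gap0 <- min(sqrt((st$positions[fil, 1] - st$positions[h, 1])^2 +
                     (st$positions[fil, 2] - st$positions[h, 2])^2))
  nb <- fil[which.min(sqrt((st$positions[fil, 1] - st$positions[h, 1])^2 +
                             (st$positions[fil, 2] - st$positions[h, 2])^2))]

  g <- grow_protrusive_filament(st, topo, cfg, time = 1)
  expect_false(any(g$events$skipped))
  expect_identical(nrow(g$state$positions), n0 + 1L)
  expect_identical(nrow(g$topology$bonds), b0 + 1L)
  new <- n0 + 1L
  expect_equal(g$state$positions[new, ],
               (st$positions[h, ] + st$positions[nb, ]) / 2)
  # strut rest span grew by one segment rest length
  srow2 <- which(g$topology$bonds$i == g$topology$struts$i[1] &
                   g$topology$bonds$j == g$topology$struts$j[1])
  expect_gt(g$topology$bonds$r0[srow2], strut_r0)
  # inserted bead sits within the pre-insertion head gap of both neighbours
  d_new <- sqrt((g$state$positions[c(h, nb), 1] - g$state$positions[new, 1])^2 +
                  (g$state$positions[c(h, nb), 2] - g$state$positions[new, 2])^2)
  expect_true(all(d_new <= gap0))
  # immediately repeated growth stalls while the strut is still compressed
  g2 <- grow_protrusive_filament(g$state, g$topology, cfg, time = 2)
  expect_true(all(g2$events$skipped))
})

test_that("three scheduled growth events add three beads and three bonds", {
  cfg <- sim_config(n_membrane = 40, n_nucleus = 12, n_filaments = 4,
                    beads_per_filament = 10, r_cell = 6, r_nucleus = 1.8,
                    n_steps = 2500L, save_every = 500L, dt = 2e-4,
                    grow_interval = 0.1, grow_max = 3L, seed = 9L)
  cell0 <- build_cell(cfg)
  traj <- run_simulation(cfg)
  expect_identical(sum(!traj$events$skipped), 3L)
  expect_identical(nrow(traj$frames[[length(traj$frames)]]$positions),
                   nrow(cell0$state$positions) + 3L)
  expect_identical(nrow(traj$topology$bonds),
                   nrow(cell0$topology$bonds) + 3L)
})

test_that("growth is inert when grow_max is zero", {
  cfg <- small_cfg(protrusive_count = 1L, grow_max = 0L)
  cell <- build_cell(cfg)
  g <- grow_protrusive_filament(cell$state, cell$topology, cfg, time = 1)
  expect_identical(g$topology$bonds, cell$topology$bonds)
  expect_identical(nrow(g$state$positions), nrow(cell$state$positions))
  traj <- run_simulation(small_cfg(n_steps = 300L, save_every = 100L,
                                   grow_max = 0L, seed = 3L))
  expect_identical(nrow(traj$frames[[length(traj$frames)]]$positions),
                   nrow(traj$frames[[1]]$positions))
})

test_that("identical config and seed give bit-identical trajectories", {
  cfg <- small_cfg(n_steps = 400L, save_every = 100L, seed = 42L,
                   grow_interval = 0.02, grow_max = 3L)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$frames[[length(t1$frames)]]$positions,
                   t2$frames[[length(t2$frames)]]$positions)
  expect_identical(t1$energies, t2$energies)
  expect_identical(t1$events, t2$events)
})

test_that("zero-temperature dynamics descend the potential monotonically", {
  cfg <- small_cfg(kT = 0, n_steps = 1000L, save_every = 50L, dt = 2e-4,
                   grow_max = 0L)
  traj <- run_simulation(cfg)
  e <- traj$energies$total
  expect_true(all(diff(e) <= 1e-9))
})

test_that("trajectory frames carry strictly increasing times from the as-built cell", {
  cfg <- small_cfg(n_steps = 300L, save_every = 100L, seed = 2L)
  traj <- run_simulation(cfg)
  expect_identical(traj$times[1], 0)
  expect_true(all(diff(traj$times) > 0))
  expect_equal(traj$frames[[1]]$positions, build_cell(cfg)$state$positions)
})
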