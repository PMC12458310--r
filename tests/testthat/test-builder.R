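test_that("default build has 700 beads and passes validation", {
  cell <- build_cell(sim_config())
  expect_identical(nrow(cell$state$positions), 700L)
  expect_identical(sum(cell$state$role == "ACTIN_HEAD"), 19L)
  expect_length(validate_cell(sim_config(), cell$state, cell$topology), 0)
})

test_that("tiny architecture yields the expected bond bookkeeping", {
  cfg <- sim_config(n_membrane = 6, n_nucleus = 3, n_filaments = 1,
                    beads_per_filament = 2, r_cell = 6, r_nucleus = 1.5)
  cell <- build_cell(cfg)
  st <- cell$state
  bd <- cell$topology$bonds
  expect_identical(nrow(st$positions), 11L)
  is_mem <- st$role == "MEMBRANE"
  is_nuc <- st$role == "NUCLEUS"
  expect_identical(sum(is_mem[bd$i] & is_mem[bd$j]), 6L)
  expect_identical(sum(is_nuc[bd$i] & is_nuc[bd$j]), 3L)
  on_f <- st$filament_id[bd$i] == 1L | st$filament_id[bd$j] == 1L
  expect_identical(sum(on_f), 2L)  # one chain bond + one anchor
})

test_that("as-built bonded and area terms are machine-relaxed", {
  cell <- build_cell(sim_config())
  e <- compute_forces(cell$state, cell$topology, sim_config())$energies
  expect_lt(abs(e$stretch), 1e-9)
  expect_lt(abs(e$bend), 1e-9)
  expect_lt(abs(e$area), 1e-9)
  # total equals the nonbonded tail recomputed by the brute-force oracle
  expect_equal(e$total,
               oracle_energy(cell$state, cell$topology, sim_config()),
               tolerance = 1e-10)
})

test_that("as-built cell is invariant under rotation by the filament angle", {
  cfg <- sim_config(n_membrane = 40, n_nucleus = 10, n_filaments = 5,
                    beads_per_filament = 4)
  cell <- build_cell(cfg)
  p <- cell$state$positions
  phi <- 2 * pi / 5
  # column-major fill: this matrix rotates row vectors by +phi
  rot <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  pr <- p %*% rot
  # rotation maps each structure onto itself with a fixed index shift
  perm <- c(((0:39 + 8) %% 40) + 1L,                        # membrane
            40L + ((0:9 + 2) %% 10) + 1L,                   # nucleus
            50L + (((0:19) + 4L) %% 20L) + 1L)              # filament beads
  expect_equal(pr, p[perm, ], tolerance = 1e-12)
})

test_that("infeasible ring spacing is rejected naming the component", {
  expect_error(build_cell(sim_config(n_membrane = 800)), "membrane ring")
  expect_error(build_cell(sim_config(n_nucleus = 600)), "nuclear ring")
  expect_error(build_cell(sim_config(r_nucleus = 10, r_cell = 12)),
               "filament")
})

test_that("validate_cell reports duplicated bonds and non-finite coordinates", {
  cfg <- sim_config(n_membrane = 12, n_nucleus = 6, n_filaments = 2,
                    beads_per_filament = 4, r_cell = 8, r_nucleus = 2)
  cell <- build_cell(cfg)
  broken <- cell$topology
  broken$bonds <- rbind(broken$bonds, broken$bonds[1, ])
  rep1 <- validate_cell(cfg, cell$state, broken)
  expect_true(any(grepl("duplicate bond \\(1,2\\)", rep1)))

  st <- cell$state
  st$positions[5, 1] <- NaN
  rep2 <- validate_cell(cfg, st, cell$topology)
  expect_true(any(grepl("non-finite coordinate at bead 5", rep2)))
  # inputs were not mutated
  expect_length(validate_cell(cfg, cell$state, cell$topology), 0)
})
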