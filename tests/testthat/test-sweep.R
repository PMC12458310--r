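tiny_base <- function() {
  sim_config(n_membrane = 40, n_nucleus = 12, n_filaments = 4,
             beads_per_filament = 5, r_cell = 6, r_nucleus = 1.8,
             n_steps = 200L, save_every = 50L, dt = 2e-4,
             grow_interval = 0.01, grow_max = 2L)
}

test_that("sweep bookkeeping: one row per grid point and replicate", {
  spec <- sweep_spec(tiny_base(), u3_values = c(1, 5),
                     kappa00_values = 10, replicates = 3L, root_seed = 7L)
  rows <- run_sweep(spec)
  expect_identical(nrow(rows), 6L)
  expect_identical(rows$seed, rep(7:9, 2))
  expect_true(all(rows$proj_mean >= 0))
  expect_true(all(rows$persistence >= 0 & rows$persistence <= 1))

  rows2 <- run_sweep(spec)
  expect_identical(rows, rows2)
})

test_that("summaries report mean and SEM per grid point, order-invariantly", {
  rows <- data.frame(u3 = c(1, 1, 2, 2), kappa00 = 10, seed = 1:4,
                     proj_mean = c(2, 4, 5, 5), proj_final = 0,
                     proj_max = 0, persistence = 0)
  s <- summarize_sweep(rows)
  expect_equal(s$mean, c(3, 5))
  expect_equal(s$sem, c(1, 0))
  expect_identical(s$n, c(2L, 2L))
  s2 <- summarize_sweep(rows[c(3, 1, 4, 2), ])
  expect_equal(s, s2)
  expect_message(summarize_sweep(rows[c(1, 3, 4), ]), "single-replicate")
})

test_that("shipped presets encode the published grid points", {
  a <- preset_adhesion_scan()
  expect_identical(a$kappa00_values, 10)
  expect_true(all(c(3.0, 30.0) %in% a$u3_values))
  expect_gte(a$replicates, 5L)
  expect_identical(total_beads(a$base_config), 700L)
  expect_lte(max(a$base_config$n_steps * a$base_config$dt /
                   cellspring:::stable_dt(a$base_config$dt,
                                          max(a$u3_values), 10)), 2e5)

  b <- preset_tension_contrast()
  expect_identical(b$u3_values, c(3.0, 30.0))
  expect_identical(b$kappa00_values, 500)
  expect_identical(total_beads(b$base_config), 700L)

  # the same presets ship as YAML config files
  for (nm in c("adhesion_scan", "tension_contrast")) {
    path <- system.file("presets", paste0(nm, ".yaml"),
                        package = "cellspring")
    expect_true(nzchar(path))
    spec <- read_sweep_spec(path)
    ref <- if (nm == "adhesion_scan") a else b
    expect_equal(spec$u3_values, ref$u3_values)
    expect_equal(spec$kappa00_values, ref$kappa00_values)
    expect_equal(unclass(spec$base_config), unclass(ref$base_config))
  }
})

test_that("a failing grid point aborts with its coordinates in the message", {
  base <- tiny_base()
  base$r_nucleus <- 0.05  # infeasible nuclear ring: the build must fail
  spec <- sweep_spec(base, u3_values = 2, kappa00_values = 10,
                     replicates = 1L)
  expect_error(run_sweep(spec), "sweep failed at u3 = 2")
})
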