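test_that("radial profile is translation invariant and tracks displaced beads", {
  st <- circle_state(n = 40, radius = 10)
  expect_equal(radial_profile(st), rep(10, 40))
  st2 <- circle_state(n = 40, radius = 10, center = c(7, -3))
  expect_equal(radial_profile(st2), rep(10, 40))
  st3 <- add_finger(circle_state(50, 10), which = 8, r_out = 16)
  r <- radial_profile(st3)
  # the centroid moves slightly when one bead moves, so compare loosely
  expect_equal(r[8], 16, tolerance = 0.2)
  expect_equal(median(r), 10, tolerance = 0.05)
})

test_that("protrusion detection finds constructed fingers and nothing on circles", {
  expect_length(detect_protrusions(circle_state(60, 10)), 0)
  expect_identical(projection_length(circle_state(60, 10)), 0)

  # single 5-bead finger pushed from R0 = 10 to 16 (centroid held fixed by
  # a symmetric counter-finger far on the other side would shift it; use
  # many beads so the centroid shift is negligible)
  st <- add_finger(circle_state(240, 10), which = 30:34, r_out = 16)
  pr <- detect_protrusions(st)
  expect_length(pr, 1)
  expect_identical(pr[[1]]$arc, 30:34)
  expect_equal(pr[[1]]$length, 6, tolerance = 0.15)
  expect_true(pr[[1]]$tip_index %in% 30:34)

  # two separated fingers, to 15 and 18
  st2 <- add_finger(add_finger(circle_state(240, 10), 10:13, 15), 100:104, 18)
  pr2 <- detect_protrusions(st2)
  expect_length(pr2, 2)
  expect_equal(max(vapply(pr2, `[[`, numeric(1), "length")), 8,
               tolerance = 0.15)
})

test_that("arcs wrapping the ring origin are detected as one protrusion", {
  st <- add_finger(circle_state(120, 10), which = c(118:120, 1:3), r_out = 15)
  pr <- detect_protrusions(st)
  expect_length(pr, 1)
  expect_length(pr[[1]]$arc, 6)
  expect_setequal(pr[[1]]$arc, c(118:120, 1:3))
})

test_that("min_arc suppresses single-bead spikes", {
  st <- add_finger(circle_state(120, 10), which = 17, r_out = 16)
  expect_length(detect_protrusions(st, min_arc = 2L), 0)
  expect_length(detect_protrusions(st, min_arc = 1L), 1)
})

test_that("projection length is invariant under rigid rotation and monotone in tip height", {
  st <- add_finger(circle_state(240, 10), which = 30:34, r_out = 16)
  l0 <- projection_length(st)
  expect_equal(projection_length(rotate_state(st, 1.234)), l0,
               tolerance = 1e-12)
  lens <- vapply(c(13, 14.5, 16, 18),
                 function(r) projection_length(
                   add_finger(circle_state(240, 10), 30:34, r)), numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("detected arcs are disjoint and above threshold", {
  set.seed(8)
  st <- circle_state(180, 10)
  st$positions <- st$positions * (1 + 0.05 * rnorm(180))
  st <- add_finger(st, 20:26, 15)
  st <- add_finger(st, 90:93, 14)
  pr <- detect_protrusions(st, delta = 2, min_arc = 2L)
  arcs <- unlist(lapply(pr, `[[`, "arc"))
  expect_identical(anyDuplicated(arcs), 0L)
  r <- radial_profile(st)
  expect_true(all(r[arcs] > median(r) + 2))
})

test_that("persistence counts supra-threshold frames in the final window", {
  circ <- circle_state(60, 10)
  fing <- add_finger(circle_state(60, 10), 5:8, 15)
  expect_identical(persistence(traj_stub(rep(list(circ), 8))), 0)
  expect_identical(persistence(traj_stub(rep(list(fing), 8))), 1)
  alt <- rep(list(circ, fing), 4)
  expect_equal(persistence(traj_stub(alt)), 0.5)
  expect_error(persistence(traj_stub(list(circ))), "fewer than 2")
})

test_that("circularity matches closed-form polygon values", {
  # regular 240-gon
  n <- 240
  R <- 12
  a <- 0.5 * n * R^2 * sin(2 * pi / n)
  p <- n * 2 * R * sin(pi / n)
  st <- circle_state(n, R)
  expect_equal(circularity(st), 4 * pi * a / p^2, tolerance = 1e-9)
  # square
  sq <- make_state(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                   role = rep("MEMBRANE", 4))
  expect_equal(circularity(sq), pi / 4)
  expect_equal(circularity(rotate_state(sq, 0.7)), pi / 4)
  expect_lt(circularity(st), 1)
})

test_that("measure_trajectory emits one row per frame plus persistence", {
  fing <- add_finger(circle_state(60, 10), 5:8, 15)
  frames <- list(circle_state(60, 10), fing, fing, fing)
  m <- measure_trajectory(traj_stub(frames))
  expect_identical(nrow(m), 4L)
  expect_named(m, c("frame_time", "projection_length", "n_protrusions",
                    "cell_area", "circularity"))
  expect_equal(m$projection_length[1], 0)
  expect_gt(m$projection_length[2], 2)
  expect_equal(m$projection_length[2], m$projection_length[4])
  expect_equal(attr(m, "persistence_fraction"), 1)
})
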