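test_that("the parameter schedule reproduces its endpoints and midpoint", {
  cfg <- grbf_config()
  expect_equal(cfg$n_iterations, 30L)
  p1 <- schedule_params(1, cfg)
  expect_identical(c(p1$k1, p1$k2), c(1.0, 3.0))
  expect_identical(p1$nc, 10L)
  p30 <- schedule_params(30, cfg)
  expect_identical(c(p30$k1, p30$k2), c(1.5, 1.5))
  expect_identical(p30$nc, 15L)
  p15 <- schedule_params(15, cfg)
  expect_equal(p15$k1, 1 + 0.5 * 14 / 29, tolerance = 1e-12)
  expect_equal(p15$k2, 3 - 1.5 * 14 / 29, tolerance = 1e-12)
  expect_error(schedule_params(0, cfg), "iteration")
  expect_error(schedule_params(31, cfg), "iteration")
  # alternative center-count reading
  pw <- schedule_params(30, grbf_config(nc_mode = "power"))
  expect_identical(pw$nc, as.integer(round(10^1.5)))
})

test_that("farthest-point sampling is deterministic and spreads points", {
  ico <- icosphere(5, 2)
  c1 <- select_centers(ico, 12, seed = 7)
  c2 <- select_centers(ico, 12, seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(c1, select_centers(ico, 12, seed = 8)))
  all_v <- select_centers(ico, nrow(ico$vertices), seed = 0)
  expect_equal(nrow(all_v), nrow(ico$vertices))
  expect_equal(nrow(unique(all_v)), nrow(ico$vertices))
  expect_error(select_centers(ico, nrow(ico$vertices) + 1), "n_centers")

  # 4 corners of a unit square: any start, the 2 centers are a diagonal
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  for (seed in 0:7) {
    ctr <- select_centers(sq, 2, seed = seed)
    expect_equal(sqrt(sum((ctr[1, ] - ctr[2, ])^2)), sqrt(2), tolerance = 1e-12)
  }
})

test_that("the Gaussian warp evaluates its kernel exactly", {
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  ctr <- matrix(c(0, 0, 0), 1, 3)
  w <- matrix(c(1, 2, -1), 1, 3)
  expect_identical(grbf_warp(pts, ctr, matrix(0, 1, 3), 5), pts)
  warped <- grbf_warp(matrix(c(0, 0, 0), 1, 3), ctr, w, 5)
  expect_equal(drop(warped), c(1, 2, -1), tolerance = 1e-12)
  at_gamma <- grbf_warp(matrix(c(5, 0, 0), 1, 3), ctr, w, 5)
  disp <- drop(at_gamma) - c(5, 0, 0)
  expect_equal(sqrt(sum(disp^2)), sqrt(6) * exp(-1), tolerance = 1e-12)
  expect_error(grbf_warp(pts, ctr, w, 0), "gamma")
})

test_that("registration recovers identity, translation and dilation", {
  ico <- icosphere(10, 3)
  st_id <- register_pair(ico, ico)
  expect_lte(rev(st_id$d_mean_trace)[1], 0.1)
  expect_lte(mean(sqrt(rowSums(st_id$displacement^2))), 0.1)

  st_tr <- register_pair(ico, translate_mesh(ico, c(2, 0, 0)))
  mean_disp <- mean(sqrt(rowSums(st_tr$displacement^2)))
  expect_equal(mean_disp, 2.0, tolerance = 0.1)  # 2.0 +/- 0.2 band

  st_dil <- register_pair(ico, icosphere(11, 3))
  expect_equal(mean(sqrt(rowSums(st_dil$displacement^2))), 1.0,
               tolerance = 0.2)

  for (st in list(st_id, st_tr, st_dil)) {
    expect_length(st$d_mean_trace, 30L)
    expect_lte(rev(st$d_mean_trace)[1], st$d_mean_trace[1])
  }
})

test_that("registration is bit-reproducible for fixed inputs and seed", {
  ico <- icosphere(8, 2)
  tgt <- translate_mesh(icosphere(8.5, 2), c(1, 0.5, 0))
  s1 <- register_pair(ico, tgt)
  s2 <- register_pair(ico, tgt)
  expect_identical(s1$warped_vertices, s2$warped_vertices)
  expect_identical(s1$d_mean_trace, s2$d_mean_trace)
  expect_identical(s1$weights, s2$weights)
})

test_that("the realized warp is smooth (bounded displacement gradient along edges)", {
  ico <- icosphere(10, 3)
  tgt <- translate_mesh(icosphere(10.7, 3), c(1.5, 0, 0))
  st <- register_pair(ico, tgt)
  e <- unique(rbind(ico$faces[, 1:2], ico$faces[, 2:3], ico$faces[, c(3, 1)]))
  dl <- sqrt(rowSums((ico$vertices[e[, 1], ] - ico$vertices[e[, 2], ])^2))
  dd <- sqrt(rowSums((st$displacement[e[, 1], ] - st$displacement[e[, 2], ])^2))
  # the spec's 0.1 mm -> < 0.5 mm bound is Lipschitz constant 4 on top of identity
  expect_lt(max(dd / dl), 4)
})

test_that("per-vertex displacement error stays below half a voxel on a moving phantom", {
  sp <- small_phantom_spec()
  ph <- generate_phantom(sp)
  ref <- extract_surface(ph$series, 0)
  m2 <- extract_surface(ph$series, 2)  # systolic peak of the small phantom
  st <- register_pair(ref, m2, grbf_config(gamma_floor_mm = 2 * sp$spacing_mm))
  # analytic ground truth at each reference vertex: rigid + radial term
  w <- radius_waveform(2, sp)
  gt <- sweep(sp$amp_mm * w * ref$normals, 2, sp$trans_mm * w, `+`)
  err <- st$displacement - gt
  expect_lt(mean(sqrt(rowSums(err^2))), 0.5 * sp$spacing_mm)
})

test_that("config validation and alternative modes work", {
  expect_error(grbf_config(n_iterations = 0), "n_iterations")
  expect_error(grbf_config(gamma_floor_mm = 0), "gamma_floor_mm")
  expect_error(grbf_config(damping = -1), "damping")
  ico <- icosphere(8, 2)
  tgt <- translate_mesh(ico, c(1, 0, 0))
  for (cfg in list(grbf_config(gamma_mode = "adaptive"),
                   grbf_config(gamma_mode = "inverse"),
                   grbf_config(prealign = "none"),
                   grbf_config(nc_mode = "power"))) {
    st <- register_pair(ico, tgt, cfg)
    expect_true(all(is.finite(st$warped_vertices)))
    expect_lte(rev(st$d_mean_trace)[1], st$d_mean_trace[1] + 1e-9)
  }
})

test_that("the convergence trace exports as CSV", {
  ico <- icosphere(6, 2)
  st <- register_pair(ico, translate_mesh(ico, c(1, 0, 0)))
  f <- tempfile(fileext = ".csv")
  write_registration_trace(st, f)
  tr <- read.csv(f)
  expect_equal(nrow(tr), 30L)
  expect_named(tr, c("iteration", "nc", "k1", "k2", "gamma_mm", "d_mean"))
  unlink(f)
})
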