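fake_state <- function(reference, warped) {
  disp <- if (nrow(warped) == nrow(reference$vertices))
    warped - reference$vertices else matrix(0, nrow(warped), 3L)
  structure(list(warped_vertices = warped, displacement = disp,
                 d_mean_trace = 0, trace = NULL, config = NULL),
            class = "registration_state")
}

test_that("displacement maps are Euclidean distances per vertex", {
  ico <- icosphere(5, 1)
  shifted <- sweep(ico$vertices, 2, c(3, 4, 0), `+`)
  m <- displacement_map(ico, fake_state(ico, shifted), phase = 3L)
  expect_true(all(abs(m$values - 5) < 1e-12))
  expect_true(all(m$valid))
  expect_equal(m$phase, 3L)

  m0 <- displacement_map(ico, fake_state(ico, ico$vertices), phase = 1L)
  expect_true(all(m0$values == 0))

  bad <- fake_state(ico, shifted[-1, ])
  expect_error(displacement_map(ico, bad, 1), "vertex counts")
})

test_that("diameter by inward-normal ray casting matches spheres and cylinders", {
  ico <- icosphere(10, 3)
  dm <- diameter_map(ico)
  expect_true(all(dm$valid))
  expect_lt(max(abs(dm$values - 20)), 0.2)

  cyl <- cylinder_mesh(radius = 10, length = 60, n_theta = 96, n_z = 40)
  dmc <- diameter_map(cyl)
  mid <- abs(cyl$vertices[, 3] - 30) < 10 & dmc$valid
  expect_gt(sum(mid), 100)
  expect_lt(max(abs(dmc$values[mid] - 20)), 0.3)

  expect_error(diameter_map(surface_mesh(ico$vertices, ico$faces)), "normals")
})

test_that("rays escaping an open region are flagged invalid", {
  ico <- icosphere(10, 3)
  keep <- ico$vertices[, 3] > 2   # open bowl, rim at z = 2
  fkeep <- keep[ico$faces[, 1]] & keep[ico$faces[, 2]] & keep[ico$faces[, 3]]
  newid <- cumsum(keep)
  bowl <- surface_mesh(ico$vertices[keep, ], matrix(newid[ico$faces[fkeep, ]], ncol = 3))
  bowl$normals <- ico$normals[keep, ]  # radial normals kept from the sphere
  dm <- diameter_map(bowl, max_ray_mm = 60)
  expect_true(any(!dm$valid))          # rays through the opening miss
  expect_true(all(dm$values[dm$valid] > 0))
})

test_that("diameter transfer matches dilation and keeps percent consistency", {
  ref <- icosphere(10, 3)
  tgt <- icosphere(10.7, 3)
  st <- register_pair(ref, tgt)
  ref_d <- diameter_map(ref)
  tgt_d <- diameter_map(tgt, phase = 5L)
  tx <- transfer_diameter(ref_d, st, tgt, tgt_d)
  ok <- tx$change$valid
  expect_gt(mean(ok), 0.95)
  expect_equal(mean(tx$change$values[ok]), 1.4, tolerance = 0.3 / 1.4)
  both <- tx$change$valid & tx$change_pct$valid
  expect_lt(max(abs(tx$change_pct$values[both] -
                      100 * tx$change$values[both] / ref_d$values[both])), 1e-9)
  expect_equal(tx$change$phase, 5L)

  # zero deformation on identical meshes -> change 0
  st0 <- register_pair(ref, ref)
  tx0 <- transfer_diameter(ref_d, st0, ref, diameter_map(ref))
  expect_lt(max(abs(tx0$change$values[tx0$change$valid])), 0.05)
})

test_that("percent change follows plain arithmetic", {
  # reference diameter 25.0, change 1.4 -> 5.6%
  ref_d <- vertex_map(rep(25, 5), kind = "diameter")
  chg <- 1.4
  expect_equal(100 * chg / 25, 5.6, tolerance = 1e-12)
})

test_that("roi_select implements the closed static box on supplied positions", {
  pos <- rbind(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5), c(2, 2, 2))
  map <- vertex_map(c(1, 2, 6, 3), valid = c(TRUE, TRUE, TRUE, FALSE),
                    kind = "displacement")
  roi <- roi_box(c(-1, -1, -1), c(2.5, 2.5, 2.5))
  sel <- roi_select(map, pos, roi)
  expect_equal(sel$values, c(1, 2))       # vertex 4 inside but invalid
  expect_equal(sum(sel$inside), 3)
  expect_error(roi_select(map, pos, roi_box(c(50, 50, 50), c(60, 60, 60))),
               "empty ROI")
  expect_error(roi_box(c(0, 0, 0), c(1, -1, 1)), "strictly")
})

test_that("phase curves aggregate valid ROI values with mean and max", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  roi <- roi_box(c(-1, -1, -1), c(2, 2, 2))
  mk <- function(vals, kind, phase = 0L, valid = rep(TRUE, length(vals)))
    vertex_map(vals, valid, phase, kind)
  maps <- list(
    displacement = list(mk(c(0, 0, 0), "displacement", 0L),
                        mk(c(1, 2, 6), "displacement", 1L)),
    diameter = list(mk(c(20, 20, 20), "diameter", 0L),
                    mk(c(21, 21, 21), "diameter", 1L)),
    change = list(mk(c(0, 0, 0), "diameter_change", 0L),
                  mk(c(1, 1, 1), "diameter_change", 1L)),
    change_pct = list(mk(c(0, 0, 0), "diameter_change_pct", 0L),
                      mk(c(5, 5, 5), "diameter_change_pct", 1L)),
    reference_positions = pos,
    diameter_positions = list(pos, pos))
  cv <- phase_curves(maps, roi)
  expect_equal(cv$mean_displacement_mm, c(0, 3))
  expect_equal(cv$max_displacement_mm, c(0, 6))
  expect_equal(cv$mean_diameter_mm, c(20, 21))
  expect_equal(cv$mean_diameter_change_mm, c(0, 1))
  expect_equal(attr(cv, "reference_phase"), 0L)

  # invalid values are excluded, and an all-invalid ROI phase errors
  maps$displacement[[2]] <- mk(c(1, 2, 100), "displacement", 1L,
                               valid = c(TRUE, TRUE, FALSE))
  cv2 <- phase_curves(maps, roi)
  expect_equal(cv2$mean_displacement_mm[2], 1.5)
  maps$displacement[[2]] <- mk(c(1, 2, 100), "displacement", 1L,
                               valid = rep(FALSE, 3))
  expect_error(phase_curves(maps, roi), "no valid vertices")
})

test_that("vertex maps validate their invariants", {
  expect_error(vertex_map(c(1, -2), kind = "diameter"), ">= 0")
  expect_error(vertex_map(c(1, NaN), kind = "displacement"), "non-finite")
  m <- vertex_map(c(1, -5), valid = c(TRUE, FALSE), kind = "diameter")
  expect_identical(m$valid, c(TRUE, FALSE))   # invalid entries unchecked
  expect_error(vertex_map(1:3, valid = c(TRUE, FALSE)), "equal length")
})

test_that("curves and vertex maps round-trip through CSV", {
  pos <- matrix(rnorm(9), 3, 3)
  m <- vertex_map(c(1.5, 2.5, 3.5), c(TRUE, FALSE, TRUE), 2L, "diameter")
  f <- tempfile(fileext = ".csv")
  write_vertex_map_csv(m, pos, f)
  df <- read.csv(f)
  expect_equal(df$value, m$values)
  expect_equal(df$valid, m$valid)
  unlink(f)
})
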