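euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  n_edges <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - n_edges + nrow(f)
}

test_that("a rasterized ball extracts to a closed genus-0 surface with the right area", {
  s <- ball_series(radius = 8, spacing = 1.6, n = 16)
  m <- extract_surface(s, 0)
  expect_equal(euler_characteristic(m), 2L)
  expect_silent(aortamotion:::check_closed_oriented(m))
  area <- mesh_area(m)
  expect_lt(abs(area - 4 * pi * 64) / (4 * pi * 64), 0.10)
  expect_gt(mesh_volume(m), 0)
  expect_error(extract_surface(ball_series(radius = 0.1), 0), "empty phase")
})

test_that("enclosed volume converges for a well-resolved ball and a single voxel stays near one voxel", {
  s <- ball_series(radius = 8, spacing = 1, n = 20)  # r/spacing = 8
  m <- extract_surface(s, 0)
  v_true <- 4 / 3 * pi * 8^3
  expect_lt(abs(mesh_volume(m) - v_true) / v_true, 0.05)

  # a single voxel is below the default smoothing scale, so extract raw
  dat <- array(0, c(2, 7, 7, 7)); dat[, 4, 4, 4] <- 1
  s1 <- segmentation_series(dat, diag(c(1, 1, 1, 1)))
  m1 <- extract_surface(s1, 0, sigma_vox = 0, taubin_iterations = 0L,
                        normal_smooth_rounds = 0L)
  expect_lte(abs(mesh_volume(m1) - 1), 0.5)  # tet dual cell: exactly half
})

test_that("Taubin smoothing changes the ball volume by less than 2%", {
  s <- ball_series(radius = 8, spacing = 1.6, n = 16)
  raw <- extract_surface(s, 0, taubin_iterations = 0L)
  smoothed <- taubin_smooth(raw, iterations = 10L)
  expect_lt(abs(mesh_volume(smoothed) - mesh_volume(raw)) /
              abs(mesh_volume(raw)), 0.02)
})

test_that("outward normals are radial on a sphere and axis-aligned on flat cube faces", {
  ico <- icosphere(10, 3)
  rad <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  ang <- acos(pmin(1, rowSums(rad * ico$normals))) * 180 / pi
  expect_lt(max(ang), 5)

  # cube mask, no smoothing: vertices on face interiors have exact axis normals
  dat <- array(0, c(2, 12, 12, 12)); dat[, 3:10, 3:10, 3:10] <- 1
  s <- segmentation_series(dat, diag(rep(1, 4)))
  m <- extract_surface(s, 0, sigma_vox = 0, taubin_iterations = 0L,
                       normal_smooth_rounds = 0L)
  top <- which(abs(m$vertices[, 3] - max(m$vertices[, 3])) < 1e-9 &
                 m$vertices[, 1] > 4 & m$vertices[, 1] < 7 &
                 m$vertices[, 2] > 4 & m$vertices[, 2] < 7)
  expect_gt(length(top), 0)
  expect_equal(m$normals[top, , drop = FALSE],
               matrix(rep(c(0, 0, 1), each = length(top)), ncol = 3),
               tolerance = 1e-9)
})

test_that("inverted winding is repaired to outward orientation", {
  ico <- icosphere(5, 2)
  flipped <- surface_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  fixed <- compute_outward_normals(flipped)
  expect_gt(mesh_volume(fixed), 0)
  rad <- fixed$vertices / sqrt(rowSums(fixed$vertices^2))
  expect_true(all(rowSums(rad * fixed$normals) > 0))
})

test_that("open meshes are rejected by the normal computation", {
  patch <- square_patch()
  expect_error(compute_outward_normals(patch), "not closed")
})

test_that("mean surface distance matches plane, identity and concentric-sphere oracles", {
  ico <- icosphere(10, 3)
  expect_lt(mean_surface_distance(ico, ico), 1e-9)

  src <- square_patch(half = 1, z = 5)
  tgt <- square_patch(half = 10, z = 0)
  expect_equal(mean_surface_distance(src, tgt), 5, tolerance = 1e-9)

  inner <- icosphere(10, 3)
  outer <- icosphere(12, 3)
  expect_equal(mean_surface_distance(inner, outer), 2, tolerance = 0.05)
  expect_gte(mean_surface_distance(outer, inner), 0)
})

test_that("closest_surface_points agrees with a brute-force per-triangle oracle", {
  ico <- icosphere(4, 1)
  set.seed(3)
  pts <- matrix(runif(30, -6, 6), 10, 3)
  cp <- closest_surface_points(pts, ico)
  # oracle: dense barycentric sampling of every triangle
  grid <- expand.grid(u = seq(0, 1, length.out = 60),
                      v = seq(0, 1, length.out = 60))
  grid <- grid[grid$u + grid$v <= 1, ]
  brute <- sapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(sapply(seq_len(nrow(ico$faces)), function(fi) {
      a <- ico$vertices[ico$faces[fi, 1], ]
      b <- ico$vertices[ico$faces[fi, 2], ]
      c_ <- ico$vertices[ico$faces[fi, 3], ]
      q <- outer(grid$u, a) + outer(grid$v, b) + outer(1 - grid$u - grid$v, c_)
      min(sqrt(rowSums(sweep(q, 2, p)^2)))
    }))
  })
  expect_lt(max(cp$distance - brute), 1e-9)       # exact <= sampled
  expect_lt(max(brute - cp$distance), 0.05)       # sampled close to exact
  # barycentric output reconstructs the closest point
  rec <- sapply(seq_len(nrow(pts)), function(i) {
    tri <- ico$faces[cp$face[i], ]
    max(abs(colSums(ico$vertices[tri, ] * cp$bary[i, ]) - cp$point[i, ]))
  })
  expect_lt(max(rec), 1e-9)
})

test_that("multi-component surfaces keep the largest part with a warning", {
  dat <- array(0, c(2, 16, 16, 16))
  dat[, 2:9, 2:9, 2:9] <- 1       # big block
  dat[, 12:14, 12:14, 12:14] <- 1 # small satellite
  s <- segmentation_series(dat, diag(rep(1, 4)))
  expect_warning(m <- extract_surface(s, 0), "components")
  expect_equal(euler_characteristic(m), 2L)
  expect_lt(abs(mesh_volume(m) - 8^3) / 8^3, 0.25)
})

test_that("PLY and OFF export write consistent headers and data", {
  ico <- icosphere(5, 1)
  ply <- tempfile(fileext = ".ply")
  off <- tempfile(fileext = ".off")
  write_mesh_ply(ico, ply, scalars = list(diameter = rep(10, nrow(ico$vertices))))
  write_mesh_off(ico, off)
  h <- readLines(ply)
  expect_equal(h[1], "ply")
  expect_true(any(grepl(paste("element vertex", nrow(ico$vertices)), h)))
  expect_true(any(grepl("property float diameter", h)))
  o <- readLines(off)
  expect_equal(o[1], "OFF")
  expect_equal(scan(text = o[2], quiet = TRUE)[1:2],
               c(nrow(ico$vertices), nrow(ico$faces)))
  unlink(c(ply, off))
})
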