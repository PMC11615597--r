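# Shared fixtures, built in code at test time.

# Binary ball mask as a 2-phase segmentation series.
ball_series <- function(radius = 8, spacing = 1.6, n = 16L, phases = 2L,
                        center = NULL) {
  cx <- (seq_len(n) - 1L) * spacing
  if (is.null(center)) center <- rep(mean(cx), 3L)
  g <- expand.grid(x = cx, y = cx, z = cx)
  d <- sqrt((g$x - center[1L])^2 + (g$y - center[2L])^2 + (g$z - center[3L])^2)
  ball <- array(as.numeric(d <= radius), c(n, n, n))
  dat <- array(0, c(phases, n, n, n))
  for (t in seq_len(phases)) dat[t, , , ] <- ball
  segmentation_series(dat, diag(c(rep(spacing, 3L), 1)))
}

# Analytic closed cylinder mesh (axis z, flat caps via a center fan).
cylinder_mesh <- function(radius = 10, length = 40, n_theta = 48L, n_z = 20L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-1L]
  zs <- seq(0, length, length.out = n_z)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(theta), radius * sin(theta), z)))
  idx <- function(iz, it) (iz - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  f <- matrix(0L, 0L, 3L)
  for (iz in seq_len(n_z - 1L)) for (it in seq_len(n_theta)) {
    a <- idx(iz, it); b <- idx(iz, it + 1L)
    c_ <- idx(iz + 1L, it); d <- idx(iz + 1L, it + 1L)
    f <- rbind(f, c(a, b, d), c(a, d, c_))
  }
  bot <- nrow(v) + 1L; top <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, 0), c(0, 0, length))
  for (it in seq_len(n_theta)) {
    f <- rbind(f, c(bot, idx(1L, it + 1L), idx(1L, it)),
               c(top, idx(n_z, it), idx(n_z, it + 1L)))
  }
  compute_outward_normals(surface_mesh(v, f))
}

# Planar square patch subdivided into 4 triangles (open mesh; normals NULL).
square_patch <- function(half = 1, z = 0, center = c(0, 0)) {
  v <- rbind(c(-half, -half, z), c(half, -half, z), c(half, half, z),
             c(-half, half, z), c(0, 0, z))
  v[, 1L] <- v[, 1L] + center[1L]
  v[, 2L] <- v[, 2L] + center[2L]
  surface_mesh(v, rbind(c(1L, 2L, 5L), c(2L, 3L, 5L),
                        c(3L, 4L, 5L), c(4L, 1L, 5L)))
}

# Reduced-size phantom for fast unit tests (overridable defaults).
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(r0_mm = 8, amp_mm = 0.5, trans_mm = c(0, 5, 0), peak_phase = 2L,
         n_phases = 6L, segment_length_mm = 25, arch_radius_mm = 14),
    list(...))
  do.call(phantom_spec, args)
}

# Translate a mesh rigidly.
translate_mesh <- function(mesh, by) {
  mesh$vertices <- sweep(mesh$vertices, 2L, by, `+`)
  mesh
}
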