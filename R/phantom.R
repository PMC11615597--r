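# Synthetic 4D phantom: a pulsating, translating curved tube ("candy cane":
# straight ascending segment plus a half-torus arch) rasterized on an
# isotropic voxel grid, with analytic ground truth for displacement and
# diameter. The defaults emulate the geometry of a 3D cine acquisition of
# the thoracic aorta: 1.6 mm isotropic voxels, 15 cardiac phases, a ~26 mm
# diameter vessel with ~0.7 mm systolic radial distension and bulk
# translation of up to 13 mm at the systolic peak.

#' Specification of the synthetic tube phantom
#'
#' The centerline is a straight segment from the origin along +z of length
#' `segment_length_mm`, continued by a half-circle arch of radius
#' `arch_radius_mm` in the x-z plane. Over the cardiac cycle the tube radius
#' is `r(t) = r0_mm + amp_mm * w(t)` and the whole tube translates rigidly
#' by `trans_mm * w(t)`, where `w` is the systolic waveform of
#' [radius_waveform()] (0 at the reference phase, 1 at `peak_phase`).
#'
#' @param r0_mm Baseline tube radius (default 12.95 mm, a 25.9 mm vessel).
#' @param amp_mm Radial distension amplitude; peak diameter change is
#'   `2 * amp_mm` (default 0.7 mm).
#' @param trans_mm Bulk translation amplitude, 3-vector in mm (default
#'   `c(0, 13, 0)`: 13 mm peak displacement, perpendicular to the
#'   centerline plane so the motion is observable from surface shape
#'   everywhere).
#' @param peak_phase 0-based phase of the systolic peak (default 5).
#' @param n_phases Number of cardiac phases (default 15).
#' @param spacing_mm Isotropic voxel size (default 1.6 mm).
#' @param segment_length_mm Length of the straight segment (default 50 mm).
#' @param arch_radius_mm Radius of the arch centerline (default 28 mm).
#' @param tilt_deg Rotation of the whole centerline (degrees about the x
#'   axis, then the y axis) applied before rasterization. The default
#'   `c(8, 6)` keeps the tube oblique to the voxel lattice the way a real
#'   vessel is; with an exactly grid-aligned axis every cross-sectional
#'   slice samples the same lattice offset, so rasterization quantization
#'   becomes a coherent per-phase diameter error of ~0.2 mm instead of
#'   averaging out.
#' @param grid_shape,origin_mm Voxel grid; when `NULL` (default) a grid
#'   that contains the tube at all phases with a 2-voxel margin is derived
#'   from the geometry.
#' @param phase_duration_ms Temporal resolution to stamp on the series
#'   (default 67 ms).
#' @param seed Integer seed recorded in the spec (the default phantom is
#'   noise free, so it only matters for downstream seeded steps).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(r0_mm = 12.95, amp_mm = 0.7, trans_mm = c(0, 13, 0),
                         peak_phase = 5L, n_phases = 15L, spacing_mm = 1.6,
                         segment_length_mm = 50, arch_radius_mm = 28,
                         tilt_deg = c(8, 6), grid_shape = NULL,
                         origin_mm = NULL, phase_duration_ms = 67,
                         seed = 0L) {
  if (r0_mm <= 2 * spacing_mm)
    stop("radius under-resolved: r0_mm must exceed 2 * spacing_mm (",
         2 * spacing_mm, " mm)")
  if (amp_mm < 0) stop("amp_mm must be >= 0")
  if (peak_phase < 0 || peak_phase >= n_phases)
    stop("peak_phase must be in [0, n_phases)")
  if (n_phases < 2L) stop("n_phases must be >= 2")
  if (length(trans_mm) != 3L) stop("trans_mm must be a 3-vector")
  if (arch_radius_mm < 0 || segment_length_mm < 0)
    stop("centerline dimensions must be >= 0")
  if (arch_radius_mm == 0 && segment_length_mm == 0)
    stop("centerline has zero length")
  spec <- structure(list(
    r0_mm = r0_mm, amp_mm = amp_mm, trans_mm = as.numeric(trans_mm),
    peak_phase = as.integer(peak_phase), n_phases = as.integer(n_phases),
    spacing_mm = spacing_mm, segment_length_mm = segment_length_mm,
    arch_radius_mm = arch_radius_mm, tilt_deg = as.numeric(tilt_deg),
    grid_shape = grid_shape,
    origin_mm = origin_mm, phase_duration_ms = phase_duration_ms,
    seed = as.integer(seed)), class = "phantom_spec")
  if (is.null(grid_shape) || is.null(origin_mm)) {
    fit <- fit_phantom_grid(spec)
    spec$grid_shape <- fit$shape
    spec$origin_mm <- fit$origin
  } else {
    spec$grid_shape <- as.integer(grid_shape)
    spec$origin_mm <- as.numeric(origin_mm)
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "phantom_spec: r0 %.2f mm (+%.2f distension), |trans| %.1f mm, ",
    "%d phases (peak %d), %.1f mm voxels, grid %s\n"),
    x$r0_mm, x$amp_mm, sqrt(sum(x$trans_mm^2)), x$n_phases, x$peak_phase,
    x$spacing_mm, paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

# Rotation matrix of the phantom tilt: Ry(b) %*% Rx(a).
phantom_rotation <- function(spec) {
  a <- spec$tilt_deg[1L] * pi / 180
  b <- spec$tilt_deg[2L] * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  ry %*% rx
}

# Dense sample of the canonical (untilted) centerline.
centerline_points <- function(spec, n = 200L) {
  pts <- matrix(0, 0L, 3L)
  if (spec$segment_length_mm > 0) {
    z <- seq(0, spec$segment_length_mm, length.out = n)
    pts <- rbind(pts, cbind(0, 0, z))
  }
  if (spec$arch_radius_mm > 0) {
    th <- seq(pi, 0, length.out = n)
    pts <- rbind(pts, cbind(spec$arch_radius_mm + spec$arch_radius_mm * cos(th),
                            0,
                            spec$segment_length_mm +
                              spec$arch_radius_mm * sin(th)))
  }
  pts
}

# Axis-aligned extent of the (tilted) tube over all phases, with margin.
fit_phantom_grid <- function(spec, margin_vox = 2L) {
  rmax <- spec$r0_mm + spec$amp_mm
  cl <- centerline_points(spec) %*% t(phantom_rotation(spec))
  lo <- apply(cl, 2L, min) - rmax + pmin(spec$trans_mm, 0)
  hi <- apply(cl, 2L, max) + rmax + pmax(spec$trans_mm, 0)
  sp <- spec$spacing_mm
  origin <- lo - margin_vox * sp
  shape <- as.integer(ceiling((hi - origin) / sp)) + margin_vox + 1L
  list(shape = shape, origin = origin)
}

#' Systolic radius waveform
#'
#' Deterministic cardiac waveform in `[0, 1]`: zero at phase 0
#' (end-diastolic reference), a raised-cosine upstroke to 1 at `peak_phase`
#' (systole), then an exponential decay onto a mid-level diastolic plateau
#' that tapers back toward 0 at the final phase.
#'
#' @param phase 0-based phase index (vectorized).
#' @param spec A [phantom_spec()].
#' @return Waveform value(s) in `[0, 1]`.
#' @export
radius_waveform <- function(phase, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(phase < 0 | phase >= spec$n_phases))
    stop("phase must be in [0, ", spec$n_phases - 1L, "]")
  pk <- spec$peak_phase
  n <- spec$n_phases
  w <- numeric(length(phase))
  up <- phase <= pk
  if (pk > 0)
    w[up] <- 0.5 * (1 - cos(pi * phase[up] / pk))
  else
    w[up] <- 1
  if (any(!up)) {
    s <- (phase[!up] - pk) / (n - 1L - pk)  # 0 just after peak, 1 at the end
    plateau <- 0.35
    decay <- plateau + (1 - plateau) * exp(-4 * s)
    taper <- ifelse(s > 0.7, 1 - ((s - 0.7) / 0.3)^2 * 0.85, 1)
    w[!up] <- decay * taper
  }
  pmin(pmax(w, 0), 1)
}

# Distance from points (n x 3, mm) to the candy-cane centerline. Points
# beyond the parameter range of a part get Inf for that part, so the tube
# ends with flat caps and the foreground volume of a straight tube is
# exactly pi r^2 L up to rasterization.
centerline_distance <- function(p, spec) {
  L <- spec$segment_length_mm
  ra <- spec$arch_radius_mm
  d_seg <- if (L > 0) {
    ifelse(p[, 3L] >= 0 & p[, 3L] <= L,
           sqrt(p[, 1L]^2 + p[, 2L]^2), Inf)
  } else rep(Inf, nrow(p))
  d_arc <- if (ra > 0) {
    dx <- p[, 1L] - ra
    dz <- p[, 3L] - L
    theta <- atan2(dz, dx)
    ax <- ra + ra * cos(theta)
    az <- L + ra * sin(theta)
    ifelse(theta >= 0,  # the arch spans theta in [0, pi]
           sqrt((p[, 1L] - ax)^2 + p[, 2L]^2 + (p[, 3L] - az)^2), Inf)
  } else rep(Inf, nrow(p))
  pmin(d_seg, d_arc)
}

#' Rasterize the phantom tube at one phase
#'
#' A voxel is foreground iff its centre lies within the phase's tube radius
#' of the (rigidly translated) centerline; distances to the straight segment
#' and the arch arc are exact, and there is no partial-volume weighting, so
#' the mask is strictly binary like the pipeline's segmentation input.
#'
#' @param spec A [phantom_spec()].
#' @param phase 0-based phase index.
#' @return 3D binary array on the spec's grid.
#' @export
rasterize_tube <- function(spec, phase) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- radius_waveform(phase, spec)
  r_t <- spec$r0_mm + spec$amp_mm * w
  offset <- spec$trans_mm * w
  check_tube_fits(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  xs <- spec$origin_mm[1L] + sp * (seq_len(d[1L]) - 1L) - offset[1L]
  ys <- spec$origin_mm[2L] + sp * (seq_len(d[2L]) - 1L) - offset[2L]
  zs <- spec$origin_mm[3L] + sp * (seq_len(d[3L]) - 1L) - offset[3L]
  p <- cbind(rep(xs, times = d[2L] * d[3L]),
             rep(rep(ys, each = d[1L]), times = d[3L]),
             rep(zs, each = d[1L] * d[2L]))
  # into the canonical (untilted) frame for the exact distance evaluation
  p <- p %*% phantom_rotation(spec)  # p %*% R == t(t(R) %*% t(p))
  array(as.numeric(centerline_distance(p, spec) <= r_t), d)
}

# The tube (at maximal radius and extreme translation) must stay strictly
# inside the grid so extracted surfaces are closed.
check_tube_fits <- function(spec) {
  rmax <- spec$r0_mm + spec$amp_mm
  cl <- centerline_points(spec) %*% t(phantom_rotation(spec))
  lo <- apply(cl, 2L, min) - rmax + pmin(spec$trans_mm, 0)
  hi <- apply(cl, 2L, max) + rmax + pmax(spec$trans_mm, 0)
  gmin <- spec$origin_mm
  gmax <- spec$origin_mm + spec$spacing_mm * (spec$grid_shape - 1L)
  if (any(lo < gmin + spec$spacing_mm) || any(hi > gmax - spec$spacing_mm))
    stop("tube exits grid: enlarge grid_shape or adjust origin_mm")
  invisible(TRUE)
}

#' Generate the synthetic 4D series with its ground truth
#'
#' Rasterizes all phases and derives the analytic ground truth on a dense
#' parametric sampling of the reference tube surface: the displacement
#' vector of a surface point is the vector sum of the rigid translation
#' `trans_mm * w(t)` and the radial distension `amp_mm * w(t)` along the
#' local outward radial direction; the ground-truth diameter is `2 * r(t)`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `series` (a [segmentation_series()]) and
#'   `ground_truth`: list with `waveform`, `curves` (data.frame of `phase`,
#'   `gt_mean_displacement_mm`, `gt_max_displacement_mm`, `gt_diameter_mm`,
#'   `gt_diameter_change_mm`) and the generating `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  data <- array(0, c(spec$n_phases, d))
  for (t in seq_len(spec$n_phases))
    data[t, , , ] <- rasterize_tube(spec, t - 1L)
  affine <- diag(c(rep(spec$spacing_mm, 3L), 1))
  affine[1:3, 4L] <- spec$origin_mm
  series <- segmentation_series(data, affine,
                                phase_duration_ms = spec$phase_duration_ms)
  list(series = series, ground_truth = phantom_ground_truth(spec))
}

# Analytic per-phase displacement summary over a dense surface sampling.
phantom_ground_truth <- function(spec, n_theta = 72L, n_axial = 120L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-1L]
  # axial samples split between segment and arch in proportion to length,
  # so the surface sampling is (approximately) area weighted
  len_seg <- spec$segment_length_mm
  len_arch <- pi * spec$arch_radius_mm
  n_seg <- round(n_axial * len_seg / (len_seg + len_arch))
  n_arch <- n_axial - n_seg
  radial <- matrix(0, 0L, 3L)
  if (len_seg > 0 && n_seg > 0) {
    # straight segment along z: radial directions in the x-y plane
    radial <- rbind(radial,
                    cbind(cos(theta), sin(theta), 0)[
                      rep(seq_len(n_theta), times = n_seg), , drop = FALSE])
  }
  if (len_arch > 0 && n_arch > 0) {
    phi <- seq(0, pi, length.out = n_arch)
    for (ph in phi) {
      # local frame of the arch circle at angle ph (plane y = 0)
      u <- c(cos(ph), 0, sin(ph))  # in-plane radial of the arch
      v <- c(0, 1, 0)
      radial <- rbind(radial, outer(cos(theta), u) + outer(sin(theta), v))
    }
  }
  radial <- radial %*% t(phantom_rotation(spec))
  w <- radius_waveform(0:(spec$n_phases - 1L), spec)
  gt_mean <- numeric(spec$n_phases)
  gt_max <- numeric(spec$n_phases)
  for (t in seq_len(spec$n_phases)) {
    disp <- sweep(spec$amp_mm * w[t] * radial, 2L, spec$trans_mm * w[t], `+`)
    mag <- sqrt(rowSums(disp^2))
    gt_mean[t] <- mean(mag)
    gt_max[t] <- max(mag)
  }
  r_t <- spec$r0_mm + spec$amp_mm * w
  list(waveform = w,
       curves = data.frame(
         phase = 0:(spec$n_phases - 1L),
         gt_mean_displacement_mm = gt_mean,
         gt_max_displacement_mm = gt_max,
         gt_diameter_mm = 2 * r_t,
         gt_diameter_change_mm = 2 * spec$amp_mm * w),
       spec = spec)
}

#' Write a generated phantom to disk
#'
#' Writes the series as 4D NIfTI (`phantom.nii.gz`), the ground-truth curves
#' as CSV (`ground_truth.csv`) and the generating spec as JSON
#' (`phantom_spec.json`) for provenance.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask_series(phantom$series, file.path(dir, "phantom.nii.gz"))
  write.csv(phantom$ground_truth$curves, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  spec <- phantom$ground_truth$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default analysis ROI for a phantom
#'
#' Axis-aligned box around the mid-portion of the straight segment (the
#' phantom's "ascending aorta"), in world mm: the rotated centerline between
#' the `lo_frac` and `hi_frac` fractions of the segment length, padded by
#' the maximal tube radius perpendicular to the tube axis (but only two
#' voxels along it, so the end caps and the arch junction stay outside),
#' and extended along the bulk translation so the tube stays inside the
#' static box at every phase.
#'
#' @param spec A [phantom_spec()] with `segment_length_mm > 0`.
#' @param lo_frac,hi_frac Fractions of the straight segment to cover.
#' @return A [roi_box()].
#' @export
phantom_roi <- function(spec, lo_frac = 0.1, hi_frac = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$segment_length_mm <= 0)
    stop("phantom has no straight segment to place the ROI on")
  z <- seq(lo_frac, hi_frac, length.out = 50L) * spec$segment_length_mm
  rot <- phantom_rotation(spec)
  cl <- cbind(0, 0, z) %*% t(rot)
  axis <- rot %*% c(0, 0, 1)  # rotated tube direction
  rad_pad <- spec$r0_mm + spec$amp_mm + 2 * spec$spacing_mm
  pad <- rad_pad * sqrt(pmax(1 - axis^2, 0)) +
    2 * spec$spacing_mm * abs(axis)
  pad <- as.numeric(pad)
  roi_box(apply(cl, 2L, min) - pad + pmin(spec$trans_mm, 0),
          apply(cl, 2L, max) + pad + pmax(spec$trans_mm, 0))
}
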