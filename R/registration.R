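# Non-rigid surface registration by iterative global Gaussian-RBF
# deformation.
#
# Each iteration warps the current source estimate toward its closest points
# on the target surface. The warp is a sum of Nc Gaussian radial basis
# functions whose width gamma is proportional to the source-target mean
# surface distance D_mean and to the decreasing schedule factor k2, so the
# deformation is coarse early and refines over the iterations while k1
# slowly increases the number of centers.

#' Configuration for G-RBF registration
#'
#' The schedule runs `n_iterations` iterations. Over them `k1` is linearly
#' interpolated from `k1_start` to `k1_end` and `k2` from `k2_start` to
#' `k2_end`; per iteration the number of deformation centers is
#' `Nc = round(nc_base * k1)` (or `round(nc_base ^ k1)` with
#' `nc_mode = "power"`) and the kernel width is
#' `gamma = k2 * 2 * D_mean`, floored at `gamma_floor_mm`.
#'
#' `gamma_mode` selects which `D_mean` enters the width. The default
#' `"schedule"` uses the initial source-target mean distance, so the
#' coarse-to-fine progression is driven purely by the decreasing `k2`
#' schedule and the kernels keep broad support throughout; `"adaptive"`
#' re-evaluates `D_mean` every iteration, which shrinks the kernels as the
#' fit improves but can strand residual misfit once their support falls
#' below the inter-center spacing; `"inverse"` is the reciprocal reading
#' `1 / (2 * D_mean * k2)`, kept selectable for completeness.
#'
#' @param n_iterations Number of iterations (default 30).
#' @param nc_base Base number of deformation centers (default 10).
#' @param k1_start,k1_end Endpoints of the center-count factor (1 to 1.5).
#' @param k2_start,k2_end Endpoints of the width factor (3 to 1.5).
#' @param gamma_floor_mm Lower bound on the kernel width in mm; default
#'   3.2 mm, i.e. twice a 1.6 mm voxel. Set to twice the actual voxel
#'   spacing of your data ([run_motion_analysis()] does this automatically).
#' @param damping Relative ridge weight for the per-iteration least-squares
#'   solve of the center weights.
#' @param seed Integer seed for the deterministic center sampling.
#' @param nc_mode,gamma_mode Alternative readings of the center-count and
#'   width rules (see Details above).
#' @param prealign `"translation"` (default) runs a rigid translation-only
#'   ICP stage (each step moves the source by the mean closest-point
#'   residual, the Procrustes-optimal translation) before the G-RBF
#'   iterations, so bulk motion is captured as a rigid shift and the RBFs
#'   model the residual deformation; `"none"` starts the G-RBF schedule
#'   directly.
#' @return An object of class `grbf_config`.
#' @export
grbf_config <- function(n_iterations = 30L, nc_base = 10L,
                        k1_start = 1.0, k1_end = 1.5,
                        k2_start = 3.0, k2_end = 1.5,
                        gamma_floor_mm = 3.2, damping = 1e-6, seed = 0L,
                        nc_mode = c("product", "power"),
                        gamma_mode = c("schedule", "adaptive", "inverse"),
                        prealign = c("translation", "none")) {
  nc_mode <- match.arg(nc_mode)
  gamma_mode <- match.arg(gamma_mode)
  prealign <- match.arg(prealign)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (nc_base < 1L) stop("nc_base must be >= 1")
  if (gamma_floor_mm <= 0) stop("gamma_floor_mm must be > 0")
  if (damping < 0) stop("damping must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 nc_base = as.integer(nc_base),
                 k1_start = k1_start, k1_end = k1_end,
                 k2_start = k2_start, k2_end = k2_end,
                 gamma_floor_mm = gamma_floor_mm, damping = damping,
                 seed = as.integer(seed),
                 nc_mode = nc_mode, gamma_mode = gamma_mode,
                 prealign = prealign),
            class = "grbf_config")
}

#' @export
print.grbf_config <- function(x, ...) {
  cat(sprintf(paste0(
    "grbf_config: %d iterations, Nc = round(%d %s k1), k1 %g->%g, ",
    "k2 %g->%g, gamma floor %g mm\n"),
    x$n_iterations, x$nc_base, if (x$nc_mode == "product") "*" else "^",
    x$k1_start, x$k1_end, x$k2_start, x$k2_end, x$gamma_floor_mm))
  invisible(x)
}

#' Per-iteration schedule parameters
#'
#' @param iteration 1-based iteration index.
#' @param config A [grbf_config()].
#' @return List with `nc` (number of centers), `k1` and `k2`.
#' @export
schedule_params <- function(iteration, config = grbf_config()) {
  n <- config$n_iterations
  if (iteration < 1L || iteration > n)
    stop("iteration must be in [1, ", n, "]")
  frac <- if (n == 1L) 0 else (iteration - 1) / (n - 1)
  k1 <- config$k1_start + frac * (config$k1_end - config$k1_start)
  k2 <- config$k2_start + frac * (config$k2_end - config$k2_start)
  nc <- if (config$nc_mode == "product") round(config$nc_base * k1)
        else round(config$nc_base^k1)
  list(nc = as.integer(nc), k1 = k1, k2 = k2)
}

# Deterministic start index for farthest-point sampling: a small
# multiplicative-congruential draw from the seed, independent of R's RNG.
fps_start_index <- function(seed, n) {
  state <- (as.numeric(seed) * 2654435761 + 1013904223) %% 2^31
  as.integer(state %% n) + 1L
}

#' Select deformation centers by farthest-point sampling
#'
#' Greedy farthest-point sampling over the mesh vertices gives a
#' well-spread, deterministic set of centers: the first point is a seeded
#' pseudo-random vertex (ties between equally far vertices resolve to the
#' lowest index), each next point maximises the distance to the set chosen
#' so far.
#'
#' @param mesh A [surface_mesh()] or an N x 3 vertex matrix.
#' @param n_centers Number of centers (at most N).
#' @param seed Integer seed choosing the starting vertex.
#' @return `n_centers` x 3 matrix of center positions.
#' @export
select_centers <- function(mesh, n_centers, seed = 0L) {
  v <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  n <- nrow(v)
  if (n_centers < 1L || n_centers > n)
    stop("n_centers must be in [1, ", n, "]")
  sel <- integer(n_centers)
  sel[1L] <- fps_start_index(seed, n)
  d2 <- rowSums(sweep(v, 2L, v[sel[1L], ], `-`)^2)
  if (n_centers > 1L) {
    for (i in 2:n_centers) {
      sel[i] <- which.max(d2)  # which.max takes the lowest index on ties
      d2 <- pmin(d2, rowSums(sweep(v, 2L, v[sel[i], ], `-`)^2))
    }
  }
  v[sel, , drop = FALSE]
}

# Squared Euclidean distances between rows of x (P x 3) and c (Nc x 3).
pairwise_sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Apply a Gaussian-RBF warp
#'
#' `warped = points + sum_c weights_c * exp(-||point - center_c||^2 / gamma^2)`
#'
#' @param points P x 3 matrix of positions in mm.
#' @param centers Nc x 3 matrix of kernel centers in mm.
#' @param weights Nc x 3 matrix of per-center displacement coefficients (mm).
#' @param gamma_mm Kernel width in mm (> 0).
#' @return P x 3 matrix of warped positions.
#' @export
grbf_warp <- function(points, centers, weights, gamma_mm) {
  if (gamma_mm <= 0) stop("gamma_mm must be > 0")
  points <- as.matrix(points)
  k <- exp(-pairwise_sq_dist(points, as.matrix(centers)) / gamma_mm^2)
  points + k %*% as.matrix(weights)
}

#' Register a source mesh to a target mesh
#'
#' A rigid translation-only ICP stage first absorbs bulk motion (see
#' `prealign` in [grbf_config()]); a pure tangential shift of a featureless
#' surface is unobservable from shape and is left untouched by it. Then the
#' iterative global G-RBF deformation runs. Each iteration: (1) evaluate the mean
#' surface distance `D_mean` of the current warped source vertices to the
#' target; (2) set the kernel width from `D_mean` and the `k2` schedule,
#' floored at `gamma_floor_mm`; (3) re-select `Nc` centers on the current
#' warped surface (the schedule changes `Nc`, so centers cannot be static);
#' (4) fit center weights to the closest-point residuals by damped least
#' squares; (5) apply the warp. Correspondences are source-vertex to closest
#' point on the target surface, so the meshes may have unrelated vertex
#' counts.
#'
#' @param source,target [surface_mesh()] objects; `source` is typically the
#'   end-diastolic reference.
#' @param config A [grbf_config()].
#' @return An object of class `registration_state`: list with
#'   `warped_vertices` (N x 3), `displacement` (N x 3, warped minus original
#'   source positions), `d_mean_trace` (one `D_mean` per iteration, measured
#'   at the start of the iteration), `trace` (data.frame of iteration, nc,
#'   k1, k2, gamma_mm, d_mean), `centers`, `weights`, `gamma_mm` (final
#'   iteration) and `config`.
#' @export
register_pair <- function(source, target, config = grbf_config()) {
  stopifnot(inherits(source, "surface_mesh"), inherits(target, "surface_mesh"))
  warped <- source$vertices
  n_it <- config$n_iterations
  # Rigid stage: translation-only ICP. Each step applies the
  # Procrustes-optimal translation for the current closest-point
  # correspondences (their mean residual) and stops when the step stalls.
  prealign_shift <- c(0, 0, 0)
  if (identical(config$prealign, "translation")) {
    for (j in seq_len(n_it)) {
      cp <- .cpp_closest_on_mesh(warped, target$vertices, target$faces)
      step <- colMeans(cp$point - warped)
      if (sqrt(sum(step^2)) < 1e-2) break
      warped <- sweep(warped, 2L, step, `+`)
      prealign_shift <- prealign_shift + step
    }
  }
  trace <- data.frame(iteration = seq_len(n_it), nc = NA_integer_,
                      k1 = NA_real_, k2 = NA_real_, gamma_mm = NA_real_,
                      d_mean = NA_real_)
  centers <- NULL
  weights <- NULL
  gamma_mm <- NA_real_
  d_mean_initial <- NA_real_
  for (i in seq_len(n_it)) {
    p <- schedule_params(i, config)
    cp <- .cpp_closest_on_mesh(warped, target$vertices, target$faces)
    d_mean <- mean(cp$distance)
    if (i == 1L) d_mean_initial <- d_mean
    gamma_mm <- switch(config$gamma_mode,
      schedule = p$k2 * 2 * d_mean_initial,
      adaptive = p$k2 * 2 * d_mean,
      inverse = 1 / (2 * d_mean * p$k2))
    gamma_mm <- max(gamma_mm, config$gamma_floor_mm)
    if (!is.finite(gamma_mm))
      stop("non-finite kernel width at iteration ", i)
    nc <- min(p$nc, nrow(warped))
    centers <- select_centers(warped, nc, seed = config$seed)
    k <- exp(-pairwise_sq_dist(warped, centers) / gamma_mm^2)
    residual <- cp$point - warped
    ktk <- crossprod(k)
    ridge <- config$damping * sum(diag(ktk)) / nc
    weights <- tryCatch(
      solve(ktk + diag(ridge, nc), crossprod(k, residual)),
      error = function(e) stop("degenerate weight solve at iteration ", i,
                               " (gamma = ", signif(gamma_mm, 4), " mm): ",
                               conditionMessage(e)))
    if (any(!is.finite(weights)))
      stop("non-finite weights at iteration ", i,
           " (degenerate gamma or duplicate centers)")
    warped <- warped + k %*% weights
    trace[i, c("nc", "k1", "k2", "gamma_mm", "d_mean")] <-
      list(nc, p$k1, p$k2, gamma_mm, d_mean)
  }
  structure(list(
    warped_vertices = warped,
    displacement = warped - source$vertices,
    d_mean_trace = trace$d_mean,
    trace = trace,
    prealign_shift = prealign_shift,
    centers = centers, weights = weights, gamma_mm = gamma_mm,
    config = config), class = "registration_state")
}

#' @export
print.registration_state <- function(x, ...) {
  cat(sprintf(
    "registration_state: %d vertices, %d iterations, D_mean %.3f -> %.3f mm\n",
    nrow(x$warped_vertices), length(x$d_mean_trace),
    x$d_mean_trace[1L], x$d_mean_trace[length(x$d_mean_trace)]))
  invisible(x)
}

#' Write the convergence trace of a registration as CSV
#'
#' Columns: iteration, nc, k1, k2, gamma_mm, d_mean.
#'
#' @param state A [register_pair()] result.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_registration_trace <- function(state, path) {
  stopifnot(inherits(state, "registration_state"))
  write.csv(state$trace, path, row.names = FALSE)
  invisible(path)
}
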