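# Per-vertex motion maps and their ROI summaries.
#
# All reference-indexed maps (displacement, diameter change) live on the
# vertices of the end-diastolic reference mesh (phase 0); diameter maps are
# computed per phase on that phase's own mesh.

#' Construct a per-vertex scalar map
#'
#' @param values Numeric vector of per-vertex values (mm, or percent for
#'   `diameter_change_pct`).
#' @param valid Logical vector flagging vertices with a defined value
#'   (e.g. diameter rays that hit an opposite wall).
#' @param phase 0-based cardiac phase the map belongs to.
#' @param kind One of `"displacement"`, `"diameter"`, `"diameter_change"`,
#'   `"diameter_change_pct"`.
#' @return An object of class `vertex_map`.
#' @export
vertex_map <- function(values, valid = rep(TRUE, length(values)), phase = 0L,
                       kind = c("displacement", "diameter", "diameter_change",
                                "diameter_change_pct")) {
  kind <- match.arg(kind)
  if (length(values) != length(valid))
    stop("values and valid must have equal length")
  if (any(!is.finite(values[valid])))
    stop("non-finite values flagged as valid")
  if (kind %in% c("displacement", "diameter") && any(values[valid] < 0))
    stop(kind, " values must be >= 0 where valid")
  structure(list(values = as.numeric(values), valid = as.logical(valid),
                 phase = as.integer(phase), kind = kind),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("vertex_map (%s, phase %d): %d vertices, %d valid, mean %.3f\n",
              x$kind, x$phase, length(x$values), sum(x$valid),
              if (length(v)) mean(v) else NA_real_))
  invisible(x)
}

#' Displacement map of one phase
#'
#' Displacement is the Euclidean distance between each reference vertex and
#' its registered position at the given phase.
#'
#' @param reference The reference [surface_mesh()] (phase 0).
#' @param state The [register_pair()] result mapping the reference to the
#'   phase's mesh.
#' @param phase 0-based phase index to stamp on the map.
#' @return A `"displacement"` [vertex_map()] on the reference vertices.
#' @export
displacement_map <- function(reference, state, phase) {
  stopifnot(inherits(reference, "surface_mesh"),
            inherits(state, "registration_state"))
  if (nrow(state$warped_vertices) != nrow(reference$vertices))
    stop("registration state does not match the reference mesh ",
         "(vertex counts differ)")
  vertex_map(sqrt(rowSums(state$displacement^2)), phase = phase,
             kind = "displacement")
}

#' Diameter map by inward-normal ray casting
#'
#' From every vertex a ray is cast along the inward normal (the negated
#' outward normal); the diameter is the distance to the first triangle hit
#' on the opposite wall. Hits closer than `self_hit_epsilon_mm` are skipped
#' (numerically degenerate self-intersections with the vertex's own fan) and
#' rays that exit without a hit within `max_ray_mm` (e.g. through branch
#' ostia or the open ends of a tube) are flagged invalid.
#'
#' @param mesh A [surface_mesh()] with outward normals.
#' @param max_ray_mm Maximum chord length considered, mm.
#' @param self_hit_epsilon_mm Self-intersection guard, mm.
#' @param phase 0-based phase index to stamp on the map.
#' @return A `"diameter"` [vertex_map()] on the mesh vertices.
#' @export
diameter_map <- function(mesh, max_ray_mm = 60, self_hit_epsilon_mm = 0.5,
                         phase = 0L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(mesh$normals))
    stop("mesh has no normals; run compute_outward_normals() first")
  if (max_ray_mm <= 0) stop("max_ray_mm must be > 0")
  hit <- .cpp_ray_first_hit(mesh$vertices, -mesh$normals,
                            mesh$vertices, mesh$faces,
                            self_hit_epsilon_mm, max_ray_mm)
  valid <- !is.na(hit$t)
  values <- ifelse(valid, hit$t, 0)
  vertex_map(values, valid, phase = phase, kind = "diameter")
}

#' Carry the reference diameter to a target phase and take the difference
#'
#' The reference diameter map is transported by the registration: each
#' warped reference vertex is projected to its closest point on the target
#' surface, the target phase's own diameter map is interpolated there
#' barycentrically, and the diameter change is the interpolated target
#' diameter minus the reference diameter. The percent change is relative to
#' the reference diameter.
#'
#' @param reference_diam `"diameter"` [vertex_map()] on the reference mesh.
#' @param state [register_pair()] result mapping reference to target.
#' @param target_mesh The target phase's [surface_mesh()].
#' @param target_diam `"diameter"` [vertex_map()] on `target_mesh`.
#' @return List with `change` (mm) and `change_pct` [vertex_map()]s on the
#'   reference vertices; vertices where either diameter is invalid are
#'   flagged invalid.
#' @export
transfer_diameter <- function(reference_diam, state, target_mesh, target_diam) {
  stopifnot(inherits(reference_diam, "vertex_map"),
            inherits(state, "registration_state"),
            inherits(target_mesh, "surface_mesh"),
            inherits(target_diam, "vertex_map"))
  if (length(reference_diam$values) != nrow(state$warped_vertices))
    stop("registration state does not match the reference diameter map")
  if (length(target_diam$values) != nrow(target_mesh$vertices))
    stop("target diameter map does not match the target mesh")
  cp <- .cpp_closest_on_mesh(state$warped_vertices, target_mesh$vertices,
                             target_mesh$faces)
  corners <- target_mesh$faces[cp$face, , drop = FALSE]
  interp <- rowSums(cp$bary * matrix(target_diam$values[corners], ncol = 3L))
  corner_valid <- matrix(target_diam$valid[corners], ncol = 3L)
  valid <- reference_diam$valid & rowSums(corner_valid) == 3L
  change <- ifelse(valid, interp - reference_diam$values, 0)
  pct_ok <- valid & reference_diam$values > 0
  change_pct <- ifelse(pct_ok, 100 * change / reference_diam$values, 0)
  list(change = vertex_map(change, valid, phase = target_diam$phase,
                           kind = "diameter_change"),
       change_pct = vertex_map(change_pct, pct_ok, phase = target_diam$phase,
                               kind = "diameter_change_pct"))
}

#' Axis-aligned region-of-interest box
#'
#' The ROI (for the ascending aorta: from the sinotubular edge up to the
#' mid-arch) is defined once on the reference phase in world mm coordinates
#' and stays static for all other phases.
#'
#' @param min_corner,max_corner 3-vectors in mm, `min_corner < max_corner`
#'   componentwise.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    stop("corners must be 3-vectors")
  if (!all(min_corner < max_corner))
    stop("min_corner must be strictly below max_corner componentwise")
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat("roi_box: [", paste(signif(x$min_corner, 4), collapse = ", "), "] to [",
      paste(signif(x$max_corner, 4), collapse = ", "), "] mm\n")
  invisible(x)
}

#' Select map values inside an ROI box
#'
#' Membership is evaluated at the supplied vertex positions against the
#' closed box. For reference-indexed maps (displacement, diameter change)
#' pass the reference-phase positions — membership is decided on the
#' reference phase and reused for all phases, even for vertices that move
#' out of the box at systole. For per-phase diameter maps pass that phase's
#' own vertex positions.
#'
#' @param map A [vertex_map()].
#' @param positions N x 3 matrix of positions corresponding 1:1 to the map's
#'   vertices.
#' @param roi A [roi_box()].
#' @return List with `values` (selected values, valid vertices only),
#'   `index` (their vertex indices) and `inside` (logical membership for all
#'   vertices, ignoring validity).
#' @export
roi_select <- function(map, positions, roi) {
  stopifnot(inherits(map, "vertex_map"), inherits(roi, "roi_box"))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(map$values))
    stop("positions must correspond 1:1 to map vertices")
  inside <- positions[, 1L] >= roi$min_corner[1L] &
    positions[, 1L] <= roi$max_corner[1L] &
    positions[, 2L] >= roi$min_corner[2L] &
    positions[, 2L] <= roi$max_corner[2L] &
    positions[, 3L] >= roi$min_corner[3L] &
    positions[, 3L] <= roi$max_corner[3L]
  if (!any(inside))
    stop("empty ROI: no vertices inside the box")
  sel <- inside & map$valid
  list(values = map$values[sel], index = which(sel), inside = inside)
}

#' Per-phase ROI motion curves
#'
#' Aggregates the per-vertex maps of every phase over the ROI: mean and max
#' displacement, mean diameter, mean diameter change in mm and percent.
#' Invalid vertices are excluded from the aggregates (not imputed). ROI
#' membership for the reference-indexed maps is fixed at the reference
#' positions; membership for each phase's diameter map is evaluated at that
#' phase's own vertex positions against the same static box.
#'
#' @param maps List with components `displacement`, `change`, `change_pct`
#'   (lists of [vertex_map()]s on the reference vertices, one per phase),
#'   `diameter` (list of per-phase [vertex_map()]s on each phase's mesh),
#'   `reference_positions` (N x 3) and `diameter_positions` (list of
#'   per-phase vertex position matrices).
#' @param roi A [roi_box()].
#' @return A data.frame of class `motion_curves` with columns `phase`,
#'   `mean_displacement_mm`, `max_displacement_mm`, `mean_diameter_mm`,
#'   `mean_diameter_change_mm`, `mean_diameter_change_pct`; attribute
#'   `reference_phase = 0`.
#' @export
phase_curves <- function(maps, roi) {
  n_phases <- length(maps$displacement)
  stopifnot(length(maps$diameter) == n_phases,
            length(maps$change) == n_phases,
            length(maps$change_pct) == n_phases,
            length(maps$diameter_positions) == n_phases)
  out <- data.frame(phase = 0:(n_phases - 1L),
                    mean_displacement_mm = NA_real_,
                    max_displacement_mm = NA_real_,
                    mean_diameter_mm = NA_real_,
                    mean_diameter_change_mm = NA_real_,
                    mean_diameter_change_pct = NA_real_)
  for (t in seq_len(n_phases)) {
    disp <- roi_select(maps$displacement[[t]], maps$reference_positions, roi)
    diam <- roi_select(maps$diameter[[t]], maps$diameter_positions[[t]], roi)
    chg <- roi_select(maps$change[[t]], maps$reference_positions, roi)
    pct <- roi_select(maps$change_pct[[t]], maps$reference_positions, roi)
    if (!length(disp$values) || !length(diam$values) || !length(chg$values))
      stop("phase ", t - 1L, ": no valid vertices inside the ROI")
    out$mean_displacement_mm[t] <- mean(disp$values)
    out$max_displacement_mm[t] <- max(disp$values)
    out$mean_diameter_mm[t] <- mean(diam$values)
    out$mean_diameter_change_mm[t] <- mean(chg$values)
    out$mean_diameter_change_pct[t] <-
      if (length(pct$values)) mean(pct$values) else NA_real_
  }
  structure(out, reference_phase = 0L,
            class = c("motion_curves", "data.frame"))
}

#' Write motion curves as CSV
#'
#' @param curves A [phase_curves()] result.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "motion_curves"))
  write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' Read motion curves from CSV
#'
#' @param path CSV written by [write_curves_csv()].
#' @return A `motion_curves` data.frame.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("phase", "mean_displacement_mm", "max_displacement_mm",
              "mean_diameter_mm", "mean_diameter_change_mm",
              "mean_diameter_change_pct")
  if (!all(needed %in% names(df)))
    stop("not a motion-curves CSV: missing ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  structure(df[needed], reference_phase = 0L,
            class = c("motion_curves", "data.frame"))
}

#' Write a vertex map as CSV
#'
#' Columns: vertex_id (1-based), x, y, z, value, valid.
#'
#' @param map A [vertex_map()].
#' @param positions N x 3 vertex positions the map lives on.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_vertex_map_csv <- function(map, positions, path) {
  stopifnot(inherits(map, "vertex_map"))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(map$values))
    stop("positions must correspond 1:1 to map vertices")
  df <- data.frame(vertex_id = seq_along(map$values),
                   x = positions[, 1L], y = positions[, 2L],
                   z = positions[, 3L],
                   value = map$values, valid = map$valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
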