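# End-to-end orchestration: masks -> meshes -> registration -> maps ->
# curves, with per-phase fault isolation and a structured results directory.

#' Run the full motion analysis on a segmentation series
#'
#' Extracts a surface for every cardiac phase, registers the end-diastolic
#' reference surface (always phase 0) directly and independently to each
#' subsequent phase, and derives per-vertex displacement, diameter and
#' diameter-change maps plus ROI motion curves. A registration failure on
#' one phase flags that phase invalid and the run continues.
#'
#' @param series A [segmentation_series()].
#' @param roi A [roi_box()] in world mm, defined on the reference phase.
#' @param config A [grbf_config()]; by default [grbf_config()] with
#'   `gamma_floor_mm` set to twice the series' smallest voxel edge.
#' @param max_ray_mm,self_hit_epsilon_mm Diameter ray-casting parameters,
#'   see [diameter_map()].
#' @param out_dir Optional directory; when given, curves, maps, registration
#'   traces and provenance are written there via [write_analysis_result()].
#' @param verbose Print per-phase progress to stderr.
#' @return An object of class `analysis_result`: list with `curves`
#'   ([phase_curves()] output), `maps` (per-phase vertex maps plus the
#'   positions they live on), `states` (per-phase registration states,
#'   `NULL` for the reference), `meshes`, `failed_phases` and `provenance`.
#' @export
run_motion_analysis <- function(series, roi, config = NULL,
                                max_ray_mm = 60, self_hit_epsilon_mm = 0.5,
                                out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(series, "segmentation_series"), inherits(roi, "roi_box"))
  if (is.null(config))
    config <- grbf_config(gamma_floor_mm = 2 * min(series$spacing))
  stopifnot(inherits(config, "grbf_config"))
  n <- series$n_phases
  say <- function(...) if (verbose) message(sprintf(...))

  say("extracting %d surfaces", n)
  meshes <- lapply(seq_len(n) - 1L, function(t) extract_surface(series, t))
  reference <- meshes[[1L]]
  nv <- nrow(reference$vertices)

  say("diameter map of the reference (%d vertices)", nv)
  ref_diam <- diameter_map(reference, max_ray_mm, self_hit_epsilon_mm,
                           phase = 0L)

  zeros <- function(kind, phase) vertex_map(numeric(nv), phase = phase, kind = kind)
  maps <- list(
    displacement = vector("list", n), diameter = vector("list", n),
    change = vector("list", n), change_pct = vector("list", n),
    reference_positions = reference$vertices,
    diameter_positions = lapply(meshes, `[[`, "vertices"))
  maps$displacement[[1L]] <- zeros("displacement", 0L)
  maps$diameter[[1L]] <- ref_diam
  maps$change[[1L]] <- vertex_map(numeric(nv), ref_diam$valid, 0L,
                                  "diameter_change")
  maps$change_pct[[1L]] <- vertex_map(numeric(nv), ref_diam$valid, 0L,
                                      "diameter_change_pct")
  states <- vector("list", n)
  failed <- integer(0)

  for (t in 2:n) {
    phase <- t - 1L
    res <- tryCatch({
      say("phase %d/%d: registering", phase, n - 1L)
      state <- register_pair(reference, meshes[[t]], config)
      tdiam <- diameter_map(meshes[[t]], max_ray_mm, self_hit_epsilon_mm,
                            phase = phase)
      tx <- transfer_diameter(ref_diam, state, meshes[[t]], tdiam)
      list(state = state, tdiam = tdiam, tx = tx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("phase ", phase, " failed: ", conditionMessage(res))
      failed <- c(failed, phase)
      # flagged gap: all-invalid maps keep the phase slot without biasing
      maps$displacement[[t]] <- vertex_map(numeric(nv), rep(FALSE, nv),
                                           phase, "displacement")
      maps$diameter[[t]] <- vertex_map(
        numeric(nrow(meshes[[t]]$vertices)),
        rep(FALSE, nrow(meshes[[t]]$vertices)), phase, "diameter")
      maps$change[[t]] <- vertex_map(numeric(nv), rep(FALSE, nv), phase,
                                     "diameter_change")
      maps$change_pct[[t]] <- vertex_map(numeric(nv), rep(FALSE, nv), phase,
                                         "diameter_change_pct")
      next
    }
    states[[t]] <- res$state
    maps$displacement[[t]] <- displacement_map(reference, res$state, phase)
    maps$diameter[[t]] <- res$tdiam
    maps$change[[t]] <- res$tx$change
    maps$change_pct[[t]] <- res$tx$change_pct
  }

  say("aggregating ROI curves")
  curves <- phase_curves(maps, roi)
  result <- structure(list(
    curves = curves, maps = maps, states = states, meshes = meshes,
    failed_phases = failed,
    provenance = list(
      package_version = as.character(utils::packageVersion("aortamotion")),
      config = unclass(config),
      roi = list(min_corner = roi$min_corner, max_corner = roi$max_corner),
      n_phases = n, spacing_mm = series$spacing,
      grid_shape = dim(series$data)[-1L],
      foreground_voxels = apply(series$data, 1L, sum))),
    class = "analysis_result")
  if (!is.null(out_dir)) write_analysis_result(result, out_dir)
  result
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("analysis_result:", nrow(x$curves), "phases",
      if (length(x$failed_phases))
        paste0("(failed: ", paste(x$failed_phases, collapse = ", "), ")"
        ) else "", "\n")
  print(as.data.frame(x$curves), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an analysis result as a structured directory
#'
#' Layout: `curves.csv`, `provenance.json`, `maps/phase_XX_<kind>.csv` (one
#' CSV per map, via [write_vertex_map_csv()]) and
#' `registration/phase_XX_trace.csv`. File contents are deterministic for a
#' fixed input and seed (no timestamps).
#'
#' @param result An [run_motion_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_result <- function(result, dir) {
  stopifnot(inherits(result, "analysis_result"))
  dir.create(file.path(dir, "maps"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "registration"), showWarnings = FALSE)
  write_curves_csv(result$curves, file.path(dir, "curves.csv"))
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  n <- nrow(result$curves)
  for (t in seq_len(n)) {
    tag <- sprintf("phase_%02d", t - 1L)
    write_vertex_map_csv(result$maps$displacement[[t]],
                         result$maps$reference_positions,
                         file.path(dir, "maps", paste0(tag, "_displacement.csv")))
    write_vertex_map_csv(result$maps$diameter[[t]],
                         result$maps$diameter_positions[[t]],
                         file.path(dir, "maps", paste0(tag, "_diameter.csv")))
    write_vertex_map_csv(result$maps$change[[t]],
                         result$maps$reference_positions,
                         file.path(dir, "maps", paste0(tag, "_diameter_change.csv")))
    if (!is.null(result$states[[t]]))
      write_registration_trace(result$states[[t]],
                               file.path(dir, "registration",
                                         paste0(tag, "_trace.csv")))
  }
  invisible(dir)
}
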