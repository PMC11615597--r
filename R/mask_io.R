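# Reading, validation and overlap metrics for 4D binary segmentation series.

#' Construct a 4D segmentation series
#'
#' A segmentation series holds one binary 3D mask per cardiac phase together
#' with the voxel geometry. Voxel indices are 0-based and map to world
#' millimetre coordinates (voxel centres) through the affine, following the
#' NIfTI RAS+ convention.
#'
#' @param data 4D array indexed `(phase, x, y, z)` containing only 0/1 values.
#' @param affine 4x4 matrix mapping 0-based voxel indices `(i, j, k, 1)` to
#'   world mm coordinates.
#' @param phase_duration_ms Optional temporal resolution in milliseconds.
#' @return An object of class `segmentation_series` with elements `data`,
#'   `spacing` (voxel edge lengths in mm, from the affine column norms),
#'   `affine`, `n_phases` and `phase_duration_ms`.
#' @export
segmentation_series <- function(data, affine, phase_duration_ms = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array indexed (phase, x, y, z)")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0 or 1; binarize the input first")
  n_phases <- dim(data)[1L]
  if (n_phases < 2L)
    stop("a series needs at least 2 cardiac phases, got ", n_phases)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0))
    stop("affine implies non-positive voxel spacing")
  counts <- apply(data, 1L, sum)
  if (any(counts == 0))
    stop("empty phase: phase(s) ", paste(which(counts == 0) - 1L, collapse = ", "),
         " contain no foreground voxels")
  if (max(spacing) / min(spacing) - 1 > 0.10)
    warning("anisotropic voxels: spacing components differ by more than 10% (",
            paste(signif(spacing, 4), collapse = " x "), " mm)")
  structure(
    list(data = data, spacing = spacing, affine = affine,
         n_phases = n_phases, phase_duration_ms = phase_duration_ms),
    class = "segmentation_series")
}

#' @export
print.segmentation_series <- function(x, ...) {
  cat("segmentation_series:", x$n_phases, "phases,",
      paste(dim(x$data)[-1L], collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Extract the 3D mask of one phase
#'
#' @param series A [segmentation_series()].
#' @param phase 0-based phase index.
#' @return 3D array `(x, y, z)`.
#' @export
mask_phase <- function(series, phase) {
  stopifnot(inherits(series, "segmentation_series"))
  if (phase < 0 || phase >= series$n_phases)
    stop("phase must be in [0, ", series$n_phases - 1L, "]")
  d <- dim(series$data)
  array(series$data[phase + 1L, , , ], d[2:4])
}

#' Read a 4D binary segmentation series from NIfTI
#'
#' Accepts either a single 4D NIfTI file or a character vector of per-phase
#' 3D files; a vector is sorted lexicographically, so phase indices should be
#' zero padded in the file names. Values are binarized at 0.5 (fractional
#' values arise e.g. from resampled probability maps).
#'
#' @param path Path to a 4D `.nii`/`.nii.gz` file, or a character vector of
#'   3D files (one per phase).
#' @param phase_duration_ms Optional temporal resolution to attach.
#' @return A [segmentation_series()].
#' @export
read_mask_series <- function(path, phase_duration_ms = NULL) {
  if (length(path) == 1L) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 3L)
      stop("input is a single 3D volume; pass a vector of per-phase files ",
           "or a 4D file")
    if (length(dim(arr)) != 4L)
      stop("expected a 4D NIfTI, got ", length(dim(arr)), " dimensions")
    affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    data <- aperm(arr, c(4L, 1L, 2L, 3L))
  } else {
    path <- sort(path)
    missing <- path[!file.exists(path)]
    if (length(missing)) stop("file not found: ", missing[1L])
    imgs <- lapply(path, RNifti::readNifti)
    arrs <- lapply(imgs, as.array)
    if (any(vapply(arrs, function(a) length(dim(a)), 1L) != 3L))
      stop("per-phase files must each contain a single 3D volume")
    d3 <- dim(arrs[[1L]])
    if (!all(vapply(arrs, function(a) all(dim(a) == d3), TRUE)))
      stop("per-phase volumes have inconsistent dimensions")
    affine <- structure(RNifti::xform(imgs[[1L]]), imagedim = NULL, code = NULL)
    data <- array(0, c(length(arrs), d3))
    for (t in seq_along(arrs)) data[t, , , ] <- arrs[[t]]
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  data[] <- as.numeric(data >= 0.5)
  segmentation_series(data, affine, phase_duration_ms = phase_duration_ms)
}

#' Write a segmentation series as a 4D NIfTI file
#'
#' The input affine is preserved (written as both qform and sform).
#'
#' @param series A [segmentation_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_series <- function(series, path) {
  stopifnot(inherits(series, "segmentation_series"))
  arr <- aperm(series$data, c(2L, 3L, 4L, 1L))
  storage.mode(arr) <- "integer"
  tr <- if (is.null(series$phase_duration_ms)) 0 else series$phase_duration_ms / 1000
  img <- RNifti::asNifti(arr, reference = list(
    pixdim = c(-1, series$spacing, tr, 0, 0, 0)))
  aff <- structure(series$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Validate a segmentation series
#'
#' Reports per-phase foreground voxel counts and 6-connected component
#' counts, and collects warnings for phases with multiple components or with
#' a phase-to-phase volume jump above 30%. Purely diagnostic: no errors are
#' raised.
#'
#' @param series A [segmentation_series()].
#' @return A `validation_report`: list with `phases` (data.frame of `phase`,
#'   `n_voxels`, `n_components`) and `warnings` (character vector).
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "segmentation_series"))
  n <- series$n_phases
  n_voxels <- integer(n)
  n_components <- integer(n)
  warnings <- character(0)
  for (t in seq_len(n)) {
    m <- mask_phase(series, t - 1L)
    n_voxels[t] <- sum(m)
    lab <- .cpp_label_components(as.integer(m), dim(m))
    n_components[t] <- attr(lab, "n_components")
    if (n_components[t] > 1L)
      warnings <- c(warnings, sprintf(
        "phase %d: multiple components (%d)", t - 1L, n_components[t]))
  }
  jump <- abs(diff(n_voxels)) / pmax(n_voxels[-n], 1L)
  for (t in which(jump > 0.30))
    warnings <- c(warnings, sprintf(
      "phase %d: volume jump of %.0f%% relative to phase %d",
      t, 100 * jump[t], t - 1L))
  structure(list(
    phases = data.frame(phase = 0:(n - 1L), n_voxels = n_voxels,
                        n_components = n_components),
    warnings = warnings), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$phases, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  else cat("no warnings\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [validate_series()].
#' @param path Optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  js <- jsonlite::toJSON(list(phases = report$phases,
                              warnings = report$warnings),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Dice similarity coefficient between two binary masks
#'
#' `DSC = 2|A n B| / (|A| + |B|)`, the standard voxel-overlap agreement score
#' between segmentations.
#'
#' @param mask_a,mask_b Binary arrays (or logical) of equal shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  a <- as.logical(mask_a)
  b <- as.logical(mask_b)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0)
    stop("Dice is undefined: both masks are empty")
  2 * sum(a & b) / (na + nb)
}
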