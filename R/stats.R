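# Group summaries and agreement / repeatability statistics.

#' Per-phase median and IQR over a group of motion curves
#'
#' Summarises one curve per subject into per-phase median and interquartile
#' range (Q3 - Q1, linear-interpolation quantiles) for each metric, the form
#' in which grouped motion results are reported.
#'
#' @param curves List of [phase_curves()] results (or data.frames with the
#'   same columns), one per subject, sharing the same number of phases.
#' @param metrics Metric columns to summarise.
#' @return Long data.frame with columns `phase`, `metric`, `median`, `q1`,
#'   `q3`, `iqr`.
#' @export
group_median_iqr <- function(curves,
                             metrics = c("mean_displacement_mm",
                                         "max_displacement_mm",
                                         "mean_diameter_mm",
                                         "mean_diameter_change_mm",
                                         "mean_diameter_change_pct")) {
  stopifnot(length(curves) >= 1L)
  n_phases <- vapply(curves, nrow, 1L)
  if (length(unique(n_phases)) != 1L)
    stop("curves have mixed phase counts: ",
         paste(unique(n_phases), collapse = ", "))
  metrics <- intersect(metrics, Reduce(intersect, lapply(curves, names)))
  if (!length(metrics)) stop("no common metric columns found")
  out <- list()
  for (m in metrics) {
    x <- sapply(curves, function(cv) cv[[m]])  # phases x subjects
    x <- matrix(x, nrow = n_phases[1L])
    q <- t(apply(x, 1L, quantile, probs = c(0.25, 0.5, 0.75),
                 type = 7, names = FALSE))
    out[[m]] <- data.frame(phase = 0:(n_phases[1L] - 1L), metric = m,
                           median = q[, 2L], q1 = q[, 1L], q3 = q[, 3L],
                           iqr = q[, 3L] - q[, 1L])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Agreement statistics between paired measurements
#'
#' Bland-Altman bias and limits of agreement plus Pearson correlation, with
#' a Shapiro-Wilk normality check on the differences (a warning gate, not a
#' hard stop). Differences are `a - b`, so a positive bias means the first
#' method reads higher.
#'
#' @param a,b Paired numeric vectors of equal length (>= 3).
#' @return An object of class `agreement_stats`: list with `bias`,
#'   `loa_low`, `loa_high` (bias -/+ 1.96 SD of the differences, sample SD),
#'   `pearson_r`, `shapiro_p` (NA when the differences have zero variance),
#'   `normality_warning` (TRUE when `shapiro_p < 0.05`) and `n`.
#' @export
agreement_stats <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite measurements")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  if (sd(a) == 0 || sd(b) == 0)
    stop("Pearson correlation undefined: zero variance in a measurement")
  r <- cor(a, b)
  shapiro_p <- if (s == 0) NA_real_ else shapiro.test(d)$p.value
  warn <- isTRUE(shapiro_p < 0.05)
  if (warn)
    warning("differences deviate from normality (Shapiro-Wilk p = ",
            signif(shapiro_p, 3), "); limits of agreement may be unreliable")
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, pearson_r = r,
                 shapiro_p = shapiro_p, normality_warning = warn, n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement_stats (n = %d): bias %.3f, LOA [%.3f, %.3f], Pearson r %.3f\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$pearson_r))
  if (!is.na(x$shapiro_p))
    cat(sprintf("Shapiro-Wilk p = %.3g%s\n", x$shapiro_p,
                if (x$normality_warning) " (normality questionable)" else ""))
  invisible(x)
}

#' Maximum variability across three repeated scans
#'
#' For a test/retest/rescan triple, the per-phase across-scan range
#' (max - min) is computed and the maximum variability is the largest range
#' over all cardiac phases.
#'
#' @param curves List of exactly 3 [phase_curves()] results (or numeric
#'   vectors of per-phase values) with equal phase counts.
#' @param metric Metric column to compare when curves are data.frames.
#' @return List of class `variability_result` with `max_variability`,
#'   `per_phase_range` and `metric`.
#' @export
max_variability <- function(curves, metric = "mean_displacement_mm") {
  if (length(curves) != 3L)
    stop("need exactly 3 curves (test, retest, rescan), got ", length(curves))
  vals <- lapply(curves, function(cv) {
    if (is.numeric(cv)) as.numeric(cv) else cv[[metric]]
  })
  if (any(vapply(vals, is.null, TRUE)))
    stop("metric '", metric, "' not found in all curves")
  n <- vapply(vals, length, 1L)
  if (length(unique(n)) != 1L)
    stop("curves have mixed phase counts")
  x <- do.call(cbind, vals)
  rng <- apply(x, 1L, max) - apply(x, 1L, min)
  structure(list(max_variability = max(rng), per_phase_range = rng,
                 metric = metric), class = "variability_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("variability_result (%s): max %.3f over %d phases\n",
              x$metric, x$max_variability, length(x$per_phase_range)))
  invisible(x)
}

#' Area-derived diameter
#'
#' `D_A = 2 * sqrt(area / pi)`: the diameter of the circle with the given
#' cross-sectional area, the standard way to reduce a lumen cross-section to
#' a single diameter.
#'
#' @param area_mm2 Cross-sectional area(s) in mm^2, >= 0.
#' @return Data.frame of class `area_diameter` with columns `area_mm2` and
#'   `da_mm`.
#' @export
diameter_from_area <- function(area_mm2) {
  area_mm2 <- as.numeric(area_mm2)
  if (any(!is.finite(area_mm2)) || any(area_mm2 < 0))
    stop("area must be finite and >= 0")
  structure(data.frame(area_mm2 = area_mm2,
                       da_mm = 2 * sqrt(area_mm2 / pi)),
            class = c("area_diameter", "data.frame"))
}

#' Emit grouped curves or agreement statistics as tidy CSV/JSON
#'
#' @param x A data.frame (e.g. from [group_median_iqr()]) or an
#'   `agreement_stats` / `variability_result` object.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_stats <- function(x, path) {
  if (inherits(x, "agreement_stats") || inherits(x, "variability_result"))
    x <- unclass(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
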