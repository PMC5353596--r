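#' Construct and validate a sensor trace
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param sensor Sensor-channel intensities (> 0).
#' @param reference Reference-channel intensities (> 0).
#' @param well A [well_geometry()].
#' @param cell_id Identifier.
#' @return A `sensor_trace` object.
#' @export
sensor_trace <- function(times, sensor, reference, well = well_geometry(),
                         cell_id = "cell") {
  if (length(times) < 6L || length(sensor) != length(times) ||
      length(reference) != length(times)) {
    stop_data("trace needs >= 6 samples with equal-length series")
  }
  if (any(diff(times) <= 0)) stop_data("times must be strictly increasing")
  if (any(sensor <= 0) || any(reference <= 0)) {
    stop_data("intensities must be positive")
  }
  structure(list(times = times, sensor = sensor, reference = reference,
                 well = well, cell_id = cell_id),
            class = "sensor_trace")
}

#' Self-referencing ratiometric normalization
#'
#' Divides the oxygen-sensitive sensor channel by the oxygen-insensitive
#' reference (rhodamine 123) channel, making the readout independent of the
#' deposited sensor volume.
#'
#' @param trace A `sensor_trace`.
#' @return Unitless ratio series, same length as the trace.
#' @export
ratiometric_normalize <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  bad <- which(trace$reference <= 0)
  if (length(bad)) {
    stop_data("non-positive reference intensity at index ",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  trace$sensor / trace$reference
}

#' Centered sliding average
#'
#' Centered moving mean with the window shrinking symmetrically at the
#' series edges, so the output has the same length as the input.
#'
#' @param series Numeric series.
#' @param window Odd window width (default 5, the instrument convention).
#' @return Smoothed series of equal length.
#' @export
sliding_average <- function(series, window = 5L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0) {
    stop_config("window must be an odd positive integer")
  }
  n <- length(series)
  if (window > n) stop_config("window exceeds series length")
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(series[(i - h):(i + h)])
  }, numeric(1))
}

#' Sensor calibration model
#'
#' Stern-Volmer parameters used to invert the sensor/reference ratio to a
#' dissolved-oxygen concentration.
#'
#' @param ksv Quenching constant, per uM.
#' @param i0 Anoxic (unquenched) ratio.
#' @param provenance `"configured"` or `"two-point"`.
#' @return A `calibration_model` object.
#' @export
calibration_model <- function(ksv, i0, provenance = "configured") {
  assert_scalar_number(ksv, "ksv", lower = 0, strict_lower = TRUE)
  assert_scalar_number(i0, "i0", lower = 0, strict_lower = TRUE)
  provenance <- match.arg(provenance, c("configured", "two-point"))
  structure(list(ksv = ksv, i0 = i0, provenance = provenance),
            class = "calibration_model")
}

#' Invert the Stern-Volmer relation: ratio series to oxygen concentration
#'
#' `C[t] = (i0 / ratio[t] - 1) / ksv`, clamped at zero from below. Ratios
#' exceeding `i0` (which would imply negative oxygen) are clamped and
#' counted; the count is attached as attribute `"n_clamped"` and a warning
#' is raised when it is non-zero beyond `tolerance`.
#'
#' @param ratio Unitless ratio series (> 0).
#' @param cal A [calibration_model()].
#' @param tolerance Relative excess over `i0` ignored without warning.
#' @return Concentration series in uM with attribute `n_clamped`.
#' @export
calibrate <- function(ratio, cal, tolerance = 0.02) {
  stopifnot(inherits(cal, "calibration_model"))
  if (any(ratio <= 0)) stop_data("ratios must be positive")
  conc <- (cal$i0 / ratio - 1) / cal$ksv
  n_clamped <- sum(ratio > cal$i0 * (1 + tolerance))
  if (n_clamped > 0) {
    warning(n_clamped, " ratio value(s) exceed i0 beyond tolerance; ",
            "concentration clamped at 0")
  }
  conc <- pmax(0, conc)
  attr(conc, "n_clamped") <- n_clamped
  conc
}

#' Two-point Stern-Volmer calibration
#'
#' Solves for `i0` and `ksv` from the ratio under anoxia (nitrogen purge)
#' and the ratio at one known oxygen concentration: `i0 = ratio_at_anoxia`,
#' `ksv = (i0 / ratio_at_known_c - 1) / known_c`.
#'
#' @param ratio_at_anoxia Ratio at zero oxygen.
#' @param ratio_at_known_c Ratio at `known_c`.
#' @param known_c Known concentration, uM (> 0).
#' @return A [calibration_model()] with provenance `"two-point"`.
#' @export
two_point_calibrate <- function(ratio_at_anoxia, ratio_at_known_c, known_c) {
  assert_scalar_number(ratio_at_anoxia, "ratio_at_anoxia",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(ratio_at_known_c, "ratio_at_known_c",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(known_c, "known_c", lower = 0, strict_lower = TRUE)
  if (ratio_at_anoxia <= ratio_at_known_c) {
    stop_data("calibration requires ratio_at_anoxia > ratio_at_known_c ",
              "(quenching must reduce the ratio)")
  }
  i0 <- ratio_at_anoxia
  ksv <- (i0 / ratio_at_known_c - 1) / known_c
  calibration_model(ksv = ksv, i0 = i0, provenance = "two-point")
}

#' Extract a single-cell OCR from a sealed-well sensor trace
#'
#' Normalizes the two channels ratiometrically, inverts the calibration to
#' an oxygen concentration series, optionally applies the 5-point sliding
#' average, restricts to the pre-depletion region (before the
#' concentration first falls below 2% of its initial value, where the
#' zero-clamp would bias the slope), fits an ordinary least squares line
#' C(t) = a + b t, and converts the slope to an OCR:
#' `ocr = max(0, -b) * V * ku` with `V` the well volume in pL and
#' `ku = 1e-3` fmol per uM*pL. Cells with OCR below `detection_floor` are
#' classified non-respiring.
#'
#' @param trace A `sensor_trace`.
#' @param cal A [calibration_model()].
#' @param smooth Apply the sliding average before fitting (default TRUE).
#' @param smooth_window Odd window width.
#' @param fit_window Optional numeric length-2 time range (min) to fit in.
#' @param detection_floor Respirer classification threshold, fmol/min.
#' @param qc_tolerance Relative ratio change tolerated by the seal check.
#' @return A one-row data frame (`ocr_result`): `cell_id`, `ocr_fmol_min`,
#'   `slope_uM_min`, `r_squared`, `respirer_class`, `sealed`, `n_points`.
#' @export
extract_ocr <- function(trace, cal, smooth = TRUE, smooth_window = 5L,
                        fit_window = NULL, detection_floor = 0.1,
                        qc_tolerance = 0.05) {
  stopifnot(inherits(trace, "sensor_trace"))
  ratio <- ratiometric_normalize(trace)
  conc <- suppressWarnings(calibrate(ratio, cal))
  # Smoothing acts on the calibrated concentration series: pre-floor it is
  # linear in time, so the centered moving average leaves the slope
  # unbiased, which smoothing the (curved) ratio would not.
  if (smooth) conc <- sliding_average(as.numeric(conc), smooth_window)

  times <- trace$times
  keep <- rep(TRUE, length(times))
  if (!is.null(fit_window)) {
    keep <- times >= fit_window[1] & times <= fit_window[2]
  }
  first <- which(keep)[1]
  if (is.na(first)) stop_data("fit_window contains no samples")
  c0 <- conc[first]
  if (c0 <= 0) {
    stop_data("trace ", trace$cell_id,
              " is entirely at the oxygen depletion floor")
  }
  # Pre-depletion region: stop before the floor, where clamping flattens the
  # series and biases the slope toward zero. When smoothing is on, points
  # whose window overlaps the floor region are contaminated too, so the cut
  # moves earlier by the half-window.
  floored <- which(keep & conc < 0.02 * c0)
  if (length(floored)) {
    cut <- min(floored)
    if (smooth) cut <- max(2L, cut - (smooth_window - 1L) %/% 2L)
    keep[seq(cut, length(keep))] <- FALSE
  }
  if (sum(keep) < 5L) {
    stop_data("fewer than 5 usable points before oxygen depletion in ",
              trace$cell_id)
  }

  t_fit <- times[keep]
  c_fit <- conc[keep]
  fit <- stats::lm(c_fit ~ t_fit)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((c_fit - mean(c_fit))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  ocr <- max(0, -slope) * trace$well$volume * UM_PL_TO_FMOL
  non_respiring <- ocr < detection_floor
  # A well that draws down demonstrates its own seal (ambient resupply would
  # prevent depletion); the flat-ratio check is only informative for wells
  # whose expected signal is constant.
  sealed <- if (non_respiring) {
    isTRUE(qc_seal(trace, tolerance = qc_tolerance))
  } else TRUE

  res <- data.frame(
    cell_id = trace$cell_id,
    ocr_fmol_min = if (non_respiring) 0 else ocr,
    slope_uM_min = slope,
    r_squared = r2,
    respirer_class = if (non_respiring) "non-respiring" else "respiring",
    sealed = sealed,
    n_points = sum(keep),
    stringsAsFactors = FALSE)
  class(res) <- c("ocr_result", class(res))
  res
}

#' Seal quality-control check
#'
#' A hermetically sealed well containing a non-consuming volume shows no
#' change in the normalized sensor ratio; for a respiring cell the relevant
#' check is applied to a dedicated QC window (e.g. a post-drawdown nitrogen
#' purge). The flag compares the mean smoothed ratio at the start and end of
#' the window.
#'
#' @param trace A `sensor_trace`.
#' @param tolerance Maximum tolerated relative change of the ratio.
#' @param qc_window Optional length-2 time range (min); default whole trace.
#' @param edge_points Number of samples averaged at each end.
#' @return Logical: `TRUE` when sealed.
#' @export
qc_seal <- function(trace, tolerance = 0.05, qc_window = NULL,
                    edge_points = 3L) {
  stopifnot(inherits(trace, "sensor_trace"))
  ratio <- ratiometric_normalize(trace)
  if (!is.null(qc_window)) {
    keep <- trace$times >= qc_window[1] & trace$times <= qc_window[2]
    ratio <- ratio[keep]
  }
  n <- length(ratio)
  k <- min(edge_points, n %/% 2)
  if (k < 1) return(NA)
  start_mean <- mean(ratio[seq_len(k)])
  end_mean <- mean(ratio[seq(n - k + 1L, n)])
  abs(end_mean - start_mean) / start_mean <= tolerance
}

#' Extract OCR for every well in a study
#'
#' @param traces Named list of `sensor_trace` objects.
#' @param manifest Manifest data frame (`cell_id`, `cell_type`, `strain`).
#' @param cal A [calibration_model()].
#' @param ... Passed to [extract_ocr()].
#' @return OCR table: one row per cell, manifest annotation columns joined.
#' @export
extract_ocr_batch <- function(traces, manifest, cal, ...) {
  rows <- lapply(traces, extract_ocr, cal = cal, ...)
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  merge(manifest[, intersect(c("cell_id", "cell_type", "strain"),
                             names(manifest)), drop = FALSE],
        tab, by = "cell_id", sort = FALSE)
}
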