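# Windowed peak height above a local edge-line baseline: the maximum intensity
# inside [center - hw, center + hw] minus the straight line through the
# window's two edge points, floored at zero.
window_peak_height <- function(shift, intensity, center, half_window) {
  lo <- center - half_window
  hi <- center + half_window
  idx <- which(shift >= lo & shift <= hi)
  if (length(idx) == 0) {
    abort(paste0("window [", lo, ", ", hi, "] contains no axis points"))
  }
  x <- shift[idx]
  y <- intensity[idx]
  if (length(idx) >= 2) {
    x1 <- x[1]; x2 <- x[length(x)]
    y1 <- y[1]; y2 <- y[length(y)]
    base <- y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  } else {
    base <- y
  }
  max(0, max(y - base))
}

#' Baseline-corrected peak intensity in a shift window
#'
#' For each spectrum, takes the maximum intensity within
#' `center +/- half_window` and subtracts a local linear baseline interpolated
#' between the window's two edge intensities (floored at zero). This local
#' edge-line correction removes any linear background exactly and is adequate
#' for the gentle polynomial baselines the generator produces.
#'
#' @param data A `sers_spectra` tibble.
#' @param center Window center (cm\eqn{^{-1}}).
#' @param half_window Half width (cm\eqn{^{-1}}), default 10.
#' @return Tibble: per-spectrum metadata plus a `peak_intensity` column.
#' @export
peak_intensity <- function(data, center, half_window = 10) {
  validate_spectra(data)
  axis <- spectra_axis(data)
  if (center + half_window < axis[1] || center - half_window > axis[length(axis)]) {
    abort(paste0("window [", center - half_window, ", ",
                 center + half_window, "] lies outside the spectral axis"))
  }
  meta <- spectra_meta(data)
  vals <- data |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::summarise(peak_intensity = window_peak_height(
      .data$shift, .data$intensity, center, half_window), .groups = "drop")
  dplyr::left_join(meta, vals, by = "spectrum_id")
}

#' Internal-standard ratiometric signal
#'
#' The quantification signal: the Schiff-base C=N peak intensity (default
#' window 1625 cm\eqn{^{-1}}) divided by the phenylacetylene internal-standard
#' intensity (default 1985 cm\eqn{^{-1}}). Because both bands scale jointly
#' with collection efficiency and laser power, the ratio cancels
#' whole-spectrum intensity drift.
#'
#' @param data A `sers_spectra` tibble.
#' @param signal_center,is_center Window centers (cm\eqn{^{-1}}).
#' @param half_window Half width (cm\eqn{^{-1}}).
#' @return Tibble: per-spectrum metadata plus a `ratio` column.
#' @export
ratiometric_signal <- function(data, signal_center = 1625,
                               is_center = 1985, half_window = 10) {
  sig <- peak_intensity(data, signal_center, half_window)
  ref <- peak_intensity(data, is_center, half_window)
  if (any(ref$peak_intensity <= 0)) {
    abort("internal standard absent (zero intensity in the IS window)")
  }
  out <- sig
  out$ratio <- sig$peak_intensity / ref$peak_intensity
  out$peak_intensity <- NULL
  out
}

#' Fit the ratiometric calibration line
#'
#' Ordinary least squares of the ratiometric signal on
#' \eqn{\log_{10}}(concentration), the model behind internal-standard SERS
#' quantification: `ratio = slope * log10(c) + intercept`.
#'
#' @param data Either a `sers_spectra` tibble (ratios are computed with
#'   [ratiometric_signal()]) or a tibble already holding `concentration` and
#'   `ratio` columns.
#' @param ... Passed to [ratiometric_signal()] when ratios are computed.
#' @return A `sers_calibration` object with fields `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n_points`, the underlying `lm` fit and the
#'   fitted data. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_calibration <- function(data, ...) {
  if (!all(c("concentration", "ratio") %in% names(data))) {
    data <- ratiometric_signal(data, ...)
  }
  pts <- data[, c("concentration", "ratio")]
  if (any(is.na(pts$concentration)) || any(pts$concentration <= 0)) {
    abort("all concentrations must be known and > 0")
  }
  if (length(unique(pts$concentration)) < 3) {
    abort("need >= 3 distinct concentrations for calibration")
  }
  pts$log10_conc <- log10(pts$concentration)
  if (var(pts$log10_conc) == 0) abort("zero variance in log10(concentration)")
  fit <- lm(ratio ~ log10_conc, data = pts)
  sm <- summary(fit)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n_points = nrow(pts),
    max_concentration = max(pts$concentration),
    fit = fit,
    data = tibble::as_tibble(pts)
  )
  structure(out, class = "sers_calibration")
}

#' @export
print.sers_calibration <- function(x, ...) {
  cat("Ratiometric SERS calibration (ratio ~ log10 concentration)\n")
  cat(sprintf("  slope      %.4f per decade\n", x$slope))
  cat(sprintf("  intercept  %.4f\n", x$intercept))
  cat(sprintf("  R-squared  %.4f\n", x$r_squared))
  cat(sprintf("  residual SD %.4g  (n = %d)\n", x$residual_sd, x$n_points))
  invisible(x)
}

#' Limit of detection from blank statistics
#'
#' Back-projects the decision level `blank_mean + multiplier * blank_sd`
#' (signal-to-noise 3:1 by default) through the calibration line:
#' \deqn{LOD = 10^{(m_b + k s_b - intercept)/slope}.}
#'
#' @param calibration A `sers_calibration`.
#' @param blank_mean,blank_sd Mean and SD of the blank ratiometric signal.
#' @param multiplier Signal-to-noise multiplier (default 3).
#' @return A `sers_lod` list with `lod` (v/v), `snr_multiplier`, `blank_mean`,
#'   `blank_sd`. Warns when the LOD reaches the top of the calibrated range.
#' @export
estimate_lod <- function(calibration, blank_mean, blank_sd, multiplier = 3) {
  if (calibration$slope <= 0) {
    abort("calibration not invertible (slope must be > 0)")
  }
  if (blank_sd < 0) abort("blank_sd must be >= 0")
  if (multiplier <= 0) abort("multiplier must be > 0")
  expo <- (blank_mean + multiplier * blank_sd - calibration$intercept) /
    calibration$slope
  lod <- 10^expo
  if (lod >= (calibration$max_concentration %||% Inf)) {
    warn("LOD at or above the calibrated concentration range")
  }
  structure(list(lod = lod, snr_multiplier = multiplier,
                 blank_mean = blank_mean, blank_sd = blank_sd),
            class = "sers_lod")
}

#' @export
print.sers_lod <- function(x, ...) {
  cat(sprintf("LOD = %.3g v/v (blank %.3g +/- %.3g, SNR %g:1)\n",
              x$lod, x$blank_mean, x$blank_sd, x$snr_multiplier))
  invisible(x)
}

#' Blank ratiometric statistics from blank spectra
#'
#' Convenience helper for LOD estimation: generates or accepts analyte-free
#' spectra (reporters and internal standard only) and returns the mean and SD
#' of their ratiometric signal.
#'
#' @param n_blanks Number of blank spectra to generate.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param class_name Substrate class used for the blank chemistry.
#' @return Tibble with `blank_mean`, `blank_sd`, `n`.
#' @export
blank_statistics <- function(n_blanks = 20,
                             config = generator_config("easy"),
                             seed = 1, class_name = "benzaldehyde") {
  seeds <- spawn_seeds(seed, n_blanks)
  specs <- purrr::map(seq_len(n_blanks), function(i) {
    set.seed(seeds[i])
    g <- generate_one(class_name, 0, config)
    new_spectra(i, class_name, 0, NA_integer_, g$shift, g$intensity)
  })
  blanks <- dplyr::bind_rows(specs)
  class(blanks) <- c("sers_spectra", class(tibble::tibble()))
  r <- ratiometric_signal(blanks)
  tibble::tibble(blank_mean = mean(r$ratio), blank_sd = sd(r$ratio),
                 n = n_blanks)
}
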