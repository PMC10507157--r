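# Line-shape kernels. Amplitude is the height at the center; fwhm the full
# width at half maximum.
peak_profile <- function(x, center, amplitude, fwhm, shape = "lorentzian") {
  if (fwhm <= 0) abort("fwhm must be > 0")
  if (shape == "lorentzian") {
    hw <- fwhm / 2
    amplitude / (1 + ((x - center) / hw)^2)
  } else if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * ((x - center) / fwhm)^2)
  } else {
    abort(paste0("unknown peak shape: ", shape))
  }
}

#' Synthetic-spectrum generator configuration
#'
#' The two presets emulate the spectral quality of the ppb-level and ppt-level
#' acquisitions: `"easy"` uses 1 cm\eqn{^{-1}} peak-center jitter, additive
#' noise at 1\% of the internal-standard amplitude and on average one erratic
#' miscellaneous peak per spectrum; `"hard"` uses 4 cm\eqn{^{-1}} jitter, 10\%
#' noise and five misc peaks. Misc peaks are placed uniformly in 1100--1500
#' cm\eqn{^{-1}}, the region where real spectra show variable, unassigned
#' structure. The concentration response is log-linear: the expected
#' anchor-to-IS ratio equals `response_slope * log10(c) + response_intercept`,
#' clipped at zero.
#'
#' @param preset `"easy"` or `"hard"`; sets `center_jitter_sd`, `noise_sd`
#'   and `misc_peak_rate`, each overridable.
#' @param axis_start,axis_stop,axis_n Shift axis: 1000--2300 cm\eqn{^{-1}},
#'   648 points.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param baseline_coefs Polynomial baseline coefficients `c(b0, b1, b2)` in
#'   the normalized coordinate `u = (shift - start) / (stop - start)`.
#' @param center_jitter_sd Per-peak center jitter SD (cm\eqn{^{-1}}).
#' @param misc_peak_rate Expected number of erratic misc peaks per spectrum.
#' @param misc_amplitude_range Uniform amplitude range for misc peaks.
#' @param misc_fwhm FWHM of misc peaks (cm\eqn{^{-1}}).
#' @param response_slope,response_intercept Log-linear ratio law (per decade /
#'   ratio units).
#' @param peak_fwhm FWHM of library peaks (cm\eqn{^{-1}}).
#' @param peak_shape `"lorentzian"` (typical Raman line shape) or
#'   `"gaussian"`.
#' @param reporter_amplitude,is_amplitude Heights of the shared 4-ATP reporter
#'   (scaled by the library's relative amplitudes) and internal-standard
#'   peaks.
#' @param n_batches Number of simulated independent measurement batches the
#'   replicate id cycles over.
#' @return A `generator_config` list.
#' @export
generator_config <- function(preset = c("easy", "hard"),
                             axis_start = 1000, axis_stop = 2300,
                             axis_n = 648,
                             noise_sd = NULL,
                             baseline_coefs = c(0.5, 0.8, -0.4),
                             center_jitter_sd = NULL,
                             misc_peak_rate = NULL,
                             misc_amplitude_range = c(0.5, 3),
                             misc_fwhm = 12,
                             response_slope = 0.35,
                             response_intercept = 3.45,
                             peak_fwhm = 10,
                             peak_shape = c("lorentzian", "gaussian"),
                             reporter_amplitude = 2,
                             is_amplitude = 10,
                             n_batches = 4) {
  preset <- match.arg(preset)
  peak_shape <- match.arg(peak_shape)
  defaults <- list(
    easy = list(jitter = 1, noise_frac = 0.01, misc = 1),
    hard = list(jitter = 4, noise_frac = 0.10, misc = 5)
  )[[preset]]
  cfg <- list(
    preset = preset,
    axis_start = axis_start, axis_stop = axis_stop, axis_n = axis_n,
    noise_sd = noise_sd %||% (defaults$noise_frac * is_amplitude),
    baseline_coefs = baseline_coefs,
    center_jitter_sd = center_jitter_sd %||% defaults$jitter,
    misc_peak_rate = misc_peak_rate %||% defaults$misc,
    misc_amplitude_range = misc_amplitude_range,
    misc_fwhm = misc_fwhm,
    response_slope = response_slope,
    response_intercept = response_intercept,
    peak_fwhm = peak_fwhm,
    peak_shape = peak_shape,
    reporter_amplitude = reporter_amplitude,
    is_amplitude = is_amplitude,
    n_batches = n_batches
  )
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$misc_peak_rate < 0) abort("misc_peak_rate must be >= 0")
  if (cfg$center_jitter_sd < 0) abort("center_jitter_sd must be >= 0")
  if (cfg$axis_n < 13) abort("axis_n must be >= 13")
  structure(cfg, class = "generator_config")
}

# Expected anchor/IS ratio at a given concentration, clipped at zero.
response_ratio <- function(concentration, config) {
  if (concentration < 0) abort("concentration must be >= 0")
  if (concentration == 0) return(0)
  max(0, config$response_slope * log10(concentration) +
        config$response_intercept)
}

# Class peak table with absolute amplitudes: reporters/IS fixed,
# characteristic peaks scaled by `char_scale`.
class_peak_table <- function(class_name, config, char_scale = 1) {
  lib <- aldehyde_library()
  peaks <- lib[lib$class == class_name, , drop = FALSE]
  if (nrow(peaks) == 0) abort(paste0("unknown class: ", class_name))
  amp_base <- c(reporter = config$reporter_amplitude,
                internal_standard = config$is_amplitude,
                characteristic = char_scale)
  peaks$amplitude <- peaks$rel_amplitude * amp_base[peaks$role]
  peaks
}

baseline_values <- function(shift, config) {
  u <- (shift - config$axis_start) / (config$axis_stop - config$axis_start)
  b <- config$baseline_coefs
  b[1] + b[2] * u + b[3] * u^2
}

sum_peaks <- function(shift, centers, amplitudes, fwhm, shape) {
  y <- numeric(length(shift))
  for (i in seq_along(centers)) {
    if (amplitudes[i] != 0) {
      y <- y + peak_profile(shift, centers[i], amplitudes[i], fwhm[i], shape)
    }
  }
  y
}

# Solve the characteristic amplitude scale so that the *measured* windowed
# anchor/IS intensity ratio of the noiseless, unjittered signal equals the
# target ratio exactly. The measured window intensity is affine in the scale,
# so two evaluations determine it.
solve_char_scale <- function(class_name, target_ratio, shift, config) {
  if (target_ratio <= 0) return(0)
  anchor <- aldehyde_library()
  anchor <- anchor$center[anchor$class == class_name & anchor$anchor][1]
  base <- baseline_values(shift, config)
  fixed <- class_peak_table(class_name, config, char_scale = 0)
  fixed <- fixed[fixed$role != "characteristic", , drop = FALSE]
  y_fixed <- base + sum_peaks(shift, fixed$center, fixed$amplitude,
                              rep(config$peak_fwhm, nrow(fixed)),
                              config$peak_shape)
  is_meas <- window_peak_height(shift, y_fixed, 1985, 10)
  if (is_meas <= 0) abort("internal standard not measurable at 1985 cm-1")
  measure_at <- function(s) {
    ch <- class_peak_table(class_name, config, char_scale = s)
    ch <- ch[ch$role == "characteristic", , drop = FALSE]
    y <- y_fixed + sum_peaks(shift, ch$center, ch$amplitude,
                             rep(config$peak_fwhm, nrow(ch)),
                             config$peak_shape)
    window_peak_height(shift, y, anchor, 10)
  }
  m1 <- measure_at(1)
  m2 <- measure_at(2)
  slope <- m2 - m1
  if (slope <= 0) abort("degenerate anchor response")
  s <- 1 + (target_ratio * is_meas - m1) / slope
  max(0, s)
}

# One random spectrum; assumes the RNG state is already set by the caller.
# `char_scale` can be precomputed (per class x concentration) by callers
# generating many spectra.
generate_one <- function(class_name, concentration, config,
                         char_scale = NULL) {
  shift <- default_axis(config$axis_start, config$axis_stop, config$axis_n)
  s <- char_scale %||% solve_char_scale(
    class_name, response_ratio(concentration, config), shift, config)
  peaks <- class_peak_table(class_name, config, char_scale = s)
  peaks <- peaks[peaks$amplitude > 0, , drop = FALSE]
  centers <- peaks$center +
    rnorm(nrow(peaks), 0, config$center_jitter_sd)
  y <- baseline_values(shift, config) +
    sum_peaks(shift, centers, peaks$amplitude,
              rep(config$peak_fwhm, nrow(peaks)), config$peak_shape)
  n_misc <- rpois(1, config$misc_peak_rate)
  if (n_misc > 0) {
    mc <- runif(n_misc, 1100, 1500)
    ma <- runif(n_misc, config$misc_amplitude_range[1],
                config$misc_amplitude_range[2])
    y <- y + sum_peaks(shift, mc, ma, rep(config$misc_fwhm, n_misc),
                       config$peak_shape)
  }
  if (config$noise_sd > 0) {
    y <- y + rnorm(length(shift), 0, config$noise_sd)
  }
  list(shift = shift, intensity = y)
}

#' Generate one synthetic SERS spectrum
#'
#' The deterministic signal is a sum of the class's library peaks on a
#' quadratic baseline; characteristic-peak amplitudes are calibrated so the
#' measured anchor/IS windowed ratio of the noiseless spectrum follows the
#' configured log-linear concentration law exactly. Randomness adds per-peak
#' center jitter, Poisson-count miscellaneous peaks in 1100--1500
#' cm\eqn{^{-1}}, and white noise.
#'
#' @param class_name One of [aldehyde_classes()].
#' @param concentration Volume fraction (v/v), `>= 0`; zero gives a blank
#'   (reporters and IS only).
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @param spectrum_id,replicate Metadata attached to the output.
#' @return A `sers_spectra` tibble with one spectrum.
#' @export
#' @examples
#' sp <- generate_spectrum("oxalaldehyde", 1e-7,
#'                         generator_config("easy"), seed = 1)
generate_spectrum <- function(class_name, concentration, config,
                              seed = NULL, spectrum_id = 1L,
                              replicate = NA_integer_) {
  if (!class_name %in% aldehyde_classes()) {
    abort(paste0("unknown class: ", class_name))
  }
  if (concentration < 0) abort("concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  g <- generate_one(class_name, concentration, config)
  new_spectra(spectrum_id, class_name, concentration, replicate,
              g$shift, g$intensity)
}

# Derive independent per-spectrum seeds from a root seed so adding spectra for
# one class does not perturb the draws of another.
spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a labeled synthetic dataset
#'
#' Emulates the study design: `n_per_class` spectra per aldehyde at a common
#' concentration, collected over `config$n_batches` simulated independent
#' measurements (the replicate id cycles over batches). Each spectrum draws
#' from its own RNG substream spawned from `seed`, so the output is
#' reproducible and per-class draws are independent.
#'
#' @param n_per_class Spectra per class (default 108, giving 648 for six
#'   classes).
#' @param classes Character vector of classes.
#' @param concentration Common volume fraction (default `1e-7`, i.e. 100 ppb).
#' @param config A [generator_config()].
#' @param seed Integer root seed.
#' @return A `sers_spectra` tibble with `n_per_class * length(classes)`
#'   spectra, grouped by class in `classes` order.
#' @export
generate_dataset <- function(n_per_class = 108,
                             classes = aldehyde_classes(),
                             concentration = 1e-7,
                             config = generator_config("easy"),
                             seed = 1) {
  if (length(classes) == 0) abort("empty class list")
  if (n_per_class < 1) abort("n_per_class must be >= 1")
  plan <- tidyr::crossing(label = factor(classes, levels = classes),
                          idx = seq_len(n_per_class)) |>
    dplyr::arrange(.data$label, .data$idx)
  plan$label <- as.character(plan$label)
  plan$replicate <- ((plan$idx - 1L) %% config$n_batches) + 1L
  seeds <- spawn_seeds(seed, nrow(plan))
  shift <- default_axis(config$axis_start, config$axis_stop, config$axis_n)
  scales <- vapply(classes, function(cl) solve_char_scale(
    cl, response_ratio(concentration, config), shift, config), numeric(1))
  specs <- purrr::pmap(
    list(plan$label, plan$replicate, seeds, seq_len(nrow(plan))),
    function(lab, rep, s, id) {
      set.seed(s)
      g <- generate_one(lab, concentration, config,
                        char_scale = scales[[lab]])
      new_spectra(id, lab, concentration, rep, g$shift, g$intensity)
    }
  )
  out <- dplyr::bind_rows(specs)
  class(out) <- c("sers_spectra", class(tibble::tibble()))
  out
}

#' Generate a benzaldehyde calibration series
#'
#' One class measured over decade-spaced concentrations (default
#' \eqn{10^{-8}}--\eqn{10^{-4}} v/v), several replicates per level, for
#' fitting the ratiometric calibration line.
#'
#' @param concentrations Positive volume fractions.
#' @param config A [generator_config()].
#' @param seed Integer root seed.
#' @param n_replicates Spectra per concentration level.
#' @param class_name Analyte class (default benzaldehyde).
#' @return A `sers_spectra` tibble.
#' @export
generate_calibration_series <- function(concentrations = 10^seq(-8, -4),
                                        config = generator_config("easy"),
                                        seed = 1, n_replicates = 3,
                                        class_name = "benzaldehyde") {
  if (any(concentrations <= 0)) {
    abort("concentrations must be > 0 (log-linear response undefined at 0)")
  }
  plan <- tidyr::crossing(concentration = concentrations,
                          rep = seq_len(n_replicates))
  seeds <- spawn_seeds(seed, nrow(plan))
  shift <- default_axis(config$axis_start, config$axis_stop, config$axis_n)
  scales <- vapply(unique(plan$concentration), function(co) solve_char_scale(
    class_name, response_ratio(co, config), shift, config), numeric(1))
  names(scales) <- as.character(unique(plan$concentration))
  specs <- purrr::pmap(
    list(plan$concentration, plan$rep, seeds, seq_len(nrow(plan))),
    function(conc, rep, s, id) {
      set.seed(s)
      g <- generate_one(class_name, conc, config,
                        char_scale = scales[[as.character(conc)]])
      new_spectra(id, class_name, conc, rep, g$shift, g$intensity)
    }
  )
  out <- dplyr::bind_rows(specs)
  class(out) <- c("sers_spectra", class(tibble::tibble()))
  out
}
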