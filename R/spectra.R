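#' The six aldehyde classes, in canonical order
#'
#' Class order is fixed throughout the package: it defines the column order of
#' one-hot label encodings, the row/column order of confusion matrices, and the
#' tie-breaking order of predictions.
#'
#' @return Character vector of six class names.
#' @export
#' @examples
#' aldehyde_classes()
aldehyde_classes <- function() {
  c("formaldehyde", "benzaldehyde", "oxalaldehyde",
    "glutaraldehyde", "salicylaldehyde", "4-nitrobenzaldehyde")
}

#' Default Raman shift axis
#'
#' The working axis spans 1000--2300 cm\eqn{^{-1}} sampled at 648 points, the
#' grid on which all synthetic spectra are generated and featurized.
#'
#' @param start,stop Axis limits in cm\eqn{^{-1}}.
#' @param n Number of points.
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
default_axis <- function(start = 1000, stop = 2300, n = 648) {
  if (n < 13) abort("axis must have at least 13 points (one per band)")
  seq(start, stop, length.out = n)
}

# Build a spectra tibble from parallel vectors; no validation here.
new_spectra <- function(spectrum_id, label, concentration, replicate,
                        shift, intensity) {
  out <- tibble::tibble(
    spectrum_id = as.integer(spectrum_id),
    label = as.character(label),
    concentration = as.numeric(concentration),
    replicate = as.integer(replicate),
    shift = as.numeric(shift),
    intensity = as.numeric(intensity)
  )
  class(out) <- c("sers_spectra", class(out))
  out
}

#' Construct a single Raman spectrum as a tidy tibble
#'
#' Spectra are stored in long form: one row per (spectrum, shift) pair with
#' metadata columns `spectrum_id`, `label`, `concentration` (volume fraction,
#' v/v) and `replicate`. Collections of spectra are simply row-bound tibbles of
#' the same shape sharing one shift axis.
#'
#' @param shift Strictly increasing Raman shifts (cm\eqn{^{-1}}).
#' @param intensity Intensities (arbitrary counts), same length as `shift`.
#' @param label Aldehyde class name or `NA`.
#' @param concentration Volume fraction (v/v) or `NA`.
#' @param replicate Integer replicate id or `NA`.
#' @param spectrum_id Integer id, default 1.
#' @return A `sers_spectra` tibble.
#' @export
#' @examples
#' sp <- raman_spectrum(default_axis(), rep(0, 648))
raman_spectrum <- function(shift, intensity, label = NA_character_,
                           concentration = NA_real_, replicate = NA_integer_,
                           spectrum_id = 1L) {
  out <- new_spectra(spectrum_id, label, concentration, replicate,
                     shift, intensity)
  validate_spectra(out)
  out
}

#' Validate a spectra tibble
#'
#' Checks the invariants every downstream stage assumes: required columns,
#' finite values, a strictly increasing per-spectrum axis, and (when more than
#' one spectrum is present) an axis shared element-wise by all spectra.
#'
#' @param data A `sers_spectra` tibble.
#' @param classes Allowed class labels; labels must be `NA` or a member.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_spectra <- function(data, classes = aldehyde_classes()) {
  needed <- c("spectrum_id", "shift", "intensity")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("spectra tibble lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("spectra tibble is empty")
  if (!all(is.finite(data$shift))) abort("non-finite Raman shift values")
  if (!all(is.finite(data$intensity))) abort("non-finite intensity values")
  split_shift <- split(data$shift, data$spectrum_id)
  for (id in names(split_shift)) {
    s <- split_shift[[id]]
    d <- diff(s)
    if (length(s) < 2 || any(d <= 0)) {
      row <- which(d <= 0)[1]
      abort(paste0("axis not strictly increasing for spectrum ", id,
                   if (length(row)) paste0(" at point ", row + 1L) else ""))
    }
  }
  axes <- unname(split_shift)
  if (length(axes) > 1) {
    ref <- axes[[1]]
    same <- vapply(axes, function(a) length(a) == length(ref) && all(a == ref),
                   logical(1))
    if (!all(same)) abort("spectra do not share an identical shift axis")
  }
  if ("label" %in% names(data)) {
    lab <- unique(data$label)
    bad <- setdiff(lab[!is.na(lab)], classes)
    if (length(bad) > 0) {
      abort(paste0("unknown class: ", paste(bad, collapse = ", ")))
    }
  }
  invisible(data)
}

#' Shared shift axis of a spectra tibble
#' @param data A `sers_spectra` tibble.
#' @return Numeric axis of the first spectrum.
#' @export
spectra_axis <- function(data) {
  data$shift[data$spectrum_id == data$spectrum_id[1]]
}

#' Number of spectra in a spectra tibble
#' @param data A `sers_spectra` tibble.
#' @return Integer count of distinct `spectrum_id`s.
#' @export
n_spectra <- function(data) length(unique(data$spectrum_id))

#' Per-spectrum metadata table
#'
#' Collapses a long spectra tibble to one row per spectrum with its metadata.
#'
#' @param data A `sers_spectra` tibble.
#' @return Tibble with columns `spectrum_id`, `label`, `concentration`,
#'   `replicate`, in first-appearance order.
#' @export
spectra_meta <- function(data) {
  data |>
    dplyr::distinct(.data$spectrum_id, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("spectrum_id", "label",
                                  "concentration", "replicate")))
}
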