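#' The canonical 12-band partition of the spectral axis
#'
#' The working range 1000--2300 cm\eqn{^{-1}} is divided into 12 sections at
#' interior edges 1030, 1152, 1174, 1195, 1280, 1350, 1410, 1450, 1522, 1545
#' and 1800 cm\eqn{^{-1}}. Bands are half-open `[lower, upper)` except the
#' last, which is closed at 2300.
#'
#' @return A `band_scheme` tibble with columns `band` (1--12), `lower`,
#'   `upper`.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  edges <- c(1000, 1030, 1152, 1174, 1195, 1280, 1350, 1410, 1450,
             1522, 1545, 1800, 2300)
  out <- tibble::tibble(band = seq_len(12),
                        lower = edges[-13], upper = edges[-1])
  structure(out, class = c("band_scheme", class(out)), edges = edges)
}

scheme_edges <- function(scheme) {
  attr(scheme, "edges") %||% c(scheme$lower, scheme$upper[nrow(scheme)])
}

#' Band membership of Raman shifts
#'
#' @param shift Numeric shifts (cm\eqn{^{-1}}).
#' @param scheme A [band_scheme()].
#' @return Integer band index 1--12 (`NA` outside the covered range). Bands
#'   are half-open on the right; the final band includes its upper edge.
#' @export
band_index <- function(shift, scheme = band_scheme()) {
  edges <- scheme_edges(scheme)
  i <- findInterval(shift, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  as.integer(i)
}

#' Extract the 12 per-band peak positions of one spectrum
#'
#' For each band, the Raman shift of the maximum intensity among the axis
#' points falling in that band; ties break toward the lowest shift. The
#' normalized position rescales each value to `[0, 1]` within its band.
#'
#' @param data A `sers_spectra` tibble with exactly one spectrum.
#' @param scheme A [band_scheme()].
#' @return Tibble with 12 rows: `band`, `lower`, `upper`, `position`
#'   (cm\eqn{^{-1}}), `position_norm`.
#' @export
extract_features <- function(data, scheme = band_scheme()) {
  if (n_spectra(data) != 1) {
    abort("extract_features() expects a single spectrum; see featurize_spectra()")
  }
  validate_spectra(data)
  bi <- band_index(data$shift, scheme)
  pos <- vapply(seq_len(nrow(scheme)), function(b) {
    in_band <- which(bi == b)
    if (length(in_band) == 0) abort(paste0("empty band ", b,
                                           ": axis does not cover it"))
    in_band_max <- in_band[which.max(data$intensity[in_band])]
    data$shift[in_band_max]
  }, numeric(1))
  out <- scheme
  out$position <- pos
  out$position_norm <- (pos - out$lower) / (out$upper - out$lower)
  class(out) <- class(tibble::tibble())
  out
}

#' Min--max normalize feature positions within their bands
#'
#' Maps each band's peak position to `(position - lower) / (upper - lower)`,
#' in `[0, 1]`, stabilizing the scale of the classifier inputs.
#'
#' @param features A wide feature table from [featurize_spectra()] (columns
#'   `f01`..`f12`).
#' @param scheme A [band_scheme()].
#' @return The feature table with `f` columns rescaled.
#' @export
normalize_features <- function(features, scheme = band_scheme()) {
  fcols <- feature_columns(features)
  for (i in seq_along(fcols)) {
    features[[fcols[i]]] <-
      (features[[fcols[i]]] - scheme$lower[i]) /
      (scheme$upper[i] - scheme$lower[i])
  }
  features
}

feature_columns <- function(features) {
  fcols <- grep("^f[0-9]{2}$", names(features), value = TRUE)
  if (length(fcols) != 12) abort("expected 12 feature columns f01..f12")
  fcols
}

#' Featurize a whole dataset
#'
#' Applies [extract_features()] to every spectrum and returns the wide
#' `n x 12` table the classifier trains on, with labels carried through and
#' row order preserved.
#'
#' @param data A `sers_spectra` tibble.
#' @param scheme A [band_scheme()].
#' @param normalize If `TRUE` (default), report band-normalized positions in
#'   `[0, 1]`; otherwise absolute cm\eqn{^{-1}}.
#' @return Tibble with columns `spectrum_id`, `label`, `f01`..`f12`.
#' @export
featurize_spectra <- function(data, scheme = band_scheme(),
                              normalize = TRUE) {
  if (nrow(data) == 0) {
    return(tibble::tibble(spectrum_id = integer(), label = character(),
                          !!!setNames(rep(list(numeric()), 12),
                                      sprintf("f%02d", 1:12))))
  }
  validate_spectra(data)
  bi <- band_index(spectra_axis(data), scheme)
  counts <- tabulate(bi, nbins = nrow(scheme))
  if (any(counts == 0)) {
    abort(paste0("empty band ", which(counts == 0)[1],
                 ": axis does not cover it"))
  }
  value_col <- if (normalize) "position_norm" else "position"
  meta <- spectra_meta(data)
  rows <- data |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::group_map(function(g, key) {
      fv <- extract_features(
        new_spectra(key$spectrum_id, NA, NA, NA, g$shift, g$intensity),
        scheme)
      vals <- as.list(fv[[value_col]])
      names(vals) <- sprintf("f%02d", fv$band)
      tibble::tibble(spectrum_id = key$spectrum_id, !!!vals)
    }) |>
    dplyr::bind_rows()
  if (nrow(meta) == 0 || nrow(rows) == 0) {
    return(tibble::tibble(spectrum_id = integer(), label = character(),
                          !!!setNames(rep(list(numeric()), 12),
                                      sprintf("f%02d", 1:12))))
  }
  meta |>
    dplyr::select(dplyr::any_of(c("spectrum_id", "label"))) |>
    dplyr::left_join(rows, by = "spectrum_id")
}
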