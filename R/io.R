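#' Read a single spectrum from CSV
#'
#' Spectrum files are two-column comma-separated text with the mandatory header
#' `raman_shift_cm1,intensity`. The axis must be strictly increasing and all
#' values finite.
#'
#' @param path Path to a spectrum CSV.
#' @return A `sers_spectra` tibble with one spectrum and no metadata.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort(paste0("spectrum file not found: ", path))
  raw <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!identical(names(raw), c("raman_shift_cm1", "intensity"))) {
    abort(paste0("bad header in ", path,
                 ": expected 'raman_shift_cm1,intensity'"))
  }
  if (nrow(raw) == 0) abort(paste0("empty spectrum file: ", path))
  shift <- suppressWarnings(as.numeric(raw$raman_shift_cm1))
  inten <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(!is.finite(shift) | !is.finite(inten))
  if (length(bad) > 0) {
    abort(paste0("non-numeric value in ", path, " at data row ", bad[1]))
  }
  d <- diff(shift)
  if (any(d <= 0)) {
    abort(paste0("axis not strictly increasing in ", path,
                 " at data row ", which(d <= 0)[1] + 1L))
  }
  new_spectra(1L, NA_character_, NA_real_, NA_integer_, shift, inten)
}

#' Write a single spectrum to CSV
#'
#' Emits exactly the dialect [read_spectrum()] accepts. Values are serialized
#' at full double precision (17 significant digits) so a read/write round trip
#' is lossless.
#'
#' @param data A `sers_spectra` tibble holding exactly one spectrum.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(data, path) {
  if (nrow(data) == 0) abort("refusing to write a zero-length spectrum")
  if (n_spectra(data) != 1) abort("write_spectrum() expects a single spectrum")
  validate_spectra(data)
  lines <- c("raman_shift_cm1,intensity",
             sprintf("%.17g,%.17g", data$shift, data$intensity))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write spectrum to ", path))
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `path,label,concentration_vv,replicate`;
#' `path` is resolved relative to the manifest's directory. Empty metadata
#' fields become `NA` (unlabeled spectra flow through quantification). All
#' referenced spectra must share an identical axis; row order is preserved.
#'
#' @param path Path to manifest CSV.
#' @param classes Allowed class labels.
#' @return A `sers_spectra` tibble; `spectrum_id` follows manifest row order.
#' @export
read_manifest <- function(path, classes = aldehyde_classes()) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  man <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("path", "label", "concentration_vv", "replicate")
  if (!identical(names(man), needed)) {
    abort("manifest header must be 'path,label,concentration_vv,replicate'")
  }
  base <- dirname(path)
  bad <- setdiff(unique(man$label[!is.na(man$label) & man$label != ""]),
                 classes)
  if (length(bad) > 0) {
    abort(paste0("unknown class: ", paste(bad, collapse = ", ")))
  }
  specs <- purrr::imap(man$path, function(p, i) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    if (!file.exists(full)) {
      abort(paste0("manifest row ", i, ": missing spectrum file ", p))
    }
    sp <- read_spectrum(full)
    lab <- man$label[i]
    conc <- man$concentration_vv[i]
    rep <- man$replicate[i]
    sp$spectrum_id <- i
    sp$label <- if (is.na(lab) || lab == "") NA_character_ else lab
    sp$concentration <-
      if (is.na(conc) || conc == "") NA_real_ else as.numeric(conc)
    sp$replicate <-
      if (is.na(rep) || rep == "") NA_integer_ else as.integer(rep)
    sp
  })
  out <- dplyr::bind_rows(specs)
  class(out) <- c("sers_spectra", class(tibble::tibble()))
  validate_spectra(out, classes = classes)
  out
}

#' Write a dataset as spectrum CSVs plus a manifest
#'
#' Inverse of [read_manifest()]: writes one CSV per spectrum (named
#' `spectrum_0001.csv`, ...) and a `manifest.csv` in `dir`.
#'
#' @param data A `sers_spectra` tibble.
#' @param dir Output directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(data, dir) {
  validate_spectra(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- spectra_meta(data)
  files <- sprintf("spectrum_%04d.csv", seq_len(nrow(meta)))
  ids <- meta$spectrum_id
  for (i in seq_along(ids)) {
    one <- data[data$spectrum_id == ids[i], , drop = FALSE]
    write_spectrum(one, file.path(dir, files[i]))
  }
  man <- tibble::tibble(
    path = files,
    label = ifelse(is.na(meta$label), "", meta$label),
    concentration_vv = ifelse(is.na(meta$concentration), "",
                              sprintf("%.17g", meta$concentration)),
    replicate = ifelse(is.na(meta$replicate), "",
                       as.character(meta$replicate))
  )
  man_path <- file.path(dir, "manifest.csv")
  readr::write_csv(man, man_path, progress = FALSE)
  invisible(man_path)
}
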