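#' Spectral signature library for the six aldehydes
#'
#' Every class shares the three 4-aminothiophenol (4-ATP) reporter bands at
#' 1141, 1179 and 1593 cm\eqn{^{-1}} and the phenylacetylene internal-standard
#' (IS) band at 1985 cm\eqn{^{-1}} in the Raman-silent region. Each class adds
#' its own Schiff-base C=N and C--C bands: the C=N stretch sits at 1625
#' (benzaldehyde), 1632 (oxalaldehyde), 1627 (glutaraldehyde), 1610
#' (salicylaldehyde) and 1652 cm\eqn{^{-1}} (4-nitrobenzaldehyde);
#' formaldehyde carries only its C--C band at 1585 cm\eqn{^{-1}}. C--C bands:
#' benzaldehyde 1574, oxalaldehyde 1575, glutaraldehyde 1588, salicylaldehyde
#' 1587 (+ a split component at 1570), 4-nitrobenzaldehyde 1558 and 1588
#' cm\eqn{^{-1}}.
#'
#' Relative amplitudes are a design choice (experimental intensities are not
#' tabulated anywhere): the `anchor` peak is the band whose internal-standard
#' ratio follows the configured concentration law, and amplitudes of all
#' characteristic peaks scale jointly with concentration.
#'
#' @return Tibble with columns `class`, `role` (`reporter`,
#'   `internal_standard`, `characteristic`), `center` (cm\eqn{^{-1}}),
#'   `rel_amplitude`, `anchor` (logical), `strongest` (logical).
#' @export
#' @examples
#' aldehyde_library() |> dplyr::count(class)
aldehyde_library <- function() {
  if (!is.null(the$library)) return(the$library)
  the$library <- build_aldehyde_library()
  the$library
}

# package-local cache (the library is immutable)
the <- new.env(parent = emptyenv())

build_aldehyde_library <- function() {
  shared <- tibble::tribble(
    ~role,               ~center, ~rel_amplitude,
    "reporter",           1141,    0.8,
    "reporter",           1179,    0.6,
    "reporter",           1593,    1.0,
    "internal_standard",  1985,    1.0
  )
  char <- tibble::tribble(
    ~class,                ~center, ~rel_amplitude, ~anchor,
    "formaldehyde",         1585,    1.00,           TRUE,
    "benzaldehyde",         1574,    1.00,           FALSE,
    "benzaldehyde",         1625,    0.75,           TRUE,
    "oxalaldehyde",         1632,    1.00,           TRUE,
    "oxalaldehyde",         1575,    0.60,           FALSE,
    "glutaraldehyde",       1627,    1.00,           TRUE,
    "glutaraldehyde",       1588,    0.60,           FALSE,
    "salicylaldehyde",      1610,    1.00,           TRUE,
    "salicylaldehyde",      1587,    0.60,           FALSE,
    "salicylaldehyde",      1570,    0.40,           FALSE,
    "4-nitrobenzaldehyde",  1652,    1.00,           TRUE,
    "4-nitrobenzaldehyde",  1558,    0.60,           FALSE,
    "4-nitrobenzaldehyde",  1588,    0.50,           FALSE
  )
  char$role <- "characteristic"
  shared_all <- tidyr::crossing(class = aldehyde_classes(), shared)
  shared_all$anchor <- FALSE
  out <- dplyr::bind_rows(shared_all, char) |>
    dplyr::arrange(factor(.data$class, levels = aldehyde_classes()),
                   .data$role, .data$center)
  out |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(strongest = .data$role == "characteristic" &
                    .data$rel_amplitude == max(
                      .data$rel_amplitude[.data$role == "characteristic"])) |>
    dplyr::ungroup()
}

#' Strongest characteristic band per class
#' @return Tibble `class`, `center` of each class's strongest
#'   concentration-dependent band (all within 1545--1800 cm\eqn{^{-1}}).
#' @export
strongest_peaks <- function() {
  aldehyde_library() |>
    dplyr::filter(.data$strongest) |>
    dplyr::distinct(.data$class, .keep_all = TRUE) |>
    dplyr::select("class", "center")
}
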