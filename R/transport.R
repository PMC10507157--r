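# Desk-scale physical models: a 1D Fick's-second-law diffusion solver used to
# compare analyte retention in a bare vs MOF-coated substrate (slower
# effective diffusivity), and the evanescent penetration depth of the
# plasmonic field.

#' Configuration for the 1D diffusion solver
#'
#' @param da Diffusion coefficient (m^2/s), > 0.
#' @param length Domain length (m).
#' @param n_grid Grid points (>= 3).
#' @param dt Time step (s); must satisfy the explicit-scheme stability bound
#'   `da * dt / dx^2 <= 0.5`.
#' @param t_end Final time (s).
#' @param initial_profile Concentration per grid point (mol/m^3); default all
#'   zero.
#' @param boundary `"closed"` (zero-flux both ends) or `"inlet"` (fixed
#'   concentration `inlet_concentration` at x = 0 for `inlet_duration`
#'   seconds, then 0, i.e. carrier purge; zero-gradient outlet).
#' @param inlet_concentration,inlet_duration Inlet boundary parameters.
#' @param save_times Snapshot times (s); snapped to the nearest step. `t_end`
#'   is always saved, as is 120 s when reachable.
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(da, length = 1e-4, n_grid = 101, dt = NULL,
                             t_end = 120,
                             initial_profile = NULL,
                             boundary = c("closed", "inlet"),
                             inlet_concentration = 1,
                             inlet_duration = t_end / 2,
                             save_times = NULL) {
  boundary <- match.arg(boundary)
  if (da <= 0) abort("da must be > 0")
  if (n_grid < 3) abort("n_grid must be >= 3")
  dx <- length / (n_grid - 1)
  dt_max <- 0.5 * dx^2 / da
  if (is.null(dt)) dt <- dt_max / 2
  if (dt <= 0) abort("dt must be > 0")
  if (da * dt / dx^2 > 0.5 + 1e-12) {
    abort(sprintf(
      "unstable time step: da*dt/dx^2 = %.3g > 0.5; maximum admissible dt = %.6g s",
      da * dt / dx^2, dt_max))
  }
  if (is.null(initial_profile)) initial_profile <- rep(0, n_grid)
  if (length(initial_profile) != n_grid) {
    abort("initial_profile must have n_grid values")
  }
  if (any(initial_profile < 0)) abort("initial concentrations must be >= 0")
  if (is.null(save_times)) {
    save_times <- unique(sort(c(
      seq(0, t_end, length.out = 5),
      if (t_end >= 120) 120, t_end)))
  }
  structure(list(da = da, length = length, n_grid = n_grid, dx = dx,
                 dt = dt, t_end = t_end, initial_profile = initial_profile,
                 boundary = boundary,
                 inlet_concentration = inlet_concentration,
                 inlet_duration = inlet_duration,
                 save_times = save_times),
            class = "diffusion_config")
}

#' Solve Fick's second law in 1D
#'
#' Explicit central-difference (FTCS) integration of
#' \eqn{\partial c/\partial t = D_a \, \partial^2 c/\partial x^2}. Closed
#' boundaries are reflecting (mass-conserving); the `"inlet"` boundary holds
#' `c = c0` at x = 0 during the injection phase and 0 afterwards, with a
#' zero-gradient outlet, mimicking flow-through exposure followed by a
#' carrier purge.
#'
#' @param config A [diffusion_config()].
#' @return A `concentration_profile`: tibble `time`, `x`, `concentration`,
#'   with attributes `dx`, `injected_mass` (total mass that entered the
#'   domain, by trapezoidal flux accounting) and `config`.
#' @export
solve_fick_1d <- function(config) {
  n <- config$n_grid
  dx <- config$dx
  dt <- config$dt
  r <- config$da * dt / dx^2
  c_now <- config$initial_profile
  n_steps <- ceiling(config$t_end / dt - 1e-9)
  save_steps <- unique(pmin(pmax(round(config$save_times / dt), 0), n_steps))
  trapz_mass <- function(v) dx * (sum(v) - (v[1] + v[n]) / 2)
  injected <- trapz_mass(c_now)
  snapshots <- vector("list", length(save_steps))
  names(snapshots) <- as.character(save_steps)
  if ("0" %in% names(snapshots)) snapshots[["0"]] <- c_now
  if (config$boundary == "inlet") c_now[1] <- inlet_value(config, 0)
  for (step in seq_len(n_steps)) {
    lap <- c(0, c_now[2:(n - 1) + 1] - 2 * c_now[2:(n - 1)] +
               c_now[2:(n - 1) - 1], 0)
    c_next <- c_now + r * lap
    if (config$boundary == "closed") {
      # reflecting ends via ghost nodes c[0] = c[2], c[n+1] = c[n-1]
      c_next[1] <- c_now[1] + 2 * r * (c_now[2] - c_now[1])
      c_next[n] <- c_now[n] + 2 * r * (c_now[n - 1] - c_now[n])
    } else {
      t_new <- step * dt
      c_next[1] <- inlet_value(config, t_new)
      c_next[n] <- c_next[n - 1]  # zero-gradient outlet
      flux_in <- -config$da * (c_now[2] - c_now[1]) / dx
      if (flux_in > 0) injected <- injected + flux_in * dt
    }
    c_now <- c_next
    key <- as.character(step)
    if (key %in% names(snapshots)) snapshots[[key]] <- c_now
  }
  x <- seq(0, config$length, length.out = n)
  saved <- tibble::tibble(
    step = rep(save_steps, each = n),
    time = rep(save_steps * dt, each = n),
    x = rep(x, length(save_steps)),
    concentration = unlist(snapshots[as.character(save_steps)],
                           use.names = FALSE)
  )
  saved$step <- NULL
  if (config$boundary == "closed") injected <- trapz_mass(config$initial_profile)
  structure(saved, class = c("concentration_profile", class(saved)),
            dx = dx, injected_mass = injected, config = config)
}

inlet_value <- function(config, t) {
  if (t <= config$inlet_duration) config$inlet_concentration else 0
}

#' Mass fraction retained in a spatial region
#'
#' Trapezoidal mass in `x` within `region` at snapshot `time`, divided by the
#' total injected mass (initial mass plus cumulative positive inlet influx).
#'
#' @param profile A `concentration_profile` from [solve_fick_1d()].
#' @param region Numeric `c(xmin, xmax)` (m); an empty intersection gives 0.
#' @param time Snapshot time (s); must be among the saved times (nearest
#'   saved time within half a step is accepted).
#' @return Fraction in `[0, 1]`.
#' @export
retained_fraction <- function(profile, region, time) {
  times <- unique(profile$time)
  hit <- which(abs(times - time) < 1e-9 * max(1, time) |
                 abs(times - time) <= attr(profile, "config")$dt / 2)
  if (length(hit) == 0) {
    abort(paste0("time ", time, " s is not among the saved snapshots"))
  }
  snap <- profile[profile$time == times[hit[1]], , drop = FALSE]
  x <- snap$x
  v <- snap$concentration
  keep <- x >= region[1] & x <= region[2]
  if (sum(keep) < 2) return(0)
  xr <- x[keep]; vr <- v[keep]
  mass <- sum(diff(xr) * (head(vr, -1) + tail(vr, -1)) / 2)
  denom <- attr(profile, "injected_mass")
  if (denom <= 0) return(0)
  min(1, mass / denom)
}

#' Evanescent penetration depth of the plasmonic field
#'
#' \deqn{Z = \frac{\lambda}{2\pi}
#'   \sqrt{\frac{\varepsilon'_{medium} - \varepsilon'_{metal}}
#'        {\varepsilon'^{\,2}_{metal}}}}
#' The decay length of the surface-plasmon field into the dielectric medium:
#' a higher-index coating (e.g. the MOF shell, \eqn{\varepsilon' = 1.34})
#' extends the field further than air (\eqn{\varepsilon' = 1.0003}).
#'
#' @param wavelength Excitation wavelength (nm).
#' @param eps_medium Real dielectric constant of the medium (> 0).
#' @param eps_metal Real dielectric constant of the metal (< 0).
#' @return Penetration depth Z in nm.
#' @export
#' @examples
#' penetration_depth(633, 1.34, -18)
penetration_depth <- function(wavelength, eps_medium, eps_metal) {
  if (wavelength <= 0) abort("wavelength must be > 0")
  if (eps_metal >= 0) abort("eps_metal must be negative for a plasmonic metal")
  if (eps_medium <= 0) abort("eps_medium must be > 0")
  radicand <- (eps_medium - eps_metal) / eps_metal^2
  if (radicand <= 0) abort("negative radicand")
  wavelength / (2 * pi) * sqrt(radicand)
}
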