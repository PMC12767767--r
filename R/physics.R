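# Stokes-Einstein relations and the device/flow model.
#
# Canonical internal units: um, s, um^2/s for everything tied to the channel;
# SI (m, m^2/s, K, Pa s) for the Stokes-Einstein conversions themselves.
# Conversions happen at these function boundaries only.

.kB <- 1.380649e-23 # Boltzmann constant, J/K

#' Medium conditions
#'
#' Temperature and viscosity of the carrier medium, the two quantities the
#' Stokes-Einstein relation needs besides the radius.
#'
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity of the medium (Pa s).
#' @return An object of class `"conditions"`.
#' @examples
#' conditions(298.15, 8.9e-4) # water at 25 C
#' @export
conditions <- function(temperature, viscosity) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0) {
    stop("`temperature` must be a single positive number (K)", call. = FALSE)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) ||
      viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Pa s)", call. = FALSE)
  }
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "conditions")
}

#' Device geometry
#'
#' Main-channel geometry of the microfluidic focuser and the positions of the
#' measurement points along the channel.
#'
#' @param channel_width Main-channel width (um).
#' @param channel_height Channel height (um).
#' @param wall_thickness Thickness of the sidewall lines as they appear in the
#'   brightfield recording (um).
#' @param positions Ordered distances of the measurement points from the
#'   channel origin at the focusing intersection (um); strictly increasing,
#'   non-negative.
#' @return An object of class `"device_geometry"`.
#' @examples
#' device_geometry(300, 20, 20, seq(1000, 51000, by = 5000))
#' @export
device_geometry <- function(channel_width, channel_height, wall_thickness,
                            positions) {
  for (nm in c("channel_width", "channel_height", "wall_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number (um)", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(positions) || length(positions) < 1L || any(!is.finite(positions)) ||
      any(positions < 0)) {
    stop("`positions` must be non-negative distances (um)", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  structure(list(channel_width = channel_width, channel_height = channel_height,
                 wall_thickness = wall_thickness, positions = positions),
            class = "device_geometry")
}

#' Pump flow configuration
#'
#' @param analyte_flow Analyte (middle inlet) pump rate (uL/min).
#' @param buffer_flow Per-side buffer pump rate (uL/min); two buffer inlets are
#'   assumed, so the total volumetric flow is `analyte_flow + 2 * buffer_flow`.
#' @return An object of class `"flow_config"`.
#' @examples
#' flow_config(analyte_flow = 1, buffer_flow = 4) # steady-state settings
#' @export
flow_config <- function(analyte_flow, buffer_flow) {
  if (!is.numeric(analyte_flow) || length(analyte_flow) != 1L || analyte_flow < 0 ||
      !is.numeric(buffer_flow) || length(buffer_flow) != 1L || buffer_flow < 0) {
    stop("flow rates must be single non-negative numbers (uL/min)", call. = FALSE)
  }
  total <- analyte_flow + 2 * buffer_flow
  if (total <= 0) stop("total flow must be positive", call. = FALSE)
  structure(list(analyte_flow = analyte_flow, buffer_flow = buffer_flow),
            class = "flow_config")
}

total_flow <- function(flow) flow$analyte_flow + 2 * flow$buffer_flow

#' Diffusion coefficient from hydrodynamic radius
#'
#' Stokes-Einstein relation `D = kB * T / (6 * pi * eta * r)` for a spherical
#' particle in a low-Reynolds-number medium.
#'
#' @param r Hydrodynamic radius (m).
#' @param cond A [conditions()] object.
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' diffusion_from_radius(1e-9, conditions(298.15, 8.9e-4)) # ~2.454e-10 m^2/s
#' @export
diffusion_from_radius <- function(r, cond) {
  stopifnot(inherits(cond, "conditions"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("radius must be positive", call. = FALSE)
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * r)
}

#' Hydrodynamic radius from diffusion coefficient
#'
#' Inverse Stokes-Einstein relation; its own inverse, so
#' `radius_from_diffusion(diffusion_from_radius(r, cond), cond)` returns `r`.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @inheritParams diffusion_from_radius
#' @return Hydrodynamic radius (m).
#' @export
radius_from_diffusion <- function(D, cond) {
  stopifnot(inherits(cond, "conditions"))
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("diffusion coefficient must be positive", call. = FALSE)
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * D)
}

#' Mean particle velocity in the main channel
#'
#' Plug-flow mean speed: the total volumetric flow (analyte plus both buffer
#' streams, which share the main channel) divided by the channel cross-section.
#'
#' @param flow A [flow_config()] object.
#' @param geom A [device_geometry()] object.
#' @return Mean speed (um/s).
#' @examples
#' # 4 + 1 + 4 uL/min through a 20 x 300 um channel -> 25 000 um/s
#' mean_velocity(flow_config(1, 4), device_geometry(300, 20, 20, 1000))
#' @export
mean_velocity <- function(flow, geom) {
  stopifnot(inherits(flow, "flow_config"), inherits(geom, "device_geometry"))
  q_ul_min <- total_flow(flow)
  if (q_ul_min <= 0) stop("total flow must be positive", call. = FALSE)
  q_um3_s <- q_ul_min * 1e9 / 60 # 1 uL = 1e9 um^3
  q_um3_s / (geom$channel_height * geom$channel_width)
}

#' Transit times to the measurement points
#'
#' Average time for a particle to reach each measurement point (distance over
#' mean speed) plus the inter-point deltas used by the sequential sigma bounds.
#'
#' @param geom A [device_geometry()] object (its `positions` are used).
#' @param v Mean particle speed (um/s).
#' @return A list with `times` (s, one per point) and `deltas` (s, one per
#'   consecutive pair).
#' @export
transit_times <- function(geom, v) {
  stopifnot(inherits(geom, "device_geometry"))
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
    stop("velocity must be positive", call. = FALSE)
  }
  t <- geom$positions / v
  list(times = t, deltas = diff(t))
}

#' Admissible variance-time slope range
#'
#' The squared width parameter of the fitted Gaussian grows as `c^2 = 4 D t`,
#' so an admissible radius range `[r_min, r_max]` bounds the slope of the
#' variance-time line to `[4 D(r_max), 4 D(r_min)]`.
#'
#' @param r_min,r_max Admissible hydrodynamic radius range (m), `r_min < r_max`.
#' @inheritParams diffusion_from_radius
#' @return Named numeric vector `c(min = , max = )`, in um^2/s.
#' @examples
#' slope_bounds(1e-9, 2e-6, conditions(298.15, 8.9e-4)) # ~ (0.491, 981.5)
#' @export
slope_bounds <- function(r_min, r_max, cond) {
  if (!is.numeric(r_min) || !is.numeric(r_max) || r_min <= 0 || r_min > r_max) {
    stop("need 0 < r_min <= r_max", call. = FALSE)
  }
  d_max <- diffusion_from_radius(r_min, cond) * 1e12 # um^2/s
  d_min <- diffusion_from_radius(r_max, cond) * 1e12
  c(min = 4 * d_min, max = 4 * d_max)
}
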