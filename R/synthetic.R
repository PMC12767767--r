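# Forward Brownian-diffusion simulator: generates measurement workbooks with
# known ground truth so every pipeline stage is testable without lab data.
#
# Each species starts as a focused Gaussian band of width parameter c0 at the
# channel center and spreads as c^2(t) = c0^2 + 4 D t; amplitudes scale as
# N / (c(t) * sqrt(pi)) so the particle-count identity holds at every point.
# The brightfield trace is flat at the baseline with a bump at each sidewall,
# and both traces get zero-padded ends emulating image rotation.

#' Species mixture for the simulator
#'
#' @param radius_nm Hydrodynamic radii (nm), all within 1 nm - 2 um.
#' @param abundance Relative abundances (> 0); each species' intensity-weighted
#'   particle count is `abundance * n_scale` (see [simulate_profiles()]).
#' @param sigma0_um Initial width parameter of the focused band (um); the
#'   free intercept of the variance-time line absorbs `sigma0^2`.
#' @return An object of class `"species_mix"`. A zero-species mix (all
#'   arguments empty) yields a flat fluorescent trace.
#' @export
species_mix <- function(radius_nm, abundance = rep(1, length(radius_nm)),
                        sigma0_um = rep(10, length(radius_nm))) {
  if (length(radius_nm)) {
    if (any(radius_nm < 1) || any(radius_nm > 2000)) {
      stop("species radii must lie within 1 nm - 2 um", call. = FALSE)
    }
    if (any(abundance <= 0)) stop("abundances must be positive", call. = FALSE)
    if (any(sigma0_um <= 0)) stop("initial sigmas must be positive", call. = FALSE)
  }
  stopifnot(length(abundance) == length(radius_nm),
            length(sigma0_um) == length(radius_nm))
  structure(list(radius_nm = radius_nm, abundance = abundance,
                 sigma0_um = sigma0_um), class = "species_mix")
}

#' Noise model for simulated profiles
#'
#' @param baseline Intensity offset under both traces (counts; default 200,
#'   the baseline standard the preprocessing normalizes to).
#' @param additive_sd Gaussian noise sd added to both traces (counts).
#' @param drift_per_point Multiplicative accumulation per measurement point
#'   applied to the fluorescent signal above baseline, emulating particles
#'   adsorbing to an untreated channel surface.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(baseline = 200, additive_sd = 0, drift_per_point = 0,
                        seed = 1) {
  if (baseline < 0 || additive_sd < 0) {
    stop("baseline and additive_sd must be non-negative", call. = FALSE)
  }
  structure(list(baseline = baseline, additive_sd = additive_sd,
                 drift_per_point = drift_per_point, seed = seed),
            class = "noise_model")
}

#' Default study geometry, flows and conditions
#'
#' The device and run settings used throughout the package's examples and
#' tests: a 300 um wide, 20 um high channel with 20 um sidewall lines, eleven
#' equidistant measurement points (1 mm to 51 mm from the focusing
#' intersection), steady-state pump rates of 1 uL/min analyte plus 4 uL/min
#' per buffer side, and water-like medium at 25 C.
#'
#' @return List with `geometry`, `flow`, `conditions`, `exposure`.
#' @export
default_study <- function() {
  list(geometry = device_geometry(channel_width = 300, channel_height = 20,
                                  wall_thickness = 20,
                                  positions = seq(1000, 51000, by = 5000)),
       flow = flow_config(analyte_flow = 1, buffer_flow = 4),
       conditions = conditions(298.15, 8.9e-4),
       exposure = 1)
}

#' Simulate a measurement set
#'
#' @param mix A [species_mix()].
#' @param geom,flow,cond Device geometry, flows and medium conditions
#'   (defaults from [default_study()]).
#' @param noise A [noise_model()].
#' @param grid_spacing Cross-channel sample spacing (um).
#' @param outside_margin Recorded stretch beyond each wall (um).
#' @param pad_points Zero samples appended at each trace end (rotation
#'   artifact).
#' @param n_scale Intensity-weighted particle count per unit abundance; the
#'   default puts the first-point peak around 1000 counts over baseline.
#' @param exposure Exposition time recorded in the metadata (s).
#' @return A [measurement_set()] with the ground truth (radii, diffusion
#'   coefficients, initial widths, noise settings) in `attr(, "ground_truth")`.
#' @export
simulate_profiles <- function(mix, geom = default_study()$geometry,
                              flow = default_study()$flow,
                              cond = default_study()$conditions,
                              noise = noise_model(),
                              grid_spacing = 2, outside_margin = 100,
                              pad_points = 30, n_scale = 2e4, exposure = 1) {
  stopifnot(inherits(mix, "species_mix"), inherits(noise, "noise_model"))
  v <- mean_velocity(flow, geom)
  tt <- transit_times(geom, v)
  D <- if (length(mix$radius_nm)) {
    diffusion_from_radius(mix$radius_nm * 1e-9, cond) * 1e12 # um^2/s
  } else {
    numeric()
  }

  # refuse parameter sets whose diffusion would reach the sidewalls
  t_max <- max(tt$times)
  if (length(D)) {
    reach <- 3 * sqrt(mix$sigma0_um^2 + 4 * D * t_max)
    if (any(reach > geom$channel_width / 2)) {
      stop("diffusion would reach the channel walls for species ",
           paste(which(reach > geom$channel_width / 2), collapse = ", "),
           "; shorten the channel, slow the diffusion, or widen the channel",
           call. = FALSE)
    }
  }

  half <- geom$channel_width / 2
  wt <- geom$wall_thickness
  span <- half + outside_margin
  x_body <- seq(-span, span, by = grid_spacing)
  n_body <- length(x_body)
  x <- seq(by = grid_spacing, length.out = n_body + 2 * pad_points,
           from = -span - pad_points * grid_spacing)
  pad_lo <- seq_len(pad_points)
  pad_hi <- n_body + pad_points + seq_len(pad_points)
  body <- pad_points + seq_len(n_body)

  bf_body <- noise$baseline +
    noise$baseline * exp(-((x_body - half) / (wt / 2))^2) +
    noise$baseline * exp(-((x_body + half) / (wt / 2))^2)

  N <- mix$abundance * n_scale
  labels <- sprintf("P%02d", seq_along(geom$positions) - 1L)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(noise$seed)

  profiles <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    t_i <- tt$times[i]
    signal <- numeric(n_body)
    for (s in seq_along(D)) {
      c2 <- mix$sigma0_um[s]^2 + 4 * D[s] * t_i
      signal <- signal + N[s] / sqrt(pi * c2) * exp(-x_body^2 / c2)
    }
    drift <- (1 + noise$drift_per_point)^(i - 1L)
    fl_body <- noise$baseline + drift * signal
    bf <- numeric(length(x))
    fl <- numeric(length(x))
    bf[body] <- bf_body
    fl[body] <- fl_body
    if (noise$additive_sd > 0) {
      bf[body] <- pmax(0, bf[body] + stats::rnorm(n_body, 0, noise$additive_sd))
      fl[body] <- pmax(0, fl[body] + stats::rnorm(n_body, 0, noise$additive_sd))
    }
    # x recorded as non-negative camera positions, 0 at the vector start
    profiles[[i]] <- profile_pair(labels[i], geom$positions[i],
                                  x - x[1L], bf, fl)
  }

  ms <- measurement_set(
    list(geometry = geom, flow = flow, conditions = cond,
         exposure = exposure, omit = character()),
    profiles)
  attr(ms, "ground_truth") <- list(
    radius_nm = mix$radius_nm, diffusion_um2_s = D,
    sigma0_um = mix$sigma0_um, n_particles = N,
    velocity_um_s = v, times_s = tt$times,
    wall_x = c(-half, half) - x[1L], # wall centers in recorded coordinates
    noise = unclass(noise))
  ms
}

#' Write the standard fixture suite
#'
#' Emits the simulator workbooks the test suite and worked examples rely on —
#' single-species (2 nm), two-species (1.5 nm + 3 nm), high-noise, drifting
#' baseline, and a degenerate flat-fluorescent workbook — together with a YAML
#' manifest of the embedded ground truth. All fixtures are synthetic.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for all noise streams.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    single_species_2nm = list(mix = species_mix(2),
                              noise = noise_model(seed = seed)),
    two_species_1p5_3nm = list(mix = species_mix(c(1.5, 3)),
                               noise = noise_model(seed = seed + 1)),
    high_noise = list(mix = species_mix(2),
                      noise = noise_model(additive_sd = 40, seed = seed + 2)),
    drifting_baseline = list(mix = species_mix(2),
                             noise = noise_model(additive_sd = 5,
                                                 drift_per_point = 0.03,
                                                 seed = seed + 3)),
    degenerate_flat = list(mix = species_mix(numeric()),
                           noise = noise_model(seed = seed + 4)))
  paths <- character()
  manifest <- list()
  for (nm in names(specs)) {
    ms <- simulate_profiles(specs[[nm]]$mix, noise = specs[[nm]]$noise)
    p <- file.path(outdir, paste0("synthetic_", nm, ".xlsx"))
    write_measurement_workbook(ms, p)
    gt <- attr(ms, "ground_truth")
    manifest[[nm]] <- list(file = basename(p),
                           radius_nm = gt$radius_nm,
                           sigma0_um = gt$sigma0_um,
                           noise = gt$noise)
    paths[nm] <- p
  }
  mpath <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  paths["manifest"] <- mpath
  invisible(paths)
}
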