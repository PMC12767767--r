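# Variance tracking across measurement points, the variance-time line, and the
# conversion to diffusion coefficients, radii and particle-count estimates.

#' Track mixture components across measurement points
#'
#' Component identity is fixed by sigma rank: the k-th widest component at each
#' point belongs to track k. The sequential sigma bounds guarantee each track's
#' variance series is non-decreasing.
#'
#' @param fits List of `mixture_fit`s in channel order (same order everywhere);
#'   `NULL` entries (failed points) are dropped from every track.
#' @param times Transit times (s), one per fit (including failed ones).
#' @return List of `component_track`s: `rank`, `times`, `variances` (c^2,
#'   um^2), `amplitudes`, `sigmas`.
#' @export
track_components <- function(fits, times) {
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no successful fits to track", call. = FALSE)
  orders <- vapply(fits[ok], `[[`, numeric(1), "order")
  if (length(unique(orders)) != 1L) {
    stop("fits have differing model orders; cannot track components",
         call. = FALSE)
  }
  order <- orders[1L]
  lapply(seq_len(order), function(k) {
    structure(list(
      rank = k,
      times = times[ok],
      variances = vapply(fits[ok], function(f) f$components$sigma[k]^2, numeric(1)),
      amplitudes = vapply(fits[ok], function(f) f$components$amplitude[k], numeric(1)),
      sigmas = vapply(fits[ok], function(f) f$components$sigma[k], numeric(1))),
      class = "component_track")
  })
}

#' Fit the variance-time line for one component track
#'
#' Ordinary least squares of the squared width parameter `c^2` on transit time,
#' with a free intercept: the focused stream enters the channel with a nonzero
#' width, which the intercept absorbs (the point-source form is recovered when
#' the intercept is zero).
#'
#' @param track A `component_track`.
#' @return List with `slope` (um^2/s), `intercept` (um^2), `r2_line`.
#' @export
fit_variance_time <- function(track) {
  stopifnot(inherits(track, "component_track"))
  if (length(track$times) < 3L) {
    stop("need at least 3 points for the variance-time line", call. = FALSE)
  }
  fit <- stats::lm(track$variances ~ track$times)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop(sprintf("component %d: non-physical (<= 0) variance-time slope",
                 track$rank), call. = FALSE)
  }
  sst <- sum((track$variances - mean(track$variances))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       r2_line = r2)
}

#' Diffusion coefficient and radius from a variance-time slope
#'
#' `D = slope / 4` (the variance convention makes the slope `4 D`), then the
#' Stokes-Einstein radius, clamped below at the configured floor.
#'
#' @param slope Variance-time slope (um^2/s), positive.
#' @param cond A [conditions()] object.
#' @param floor_nm Radius floor (nm); radii below it are reported at the floor
#'   with `clamped = TRUE`.
#' @return List with `D` (um^2/s), `radius` (nm), `clamped`.
#' @export
diffusion_and_radius <- function(slope, cond, floor_nm = 1) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("slope must be positive", call. = FALSE)
  }
  D <- slope / 4
  r_nm <- radius_from_diffusion(D * 1e-12, cond) * 1e9
  clamped <- r_nm < floor_nm
  list(D = D, radius = max(r_nm, floor_nm), clamped = clamped)
}

#' Particle-count estimate from one fitted Gaussian
#'
#' The area identity of the diffusion density gives `N = a * c * sqrt(pi)`,
#' in intensity-weighted arbitrary units (amplitudes are camera counts).
#'
#' @param a Component amplitude (counts).
#' @param c Component width parameter (um).
#' @return The estimate `N`.
#' @export
estimate_particle_count <- function(a, c) {
  if (any(a < 0) || any(c <= 0)) stop("need a >= 0 and c > 0", call. = FALSE)
  a * c * sqrt(pi)
}

#' Summarize component tracks into a radius report
#'
#' Fits each track's variance-time line, converts slopes to diffusion
#' coefficients and radii, and reports the pair convention used for order-2
#' fits: the higher and lower approximate radius, plus their arithmetic mean
#' as the single approximate radius for the measurement. Tracks with
#' non-physical slopes are reported as failures, not as fabricated radii.
#'
#' @param tracks List of `component_track`s from [track_components()].
#' @param cond A [conditions()] object.
#' @param floor_nm Radius floor (nm).
#' @param r_max_nm Admissible radius maximum (nm); a component whose slope is
#'   so shallow that its radius lands above this (e.g. a width track stalled
#'   at the sigma cap) is reported as a failure, not a radius.
#' @param provenance Optional list recorded verbatim (config, seed, omitted
#'   points, clamp/skip events).
#' @return A `radius_report`: `results` (one row per component rank: slope,
#'   intercept, r2_line, D, radius, clamped, n_particles), `higher`, `lower`,
#'   `mean_radius` (nm), `failures`, `provenance`.
#' @export
summarize_tracks <- function(tracks, cond, floor_nm = 1, r_max_nm = Inf,
                             provenance = list()) {
  if (!length(tracks)) stop("no tracks to summarize", call. = FALSE)
  rows <- list()
  failures <- character()
  for (tr in tracks) {
    res <- tryCatch(fit_variance_time(tr), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    dr <- diffusion_and_radius(res$slope, cond, floor_nm)
    if (dr$radius > r_max_nm) {
      failures <- c(failures, sprintf(
        "component %d: radius %.3g nm above the admissible maximum (stalled variance track)",
        tr$rank, dr$radius))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rank = tr$rank, slope = res$slope, intercept = res$intercept,
      r2_line = res$r2_line, D_um2_s = dr$D, radius_nm = dr$radius,
      clamped = dr$clamped,
      n_particles = mean(estimate_particle_count(tr$amplitudes, tr$sigmas)))
  }
  if (!length(rows)) {
    stop("no component produced a physical variance-time slope",
         call. = FALSE)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 higher = max(results$radius_nm),
                 lower = min(results$radius_nm),
                 mean_radius = mean(results$radius_nm),
                 failures = failures,
                 provenance = provenance),
            class = "radius_report")
}

#' @export
print.radius_report <- function(x, ...) {
  cat("Approximate hydrodynamic radii (nm):\n")
  cat(sprintf("  higher %.3f | lower %.3f | mean %.3f\n",
              x$higher, x$lower, x$mean_radius))
  print(x$results, digits = 4, row.names = FALSE)
  if (length(x$failures)) {
    cat("failed components:\n ", paste(x$failures, collapse = "\n  "), "\n")
  }
  invisible(x)
}
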