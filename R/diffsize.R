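# The main model-fitting entry point: workbook in, radius report out.

#' Control parameters for a diffusional-sizing run
#'
#' @param order Mixture order (1-8). The default of 2 reflects the standard
#'   finding that a second component captures the small-particle bias of the
#'   method while further components stop improving the fit.
#' @param r_min_nm,r_max_nm Admissible hydrodynamic radius range (nm); together
#'   with the medium conditions it bounds the variance-time slope and hence how
#'   fast fitted widths may grow between points.
#' @param baseline Baseline intensity standard (counts).
#' @param patience Consecutive non-improving multistart restarts before a fit
#'   stops.
#' @param seed Integer seed governing every randomized start.
#' @param omit Measurement-point labels excluded from evaluation.
#' @param fluor_baseline_region `"outside"` or `"inside"`: section whose mean
#'   defines the fluorescent step-1 baseline.
#' @param sigma_cap Global cap on the Gaussian width parameter (um).
#' @param b_limit Center bound for fitted components (um).
#' @param floor_nm Reported radius floor (nm).
#' @return A list of class `"diffsize_control"`.
#' @export
diffsize_control <- function(order = 2, r_min_nm = 1, r_max_nm = 2000,
                             baseline = 200, patience = 5, seed = 1,
                             omit = character(),
                             fluor_baseline_region = c("outside", "inside"),
                             sigma_cap = 100, b_limit = 5, floor_nm = 1) {
  if (order < 1 || order > 8 || order != round(order)) {
    stop("`order` must be an integer between 1 and 8", call. = FALSE)
  }
  if (r_min_nm <= 0 || r_min_nm >= r_max_nm) {
    stop("need 0 < r_min_nm < r_max_nm", call. = FALSE)
  }
  if (patience < 1) stop("`patience` must be at least 1", call. = FALSE)
  structure(list(order = as.integer(order), r_min_nm = r_min_nm,
                 r_max_nm = r_max_nm, baseline = baseline,
                 patience = as.integer(patience), seed = as.integer(seed),
                 omit = as.character(omit),
                 fluor_baseline_region = match.arg(fluor_baseline_region),
                 sigma_cap = sigma_cap, b_limit = b_limit,
                 floor_nm = floor_nm),
            class = "diffsize_control")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [diffsize_control()] may appear in the file; missing fields
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A `"diffsize_control"`.
#' @export
read_diffsize_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(diffsize_control))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(diffsize_control, cfg)
}

# drop omitted points from an in-memory measurement set
omit_points <- function(ms, omit) {
  if (!length(omit)) return(ms)
  labs <- labels_of(ms)
  unknown <- setdiff(omit, labs)
  if (length(unknown)) {
    stop("omit label(s) not present: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(labs %in% omit)
  if (sum(keep) < 3L) {
    stop("fewer than 3 usable measurement points after omission", call. = FALSE)
  }
  g <- ms$metadata$geometry
  meta <- ms$metadata
  meta$geometry <- device_geometry(g$channel_width, g$channel_height,
                                   g$wall_thickness, g$positions[keep])
  meta$omit <- union(meta$omit, omit)
  measurement_set(meta, ms$profiles[keep])
}

config_hash <- function(control) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(control), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Fit the diffusional-sizing model to a measurement set
#'
#' Runs the full analysis: reads the workbook (or takes a
#' [measurement_set()]), preprocesses every cross-channel profile (crop, wall
#' location, baseline and area normalization, zero and center), fits a bounded
#' multistart Gaussian mixture to each inside-channel fluorescent profile with
#' sequentially widening sigma bounds, regresses each component's squared
#' width on transit time, and converts the slopes to diffusion coefficients
#' and Stokes-Einstein radii.
#'
#' @param x Path to a measurement workbook, or a [measurement_set()].
#' @param control A [diffsize_control()].
#' @return An object of class `"diffsize"` with components `report` (the
#'   `radius_report`), `fits`, `tracks`, `gof` (per-point GoF at the fitted
#'   order), `profiles` (preprocessed), `times`, `slope_bounds`, `velocity`,
#'   `metadata`, `control`, `events` (clamps, skips, failures) and `call`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `fitted`, `residuals`,
#'   `predict`, `simulate`.
#' @examples
#' \donttest{
#' ms <- simulate_profiles(species_mix(2), noise = noise_model(additive_sd = 5))
#' fit <- diffsize(ms, diffsize_control(order = 1, seed = 7))
#' coef(fit)
#' }
#' @export
diffsize <- function(x, control = diffsize_control()) {
  stopifnot(inherits(control, "diffsize_control"))
  cl <- match.call()
  ms <- if (inherits(x, "measurement_set")) {
    omit_points(x, control$omit)
  } else if (is.character(x) && length(x) == 1L) {
    read_measurement_workbook(x, omit = control$omit)
  } else {
    stop("`x` must be a workbook path or a measurement_set", call. = FALSE)
  }

  meta <- ms$metadata
  v <- mean_velocity(meta$flow, meta$geometry)
  tt <- transit_times(meta$geometry, v)
  sb <- slope_bounds(control$r_min_nm * 1e-9, control$r_max_nm * 1e-9,
                     meta$conditions)

  sps <- preprocess_profiles(ms, standard = control$baseline,
                             fluor_baseline_region = control$fluor_baseline_region)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(control$seed)
  ch <- fit_profile_chain(sps, tt$times, control$order, sb,
                          global_cap = control$sigma_cap,
                          b_limit = control$b_limit,
                          patience = control$patience)

  labels <- vapply(sps, function(s) s$pair$label, character(1))
  gof <- do.call(rbind, lapply(seq_along(sps), function(i) {
    f <- ch$fits[[i]]
    if (is.null(f)) {
      data.frame(label = labels[i], time_s = tt$times[i], sse = NA_real_,
                 rmse = NA_real_, r2 = NA_real_, adj_r2 = NA_real_,
                 n_restarts = NA_integer_)
    } else {
      data.frame(label = labels[i], time_s = tt$times[i], sse = f$gof$sse,
                 rmse = f$gof$rmse, r2 = f$gof$r2, adj_r2 = f$gof$adj_r2,
                 n_restarts = f$n_restarts)
    }
  }))

  tracks <- track_components(ch$fits, tt$times)
  events <- ch$events
  provenance <- list(config = unclass(control),
                     config_hash = config_hash(control),
                     seed = control$seed, omit = meta$omit,
                     events = events)
  report <- summarize_tracks(tracks, meta$conditions,
                             floor_nm = control$floor_nm,
                             r_max_nm = control$r_max_nm,
                             provenance = provenance)
  if (any(report$results$clamped)) {
    events <- c(events, sprintf("component %d: radius clamped at the %g nm floor",
                                report$results$rank[report$results$clamped],
                                control$floor_nm))
    report$provenance$events <- events
  }

  structure(list(report = report, fits = ch$fits, tracks = tracks, gof = gof,
                 profiles = sps, times = tt$times, deltas = tt$deltas,
                 slope_bounds = sb, velocity = v, metadata = meta,
                 control = control, events = events, call = cl),
            class = "diffsize")
}

#' @export
print.diffsize <- function(x, ...) {
  cat("Diffusional sizing fit\n")
  cat(sprintf("  %d measurement points, mixture order %d, seed %d\n",
              length(x$profiles), x$control$order, x$control$seed))
  cat(sprintf("  mean particle speed %.0f um/s, transit %.3f-%.3f s\n",
              x$velocity, min(x$times), max(x$times)))
  cat(sprintf("  approximate radius %.3f nm (higher %.3f, lower %.3f)\n",
              x$report$mean_radius, x$report$higher, x$report$lower))
  if (length(x$events)) cat("  events:", length(x$events), "(see $events)\n")
  invisible(x)
}

#' @export
summary.diffsize <- function(object, ...) {
  structure(list(report = object$report, gof = object$gof,
                 control = object$control, velocity = object$velocity,
                 events = object$events,
                 n_points = length(object$profiles)),
            class = "summary.diffsize")
}

#' @export
print.summary.diffsize <- function(x, ...) {
  cat(sprintf("Diffusional sizing: order-%d mixture over %d points\n\n",
              x$control$order, x$n_points))
  print(x$report)
  cat("\nPer-point goodness of fit:\n")
  print(x$gof, digits = 4, row.names = FALSE)
  if (length(x$events)) {
    cat("\nEvents:\n ", paste(x$events, collapse = "\n  "), "\n")
  }
  invisible(x)
}

#' Extract sizing coefficients
#'
#' @param object A `"diffsize"` fit.
#' @param ... Ignored.
#' @return Matrix with one row per component rank: variance-time `slope`
#'   (um^2/s) and `intercept` (um^2), `D_um2_s`, `radius_nm`.
#' @export
coef.diffsize <- function(object, ...) {
  r <- object$report$results
  m <- as.matrix(r[, c("slope", "intercept", "D_um2_s", "radius_nm")])
  rownames(m) <- paste0("component", r$rank)
  m
}

#' Fitted mixture values at each measurement point
#'
#' @param object A `"diffsize"` fit.
#' @param ... Ignored.
#' @return Named list (one element per point) of fitted intensities over the
#'   inside section; `NULL` where the fit failed.
#' @export
fitted.diffsize <- function(object, ...) {
  stats::setNames(lapply(seq_along(object$profiles), function(i) {
    f <- object$fits[[i]]
    if (is.null(f)) return(NULL)
    sp <- object$profiles[[i]]
    mixture_value(f$components, sp$pair$x[sp$inside])
  }), vapply(object$profiles, function(s) s$pair$label, character(1)))
}

#' @export
residuals.diffsize <- function(object, ...) {
  fv <- fitted(object)
  stats::setNames(lapply(seq_along(object$profiles), function(i) {
    if (is.null(fv[[i]])) return(NULL)
    sp <- object$profiles[[i]]
    sp$pair$fluorescent[sp$inside] - fv[[i]]
  }), names(fv))
}

#' Predict mixture intensities at new positions
#'
#' @param object A `"diffsize"` fit.
#' @param point Measurement-point label (default: the last fitted point).
#' @param x Positions (um, centered frame); defaults to the point's inside
#'   section.
#' @param ... Ignored.
#' @return Predicted intensities.
#' @export
predict.diffsize <- function(object, point = NULL, x = NULL, ...) {
  labels <- vapply(object$profiles, function(s) s$pair$label, character(1))
  ok <- which(!vapply(object$fits, is.null, logical(1)))
  if (is.null(point)) point <- labels[ok[length(ok)]]
  i <- match(point, labels)
  if (is.na(i) || is.null(object$fits[[i]])) {
    stop("no successful fit for point ", point, call. = FALSE)
  }
  if (is.null(x)) {
    sp <- object$profiles[[i]]
    x <- sp$pair$x[sp$inside]
  }
  mixture_value(object$fits[[i]]$components, x)
}

#' Plot diagnostics for a sizing fit
#'
#' `which = "variance"` draws the variance-time points and fitted lines for
#' each component track; `which = "profile"` overlays one centered fluorescent
#' profile with its fitted mixture.
#'
#' @param x A `"diffsize"` fit.
#' @param which `"variance"` or `"profile"`.
#' @param point Measurement-point label for `which = "profile"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.diffsize <- function(x, which = c("variance", "profile"), point = NULL,
                          ...) {
  which <- match.arg(which)
  if (which == "variance") {
    ts <- unlist(lapply(x$tracks, `[[`, "times"))
    vs <- unlist(lapply(x$tracks, `[[`, "variances"))
    graphics::plot(ts, vs, xlab = "transit time (s)",
                   ylab = expression(c^2 ~ (mu * m^2)),
                   main = "Variance-time regression", ...)
    for (k in seq_along(x$tracks)) {
      tr <- x$tracks[[k]]
      graphics::points(tr$times, tr$variances, col = k, pch = 16)
      row <- x$report$results[x$report$results$rank == tr$rank, ]
      if (nrow(row)) {
        graphics::abline(row$intercept, row$slope, col = k, lty = 2)
      }
    }
  } else {
    labels <- vapply(x$profiles, function(s) s$pair$label, character(1))
    if (is.null(point)) point <- labels[length(labels)]
    i <- match(point, labels)
    sp <- x$profiles[[i]]
    xs <- sp$pair$x[sp$inside]
    graphics::plot(xs, sp$pair$fluorescent[sp$inside], type = "l",
                   xlab = "position (um)", ylab = "intensity (counts)",
                   main = paste("Centered profile", point), ...)
    if (!is.null(x$fits[[i]])) {
      graphics::lines(xs, mixture_value(x$fits[[i]]$components, xs),
                      col = 2, lwd = 2)
    }
  }
  invisible(x)
}

#' Simulate measurement sets from a fitted model
#'
#' Generates synthetic workbook-ready measurement sets whose species have the
#' fitted radii, under the fit's own geometry, flows and conditions — a
#' parametric-bootstrap-style check that the pipeline recovers what it
#' reported.
#'
#' @param object A `"diffsize"` fit.
#' @param nsim Number of sets.
#' @param seed Integer seed for the noise streams.
#' @param noise A [noise_model()]; its seed is advanced per replicate.
#' @param ... Ignored.
#' @return A list of [measurement_set()]s of length `nsim`.
#' @export
simulate.diffsize <- function(object, nsim = 1, seed = 1,
                              noise = noise_model(additive_sd = 5), ...) {
  r <- pmin(pmax(object$report$results$radius_nm, 1), 2000)
  lapply(seq_len(nsim), function(i) {
    nz <- noise
    nz$seed <- seed + i - 1L
    simulate_profiles(species_mix(r),
                      geom = object$metadata$geometry,
                      flow = object$metadata$flow,
                      cond = object$metadata$conditions,
                      noise = nz)
  })
}

#' Goodness-of-fit order scan for a workbook or measurement set
#'
#' Convenience wrapper: preprocesses the set and runs [order_scan()] over
#' mixture orders 1..`max_order`.
#'
#' @param x Workbook path or [measurement_set()].
#' @param control A [diffsize_control()] (its `order` is ignored).
#' @param max_order Largest order to scan.
#' @return A `"gof_scan"` data frame.
#' @export
gof_order_scan <- function(x, control = diffsize_control(), max_order = 8) {
  ms <- if (inherits(x, "measurement_set")) {
    omit_points(x, control$omit)
  } else {
    read_measurement_workbook(x, omit = control$omit)
  }
  meta <- ms$metadata
  v <- mean_velocity(meta$flow, meta$geometry)
  tt <- transit_times(meta$geometry, v)
  sb <- slope_bounds(control$r_min_nm * 1e-9, control$r_max_nm * 1e-9,
                     meta$conditions)
  sps <- preprocess_profiles(ms, standard = control$baseline,
                             fluor_baseline_region = control$fluor_baseline_region)
  order_scan(sps, tt$times, sb, max_order = max_order,
             global_cap = control$sigma_cap, b_limit = control$b_limit,
             patience = control$patience, seed = control$seed)
}
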