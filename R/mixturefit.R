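# Bounded multistart Gaussian-mixture fitting of centered fluorescent profiles.
#
# Width convention: a component is a * exp(-((x - b) / c)^2), i.e. c is the
# e-folding half-width parameter, NOT the probabilistic standard deviation.
# Matching this exponent against the 1-D diffusion density gives c^2 = 4 D t,
# so "variance" everywhere downstream means this c^2. Keeping the convention
# end to end is what makes the variance-time slope equal 4 D without a stray
# factor of two.

#' Evaluate a Gaussian mixture
#'
#' `sum_k a_k * exp(-((x - b_k) / c_k)^2)` over the components.
#'
#' @param components Data frame with columns `amplitude`, `center`, `sigma`
#'   (one row per component; `sigma` is the `c` width parameter, um).
#' @param x Positions (um).
#' @return Intensity values at `x`.
#' @export
mixture_value <- function(components, x) {
  stopifnot(is.data.frame(components),
            all(c("amplitude", "center", "sigma") %in% names(components)))
  v <- numeric(length(x))
  for (k in seq_len(nrow(components))) {
    v <- v + components$amplitude[k] *
      exp(-((x - components$center[k]) / components$sigma[k])^2)
  }
  v
}

#' Goodness-of-fit metrics
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @param p Number of free parameters (3 per Gaussian component).
#' @return List with `sse`, `rmse` (`sqrt(sse / dfe)`), `r2`, `adj_r2`, `dfe`.
#' @export
gof_metrics <- function(observed, fitted, p) {
  n <- length(observed)
  stopifnot(length(fitted) == n, n > p)
  res <- observed - fitted
  sse <- sum(res^2)
  dfe <- n - p
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant; R^2 undefined", call. = FALSE)
  list(sse = sse,
       rmse = sqrt(sse / dfe),
       r2 = 1 - sse / sst,
       adj_r2 = 1 - (sse / dfe) / (sst / (n - 1)),
       dfe = dfe)
}

#' Per-component sigma bounds for the next measurement point
#'
#' The admissible variance-time slope range translates, over the inter-point
#' transit time `dt`, into how much each component's width may grow between
#' consecutive profiles: `c` is bounded to
#' `[sqrt(c_prev^2 + slope_min * dt), sqrt(c_prev^2 + slope_max * dt)]`
#' (capped at the global maximum). The lower bound never falls below the
#' previous width, which is what forces the fitted curves to widen point by
#' point. The first profile is only constrained to `(eps, global_cap]`.
#'
#' @param prev A `mixture_fit` for the previous point, or `NULL` for the first.
#' @param dt Transit-time difference to the previous fitted point (s).
#' @param slopes Admissible slope range from [slope_bounds()] (um^2/s).
#' @param order Number of components (used when `prev` is `NULL`).
#' @param global_cap Global sigma cap (um).
#' @param eps Sigma lower floor (um).
#' @param on_saturation What to do when a component's previous width is
#'   already at the global cap so that the mandatory minimum growth cannot
#'   fit under it: `"error"` (default) raises an infeasible-bounds error;
#'   `"pin"` clamps that component to the cap so the rest of the chain can
#'   continue (its stalled variance track is later reported as a
#'   non-physical slope rather than a radius).
#' @return `order x 2` matrix of `(low, high)` sigma bounds, one row per
#'   component in sigma-descending rank order.
#' @export
sequential_sigma_bounds <- function(prev, dt, slopes, order = NULL,
                                    global_cap = 100, eps = 1e-3,
                                    on_saturation = c("error", "pin")) {
  on_saturation <- match.arg(on_saturation)
  if (dt < 0) stop("`dt` must be non-negative", call. = FALSE)
  if (is.null(prev)) {
    stopifnot(!is.null(order))
    return(matrix(rep(c(eps, global_cap), each = order), ncol = 2,
                  dimnames = list(NULL, c("low", "high"))))
  }
  stopifnot(inherits(prev, "mixture_fit"))
  c_prev <- prev$components$sigma
  low <- sqrt(c_prev^2 + slopes[[1L]] * dt)
  high <- pmin(sqrt(c_prev^2 + slopes[[2L]] * dt), global_cap)
  if (any(low > high + 1e-9)) {
    if (on_saturation == "error") {
      stop("infeasible sigma bounds: previous width already at the global cap",
           call. = FALSE)
    }
    low <- pmin(low, high)
  }
  cbind(low = low, high = pmax(high, low))
}

.draw_start <- function(order, amp_max, b_limit, sigma_bounds) {
  a <- stats::runif(order, 0, 2 * amp_max)
  b <- stats::runif(order, -b_limit, b_limit)
  cc <- exp(stats::runif(order, log(sigma_bounds[, 1L]),
                         log(sigma_bounds[, 2L])))
  rbind(a, b, cc)
}

#' Fit a Gaussian mixture to one centered profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box constraints)
#' from randomized starting points. Restarting stops once `patience`
#' consecutive restarts fail to improve the best RMSE. Amplitudes are
#' non-negative, centers confined to `[-b_limit, b_limit]` um and widths to the
#' supplied per-component bounds. Components are returned sorted by sigma,
#' descending, which fixes their identity across restarts and across
#' measurement points.
#'
#' @param x,y Positions (um) and zeroed intensities of the inside section.
#' @param order Number of Gaussian components (1-8).
#' @param sigma_bounds `order x 2` matrix of `(low, high)` sigma bounds, e.g.
#'   from [sequential_sigma_bounds()].
#' @param b_limit Center bound (um); the peak sits within 5 um of the center.
#' @param patience Consecutive non-improving restarts before stopping.
#' @param seed Optional integer; when given, the RNG state is set (and
#'   restored) so the fit is reproducible in isolation.
#' @return A `mixture_fit`: `order`, `components` (sigma-descending),
#'   `gof`, `n_restarts`, `seed`.
#' @export
fit_mixture <- function(x, y, order, sigma_bounds, b_limit = 5, patience = 5,
                        seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, order >= 1, order <= 8)
  if (n <= 3 * order) {
    stop("inside section has too few points for this model order", call. = FALSE)
  }
  sigma_bounds <- matrix(sigma_bounds, ncol = 2)
  if (nrow(sigma_bounds) != order || any(sigma_bounds[, 1L] > sigma_bounds[, 2L])) {
    stop("sigma bounds must be an order x 2 matrix with low <= high",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  amp_max <- max(y, 1e-12)
  lower <- as.numeric(rbind(0, -b_limit, sigma_bounds[, 1L]))
  upper <- as.numeric(rbind(Inf, b_limit, sigma_bounds[, 2L]))
  residual <- function(par) {
    pm <- matrix(par, nrow = 3)
    v <- numeric(n)
    for (k in seq_len(order)) {
      v <- v + pm[1L, k] * exp(-((x - pm[2L, k]) / pm[3L, k])^2)
    }
    y - v
  }

  best <- NULL
  best_rmse <- Inf
  streak <- 0L
  n_restarts <- 0L
  dfe <- n - 3 * order
  while (streak < patience) {
    start <- as.numeric(.draw_start(order, amp_max, b_limit, sigma_bounds))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = residual,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    n_restarts <- n_restarts + 1L
    if (!is.null(fit)) {
      rmse <- sqrt(sum(fit$fvec^2) / dfe)
      improved <- is.finite(rmse) &&
        (!is.finite(best_rmse) ||
           rmse < best_rmse - 1e-12 * max(1, best_rmse))
      if (improved) {
        best <- fit
        best_rmse <- rmse
        streak <- 0L
        next
      }
    }
    streak <- streak + 1L
  }
  if (is.null(best)) {
    stop("optimizer failed on every start (", n_restarts, " attempts)",
         call. = FALSE)
  }

  pm <- matrix(best$par, nrow = 3)
  comp <- data.frame(amplitude = pm[1L, ], center = pm[2L, ], sigma = pm[3L, ])
  ord <- order(comp$sigma, decreasing = TRUE)
  comp <- comp[ord, , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(order = order, components = comp,
                 gof = gof_metrics(y, y - residual(best$par), p = 3 * order),
                 n_restarts = n_restarts, seed = seed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit, order %d (RMSE %.4g, adj R^2 %.5f, %d restarts)\n",
              x$order, x$gof$rmse, x$gof$adj_r2, x$n_restarts))
  print(x$components, digits = 4)
  invisible(x)
}

# Fit a chain of profiles at one model order, threading the sequential sigma
# bounds (and accumulating dt across any failed points). Returns fits (NULL on
# failure) and a log of events.
fit_profile_chain <- function(sps, times, order, slopes, global_cap = 100,
                              b_limit = 5, patience = 5) {
  fits <- vector("list", length(sps))
  events <- character()
  prev <- NULL
  dt_acc <- 0
  for (i in seq_along(sps)) {
    dt <- if (i == 1L) 0 else times[i] - times[i - 1L]
    dt_acc <- dt_acc + dt
    res <- tryCatch({
      bnds <- sequential_sigma_bounds(prev, dt_acc, slopes, order = order,
                                      global_cap = global_cap,
                                      on_saturation = "pin")
      if (any(bnds[, "low"] >= global_cap)) {
        events <- c(events, sprintf(
          "point %s (order %d): component(s) %s pinned at the sigma cap",
          sps[[i]]$pair$label, order,
          paste(which(bnds[, "low"] >= global_cap), collapse = ",")))
      }
      fit_mixture(sps[[i]]$pair$x[sps[[i]]$inside],
                  sps[[i]]$pair$fluorescent[sps[[i]]$inside],
                  order, bnds, b_limit = b_limit, patience = patience)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      events <- c(events, sprintf("point %s (order %d): %s",
                                  sps[[i]]$pair$label, order,
                                  conditionMessage(res)))
      fits[i] <- list(NULL)
    } else {
      fits[[i]] <- res
      prev <- res
      dt_acc <- 0
    }
  }
  list(fits = fits, events = events)
}

#' Goodness-of-fit scan over model orders
#'
#' Fits every measurement point with mixtures of 1 to `max_order` components
#' (each order run as its own sequentially-bounded chain) and tabulates all
#' four goodness-of-fit metrics. The scan is advisory: it shows whether adding
#' components beyond the default order still buys fit quality.
#'
#' @param sps Preprocessed profiles from [preprocess_profiles()].
#' @param times Transit times (s), one per profile.
#' @param slopes Admissible slope range from [slope_bounds()].
#' @param max_order Largest model order to scan.
#' @param global_cap,b_limit,patience As in [fit_mixture()].
#' @param seed Integer seed; each order's chain draws from a deterministic
#'   stream derived from it.
#' @return A data frame of class `"gof_scan"`: `order`, `label`, `sse`,
#'   `rmse`, `r2`, `adj_r2`, `error` (NA when the fit succeeded).
#' @export
order_scan <- function(sps, times, slopes, max_order = 8, global_cap = 100,
                       b_limit = 5, patience = 5, seed = 1) {
  labels <- vapply(sps, function(s) s$pair$label, character(1))
  rows <- list()
  for (o in seq_len(max_order)) {
    set.seed(seed + o)
    ch <- fit_profile_chain(sps, times, o, slopes, global_cap = global_cap,
                            b_limit = b_limit, patience = patience)
    for (i in seq_along(sps)) {
      f <- ch$fits[[i]]
      rows[[length(rows) + 1L]] <- if (is.null(f)) {
        err <- grep(sprintf("point %s \\(order %d\\)", labels[i], o),
                    ch$events, value = TRUE)
        data.frame(order = o, label = labels[i], sse = NA_real_,
                   rmse = NA_real_, r2 = NA_real_, adj_r2 = NA_real_,
                   error = if (length(err)) err[1L] else "fit failed")
      } else {
        data.frame(order = o, label = labels[i], sse = f$gof$sse,
                   rmse = f$gof$rmse, r2 = f$gof$r2, adj_r2 = f$gof$adj_r2,
                   error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gof_scan", "data.frame")
  out
}

#' Plot a goodness-of-fit scan
#'
#' One panel per metric, model order on the x axis, one line per measurement
#' point.
#'
#' @param x A `"gof_scan"` data frame from [order_scan()].
#' @param ... Ignored.
#' @export
plot.gof_scan <- function(x, ...) {
  metrics <- c("sse", "rmse", "r2", "adj_r2")
  labels <- unique(x$label)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    graphics::matplot(
      x = sort(unique(x$order)),
      y = vapply(labels, function(l) x[[m]][x$label == l][order(x$order[x$label == l])],
                 numeric(length(unique(x$order)))),
      type = "b", pch = 1, lty = 1, xlab = "model order", ylab = m,
      main = toupper(m))
  }
  invisible(x)
}
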