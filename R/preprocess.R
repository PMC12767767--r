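# Profile preprocessing: crop rotation-induced zero ends, locate the channel
# sidewalls from the brightfield trace, split into inside/outside sections,
# normalize baselines and inside areas, then zero and center on the peak.

#' Crop rotation-induced zero ends from a profile pair
#'
#' Image rotation leaves zero-intensity stretches at both ends of the recorded
#' vector. A band `mean +/- sd` is laid around the raw brightfield trace (sd is
#' the population standard deviation, zeros included) and points are removed
#' from each end until the first one whose brightfield intensity exceeds the
#' band's lower limit. The fluorescent trace and `x` are cropped identically.
#'
#' @param pair A [profile_pair()].
#' @return The cropped [profile_pair()].
#' @export
crop_profile <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  bf <- pair$brightfield
  n <- length(bf)
  mu <- mean(bf)
  sd_pop <- sqrt(mean((bf - mu)^2))
  lower <- mu - sd_pop
  keep <- which(bf > lower)
  if (!length(keep)) {
    stop(sprintf("profile '%s': every point is below the crop band's lower limit",
                 pair$label), call. = FALSE)
  }
  i1 <- keep[1L]
  i2 <- keep[length(keep)]
  if (i1 == 1L && i2 == n) return(pair)
  profile_pair(pair$label, pair$position, pair$x[i1:i2],
               pair$brightfield[i1:i2], pair$fluorescent[i1:i2])
}

sectioned_profile <- function(pair, wall_centers, inside, outside_left,
                              outside_right) {
  structure(list(pair = pair, wall_centers = wall_centers, inside = inside,
                 outside_left = outside_left, outside_right = outside_right),
            class = "sectioned_profile")
}

#' @export
print.sectioned_profile <- function(x, ...) {
  cat(sprintf("Sectioned profile '%s': walls at %.1f / %.1f um, inside %d pts, outside %d + %d pts\n",
              x$pair$label, x$wall_centers[1], x$wall_centers[2],
              length(x$inside), length(x$outside_left), length(x$outside_right)))
  invisible(x)
}

#' Locate the channel sidewalls and section a profile
#'
#' Starting from the fluorescent maximum, the brightfield trace is scanned in
#' both directions; in each scanned portion the wall is marked by the intensity
#' minimum or maximum, whichever deviates more from the brightfield mean (the
#' sidewalls are the only features that deviate strongly after cropping, and
#' they can image bright or dark). A region of width `2 * wall_thickness`
#' centered on each wall is excluded — the displayed line thickness is doubled
#' to absorb the uncertainty between a spike's position and the line's middle —
#' leaving three sections: inside the channel and the two outside stretches.
#'
#' @param pair A cropped [profile_pair()].
#' @param wall_thickness Sidewall line thickness (um).
#' @return A `sectioned_profile`: the pair plus `wall_centers` (um) and integer
#'   index vectors `inside`, `outside_left`, `outside_right`.
#' @export
locate_walls <- function(pair, wall_thickness) {
  stopifnot(inherits(pair, "profile_pair"))
  x <- pair$x
  bf <- pair$brightfield
  fl <- pair$fluorescent
  n <- length(x)

  peak_candidates <- which(fl == max(fl))
  mid <- (x[1L] + x[n]) / 2
  m <- peak_candidates[which.min(abs(x[peak_candidates] - mid))]

  mu <- mean(bf)
  wall_index <- function(idx) {
    seg <- bf[idx]
    i_min <- idx[which.min(seg)]
    i_max <- idx[which.max(seg)]
    if (abs(bf[i_min] - mu) > abs(bf[i_max] - mu)) i_min else i_max
  }
  wl <- wall_index(seq_len(m))
  wr <- wall_index(m:n)

  if (x[wl] - x[1L] < wall_thickness || x[n] - x[wr] < wall_thickness) {
    stop(sprintf("profile '%s': wall extremum within one wall thickness of the trace end",
                 pair$label), call. = FALSE)
  }
  if (x[wl] >= x[wr]) {
    stop(sprintf("profile '%s': walls not found on both sides of the peak",
                 pair$label), call. = FALSE)
  }

  inside <- which(x > x[wl] + wall_thickness & x < x[wr] - wall_thickness)
  outside_left <- which(x < x[wl] - wall_thickness)
  outside_right <- which(x > x[wr] + wall_thickness)
  if (!length(inside)) {
    stop(sprintf("profile '%s': no points between the wall exclusion zones",
                 pair$label), call. = FALSE)
  }
  sectioned_profile(pair, c(x[wl], x[wr]), inside, outside_left, outside_right)
}

#' Normalize a brightfield trace to the baseline standard
#'
#' Multiplies the brightfield trace by `standard / mean(inside)` so the mean
#' brightfield intensity inside the channel sits exactly on the standard
#' baseline (200 counts by default, the most commonly observed level).
#'
#' @param sp A `sectioned_profile`.
#' @param standard Baseline intensity standard (counts).
#' @return The `sectioned_profile` with rescaled brightfield.
#' @export
normalize_brightfield <- function(sp, standard = 200) {
  stopifnot(inherits(sp, "sectioned_profile"))
  m <- mean(sp$pair$brightfield[sp$inside])
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("profile '%s': non-positive mean brightfield inside the channel",
                 sp$pair$label), call. = FALSE)
  }
  sp$pair$brightfield <- sp$pair$brightfield * (standard / m)
  sp
}

#' Normalize a set of fluorescent traces
#'
#' Two steps applied across the whole measurement set. Step 1 scales each
#' fluorescent trace so its baseline equals the standard, removing slow changes
#' in external light between points; the baseline is taken from the outside
#' sections by default (the inside carries the analyte signal). Step 2 scales
#' each trace by the ratio of the largest inside-channel integral in the set to
#' its own, so all profiles enclose the same area; integrals are trapezoidal
#' and ignore the sections outside the channel.
#'
#' @param sps List of `sectioned_profile`s (one measurement set).
#' @param standard Baseline intensity standard (counts).
#' @param baseline_region `"outside"` (default) or `"inside"`: which section's
#'   mean defines the step-1 baseline.
#' @return The list with rescaled fluorescent traces.
#' @export
normalize_fluorescent_set <- function(sps, standard = 200,
                                      baseline_region = c("outside", "inside")) {
  baseline_region <- match.arg(baseline_region)
  sps <- lapply(sps, function(sp) {
    idx <- if (baseline_region == "outside") {
      c(sp$outside_left, sp$outside_right)
    } else {
      sp$inside
    }
    if (!length(idx)) {
      stop(sprintf("profile '%s': no %s points to estimate the baseline from",
                   sp$pair$label, baseline_region), call. = FALSE)
    }
    base <- mean(sp$pair$fluorescent[idx])
    if (!is.finite(base) || base <= 0) {
      stop(sprintf("profile '%s': non-positive fluorescent baseline",
                   sp$pair$label), call. = FALSE)
    }
    sp$pair$fluorescent <- sp$pair$fluorescent * (standard / base)
    sp
  })
  ints <- vapply(sps, function(sp) {
    pracma::trapz(sp$pair$x[sp$inside], sp$pair$fluorescent[sp$inside])
  }, numeric(1))
  if (any(ints <= 0)) {
    stop("non-positive inside-channel integral; cannot area-normalize",
         call. = FALSE)
  }
  target <- max(ints)
  Map(function(sp, i) {
    sp$pair$fluorescent <- sp$pair$fluorescent * (target / i)
    sp
  }, sps, ints)
}

#' Zero the baseline and center a profile on its fluorescent peak
#'
#' Subtracts the mean of the outside-section fluorescent intensities so the
#' baseline sits on the intensity-zero axis, then shifts `x` so the fluorescent
#' peak (inside the channel) sits at `x = 0`; the brightfield trace and wall
#' centers ride along rigidly.
#'
#' @param sp A normalized `sectioned_profile`.
#' @return The zeroed, centered `sectioned_profile`.
#' @export
zero_and_center <- function(sp) {
  stopifnot(inherits(sp, "sectioned_profile"))
  out <- c(sp$outside_left, sp$outside_right)
  if (!length(out)) {
    stop(sprintf("profile '%s': no outside points to estimate the baseline from",
                 sp$pair$label), call. = FALSE)
  }
  fl <- sp$pair$fluorescent
  base <- mean(fl[out])
  sd_out <- stats::sd(fl[out])
  if (!is.finite(sd_out)) sd_out <- 0
  fl <- fl - base
  peak_val <- max(fl[sp$inside])
  if (peak_val <= 3 * sd_out + 1e-6) {
    stop(sprintf("profile '%s': no fluorescent signal above baseline + 3 sd",
                 sp$pair$label), call. = FALSE)
  }
  pk <- sp$inside[which.max(fl[sp$inside])]
  shift <- sp$pair$x[pk]
  sp$pair$fluorescent <- fl
  sp$pair$x <- sp$pair$x - shift
  sp$wall_centers <- sp$wall_centers - shift
  sp
}

#' Run all preprocessing stages on a measurement set
#'
#' Crop, wall location, brightfield normalization, two-step fluorescent
#' normalization and zero/center, in that order, for every measurement point.
#'
#' @param ms A [measurement_set()].
#' @param standard Baseline intensity standard (counts).
#' @param fluor_baseline_region Passed to [normalize_fluorescent_set()].
#' @return List of preprocessed `sectioned_profile`s, in channel order.
#' @export
preprocess_profiles <- function(ms, standard = 200,
                                fluor_baseline_region = "outside") {
  stopifnot(inherits(ms, "measurement_set"))
  wt <- ms$metadata$geometry$wall_thickness
  sps <- lapply(ms$profiles, function(p) locate_walls(crop_profile(p), wt))
  sps <- lapply(sps, normalize_brightfield, standard = standard)
  sps <- normalize_fluorescent_set(sps, standard = standard,
                                   baseline_region = fluor_baseline_region)
  lapply(sps, zero_and_center)
}
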