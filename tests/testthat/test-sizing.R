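fake_fit <- function(sigmas, amplitudes = rep(100, length(sigmas))) {
  o <- order(sigmas, decreasing = TRUE)
  structure(list(order = length(sigmas),
                 components = data.frame(amplitude = amplitudes[o],
                                         center = 0, sigma = sigmas[o])),
            class = "mixture_fit")
}

test_that("components are tracked by sigma rank across points", {
  fits <- lapply(c(10, 12, 14, 16, 18), function(s) fake_fit(s))
  tr <- track_components(fits, times = 1:5 / 10)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$variances, c(10, 12, 14, 16, 18)^2)

  # order 2 with well-separated sigmas never swaps rank
  fits2 <- lapply(1:5, function(i) fake_fit(c(8 + i, 20 + 2 * i)))
  tr2 <- track_components(fits2, 1:5 / 10)
  expect_equal(tr2[[1]]$sigmas, 20 + 2 * (1:5))
  expect_equal(tr2[[2]]$sigmas, 8 + (1:5))
  expect_true(all(diff(tr2[[1]]$variances) >= 0))

  bad <- c(fits[1:2], list(fake_fit(c(5, 10))))
  expect_error(track_components(bad, 1:3), "differing")
  # failed points are dropped from every track
  with_null <- fits
  with_null[3] <- list(NULL)
  tr3 <- track_components(with_null, 1:5 / 10)
  expect_equal(tr3[[1]]$times, c(1, 2, 4, 5) / 10)
})

test_that("the variance-time line is ordinary least squares with intercept", {
  tr <- structure(list(rank = 1, times = c(0.1, 0.2, 0.3),
                       variances = c(40, 80, 120),
                       amplitudes = rep(1, 3), sigmas = sqrt(c(40, 80, 120))),
                  class = "component_track")
  f <- fit_variance_time(tr)
  expect_equal(f$slope, 400)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r2_line, 1)

  # constant shift moves only the intercept
  tr$variances <- tr$variances + 25
  f2 <- fit_variance_time(tr)
  expect_equal(f2$slope, 400)
  expect_equal(f2$intercept, 25)

  tr$variances <- c(120, 105, 80)
  expect_error(fit_variance_time(tr), "non-physical")
  tr$times <- tr$times[1:2]
  expect_error(fit_variance_time(tr), "at least 3")
})

test_that("slopes convert to diffusion coefficients and clamped radii", {
  dr <- diffusion_and_radius(400, cond_water25)
  expect_equal(dr$D, 100)
  expect_equal(dr$radius, 2.4537, tolerance = 1e-4)
  expect_false(dr$clamped)

  # a slope implying r < 1 nm is reported at the floor, flagged
  big <- diffusion_and_radius(4000, cond_water25, floor_nm = 1)
  expect_equal(big$radius, 1)
  expect_true(big$clamped)

  # radius is inversely proportional to slope (pre-clamp)
  r1 <- diffusion_and_radius(100, cond_water25)$radius
  r4 <- diffusion_and_radius(400, cond_water25)$radius
  expect_equal(r1 / r4, 4)
})

test_that("particle counts follow the area identity N = a c sqrt(pi)", {
  expect_equal(estimate_particle_count(100, 10), 1772.4539, tolerance = 1e-7)
  expect_equal(estimate_particle_count(0, 10), 0)
  expect_equal(estimate_particle_count(6, 10), 3 * estimate_particle_count(2, 10))
  expect_error(estimate_particle_count(-1, 10), "a >= 0")
})

test_that("the report follows the higher/lower pair convention", {
  # build two exact tracks whose radii are 2.03 and 1.42 nm
  mk_track <- function(rank, r_nm) {
    slope <- 4 * diffusion_from_radius(r_nm * 1e-9, cond_water25) * 1e12
    t <- seq(0.1, 1, by = 0.1)
    structure(list(rank = rank, times = t, variances = 100 + slope * t,
                   amplitudes = rep(50, 10), sigmas = sqrt(100 + slope * t)),
              class = "component_track")
  }
  rep_ <- summarize_tracks(list(mk_track(1, 1.42), mk_track(2, 2.03)),
                           cond_water25,
                           provenance = list(seed = 7, omit = "P10"))
  expect_equal(rep_$higher, 2.03, tolerance = 1e-6)
  expect_equal(rep_$lower, 1.42, tolerance = 1e-6)
  # the single approximate radius is the mean of the pair: (2.03+1.42)/2
  expect_equal(rep_$mean_radius, 1.725, tolerance = 1e-6)
  expect_gte(rep_$higher, rep_$lower)
  expect_equal(rep_$provenance$seed, 7)

  # a non-physical component is reported as a failure, not a radius
  shrink <- mk_track(3, 2)
  shrink$variances <- rev(shrink$variances)
  rep2 <- summarize_tracks(list(mk_track(1, 2), shrink), cond_water25)
  expect_equal(nrow(rep2$results), 1)
  expect_match(rep2$failures, "non-physical")
  expect_error(summarize_tracks(list(shrink), cond_water25), "no component")

  # a stalled track (width pinned at the cap) must not yield a huge radius
  stalled <- mk_track(2, 2)
  stalled$variances <- 10000 + (0:9) * 1e-10
  rep3 <- summarize_tracks(list(mk_track(1, 2), stalled), cond_water25,
                           r_max_nm = 2000)
  expect_equal(nrow(rep3$results), 1)
  expect_match(rep3$failures, "admissible maximum")
  expect_lte(rep3$higher, 2000)
})
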