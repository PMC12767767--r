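# wall-spike brightfield builder used by the sectioning tests
wall_profile <- function(x, wall_x = c(50, 1400), level = 200, spike = 400,
                         peak_x = 700, wall_sd = 10) {
  bf <- rep(level, length(x))
  for (w in wall_x) bf <- bf + (spike - level) * exp(-((x - w) / wall_sd)^2)
  fl <- level + 300 * exp(-((x - peak_x) / 40)^2)
  profile_pair("T", 1000, x, bf, fl)
}

test_that("cropping removes zero ends up to the brightfield band", {
  p <- profile_pair("T", 0, 0:6, c(0, 0, 120, 150, 160, 158, 0),
                    rep(100, 7))
  # mean 84, population sd 73.75, lower limit 10.25 -> keep indices 3..6
  cr <- crop_profile(p)
  expect_equal(cr$brightfield, c(120, 150, 160, 158))
  expect_equal(cr$x, 2:5)

  # no zero ends: unchanged
  p2 <- profile_pair("T", 0, 0:3, c(200, 210, 190, 205), rep(1, 4))
  expect_identical(crop_profile(p2), p2)

  expect_error(crop_profile(profile_pair("T", 0, 0:3, rep(0, 4), rep(1, 4))),
               "lower limit")
})

test_that("cropping is idempotent on simulated recordings", {
  for (pt in c(1, 6, 11)) {
    p <- sim_pair(point = pt, additive_sd = 8, seed = pt)
    once <- crop_profile(p)
    expect_identical(crop_profile(once), once)
    expect_gt(length(p$x), length(once$x)) # pads were actually removed
  }
})

test_that("walls are found from the strongest brightfield deviation", {
  x <- seq(0, 1450, by = 2.5)
  p <- wall_profile(x)
  sp <- locate_walls(p, wall_thickness = 20)
  expect_equal(sp$wall_centers, c(50, 1400), tolerance = 1e-9)

  # dark walls (dips, not spikes) are found by the same deviation criterion
  bf_dark <- 200 - (p$brightfield - 200) * (180 / 200)
  pd <- profile_pair("T", 1000, x, bf_dark, p$fluorescent)
  spd <- locate_walls(pd, wall_thickness = 20)
  expect_equal(spd$wall_centers, c(50, 1400), tolerance = 1e-9)

  # excluded regions have width 2 * wall_thickness
  expect_equal(min(x[sp$inside]), 50 + 20 + 2.5, tolerance = 2.5)
  expect_equal(max(x[sp$outside_left]), 50 - 20 - 2.5, tolerance = 2.5)
  expect_true(all(diff(c(max(sp$outside_left), min(sp$inside))) > 0))

  # wall hard against the trace end is an error
  expect_error(locate_walls(wall_profile(x, wall_x = c(10, 1400)), 20),
               "wall extremum")
})

test_that("sectioning is invariant under rigid x shifts", {
  x <- seq(0, 1450, by = 2.5)
  p <- wall_profile(x)
  sp <- locate_walls(p, 20)
  p_shift <- profile_pair("T", 1000, x + 137, p$brightfield, p$fluorescent)
  sp_shift <- locate_walls(p_shift, 20)
  expect_equal(sp_shift$wall_centers, sp$wall_centers + 137)
  expect_identical(sp_shift$inside, sp$inside)
  expect_identical(sp_shift$outside_left, sp$outside_left)
  expect_identical(sp_shift$outside_right, sp$outside_right)
})

test_that("brightfield normalization puts the inside mean on the standard", {
  x <- seq(0, 1450, by = 2.5)
  sp <- locate_walls(wall_profile(x), 20)
  sp$pair$brightfield <- sp$pair$brightfield * 0.8 # inside mean 160
  out <- normalize_brightfield(sp, standard = 200)
  expect_equal(mean(out$pair$brightfield[out$inside]), 200)
  # already on standard: unchanged
  again <- normalize_brightfield(out, standard = 200)
  expect_equal(again$pair$brightfield, out$pair$brightfield)
})

test_that("fluorescent normalization equalizes inside areas and keeps shape", {
  ms <- sim_single(additive_sd = 4, seed = 9)
  wt <- ms$metadata$geometry$wall_thickness
  sps <- lapply(ms$profiles, function(p) locate_walls(crop_profile(p), wt))
  pre <- lapply(sps, function(sp) sp$pair$fluorescent[sp$inside])
  post <- normalize_fluorescent_set(sps, standard = 200)
  ints <- vapply(post, function(sp) {
    pracma::trapz(sp$pair$x[sp$inside], sp$pair$fluorescent[sp$inside])
  }, numeric(1))
  expect_equal(max(abs(ints / max(ints) - 1)), 0, tolerance = 1e-9)
  # scaling is linear, so the inside shape is untouched
  for (i in seq_along(post)) {
    expect_equal(cor(pre[[i]], post[[i]]$pair$fluorescent[post[[i]]$inside]), 1)
  }
  # a single-profile set only gets the baseline step
  single <- normalize_fluorescent_set(sps[1], standard = 200)
  base <- mean(single[[1]]$pair$fluorescent[c(single[[1]]$outside_left,
                                              single[[1]]$outside_right)])
  expect_equal(base, 200)
})

test_that("zeroing and centering put the baseline at 0 and the peak at x = 0", {
  ms <- sim_single(additive_sd = 2, seed = 5)
  wt <- ms$metadata$geometry$wall_thickness
  sps <- normalize_fluorescent_set(
    lapply(ms$profiles, function(p) locate_walls(crop_profile(p), wt)), 200)
  sp0 <- sps[[1]]
  out <- zero_and_center(sp0)
  outside <- c(out$outside_left, out$outside_right)
  expect_equal(mean(out$pair$fluorescent[outside]), 0, tolerance = 1e-9)
  pk <- out$inside[which.max(out$pair$fluorescent[out$inside])]
  expect_equal(out$pair$x[pk], 0)
  # walls ride along rigidly
  shift <- sp0$pair$x[pk] - out$pair$x[pk]
  expect_equal(out$wall_centers, sp0$wall_centers - shift)

  # a flat fluorescent trace has no signal to center on
  flat <- sp0
  flat$pair$fluorescent <- rep(200, length(flat$pair$x))
  expect_error(zero_and_center(flat), "no fluorescent signal")
})

test_that("wall centers are recovered within one sample spacing", {
  ms <- sim_single(additive_sd = 8, seed = 3)
  gt <- attr(ms, "ground_truth")
  spacing <- diff(ms$profiles[[1]]$x[1:2])
  width <- ms$metadata$geometry$channel_width
  wt <- ms$metadata$geometry$wall_thickness
  for (p in ms$profiles) {
    sp <- locate_walls(crop_profile(p), wt)
    expect_lt(abs(sp$wall_centers[1] - gt$wall_x[1]), spacing + 1e-9)
    expect_lt(abs(sp$wall_centers[2] - gt$wall_x[2]), spacing + 1e-9)
  }
  # the wall separation survives the full preprocessing chain
  sps <- preprocess_profiles(ms)
  for (sp in sps) {
    expect_equal(diff(sp$wall_centers), width, tolerance = 2 * spacing / width)
  }
})
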