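unit_bounds <- function(order) matrix(rep(c(1e-3, 100), each = order), ncol = 2)

test_that("mixture evaluation follows the e-folding width convention", {
  one <- data.frame(amplitude = 100, center = 0, sigma = 10)
  expect_equal(mixture_value(one, 0), 100)
  expect_equal(mixture_value(one, 10), 100 / exp(1)) # 36.788: no factor 2
  two <- rbind(one, one)
  xs <- seq(-30, 30, by = 5)
  expect_equal(mixture_value(two, xs), 2 * mixture_value(one, xs))
})

test_that("goodness-of-fit metrics match their definitions", {
  obs <- c(2, 0, 2, 0)
  fit <- rep(1, 4) # residuals (1, -1, 1, -1)
  g <- gof_metrics(obs, fit, p = 1)
  expect_equal(g$sse, 4)
  expect_equal(g$dfe, 3)
  expect_equal(g$rmse, 1.1547005, tolerance = 1e-7)

  perfect <- gof_metrics(obs, obs, p = 1)
  expect_equal(perfect$sse, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  # a useless extra parameter lowers adj_r2, leaves r2 unchanged
  g2 <- gof_metrics(obs, fit, p = 2)
  expect_equal(g2$r2, g$r2)
  expect_lt(g2$adj_r2, g$adj_r2)
  expect_error(gof_metrics(rep(1, 4), fit, 1), "constant")
})

test_that("a noiseless single Gaussian is recovered to 1e-6", {
  x <- seq(-150, 150, by = 1)
  truth <- data.frame(amplitude = 100, center = 0, sigma = 10)
  y <- mixture_value(truth, x)
  f <- fit_mixture(x, y, 1, unit_bounds(1), seed = 7)
  expect_equal(f$components$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$components$center, 0, tolerance = 1e-6)
  expect_equal(f$components$sigma, 10, tolerance = 1e-6)
  expect_lt(f$gof$rmse, 1e-6)
})

test_that("two well-separated components are both recovered within 1%", {
  x <- seq(-150, 150, by = 1)
  truth <- data.frame(amplitude = c(40, 80), center = c(0, 0),
                      sigma = c(20, 8)) # sigma-descending order
  y <- mixture_value(truth, x)
  f <- fit_mixture(x, y, 2, unit_bounds(2), seed = 11)
  expect_equal(f$components$sigma, truth$sigma, tolerance = 0.01)
  expect_equal(f$components$amplitude, truth$amplitude, tolerance = 0.01)
  # bound contract
  expect_true(all(f$components$sigma > 0 & f$components$sigma <= 100))
  expect_true(all(abs(f$components$center) <= 5))
  # nested models: adding a component can only lower the attainable SSE
  f1 <- fit_mixture(x, y, 1, unit_bounds(1), seed = 11)
  expect_lte(f$gof$sse, f1$gof$sse + 1e-9)
})

test_that("fits are reproducible for a fixed seed", {
  x <- seq(-130, 130, by = 2)
  y <- mixture_value(data.frame(amplitude = 90, center = 1, sigma = 14), x) +
    sin(x / 7) # deterministic perturbation
  f1 <- fit_mixture(x, y, 2, unit_bounds(2), seed = 3)
  f2 <- fit_mixture(x, y, 2, unit_bounds(2), seed = 3)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$n_restarts, f2$n_restarts)
})

test_that("order-1 fits agree with an exhaustive grid-search oracle", {
  x <- seq(-150, 150, by = 10) # 31 points
  a_grid <- seq(80, 120, by = 2)
  b_grid <- seq(-5, 5, by = 0.5)
  c_grid <- seq(8, 16, by = 0.5)

  cases <- list(list(a = 100, b = 1, c = 12, noise = 0),
                list(a = 96, b = -2.5, c = 10.5, noise = 3))
  for (cs in cases) {
    y <- mixture_value(data.frame(amplitude = cs$a, center = cs$b,
                                  sigma = cs$c), x)
    if (cs$noise > 0) {
      set.seed(99)
      y <- y + rnorm(length(x), 0, cs$noise)
    }
    oracle <- grid_search_gauss(x, y, a_grid, b_grid, c_grid)
    f <- fit_mixture(x, y, 1, unit_bounds(1), seed = 21)
    expect_lte(abs(f$components$amplitude - oracle$a), 2 + 1e-9)
    expect_lte(abs(f$components$center - oracle$b), 0.5 + 1e-9)
    expect_lte(abs(f$components$sigma - oracle$c), 0.5 + 1e-9)
    expect_lte(f$gof$sse, oracle$sse + 1e-9)
  }
})

test_that("sequential sigma bounds widen by the admissible slopes", {
  slopes <- slope_bounds(1e-9, 2e-6, cond_water25)
  prev <- structure(list(order = 1,
                         components = data.frame(amplitude = 100, center = 0,
                                                 sigma = 10)),
                    class = "mixture_fit")
  b <- sequential_sigma_bounds(prev, dt = 0.1, slopes)
  expect_equal(unname(b[1, "low"]), 10.00245, tolerance = 1e-5)
  expect_equal(unname(b[1, "high"]), 14.0766, tolerance = 1e-4)
  # widths can never shrink
  expect_gte(b[1, "low"], 10)

  collapsed <- sequential_sigma_bounds(prev, dt = 0, slopes)
  expect_equal(unname(collapsed[1, "low"]), unname(collapsed[1, "high"]))

  first <- sequential_sigma_bounds(NULL, 0, slopes, order = 3)
  expect_equal(dim(first), c(3, 2))
  expect_equal(unname(first[, "high"]), rep(100, 3))

  at_cap <- prev
  at_cap$components$sigma <- 100
  expect_error(sequential_sigma_bounds(at_cap, 0.1, slopes), "infeasible")
})

test_that("the order scan flags the true number of components", {
  ms <- simulate_profiles(species_mix(c(1.5, 3)), noise = noise_model(seed = 2))
  sc <- gof_order_scan(ms, diffsize_control(seed = 4), max_order = 3)
  expect_equal(nrow(sc), 3 * 11)
  m <- aggregate(rmse ~ order, sc, mean)
  expect_gt(m$rmse[1] / m$rmse[2], 10) # order 1 -> 2: large gain
  expect_lt(abs(m$rmse[2] - m$rmse[3]), 0.1 * m$rmse[1]) # 2 -> 3: negligible
  # a pure single-species set is already captured at order 1
  ms1 <- sim_single()
  sc1 <- gof_order_scan(ms1, diffsize_control(seed = 4), max_order = 1)
  expect_true(all(sc1$r2 > 0.999))
})
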