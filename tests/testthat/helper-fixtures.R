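# Shared fixtures: the reference medium (water at 25 C) and small simulated
# measurement sets built in code.

cond_water25 <- conditions(298.15, 8.9e-4)

study <- default_study()

sim_single <- function(r_nm = 2, additive_sd = 0, seed = 1, ...) {
  simulate_profiles(species_mix(r_nm),
                    noise = noise_model(additive_sd = additive_sd, seed = seed),
                    ...)
}

# one noiseless profile pair pulled through crop for preprocessing tests
sim_pair <- function(r_nm = 2, point = 1, additive_sd = 0, seed = 1) {
  sim_single(r_nm, additive_sd = additive_sd, seed = seed)$profiles[[point]]
}

# brute-force SSE grid search for an order-1 mixture: the independent oracle
# for the bounded multistart fitter
grid_search_gauss <- function(x, y, a_grid, b_grid, c_grid) {
  best <- list(sse = Inf)
  for (b in b_grid) {
    for (cc in c_grid) {
      e <- exp(-((x - b) / cc)^2)
      see <- sum(e^2)
      sye <- sum(y * e)
      syy <- sum(y^2)
      sse <- syy - 2 * a_grid * sye + a_grid^2 * see
      i <- which.min(sse)
      if (sse[i] < best$sse) {
        best <- list(a = a_grid[i], b = b, c = cc, sse = sse[i])
      }
    }
  }
  best
}
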