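# shared fixtures built in code

baseline_params <- function() hgo_parameters(c = 35, k1 = 20, k2 = 0.8, alpha = 30)
baseline_geom <- function() unloaded_geometry(D_i = 1.0, D_o = 1.2, L = 3.0)

# a clean triangular 3-cycle pressure wave trace (inflation kind)
triangle_trace <- function(n_per_limb = 20, n_cycles = 3, lambda_z = 1.5,
                           noise_sd = 0) {
  up <- seq(0, 20, length.out = n_per_limb)
  down <- rev(up)[-c(1, n_per_limb)]
  P <- rep(c(up, down), n_cycles)
  m <- length(P)
  d_o <- 1.2 + 0.01 * P + if (noise_sd > 0) rnorm(m, 0, noise_sd) else 0
  protocol_trace(data.frame(t = seq_len(m) - 1, P = P, d_o = d_o,
                            lambda_z = rep(lambda_z, m),
                            f = rep(2, m)),
                 kind = "inflation", fixed_value = lambda_z,
                 protocol_id = "tri")
}

# quick small simulated sample (fewer points per limb than the default
# schedule, for unit-test speed); cached per parameter signature
local_sim_cache <- new.env(parent = emptyenv())
quick_sample <- function(params = baseline_params(), geom = baseline_geom(),
                         noise = noise_model(0, 0), seed = 7,
                         n_per_limb = 15) {
  key <- paste(params$c, params$k1, params$k2, params$alpha,
               geom$D_i, geom$D_o, geom$L, noise$sd_d_o, noise$sd_f,
               seed, n_per_limb, sep = "_")
  if (is.null(local_sim_cache[[key]])) {
    local_sim_cache[[key]] <- simulate_sample(
      params, geom, noise = noise, seed = seed,
      schedule_args = list(n_per_limb = n_per_limb))
  }
  local_sim_cache[[key]]
}

expect_rel_equal <- function(object, expected, tol = 1e-8) {
  expect_true(all(abs(object - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("max rel diff %.3g vs tol %.3g",
                              max(abs(object - expected) /
                                    pmax(abs(expected), .Machine$double.eps)),
                              tol))
}
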