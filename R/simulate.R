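#' Solve the inflation-extension equilibrium of the model vessel
#'
#' Forward problem of the biaxial test: given constitutive parameters,
#' unloaded geometry, a fixed axial stretch and a luminal pressure, find the
#' loaded outer diameter at which the model-predicted circumferential stress
#' balances the Laplace stress `P d_i / (d_o - d_i)`, with the inner
#' diameter closed by incompressibility. The axial force then follows from
#' the axial equilibrium:
#' `f = sigma_z pi (d_o^2 - d_i^2) / 4 - P pi d_i^2 / 4`.
#'
#' @param params an [hgo_parameters()].
#' @param geom an [unloaded_geometry()].
#' @param lambda_z axial stretch (scalar).
#' @param P luminal pressure, kPa (scalar).
#' @param stretch_range bracket for the circumferential stretch of the outer
#'   wall, as multiples of the unloaded outer diameter (default `c(0.5, 3)`).
#' @param tol root tolerance on the outer diameter, mm (default 1e-10).
#' @param tension_only passed to the model evaluations.
#' @return list with `state` (one-row `biaxial_state`) and `f` (mN).
#' @export
solve_equilibrium <- function(params, geom, lambda_z, P,
                              stretch_range = c(0.5, 3), tol = 1e-10,
                              tension_only = TRUE) {
  stopifnot(P >= 0, lambda_z > 0)
  wall <- geom$D_o^2 - geom$D_i^2
  do_min <- max(geom$D_o * stretch_range[1],
                sqrt(wall / lambda_z) * (1 + 1e-9))
  do_max <- geom$D_o * stretch_range[2]
  alpha_rad <- params$alpha * pi / 180
  resid <- function(d_o) {
    d_i <- sqrt(d_o^2 - wall / lambda_z)
    lambda_t <- 0.5 * (d_i / geom$D_i + d_o / geom$D_o)
    pred <- .stress_kernel(params$c, params$k1, params$k2, alpha_rad,
                           lambda_t, lambda_z, tension_only = tension_only)
    lap <- if (d_i > 0) P * d_i / (d_o - d_i) else 0
    pred$sigma_t - lap
  }
  f_lo <- resid(do_min)
  f_hi <- resid(do_max)
  if (f_lo * f_hi > 0) {
    # at large axial stretch the zero-pressure diameter can sit below the
    # nominal bracket; fall back to the incompressibility feasibility limit
    do_feas <- sqrt(wall / lambda_z) * (1 + 1e-9)
    if (do_feas < do_min) {
      do_min <- do_feas
      f_lo <- resid(do_min)
    }
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf("no equilibrium bracket for d_o in [%.4g, %.4g] mm (lambda_z = %.4g, P = %.4g kPa)",
                 do_min, do_max, lambda_z, P), call. = FALSE)
  }
  root <- stats::uniroot(resid, c(do_min, do_max), f.lower = f_lo,
                         f.upper = f_hi, tol = tol)$root
  st <- compute_state(geom, d_o = root, lambda_z = lambda_z)
  pred <- hgo_stress(params, st$lambda_t, st$lambda_z,
                     tension_only = tension_only)
  f <- pred$sigma_z * pi * (st$d_o^2 - st$d_i^2) / 4 - P * pi * st$d_i^2 / 4
  list(state = st, f = f)
}

#' Model-implied in vivo axial stretch
#'
#' The axial stretch at which the axial force is invariant to inflation:
#' root of `f(lambda_z, P_hi) - f(lambda_z, P_lo)` over `lambda_z`. This is
#' the quantity the bench protocol locates empirically ("almost no change in
#' force" during inflation) and is fully determined by the constitutive
#' parameters and geometry.
#'
#' @inheritParams solve_equilibrium
#' @param P_range pressures (kPa) whose force difference defines the slope
#'   (default 0 and 150 mmHg converted to kPa).
#' @param interval search interval for `lambda_z`.
#' @return in vivo axial stretch (dimensionless).
#' @export
in_vivo_stretch_model <- function(params, geom,
                                  P_range = mmhg_to_kpa(c(0, 150)),
                                  interval = c(1.02, 2.2),
                                  tension_only = TRUE) {
  df <- function(lz) {
    tryCatch(
      solve_equilibrium(params, geom, lz, P_range[2],
                        tension_only = tension_only)$f -
        solve_equilibrium(params, geom, lz, P_range[1],
                          tension_only = tension_only)$f,
      error = function(e) NA_real_)   # no equilibrium at this stretch
  }
  # coarse scan first: parts of the interval can be unphysical for stiff
  # fiber parameters (no zero-stress configuration at high axial stretch)
  grid <- seq(interval[1], interval[2], length.out = 13)
  vals <- vapply(grid, df, numeric(1))
  ok <- which(is.finite(vals))
  if (!length(ok)) {
    stop("no evaluable axial stretch in [", interval[1], ", ", interval[2],
         "]; cannot locate the force-invariance stretch", call. = FALSE)
  }
  cross <- ok[which(vals[ok[-length(ok)]] * vals[ok[-1]] <= 0)]
  if (length(cross)) {
    i <- cross[1]
    j <- ok[which(ok == i) + 1]
    root <- tryCatch(
      stats::uniroot(df, c(grid[i], grid[j]), f.lower = vals[i],
                     f.upper = vals[j], tol = 1e-8)$root,
      error = function(e) NA_real_)
    if (is.finite(root)) return(root)
  }
  grid[ok[which.min(abs(vals[ok]))]]
}

#' The six-protocol schedule of a biaxial test session
#'
#' Three inflation protocols (0-150 mmHg pressure ramps) at axial stretches
#' `lambda_iv - delta`, `lambda_iv`, `lambda_iv + delta`, and three axial
#' protocols sweeping `[lambda_iv - delta, lambda_iv + delta]` at fixed
#' pressures 50, 100 and 150 mmHg. Each protocol is rendered as
#' `n_cycles` triangular loading/unloading cycles with `n_per_limb` samples
#' per limb.
#'
#' @param lambda_iv in vivo axial stretch the schedule is centered on.
#' @param delta stretch offset for the off-center protocols (default 0.15,
#'   within the bench practice of 0.1-0.2).
#' @param P_max_mmHg top inflation pressure, mmHg (default 150).
#' @param axial_pressures_mmHg fixed pressures of the axial protocols, mmHg.
#' @param n_per_limb samples per monotone limb (default 50).
#' @param n_cycles cycles per protocol (default 3).
#' @return list of six protocol specs: `kind`, `fixed_value` (kPa or
#'   stretch), `driven` (vector of driven-variable values for one cycle's
#'   loading limb), `protocol_id`.
#' @export
generate_protocol_schedule <- function(lambda_iv, delta = 0.15,
                                       P_max_mmHg = 150,
                                       axial_pressures_mmHg = c(50, 100, 150),
                                       n_per_limb = 50, n_cycles = 3) {
  if (delta >= lambda_iv - 0.5) {
    stop("invalid schedule: delta = ", delta,
         " too large for lambda_iv = ", lambda_iv, call. = FALSE)
  }
  P_grid <- mmhg_to_kpa(seq(0, P_max_mmHg, length.out = n_per_limb))
  lz_grid <- seq(lambda_iv - delta, lambda_iv + delta,
                 length.out = n_per_limb)
  c(
    lapply(seq_along(c(-delta, 0, delta)), function(i) {
      list(kind = "inflation",
           fixed_value = lambda_iv + c(-delta, 0, delta)[i],
           driven = P_grid, n_cycles = n_cycles,
           protocol_id = paste0("inflation_", i))
    }),
    lapply(seq_along(axial_pressures_mmHg), function(i) {
      list(kind = "axial",
           fixed_value = mmhg_to_kpa(axial_pressures_mmHg[i]),
           driven = lz_grid, n_cycles = n_cycles,
           protocol_id = paste0("axial_", i))
    })
  )
}

#' Measurement-noise model of the myograph
#'
#' Independent Gaussian noise on the tracked outer diameter and the force
#' transducer; the driven variables (pressure, axial stretch) are treated as
#' exact. Defaults are instrument-level: 5 um on diameter, 0.05 mN on force.
#'
#' @param sd_d_o diameter noise SD, mm.
#' @param sd_f force noise SD, mN.
#' @export
noise_model <- function(sd_d_o = 0.005, sd_f = 0.05) {
  stopifnot(sd_d_o >= 0, sd_f >= 0)
  structure(list(sd_d_o = sd_d_o, sd_f = sd_f), class = "noise_model")
}

# render one protocol spec into a full cyclic trace of equilibrium solutions
.render_protocol <- function(spec, params, geom, noise, sample_id,
                             tension_only = TRUE) {
  n <- length(spec$driven)
  sol <- vector("list", n)
  for (j in seq_len(n)) {
    lz <- if (spec$kind == "inflation") spec$fixed_value else spec$driven[j]
    P <- if (spec$kind == "inflation") spec$driven[j] else spec$fixed_value
    sol[[j]] <- tryCatch(
      solve_equilibrium(params, geom, lz, P, tension_only = tension_only),
      error = function(e) {
        stop("equilibrium failure in ", spec$protocol_id, " at point ", j,
             " (P = ", format(P), " kPa, lambda_z = ", format(lz), "): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  d_o <- vapply(sol, function(s) s$state$d_o, numeric(1))
  f <- vapply(sol, function(s) s$f, numeric(1))
  lz <- if (spec$kind == "inflation") rep(spec$fixed_value, n) else spec$driven
  P <- if (spec$kind == "inflation") spec$driven else rep(spec$fixed_value, n)
  # triangular cycles: loading limb then unloading limb; the unloading limb
  # stops one point short of the minimum so consecutive cycles chain into
  # strictly monotone limbs without duplicated records
  up <- seq_len(n)
  down <- if (n > 2) seq(n - 1L, 2L) else integer(0)
  idx <- rep(c(up, down), spec$n_cycles)
  m <- length(idx)
  data <- data.frame(t = seq(0, by = 1, length.out = m),
                     P = P[idx], d_o = d_o[idx], lambda_z = lz[idx],
                     f = f[idx])
  if (noise$sd_d_o > 0) data$d_o <- data$d_o + stats::rnorm(m, 0, noise$sd_d_o)
  if (noise$sd_f > 0) data$f <- data$f + stats::rnorm(m, 0, noise$sd_f)
  protocol_trace(data, kind = spec$kind, fixed_value = spec$fixed_value,
                 sample_id = sample_id, protocol_id = spec$protocol_id)
}

#' Simulate one sample's full biaxial test session
#'
#' Solves the model equilibrium at every scheduled protocol point, renders
#' the triangular cycles (limbs identical before noise), and adds seeded
#' Gaussian measurement noise. When `lambda_iv` is not supplied it is the
#' model-implied force-invariance stretch ([in_vivo_stretch_model()]), so
#' that the simulated bench protocol is self-consistent: re-estimating the
#' in vivo stretch from the noiseless traces recovers it.
#'
#' @inheritParams solve_equilibrium
#' @param meta a [sample_meta()] (optional).
#' @param lambda_iv in vivo axial stretch to center the schedule on;
#'   `NULL` (default) uses the model-implied value.
#' @param noise a [noise_model()].
#' @param seed RNG seed for the noise draws.
#' @param schedule_args extra arguments for [generate_protocol_schedule()].
#' @return an object of class `simulated_sample`: list with `traces` (six
#'   [protocol_trace()]s), `params`, `geom`, `lambda_iv`, `meta`, `noise`,
#'   `seed`.
#' @export
simulate_sample <- function(params, geom, meta = NULL, lambda_iv = NULL,
                            noise = noise_model(), seed = 1L,
                            tension_only = TRUE, schedule_args = list()) {
  if (is.null(lambda_iv)) {
    lambda_iv <- in_vivo_stretch_model(params, geom,
                                       tension_only = tension_only)
  }
  schedule <- do.call(generate_protocol_schedule,
                      c(list(lambda_iv = lambda_iv), schedule_args))
  sample_id <- if (is.null(meta)) NA_character_ else meta$sample_id
  traces <- withr::with_seed(as.integer(seed), {
    lapply(schedule, .render_protocol, params = params, geom = geom,
           noise = noise, sample_id = sample_id,
           tension_only = tension_only)
  })
  structure(list(traces = traces, params = params, geom = geom,
                 lambda_iv = lambda_iv, meta = meta, noise = noise,
                 seed = as.integer(seed)),
            class = "simulated_sample")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat(sprintf("Simulated sample%s: %d protocols, lambda_iv = %.4f\n",
              if (!is.null(x$meta)) paste0(" ", x$meta$sample_id) else "",
              length(x$traces), x$lambda_iv))
  invisible(x)
}
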