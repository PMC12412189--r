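#' Group mean blood pressures
#'
#' Packaged means of the awake mean blood pressure by genotype and age used
#' to define each sample's physiologic evaluation pressure.
#'
#' @return data.frame with columns `genotype`, `age`, `mbp_mmHg`.
#' @export
default_pressure_table <- function() {
  data.frame(genotype = rep(c("WT", "MU"), each = 4),
             age = rep(1:4, 2),
             mbp_mmHg = c(99, 106, 104, 106,   # WT, ages 1-4
                          96, 109, 105, 104))  # MU, ages 1-4
}

#' Look up a sample's physiologic evaluation pressure
#'
#' @param genotype,age the sample's group, or pass a [sample_meta()] as
#'   `genotype`.
#' @param table pressure table (default [default_pressure_table()]).
#' @return pressure in kPa.
#' @export
lookup_pressure <- function(genotype, age = NULL,
                            table = default_pressure_table()) {
  if (inherits(genotype, "sample_meta")) {
    age <- genotype$age
    genotype <- genotype$genotype
  }
  hit <- table$genotype == genotype & table$age == age
  if (sum(hit) != 1) {
    stop("no pressure-table entry for (", genotype, ", ", age, " mo)",
         call. = FALSE)
  }
  mmhg_to_kpa(table$mbp_mmHg[hit])
}

#' Physiologic biaxial state of a sample
#'
#' The state at the sample's operating point: the in vivo axial stretch and
#' the group's mean blood pressure. The inner diameter is linearly
#' interpolated from the pressure-diameter data of the chosen loading limb
#' of the inflation protocol at the in vivo stretch; circumferential and
#' radial stretches follow from the unloaded geometry and incompressibility.
#'
#' @param traces the sample's list of [protocol_trace()]s.
#' @param geom the sample's [unloaded_geometry()].
#' @param lambda_iv in vivo axial stretch.
#' @param P_eval evaluation pressure, kPa.
#' @param cycle_index loading cycle to use (default 3).
#' @param stretch_tol warn when the nearest inflation protocol's fixed
#'   stretch is farther than this from `lambda_iv` (default 0.01).
#' @return list with `state` (one-row `biaxial_state`) and `f_interp`
#'   (axial force interpolated at `P_eval`, mN).
#' @export
physiologic_state <- function(traces, geom, lambda_iv, P_eval,
                              cycle_index = 3, stretch_tol = 0.01) {
  infl <- Filter(function(tr) tr$kind == "inflation", traces)
  if (!length(infl)) stop("no inflation protocol available", call. = FALSE)
  gap <- vapply(infl, function(tr) abs(tr$fixed_value - lambda_iv), numeric(1))
  pick <- which.min(gap)
  if (gap[pick] > stretch_tol) {
    warning(sprintf("nearest inflation protocol is at lambda_z = %.4f, %.4f away from lambda_iv",
                    infl[[pick]]$fixed_value, gap[pick]), call. = FALSE)
  }
  limb <- select_loading_cycle(infl[[pick]], cycle_index = cycle_index)
  df <- trace_states(limb, geom)
  d_i <- interpolate_at_pressure(df, P_eval)
  f_interp <- stats::approx(df$P, df$f, xout = P_eval, ties = "ordered")$y
  state <- compute_state(geom, d_i = d_i, lambda_z = lambda_iv)
  list(state = state, f_interp = f_interp)
}

#' Evaluate all physiologic biomechanical metrics at a state
#'
#' Strain energy, model-predicted wall stresses (totals and their
#' isotropic/anisotropic splits) and incremental moduli from the fitted
#' constitutive model at the physiologic state, with the deformed inner
#' diameter carried through.
#'
#' @param state one-row `biaxial_state` (from [physiologic_state()]).
#' @param params fitted [hgo_parameters()].
#' @param P_eval evaluation pressure, kPa (recorded in the output).
#' @param tension_only passed to the model evaluations.
#' @return one-row data.frame of metrics (all energies/stresses/moduli in
#'   kPa).
#' @export
evaluate_metrics <- function(state, params, P_eval = NA_real_,
                             tension_only = TRUE) {
  en <- hgo_energy(params, state$lambda_t, state$lambda_z,
                   tension_only = tension_only)
  sx <- hgo_stress(params, state$lambda_t, state$lambda_z,
                   tension_only = tension_only)
  mo <- hgo_moduli(params, state$lambda_t, state$lambda_z,
                   tension_only = tension_only)
  cbind(data.frame(d_i = state$d_i, lambda_t = state$lambda_t,
                   lambda_z = state$lambda_z, P_eval = P_eval),
        en, sx, mo)
}

#' Physiologic metrics for one sample
#'
#' Convenience chain: pressure lookup, physiologic state from the
#' pressure-diameter data, model-predicted metrics from the fitted
#' parameters, plus the experimental (Laplace) stresses at the interpolated
#' state as comparison columns.
#'
#' @param traces the sample's [protocol_trace()]s.
#' @param geom the sample's [unloaded_geometry()].
#' @param params fitted [hgo_parameters()].
#' @param meta [sample_meta()] (for the pressure lookup and output columns).
#' @param lambda_iv in vivo axial stretch; defaults to
#'   [estimate_in_vivo_stretch()] on the inflation protocols.
#' @param pressure_table group pressures (default packaged table).
#' @param cycle_index loading cycle used (default 3).
#' @return one-row data.frame: metadata, metrics, and
#'   `sigma_t_exp`/`sigma_z_exp` comparison columns.
#' @export
sample_metrics <- function(traces, geom, params, meta, lambda_iv = NULL,
                           pressure_table = default_pressure_table(),
                           cycle_index = 3) {
  if (is.null(lambda_iv)) {
    limbs <- lapply(Filter(function(tr) tr$kind == "inflation", traces),
                    select_loading_cycle, cycle_index = cycle_index)
    lambda_iv <- estimate_in_vivo_stretch(limbs)
  }
  P_eval <- lookup_pressure(meta, table = pressure_table)
  ps <- physiologic_state(traces, geom, lambda_iv, P_eval,
                          cycle_index = cycle_index)
  metrics <- evaluate_metrics(ps$state, params, P_eval = P_eval)
  exp_sx <- experimental_stress(P_eval, ps$f_interp, ps$state$d_i,
                                ps$state$d_o)
  cbind(data.frame(sample_id = meta$sample_id, animal_id = meta$animal_id,
                   genotype = meta$genotype, vessel = meta$vessel,
                   age = meta$age, sex = meta$sex, lambda_iv = lambda_iv),
        metrics,
        data.frame(sigma_t_exp = exp_sx$sigma_t, sigma_z_exp = exp_sx$sigma_z))
}
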