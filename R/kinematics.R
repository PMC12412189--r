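#' Mid-wall biaxial state from loaded/unloaded geometry
#'
#' The vessel is treated as an incompressible thick-walled cylinder deforming
#' without shear. Given the measured loaded outer diameter and axial stretch,
#' wall-volume conservation closes the kinematics:
#' \deqn{d_i^2 = d_o^2 - (D_o^2 - D_i^2) / \lambda_z}
#' \deqn{\lambda_\theta = \tfrac12 (d_i/D_i + d_o/D_o), \quad
#'       \lambda_r = 1/(\lambda_\theta \lambda_z)}
#' so that \eqn{\lambda_\theta \lambda_z \lambda_r = 1} holds by construction.
#'
#' @param geom an [unloaded_geometry()].
#' @param d_o loaded outer diameter(s), mm. Alternatively supply `d_i` to use
#'   a directly tracked inner diameter.
#' @param lambda_z axial stretch(es) `l / L`; recycled against `d_o`.
#' @param d_i loaded inner diameter(s), mm; exactly one of `d_o`, `d_i` must
#'   be given and the other is derived from incompressibility.
#' @return a data.frame (class `biaxial_state`) with columns `lambda_t`,
#'   `lambda_z`, `lambda_r`, `d_i`, `d_o`.
#' @export
compute_state <- function(geom, d_o = NULL, lambda_z, d_i = NULL) {
  stopifnot(inherits(geom, "unloaded_geometry"))
  if (is.null(d_o) == is.null(d_i)) {
    stop("supply exactly one of d_o, d_i", call. = FALSE)
  }
  if (any(lambda_z <= 0)) stop("lambda_z must be positive", call. = FALSE)
  wall <- geom$D_o^2 - geom$D_i^2
  if (is.null(d_i)) {
    if (any(d_o <= 0)) stop("d_o must be positive", call. = FALSE)
    di2 <- d_o^2 - wall / lambda_z
    if (any(di2 < 0)) {
      stop("infeasible geometry: d_i^2 = ", format(min(di2)),
           " < 0 (wall volume exceeds what the measured d_o allows)",
           call. = FALSE)
    }
    d_i <- sqrt(di2)
  } else {
    if (any(d_i <= 0)) stop("d_i must be positive", call. = FALSE)
    d_o <- sqrt(d_i^2 + wall / lambda_z)
  }
  lambda_t <- 0.5 * (d_i / geom$D_i + d_o / geom$D_o)
  out <- data.frame(lambda_t = lambda_t, lambda_z = lambda_z,
                    lambda_r = 1 / (lambda_t * lambda_z),
                    d_i = d_i, d_o = d_o)
  class(out) <- c("biaxial_state", "data.frame")
  out
}

#' Average experimental Cauchy stresses
#'
#' Laplace-type mean wall stresses of a pressurized, axially loaded cylinder:
#' \deqn{\sigma_\theta = P d_i / (d_o - d_i)}
#' \deqn{\sigma_z = (4 f + P \pi d_i^2) / (\pi (d_o^2 - d_i^2))}
#'
#' @param P luminal pressure, kPa.
#' @param f axial force, mN.
#' @param d_i,d_o loaded inner/outer diameter, mm.
#' @return data.frame with columns `sigma_t`, `sigma_z` (kPa). All arguments
#'   are vectorized and recycled.
#' @export
experimental_stress <- function(P, f, d_i, d_o) {
  if (any(d_o <= d_i)) {
    stop("require d_i < d_o for wall stress computation", call. = FALSE)
  }
  if (any(d_i <= 0)) stop("d_i must be positive", call. = FALSE)
  data.frame(sigma_t = P * d_i / (d_o - d_i),
             sigma_z = (4 * f + P * pi * d_i^2) / (pi * (d_o^2 - d_i^2)))
}

#' Kinematics and experimental stresses along a trace
#'
#' @param trace a [protocol_trace()].
#' @param geom the sample's [unloaded_geometry()].
#' @return data.frame: the trace's records joined with the computed
#'   `biaxial_state` columns and experimental `sigma_t`, `sigma_z`.
#' @export
trace_states <- function(trace, geom) {
  stopifnot(inherits(trace, "protocol_trace"))
  st <- compute_state(geom, d_o = trace$data$d_o, lambda_z = trace$data$lambda_z)
  sx <- experimental_stress(trace$data$P, trace$data$f, st$d_i, st$d_o)
  cbind(trace$data, st[c("lambda_t", "lambda_r", "d_i")], sx)
}

#' Estimate the in vivo axial stretch from force-pressure invariance
#'
#' The in vivo axial stretch is the stretch at which axial force barely
#' changes during inflation. For each tested stretch the slope of force
#' versus pressure is estimated by least squares over the inflation range;
#' the zero crossing of slope versus stretch is located by linear
#' interpolation between the bracketing stretches (or, lacking a sign
#' change, the stretch with the smallest absolute slope is returned).
#'
#' @param traces list of inflation [protocol_trace()]s at two or more
#'   distinct fixed axial stretches (whole traces or selected limbs).
#' @return estimated in vivo axial stretch (dimensionless).
#' @export
estimate_in_vivo_stretch <- function(traces) {
  infl <- Filter(function(tr) inherits(tr, "protocol_trace") &&
                   tr$kind == "inflation", traces)
  if (length(infl) < 2) {
    stop("need inflation protocols at >= 2 distinct axial stretches, got ",
         length(infl), call. = FALSE)
  }
  lz <- vapply(infl, function(tr) tr$fixed_value, numeric(1))
  if (length(unique(round(lz, 10))) < 2) {
    stop("inflation protocols share a single axial stretch; cannot bracket",
         call. = FALSE)
  }
  slope <- vapply(infl, function(tr) {
    unname(stats::coef(stats::lm(f ~ P, data = tr$data))[2])
  }, numeric(1))
  o <- order(lz)
  lz <- lz[o]; slope <- slope[o]
  exact <- which(slope == 0)
  if (length(exact)) return(lz[exact[1]])
  cross <- which(slope[-1] * slope[-length(slope)] < 0)
  if (length(cross)) {
    i <- cross[1]
    return(lz[i] + (0 - slope[i]) * (lz[i + 1] - lz[i]) /
             (slope[i + 1] - slope[i]))
  }
  lz[which.min(abs(slope))]
}

#' Interpolate inner diameter at a target pressure
#'
#' Linear interpolation of inner diameter versus pressure along a loading
#' limb; no extrapolation outside the limb's pressure range.
#'
#' @param limb a [protocol_trace()] limb (inflation protocol) or a
#'   data.frame with columns `P` and `d_i`.
#' @param P_target target pressure, kPa.
#' @param geom [unloaded_geometry()], needed when `limb` is a trace (to form
#'   `d_i` from the recorded outer diameter).
#' @return inner diameter (mm) at `P_target`.
#' @export
interpolate_at_pressure <- function(limb, P_target, geom = NULL) {
  if (inherits(limb, "protocol_trace")) {
    if (is.null(geom)) stop("supply geom to derive d_i from the trace", call. = FALSE)
    df <- trace_states(limb, geom)
  } else {
    df <- limb
  }
  stopifnot(all(c("P", "d_i") %in% names(df)))
  rng <- range(df$P)
  if (P_target < rng[1] || P_target > rng[2]) {
    stop(sprintf("P_target = %.4g kPa outside limb range [%.4g, %.4g]; refusing to extrapolate",
                 P_target, rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(df$P, df$d_i, xout = P_target, ties = "ordered")$y
}
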