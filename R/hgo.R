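#' Strain invariants of a biaxial state
#'
#' For the diagonal deformation `F = diag(lambda_t, lambda_z, lambda_r)`,
#' `I1 = lambda_t^2 + lambda_z^2 + lambda_r^2` and the fourth invariant of
#' each fiber family at +/- alpha from the circumferential direction is
#' `I4 = lambda_t^2 cos^2(alpha) + lambda_z^2 sin^2(alpha)` (identical for
#' the two families by the cos^2 symmetry).
#'
#' @param lambda_t,lambda_z circumferential and axial stretch (vectorized).
#' @param alpha fiber angle, degrees.
#' @param lambda_r radial stretch; defaults to the incompressible closure
#'   `1/(lambda_t lambda_z)`.
#' @return data.frame with columns `I1`, `I4`.
#' @export
hgo_invariants <- function(lambda_t, lambda_z, alpha,
                           lambda_r = 1 / (lambda_t * lambda_z)) {
  a <- alpha * pi / 180
  data.frame(I1 = lambda_t^2 + lambda_z^2 + lambda_r^2,
             I4 = lambda_t^2 * cos(a)^2 + lambda_z^2 * sin(a)^2)
}

# exponent overflow guard shared by energy/stress/moduli
.hgo_guard <- function(k2, q) {
  expo <- k2 * q^2
  if (any(expo > 700)) {
    i <- which.max(expo)
    stop(sprintf("fiber energy overflow: k2 (I4 - 1)^2 = %.3g at record %d; state outside the model's representable range",
                 expo[i], i), call. = FALSE)
  }
}

# per-family fiber stress coefficient psi' = dW_fam/dI4 = k1 q exp(k2 q^2),
# with the tension-only switch zeroing compressed families (q <= 0)
.fiber_dpsi <- function(k1, k2, q, tension_only) {
  .hgo_guard(k2, q)
  v <- k1 * q * exp(k2 * q^2)
  if (tension_only) v[q <= 0] <- 0
  v
}

# lean vector kernel for the predicted stresses (no data.frame allocation);
# used by the fitting objective and the equilibrium root-finder where it is
# evaluated tens of thousands of times
.stress_kernel <- function(c, k1, k2, alpha_rad, lambda_t, lambda_z,
                           tension_only = TRUE) {
  lambda_r2 <- 1 / (lambda_t * lambda_z)^2
  lt2 <- lambda_t^2
  lz2 <- lambda_z^2
  cos2 <- cos(alpha_rad)^2
  sin2 <- 1 - cos2
  q <- lt2 * cos2 + lz2 * sin2 - 1
  expo <- k2 * q^2
  if (any(expo > 700)) {
    i <- which.max(expo)
    stop(sprintf("fiber energy overflow: k2 (I4 - 1)^2 = %.3g at record %d; state outside the model's representable range",
                 expo[i], i), call. = FALSE)
  }
  dpsi <- k1 * q * exp(expo)
  if (tension_only) dpsi[q <= 0] <- 0
  s_t_iso <- c * (lt2 - lambda_r2)
  s_z_iso <- c * (lz2 - lambda_r2)
  s_t_ani <- 4 * lt2 * dpsi * cos2
  s_z_ani <- 4 * lz2 * dpsi * sin2
  list(sigma_t = s_t_iso + s_t_ani, sigma_t_iso = s_t_iso,
       sigma_z = s_z_iso + s_z_ani, sigma_z_iso = s_z_iso)
}

# per-family second derivative d2W_fam/dI4^2 = k1 exp(k2 q^2)(1 + 2 k2 q^2)
.fiber_d2psi <- function(k1, k2, q, tension_only) {
  .hgo_guard(k2, q)
  v <- k1 * exp(k2 * q^2) * (1 + 2 * k2 * q^2)
  if (tension_only) v[q <= 0] <- 0
  v
}

#' HGO strain-energy density with isotropic/anisotropic split
#'
#' `W = Wiso + Wani` with `Wiso = (c/2)(I1 - 3)` for the Neo-Hookean matrix
#' (attributed to elastic fibers) and, for each of the two symmetric fiber
#' families (attributed to collagen),
#' `W_fam = (k1 / 2 k2)(exp(k2 (I4 - 1)^2) - 1)`.
#' By default fibers only contribute in extension (`I4 > 1`); physiologic
#' states of interest have `I4 > 1` so the switch rarely matters. Below
#' `k2 < 1e-8` the family term switches to its series expansion
#' `(k1/2) q^2 (1 + k2 q^2 / 2 + k2^2 q^4 / 6)` to stay numerically exact
#' through the `k2 -> 0` limit.
#'
#' @param params an [hgo_parameters()].
#' @param lambda_t,lambda_z stretches (vectorized).
#' @param tension_only logical; zero compressed fiber families (default TRUE).
#' @return data.frame with columns `W`, `W_iso`, `W_ani` (kPa).
#' @export
hgo_energy <- function(params, lambda_t, lambda_z, tension_only = TRUE) {
  stopifnot(inherits(params, "hgo_parameters"))
  inv <- hgo_invariants(lambda_t, lambda_z, params$alpha)
  W_iso <- params$c / 2 * (inv$I1 - 3)
  q <- inv$I4 - 1
  .hgo_guard(params$k2, q)
  fam <- if (params$k2 < 1e-8) {
    # series branch, exact through k2 = 0
    params$k1 / 2 * q^2 * (1 + params$k2 * q^2 / 2 + params$k2^2 * q^4 / 6)
  } else {
    params$k1 / (2 * params$k2) * expm1(params$k2 * q^2)
  }
  if (tension_only) fam[q <= 0] <- 0
  W_ani <- 2 * fam   # two symmetric families with identical I4
  data.frame(W = W_iso + W_ani, W_iso = W_iso, W_ani = W_ani)
}

#' Model-predicted Cauchy stresses with isotropic/anisotropic split
#'
#' Stresses follow from `sigma = 2 F (dW/dC) F^T - p I` for the
#' incompressible cylinder; the Lagrange multiplier is eliminated by the
#' radial traction condition (default `sigma_rr = 0`, consistent with the
#' Laplace-type mean experimental stresses the model is fitted to):
#' \deqn{\sigma_{\theta,iso} = c (\lambda_\theta^2 - \lambda_r^2), \quad
#'       \sigma_{z,iso} = c (\lambda_z^2 - \lambda_r^2)}
#' \deqn{\sigma_{\theta,ani} = 2 \lambda_\theta^2 \sum_j k_1 (I_{4j}-1)
#'       e^{k_2 (I_{4j}-1)^2} \cos^2\alpha_j}
#' and analogously with \eqn{\sin^2\alpha_j} in the axial direction; the
#' fibers carry no radial load.
#'
#' @inheritParams hgo_energy
#' @param sigma_r radial stress boundary value, kPa (default 0; set to
#'   `-P/2` for the mid-wall compromise convention).
#' @return data.frame with columns `sigma_t`, `sigma_t_iso`, `sigma_t_ani`,
#'   `sigma_z`, `sigma_z_iso`, `sigma_z_ani` (kPa).
#' @export
hgo_stress <- function(params, lambda_t, lambda_z, tension_only = TRUE,
                       sigma_r = 0) {
  stopifnot(inherits(params, "hgo_parameters"))
  lambda_r <- 1 / (lambda_t * lambda_z)
  a <- params$alpha * pi / 180
  inv <- hgo_invariants(lambda_t, lambda_z, params$alpha, lambda_r)
  q <- inv$I4 - 1
  dpsi <- .fiber_dpsi(params$k1, params$k2, q, tension_only)
  # sum over the two families doubles the single-family coefficient
  s_t_ani <- 2 * lambda_t^2 * (2 * dpsi * cos(a)^2)
  s_z_ani <- 2 * lambda_z^2 * (2 * dpsi * sin(a)^2)
  s_t_iso <- params$c * (lambda_t^2 - lambda_r^2) + sigma_r
  s_z_iso <- params$c * (lambda_z^2 - lambda_r^2) + sigma_r
  data.frame(sigma_t = s_t_iso + s_t_ani, sigma_t_iso = s_t_iso,
             sigma_t_ani = s_t_ani,
             sigma_z = s_z_iso + s_z_ani, sigma_z_iso = s_z_iso,
             sigma_z_ani = s_z_ani)
}

#' Incremental elastic moduli at a biaxial state
#'
#' Linearized material stiffness about the current state, derived from the
#' strain-energy density expressed in the in-plane Cauchy-Green components
#' with the radial component eliminated by incompressibility
#' (`Crr = 1/(Ctt Czz)`):
#' \deqn{\zeta_\theta = 4 \lambda_\theta^2 \frac{\partial W}{\partial C_{\theta\theta}}
#'       + 4 \lambda_\theta^4 \frac{\partial^2 W}{\partial C_{\theta\theta}^2}}
#' and analogously for \eqn{\zeta_z}. Closed form:
#' \deqn{\zeta_\theta = 2 c (\lambda_\theta^2 + \lambda_r^2)
#'       + 4 \lambda_\theta^2 S_1 \cos^2\alpha
#'       + 4 \lambda_\theta^4 S_2 \cos^4\alpha}
#' with `S1 = sum_j k1 q e^{k2 q^2}`, `S2 = sum_j k1 e^{k2 q^2}(1 + 2 k2 q^2)`,
#' `q = I4 - 1`. In the Neo-Hookean limit (`k1 = 0`) this reduces to
#' `zeta_t = 2 c (lambda_t^2 + lambda_r^2)`, i.e. `4 c` at the reference
#' state.
#'
#' @inheritParams hgo_energy
#' @param constrained logical; if `FALSE`, derivatives are taken of W at
#'   frozen radial stretch (the incompressibility reaction is ignored),
#'   provided for sensitivity checks only.
#' @return data.frame with columns `zeta_t`, `zeta_z` (kPa).
#' @export
hgo_moduli <- function(params, lambda_t, lambda_z, tension_only = TRUE,
                       constrained = TRUE) {
  stopifnot(inherits(params, "hgo_parameters"))
  lambda_r <- 1 / (lambda_t * lambda_z)
  a <- params$alpha * pi / 180
  inv <- hgo_invariants(lambda_t, lambda_z, params$alpha, lambda_r)
  q <- inv$I4 - 1
  S1 <- 2 * .fiber_dpsi(params$k1, params$k2, q, tension_only)
  S2 <- 2 * .fiber_d2psi(params$k1, params$k2, q, tension_only)
  iso_t <- if (constrained) {
    2 * params$c * (lambda_t^2 + lambda_r^2)
  } else {
    2 * params$c * lambda_t^2
  }
  iso_z <- if (constrained) {
    2 * params$c * (lambda_z^2 + lambda_r^2)
  } else {
    2 * params$c * lambda_z^2
  }
  data.frame(
    zeta_t = iso_t + 4 * lambda_t^2 * S1 * cos(a)^2 +
      4 * lambda_t^4 * S2 * cos(a)^4,
    zeta_z = iso_z + 4 * lambda_z^2 * S1 * sin(a)^2 +
      4 * lambda_z^4 * S2 * sin(a)^4)
}
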