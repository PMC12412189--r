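test_that("invariants: reference state, frozen example, angle symmetry", {
  inv0 <- hgo_invariants(1, 1, 30)
  expect_equal(inv0$I1, 3, tolerance = 1e-12)
  expect_equal(inv0$I4, 1, tolerance = 1e-12)
  inv <- hgo_invariants(1.4, 1.2, 30)
  expect_equal(inv$I1, 3.75430839002, tolerance = 1e-9)
  expect_equal(inv$I4, 1.83, tolerance = 1e-12)
  # I4 is even in alpha (cos^2 symmetry)
  set.seed(3)
  lt <- runif(20, 0.9, 1.6); lz <- runif(20, 0.9, 1.6); a <- runif(20, 0, 90)
  for (i in 1:20) {
    expect_equal(hgo_invariants(lt[i], lz[i], a[i])$I4,
                 hgo_invariants(lt[i], lz[i], -a[i])$I4, tolerance = 1e-12)
  }
})

test_that("strain energy: zero at reference, frozen example, decomposition", {
  p <- hgo_parameters(20, 10, 0.5, 30)
  e0 <- hgo_energy(p, 1, 1)
  expect_equal(unlist(e0), c(W = 0, W_iso = 0, W_ani = 0), tolerance = 1e-12)
  e <- hgo_energy(p, 1.4, 1.2)
  expect_equal(e$W_iso, 7.54308390023, tolerance = 1e-9)
  expect_equal(e$W_ani, 8.22427077472, tolerance = 1e-9)
  expect_equal(e$W, e$W_iso + e$W_ani, tolerance = 1e-12)
})

test_that("k2 -> 0 limit follows the series expansion continuously", {
  # series oracle: W_ani -> k1 q^2 (both families) as k2 -> 0
  lt <- 1.3; lz <- 1.15
  q <- hgo_invariants(lt, lz, 40)$I4 - 1
  for (k2 in c(0, 1e-12, 1e-9)) {
    p <- hgo_parameters(10, 8, k2, 40, strict = FALSE)
    expect_equal(hgo_energy(p, lt, lz)$W_ani, 8 * q^2,
                 tolerance = 1e-8)
  }
  # continuity across the Taylor-branch threshold (the small genuine
  # dW/dk2 slope over the k2 step is the only admissible difference)
  lo <- hgo_energy(hgo_parameters(10, 8, 1e-8 * 0.99, 40, strict = FALSE),
                   lt, lz)$W_ani
  hi <- hgo_energy(hgo_parameters(10, 8, 1e-8 * 1.01, 40, strict = FALSE),
                   lt, lz)$W_ani
  expect_equal(lo, hi, tolerance = 1e-9)
})

test_that("predicted stresses: reference zero, frozen example, alpha = 0", {
  p <- hgo_parameters(20, 10, 0.5, 30)
  s0 <- hgo_stress(p, 1, 1)
  expect_true(all(abs(unlist(s0)) < 1e-12))
  s <- hgo_stress(p, 1.4, 1.2)
  expect_equal(s$sigma_t_iso, 32.1138321995, tolerance = 1e-9)
  expect_equal(s$sigma_t_ani, 68.8728655445, tolerance = 1e-9)
  expect_equal(s$sigma_t, 100.986697744, tolerance = 1e-9)
  expect_equal(s$sigma_z_iso, 21.7138321995, tolerance = 1e-9)
  expect_equal(s$sigma_z_ani, 16.866824215, tolerance = 1e-9)
  expect_equal(s$sigma_z, 38.5806564145, tolerance = 1e-9)
  # purely circumferential fibers carry no axial load
  p0 <- hgo_parameters(20, 10, 0.5, 0)
  set.seed(5)
  s <- hgo_stress(p0, runif(10, 1, 1.6), runif(10, 1, 1.6))
  expect_true(all(s$sigma_z_ani == 0))
})

test_that("stress-energy consistency: sigma = 2F(dW/dC)F' - pI by central FD", {
  set.seed(11)
  max_rel <- 0
  for (i in 1:60) {
    p <- hgo_parameters(runif(1, 5, 80), runif(1, 1, 80), runif(1, 0.05, 4),
                        runif(1, 5, 85))
    lt <- runif(1, 1.02, 1.6); lz <- runif(1, 1.02, 1.6)
    s <- hgo_stress(p, lt, lz)
    # FD oracle on W(lt, lz) with lr eliminated by incompressibility:
    # sigma_tt - sigma_rr = lt dW/dlt, sigma_zz - sigma_rr = lz dW/dlz
    h <- 1e-6
    Wf <- function(a, b) hgo_energy(p, a, b)$W
    d_t <- (Wf(lt + h, lz) - Wf(lt - h, lz)) / (2 * h)
    d_z <- (Wf(lt, lz + h) - Wf(lt, lz - h)) / (2 * h)
    max_rel <- max(max_rel,
                   abs(s$sigma_t - lt * d_t) / max(abs(s$sigma_t), 1),
                   abs(s$sigma_z - lz * d_z) / max(abs(s$sigma_z), 1))
  }
  expect_lt(max_rel, 1e-6)
})

test_that("decomposition closure and +/- alpha symmetry of stresses", {
  set.seed(12)
  for (i in 1:25) {
    p <- hgo_parameters(runif(1, 5, 60), runif(1, 1, 60), runif(1, 0.1, 3),
                        runif(1, 0, 90))
    lt <- runif(1, 0.9, 1.7); lz <- runif(1, 0.9, 1.7)
    s <- hgo_stress(p, lt, lz)
    expect_equal(s$sigma_t, s$sigma_t_iso + s$sigma_t_ani, tolerance = 1e-12)
    expect_equal(s$sigma_z, s$sigma_z_iso + s$sigma_z_ani, tolerance = 1e-12)
    e <- hgo_energy(p, lt, lz)
    expect_equal(e$W, e$W_iso + e$W_ani, tolerance = 1e-12)
  }
})

test_that("moduli: Neo-Hookean closed form and FD oracle of constrained W", {
  # k1 = 0 (relaxed mode): zeta_t = 2c(lt^2 + lr^2), = 4c at reference
  pnh <- hgo_parameters(20, 0, 1, 30, strict = FALSE)
  m0 <- hgo_moduli(pnh, 1, 1)
  expect_equal(m0$zeta_t, 80, tolerance = 1e-12)
  expect_equal(m0$zeta_z, 80, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    lt <- runif(1, 0.9, 1.6); lz <- runif(1, 0.9, 1.6)
    lr2 <- 1 / (lt * lz)^2
    m <- hgo_moduli(pnh, lt, lz)
    expect_equal(m$zeta_t, 2 * 20 * (lt^2 + lr2), tolerance = 1e-10)
    expect_equal(m$zeta_z, 2 * 20 * (lz^2 + lr2), tolerance = 1e-10)
  }
  # general FD oracle: zeta_t = 4x W_x + 4x^2 W_xx with x = C_tt, under
  # C_rr = 1/(C_tt C_zz)
  set.seed(7)
  for (i in 1:40) {
    p <- hgo_parameters(runif(1, 5, 80), runif(1, 1, 80), runif(1, 0.05, 4),
                        runif(1, 5, 85))
    lt <- runif(1, 1.05, 1.6); lz <- runif(1, 1.05, 1.6)
    Wc <- function(x, y) hgo_energy(p, sqrt(x), sqrt(y))$W
    x <- lt^2; y <- lz^2
    h <- 1e-4 * x   # balances truncation against roundoff in the 2nd FD
    W1 <- (Wc(x + h, y) - Wc(x - h, y)) / (2 * h)
    W2 <- (Wc(x + h, y) - 2 * Wc(x, y) + Wc(x - h, y)) / h^2
    m <- hgo_moduli(p, lt, lz)
    expect_equal(m$zeta_t, 4 * x * W1 + 4 * x^2 * W2,
                 tolerance = 1e-5)
  }
})

test_that("fiber recruitment: zeta_t strictly increases with lambda_t", {
  p <- hgo_parameters(20, 15, 1.2, 35)
  lt <- seq(1.0, 1.7, by = 0.05)
  z <- hgo_moduli(p, lt, 1.3)$zeta_t
  expect_true(all(diff(z) > 0))
})

test_that("overflow guard names the offending state", {
  p <- hgo_parameters(20, 10, 50, 30)
  expect_error(hgo_energy(p, 3.5, 3.5), "overflow")
})

test_that("parameters serialize to JSON and back with units intact", {
  p <- hgo_parameters(35.5, 20.25, 0.875, 41.2)
  path <- withr::local_tempfile(fileext = ".json")
  hgo_params_to_json(p, path)
  q <- hgo_params_from_json(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_match(paste(readLines(path), collapse = ""), "kPa")
})
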