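#' Assemble the fitting dataset for one sample
#'
#' Pools the chosen loading limb (default the third) of all protocols into
#' per-record states and experimental stresses — the data the constitutive
#' model is regressed against.
#'
#' @param traces list of the sample's six [protocol_trace()]s.
#' @param geom the sample's [unloaded_geometry()].
#' @param cycle_index which loading cycle to use (default 3).
#' @param window smoothing window for cycle segmentation.
#' @return an object of class `fit_dataset`: data.frame with columns
#'   `lambda_t`, `lambda_z`, `sigma_t_exp`, `sigma_z_exp`, `P`, `f`, `d_i`,
#'   `d_o`, `protocol_id`.
#' @export
build_fit_dataset <- function(traces, geom, cycle_index = 3, window = 5) {
  parts <- lapply(traces, function(tr) {
    limb <- select_loading_cycle(tr, cycle_index = cycle_index, window = window)
    df <- trace_states(limb, geom)
    data.frame(lambda_t = df$lambda_t, lambda_z = df$lambda_z,
               sigma_t_exp = df$sigma_t, sigma_z_exp = df$sigma_z,
               P = df$P, f = df$f, d_i = df$d_i, d_o = df$d_o,
               protocol_id = limb$protocol_id)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (nrow(out) < 20) {
    stop("fit dataset has ", nrow(out), " records; need at least 20",
         call. = FALSE)
  }
  class(out) <- c("fit_dataset", "data.frame")
  out
}

#' Normalized fitting error and isotropic-contribution penalty
#'
#' The regression error is the sum of squared stress residuals in each
#' direction, each normalized by that direction's sum of squared
#' experimental stresses:
#' \deqn{error = \frac{\sum (\sigma_{\theta,exp} - \sigma_{\theta,pred})^2}
#'       {\sum \sigma_{\theta,exp}^2} +
#'       \frac{\sum (\sigma_{z,exp} - \sigma_{z,pred})^2}{\sum \sigma_{z,exp}^2}}
#' A per-record penalty discourages fits in which the Neo-Hookean matrix
#' carries less than 10 % of the predicted circumferential stress:
#' `penalty(i) = 0.1 - sigma_t_iso(i)/sigma_t_total(i)` whenever that
#' fraction falls below 0.1 (records with non-positive predicted total
#' contribute the maximal penalty 0.1), and the minimized objective is
#' `error + sum(penalty^2)`.
#'
#' @param params an [hgo_parameters()].
#' @param data a [build_fit_dataset()] result (or data.frame with columns
#'   `lambda_t`, `lambda_z`, `sigma_t_exp`, `sigma_z_exp`).
#' @param tension_only passed to [hgo_stress()].
#' @return list with elements `error`, `penalty_total` (= sum of squared
#'   per-record penalties), `objective`, and the per-record `penalty` vector.
#' @export
hgo_objective <- function(params, data, tension_only = TRUE) {
  den_t <- sum(data$sigma_t_exp^2)
  den_z <- sum(data$sigma_z_exp^2)
  if (den_t <= 0 || den_z <= 0) {
    stop("degenerate data: all-zero experimental stresses in one direction",
         call. = FALSE)
  }
  pred <- .stress_kernel(params$c, params$k1, params$k2,
                         params$alpha * pi / 180,
                         data$lambda_t, data$lambda_z,
                         tension_only = tension_only)
  err <- sum((data$sigma_t_exp - pred$sigma_t)^2) / den_t +
    sum((data$sigma_z_exp - pred$sigma_z)^2) / den_z
  # iso share of the predicted circumferential stress; records with
  # non-positive total (or negative share: matrix in circumferential
  # compression) carry the maximal penalty 0.1, so the per-record penalty is
  # bounded in [0, 0.1] and near-zero-stress records cannot dominate
  frac <- ifelse(pred$sigma_t > 0, pred$sigma_t_iso / pred$sigma_t, 0)
  penalty <- pmin(pmax(0, 0.1 - frac), 0.1)
  list(error = err, penalty_total = sum(penalty^2),
       objective = err + sum(penalty^2), penalty = penalty)
}

#' Default multi-start search box for the HGO fit
#'
#' A search box (not a reporting constraint) spanning the magnitudes seen in
#' murine aortic fits; the optimizer works on log10(c, k1, k2) and linear
#' alpha inside these bounds.
#' @return list with `lower` and `upper` named numeric vectors.
#' @export
hgo_fit_bounds <- function() {
  list(lower = c(c = 1, k1 = 0.1, k2 = 1e-3, alpha = 0),
       upper = c(c = 200, k1 = 500, k2 = 50, alpha = 90))
}

.theta_to_params <- function(theta, strict = FALSE) {
  hgo_parameters(c = 10^theta[1], k1 = 10^theta[2], k2 = 10^theta[3],
                 alpha = theta[4], strict = strict)
}

#' Fit the HGO model to one sample's biaxial data
#'
#' Penalized constrained nonlinear regression: minimizes
#' [hgo_objective()] over `c, k1, k2 > 0` and `alpha` in `[0, 90]` degrees
#' with L-BFGS-B on `(log10 c, log10 k1, log10 k2, alpha)`, from `n_starts`
#' Latin-hypercube initial guesses over the search box. Deterministic given
#' `seed`.
#'
#' @param data a [build_fit_dataset()] result.
#' @param n_starts number of multi-start initial guesses (default 10).
#' @param seed RNG seed for the Latin-hypercube start draw.
#' @param bounds search box, see [hgo_fit_bounds()].
#' @param tension_only passed to the model evaluations.
#' @return an object of class `hgo_fit`: list with `params`
#'   ([hgo_parameters()]), `error`, `penalty_total`, `objective`, `r2`,
#'   `n_starts`, `converged` (per-start flags), `best_start`, `starts`
#'   (matrix of initial guesses), `objectives` (per-start minima).
#' @export
fit_hgo <- function(data, n_starts = 10, seed = 1L, bounds = hgo_fit_bounds(),
                    tension_only = TRUE) {
  stopifnot(is.data.frame(data), n_starts >= 1)
  lo <- c(log10(bounds$lower[1:3]), bounds$lower[4])
  hi <- c(log10(bounds$upper[1:3]), bounds$upper[4])
  starts <- withr::with_seed(as.integer(seed), lhs::randomLHS(n_starts, 4))
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- c("log10_c", "log10_k1", "log10_k2", "alpha")
  fn <- function(theta) {
    hgo_objective(.theta_to_params(theta), data,
                  tension_only = tension_only)$objective
  }
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B", lower = lo,
                   upper = hi,
                   control = list(maxit = 500, factr = 1e2, pgtol = 1e-12)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  values <- vapply(results, function(r) r$value, numeric(1))
  converged <- vapply(results, function(r) identical(r$convergence, 0L),
                      logical(1))
  if (!any(is.finite(values))) {
    diag <- vapply(results, function(r) r$message %||% "", character(1))
    stop("no start converged; per-start diagnostics: ",
         paste(sprintf("[%d] %s", seq_len(n_starts), diag), collapse = "; "),
         call. = FALSE)
  }
  best <- which.min(values)
  params <- .theta_to_params(results[[best]]$par)
  obj <- hgo_objective(params, data, tension_only = tension_only)
  structure(list(params = params, error = obj$error,
                 penalty_total = obj$penalty_total,
                 objective = obj$objective,
                 r2 = goodness_of_fit(data, params, tension_only = tension_only),
                 n_starts = n_starts, converged = converged,
                 best_start = best, starts = starts, objectives = values,
                 seed = as.integer(seed)),
            class = "hgo_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hgo_fit <- function(x, ...) {
  cat(sprintf("HGO fit: objective %.3e (error %.3e, penalty %.3e), R^2 = %.5f\n",
              x$objective, x$error, x$penalty_total, x$r2))
  print(x$params)
  invisible(x)
}

#' Coefficient of determination of a fitted parameter set
#'
#' Pooled over both stress directions:
#' `r2 = 1 - SS_res / SS_tot`, with residuals summed over the
#' circumferential and axial components and total sums of squares about the
#' per-direction means.
#'
#' @inheritParams hgo_objective
#' @return numeric scalar `r2 <= 1`.
#' @export
goodness_of_fit <- function(data, params, tension_only = TRUE) {
  pred <- hgo_stress(params, data$lambda_t, data$lambda_z,
                     tension_only = tension_only)
  ss_tot <- sum((data$sigma_t_exp - mean(data$sigma_t_exp))^2) +
    sum((data$sigma_z_exp - mean(data$sigma_z_exp))^2)
  if (ss_tot <= 0) {
    stop("degenerate data: zero total stress variance", call. = FALSE)
  }
  ss_res <- sum((data$sigma_t_exp - pred$sigma_t)^2) +
    sum((data$sigma_z_exp - pred$sigma_z)^2)
  1 - ss_res / ss_tot
}

#' Screen fitted samples for parameter outliers
#'
#' Within each vessel cohort (pooling ages and genotypes), a sample is
#' flagged when any of the five reported quantities — `c`, `k1`, `k2`,
#' `alpha`, and the nonlinearity ratio `k1/k2` — deviates more than
#' `threshold` standard deviations from the cohort mean. Flagged samples are
#' excluded from all downstream analyses.
#'
#' @param fits data.frame with one row per sample containing columns `c`,
#'   `k1`, `k2`, `alpha` and the grouping column.
#' @param group_col grouping column name (default `"vessel"`).
#' @param threshold SD multiple defining an outlier (default 3).
#' @param quantities which fitted quantities the rule applies to.
#' @return the input with logical column `outlier` appended (and a
#'   `which_quantity` column naming the first offending quantity, `NA` when
#'   none). Groups with fewer than 3 samples are left unscreened with a
#'   warning.
#' @export
screen_outliers <- function(fits, group_col = "vessel", threshold = 3,
                            quantities = c("c", "k1", "k2", "alpha", "k1_k2")) {
  stopifnot(is.data.frame(fits))
  if (!"k1_k2" %in% names(fits) && all(c("k1", "k2") %in% names(fits))) {
    fits$k1_k2 <- fits$k1 / fits$k2
  }
  fits$outlier <- FALSE
  fits$which_quantity <- NA_character_
  for (g in unique(fits[[group_col]])) {
    idx <- which(fits[[group_col]] == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has ", length(idx),
              " samples (< 3); outlier screening skipped", call. = FALSE)
      next
    }
    for (qn in quantities) {
      x <- fits[[qn]][idx]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) next
      off <- abs(x - mean(x)) > threshold * s
      newly <- idx[off & !fits$outlier[idx]]
      fits$which_quantity[newly] <- qn
      fits$outlier[idx] <- fits$outlier[idx] | off
    }
  }
  fits
}
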