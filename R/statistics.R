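#' Z-score standardization of metric columns
#'
#' Each listed column is centered and scaled to mean 0, SD 1 using the
#' population SD convention (denominator n). The transformation parameters
#' are stored in attributes `zscore_center` / `zscore_scale` for
#' back-conversion.
#'
#' @param table data.frame of per-sample metrics.
#' @param columns character vector of columns to standardize.
#' @return the table with listed columns standardized.
#' @export
zscore_normalize <- function(table, columns) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)))
  center <- scale_ <- stats::setNames(numeric(length(columns)), columns)
  n <- nrow(table)
  for (col in columns) {
    x <- table[[col]]
    mu <- mean(x)
    sdev <- stats::sd(x) * sqrt((n - 1) / n)   # population SD
    if (!is.finite(sdev) || sdev == 0) {
      stop("column '", col, "' has zero variance; cannot standardize",
           call. = FALSE)
    }
    table[[col]] <- (x - mu) / sdev
    center[col] <- mu
    scale_[col] <- sdev
  }
  attr(table, "zscore_center") <- center
  attr(table, "zscore_scale") <- scale_
  table
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is the coefficient of
#' determination of predictor `j` regressed on all the others. Perfect
#' collinearity is reported as `Inf`, not an error.
#'
#' @param design data.frame or matrix of predictor columns (>= 2 columns,
#'   more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  p <- ncol(design)
  if (p < 2) stop("need >= 2 predictors for VIF", call. = FALSE)
  if (nrow(design) <= p) stop("need n > number of predictors", call. = FALSE)
  out <- stats::setNames(numeric(p), names(design))
  for (j in seq_len(p)) {
    fit <- stats::lm(design[[j]] ~ ., data = design[-j])
    r2 <- summary(fit)$r.squared
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

# fit response ~ predictors with a random intercept per grouping factor when
# the data contain repeated measures; plain least squares otherwise
.fit_regression <- function(table, response, predictors, group) {
  use_mixed <- !is.null(group) && group %in% names(table) &&
    any(duplicated(table[[group]]))
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (use_mixed) {
    fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = table, REML = TRUE)))
  } else {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(fml, data = table)
  }
  list(fit = fit, mixed = use_mixed)
}

# per-coefficient Wald p-values (Satterthwaite df for mixed fits)
.coef_pvalues <- function(fitted) {
  ct <- if (fitted$mixed) {
    stats::coef(summary(fitted$fit))
  } else {
    summary(fitted$fit)$coefficients
  }
  stats::setNames(ct[, ncol(ct)], rownames(ct))
}

# fixed-effects (marginal) R^2; for mixed fits the Nakagawa-style variance
# partition var(Xb) / (var(Xb) + var_random + var_residual)
.marginal_r2 <- function(fitted, table, response) {
  if (!fitted$mixed) return(summary(fitted$fit)$r.squared)
  X <- stats::model.matrix(fitted$fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fitted$fit)))
  vc <- as.data.frame(lme4::VarCorr(fitted$fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f / (var_f + var_r + var_e)
}

.adjust_r2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# standalone (single-predictor) adjusted R^2 against the response, used as
# the "relative contribution" when arbitrating a collinear pair
.standalone_contribution <- function(table, response, predictor, group) {
  fitted <- .fit_regression(table, response, predictor, group)
  .adjust_r2(.marginal_r2(fitted, table, response), nrow(table), 1)
}

#' Forward-stepwise mixed regression with VIF screening
#'
#' Builds the best model for a response (the physiologic deformed inner
#' diameter) from standardized biomechanical metrics. At each step the
#' candidate with the smallest Wald p-value enters if `p < alpha` and its
#' entry keeps every predictor's VIF below `vif_threshold`. When a candidate
#' is collinear (VIF >= threshold) with a retained metric, whichever of the
#' pair has the higher standalone contribution to the response is kept and
#' the other is excluded from further consideration. A random intercept per
#' `group` (animal) captures the repeated-measures structure; a
#' fixed-effects-only fit is used automatically when every animal
#' contributes a single row.
#'
#' @param table data.frame with the response, standardized candidate columns
#'   and the grouping column.
#' @param response response column name.
#' @param candidates character vector of candidate predictor columns.
#' @param group grouping column for the random intercept (default
#'   `"animal_id"`).
#' @param alpha entry threshold on the Wald p-value (default 0.05).
#' @param vif_threshold collinearity exclusion threshold (default 3).
#' @param multiplicity `"bonferroni"` (default) divides the entry threshold
#'   by the number of candidate metrics (fixed-family correction), so the
#'   probability of any spurious entry per step is controlled at `alpha`;
#'   `"none"` applies the raw threshold to the per-candidate p-value.
#' @return an object of class `model_report`: list with `predictors` (entry
#'   order), `coefficients`, `p_values`, `vif`, `r2`, `adj_r2`,
#'   `contributions` (shares of the adjusted R^2, see
#'   [relative_contributions()]), `random_variance`, `mixed`, `excluded`,
#'   `n`, and the fitted `model`.
#' @export
stepwise_mixed_model <- function(table, response, candidates,
                                 group = "animal_id", alpha = 0.05,
                                 vif_threshold = 3,
                                 multiplicity = c("bonferroni", "none")) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(is.data.frame(table), response %in% names(table))
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  missing_cols <- setdiff(candidates, names(table))
  if (length(missing_cols)) {
    stop("candidate column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) < length(candidates) + 3) {
    stop("too few rows (", nrow(table), ") for ", length(candidates),
         " candidates", call. = FALSE)
  }
  selected <- character(0)
  excluded <- character(0)
  repeat {
    pool <- setdiff(candidates, c(selected, excluded))
    if (!length(pool)) break
    entry_p <- stats::setNames(rep(NA_real_, length(pool)), pool)
    swaps <- list()
    for (cand in pool) {
      tentative <- c(selected, cand)
      if (length(tentative) >= 2) {
        v <- vif(table[tentative])
        if (any(v >= vif_threshold)) {
          conflicts <- setdiff(names(v)[v >= vif_threshold], cand)
          if (!length(conflicts)) conflicts <- selected
          cand_contrib <- .standalone_contribution(table, response, cand, group)
          conf_contrib <- vapply(conflicts, .standalone_contribution,
                                 numeric(1), table = table,
                                 response = response, group = group)
          if (cand_contrib > max(conf_contrib)) {
            swaps[[cand]] <- conflicts   # candidate dominates: drop conflicts
          }
          next   # collinear entries never get a p-value this round
        }
      }
      fitted <- .fit_regression(table, response, tentative, group)
      entry_p[cand] <- .coef_pvalues(fitted)[cand]
    }
    if (length(swaps)) {
      losers <- unique(unlist(swaps))
      selected <- setdiff(selected, losers)
      excluded <- c(excluded, losers)
      next
    }
    if (all(is.na(entry_p))) {
      excluded <- c(excluded, pool)   # everything left is collinear and loses
      next
    }
    best <- names(which.min(entry_p))
    threshold <- if (multiplicity == "bonferroni") {
      alpha / length(candidates)   # fixed-family correction
    } else {
      alpha
    }
    if (entry_p[best] >= threshold) break
    selected <- c(selected, best)
  }
  fitted <- .fit_regression(table, response, selected, group)
  n <- nrow(table)
  r2 <- .marginal_r2(fitted, table, response)
  adj_r2 <- .adjust_r2(r2, n, length(selected))
  pv <- .coef_pvalues(fitted)
  coefs <- if (fitted$mixed) lme4::fixef(fitted$fit) else stats::coef(fitted$fit)
  random_var <- if (fitted$mixed) {
    vc <- as.data.frame(lme4::VarCorr(fitted$fit))
    sum(vc$vcov[vc$grp != "Residual"])
  } else {
    NA_real_
  }
  contributions <- if (length(selected)) {
    relative_contributions(table, response, selected, group = group,
                           adj_r2 = adj_r2)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(predictors = selected,
                 coefficients = coefs[selected],
                 p_values = pv[selected],
                 vif = if (length(selected) >= 2) vif(table[selected]) else
                   stats::setNames(rep(NA_real_, length(selected)), selected),
                 r2 = r2, adj_r2 = adj_r2,
                 contributions = contributions,
                 random_variance = random_var, mixed = fitted$mixed,
                 excluded = excluded, n = n, model = fitted$fit),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Stepwise", if (x$mixed) "mixed" else "fixed-effects",
      "model:", if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "(empty)", "\n")
  cat(sprintf("  adjusted R^2 (marginal, fixed effects) = %.4f, n = %d\n",
              x$adj_r2, x$n))
  if (length(x$predictors)) {
    print(data.frame(coefficient = x$coefficients, p_value = x$p_values,
                     VIF = x$vif, contribution = x$contributions))
  }
  invisible(x)
}

#' Relative contributions of predictors to the adjusted R^2
#'
#' Averaged-over-orderings decomposition: each predictor's contribution is
#' its mean marginal R^2 gain over all entry orders of the selected
#' predictors, rescaled so the shares sum to the model's adjusted R^2.
#'
#' @param table data.frame with the response and predictor columns.
#' @param response response column name.
#' @param predictors predictors of the fitted model.
#' @param group random-intercept grouping column (or `NULL`).
#' @param adj_r2 the model's adjusted R^2; computed if omitted.
#' @return named numeric vector of shares summing to `adj_r2`.
#' @export
relative_contributions <- function(table, response, predictors,
                                   group = "animal_id", adj_r2 = NULL) {
  k <- length(predictors)
  if (!k) stop("need a fitted model with >= 1 predictor", call. = FALSE)
  if (is.null(adj_r2)) {
    fitted <- .fit_regression(table, response, predictors, group)
    adj_r2 <- .adjust_r2(.marginal_r2(fitted, table, response),
                         nrow(table), k)
  }
  r2_of <- local({
    cache <- new.env(parent = emptyenv())
    function(set) {
      key <- if (length(set)) paste(sort(set), collapse = "|") else ".null."
      if (!is.null(cache[[key]])) return(cache[[key]])
      val <- if (!length(set)) 0 else {
        f <- .fit_regression(table, response, set, group)
        .marginal_r2(f, table, response)
      }
      cache[[key]] <- val
      val
    }
  })
  perms <- all_permutations(predictors)
  gains <- stats::setNames(numeric(k), predictors)
  for (perm in perms) {
    prev <- character(0)
    for (pred in perm) {
      gains[pred] <- gains[pred] + (r2_of(c(prev, pred)) - r2_of(prev))
      prev <- c(prev, pred)
    }
  }
  gains <- gains / length(perms)
  gains / sum(gains) * adj_r2
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in all_permutations(x[-i])) out <- c(out, list(c(x[i], tail)))
  }
  out
}

#' Three-way factorial ANOVA with percent variation
#'
#' Fixed-effects factorial ANOVA of a metric on age, vessel and genotype
#' with all interactions. Percent variation of each term is
#' `100 * SS_term / SS_total` (total includes the residual), which
#' partitions exactly for balanced designs.
#'
#' @param table data.frame of per-sample metrics.
#' @param response response column name.
#' @param factors the three factor columns (default age, vessel, genotype).
#' @param type sums-of-squares type: `"III"` (default, with sum-to-zero
#'   contrasts) or `"I"`.
#' @return data.frame with columns `term`, `df`, `sum_sq`, `F`, `p_value`,
#'   `percent_variation`, `significant` (at 0.05).
#' @export
three_way_anova <- function(table, response,
                            factors = c("age", "vessel", "genotype"),
                            type = c("III", "I")) {
  type <- match.arg(type)
  stopifnot(response %in% names(table), all(factors %in% names(table)))
  for (f in factors) table[[f]] <- factor(table[[f]])
  cells <- table(table[factors])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lbl <- apply(empty, 1, function(i) {
      paste(mapply(function(f, j) paste0(f, "=", dimnames(cells)[[f]][j]),
                   factors, i), collapse = ", ")
    })
    stop("empty design cell(s): ", paste(lbl, collapse = "; "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  if (type == "III") {
    fit <- stats::lm(fml, data = table,
                     contrasts = stats::setNames(
                       rep(list("contr.sum"), length(factors)), factors))
    a <- tryCatch(car::Anova(fit, type = 3),
                  error = function(e) NULL)
    if (is.null(a)) {
      # zero residual variance (an exactly planted response); sequential SS
      # coincide with type III here for the balanced designs this arises in
      a <- stats::anova(fit)
    } else {
      a <- a[!rownames(a) %in% "(Intercept)", ]
    }
  } else {
    fit <- stats::lm(fml, data = table)
    a <- stats::anova(fit)
  }
  ss <- a[["Sum Sq"]]
  terms <- trimws(rownames(a))
  out <- data.frame(term = terms, df = a[["Df"]], sum_sq = ss,
                    F = a[["F value"]], p_value = a[["Pr(>F)"]])
  out$percent_variation <- 100 * out$sum_sq / sum(out$sum_sq)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  rownames(out) <- NULL
  out
}
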