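#' Candidate biomechanical metrics for the diameter models
#'
#' The physiologic metrics offered to the stepwise regressions: stretch
#' ratios, stored strain energy and wall stresses with their
#' isotropic/anisotropic splits, and the incremental moduli.
#' @export
metric_candidates <- function() {
  c("lambda_t", "lambda_z", "W", "W_iso", "W_ani",
    "sigma_t", "sigma_t_iso", "sigma_t_ani",
    "sigma_z", "sigma_z_iso", "sigma_z_ani",
    "zeta_t", "zeta_z")
}

#' Run the full analysis pipeline on a virtual cohort
#'
#' End-to-end chain: simulate the cohort, assemble each sample's fitting
#' dataset from the third loading limbs, fit the HGO model, screen parameter
#' outliers per vessel, evaluate physiologic metrics at each group's mean
#' blood pressure, then run the cohort statistics: three-way ANOVAs and the
#' per-genotype forward-stepwise mixed models predicting deformed inner
#' diameter. All stages are deterministic given the design's seed.
#'
#' @param design a [cohort_design()].
#' @param out_dir directory for the output tables; `NULL` returns results
#'   in memory only.
#' @param n_starts multi-start count for each HGO fit.
#' @param candidates candidate metric columns for the stepwise models.
#' @param anova_responses metric columns to run three-way ANOVAs on.
#' @return an object of class `pipeline_result`: list with `cohort`,
#'   `fits` (per-sample parameter table with outlier flags), `metrics`
#'   (per-sample physiologic metrics), `anova` (long table over responses),
#'   `models` (per-genotype [stepwise_mixed_model()] reports), and
#'   `provenance`.
#' @export
run_pipeline <- function(design, out_dir = NULL, n_starts = 10,
                         candidates = metric_candidates(),
                         anova_responses = c("d_i", "W", "sigma_t",
                                             "sigma_z", "zeta_t", "zeta_z")) {
  stopifnot(inherits(design, "cohort_design"))
  cohort <- generate_cohort(design)

  fit_rows <- vector("list", length(cohort$samples))
  fits <- vector("list", length(cohort$samples))
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    dataset <- build_fit_dataset(s$traces, s$geom)
    fits[[i]] <- fit_hgo(dataset, n_starts = n_starts,
                         seed = design$seed + i)
    p <- fits[[i]]$params
    fit_rows[[i]] <- data.frame(
      sample_id = s$meta$sample_id, animal_id = s$meta$animal_id,
      genotype = s$meta$genotype, vessel = s$meta$vessel,
      age = s$meta$age, sex = s$meta$sex,
      c = p$c, k1 = p$k1, k2 = p$k2, alpha = p$alpha,
      k1_k2 = p$k1 / p$k2, r2 = fits[[i]]$r2,
      error = fits[[i]]$error, penalty_total = fits[[i]]$penalty_total,
      objective = fits[[i]]$objective)
  }
  fit_table <- do.call(rbind, fit_rows)
  fit_table <- screen_outliers(fit_table, group_col = "vessel")

  keep <- which(!fit_table$outlier)
  metric_rows <- lapply(keep, function(i) {
    s <- cohort$samples[[i]]
    sample_metrics(s$traces, s$geom, fits[[i]]$params, s$meta,
                   pressure_table = design$pressure_table)
  })
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL

  anova_tables <- lapply(anova_responses, function(resp) {
    cbind(response = resp, three_way_anova(metrics, resp))
  })
  anova_long <- do.call(rbind, anova_tables)

  models <- lapply(stats::setNames(nm = c("WT", "MU")), function(g) {
    sub <- metrics[metrics$genotype == g, , drop = FALSE]
    if (nrow(sub) < length(candidates) + 3) {
      message("genotype ", g, ": ", nrow(sub),
              " rows is too few for ", length(candidates),
              " candidates; stepwise model skipped")
      return(NULL)
    }
    sub <- zscore_normalize(sub, c("d_i", candidates))
    stepwise_mixed_model(sub, response = "d_i", candidates = candidates,
                         group = "animal_id")
  })

  provenance <- list(package = "aortamech",
                     version = as.character(utils::packageVersion("aortamech")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     seed = design$seed,
                     n_samples = nrow(cohort$manifest),
                     n_outliers = sum(fit_table$outlier),
                     design_hash = design_hash(design))
  result <- structure(list(cohort = cohort, fits = fit_table,
                           metrics = metrics, anova = anova_long,
                           models = models, provenance = provenance),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# md5 of the design serialized to canonical JSON
design_hash <- function(design) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(design), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write pipeline outputs to disk
#'
#' Emits `fits.csv`, `metrics.csv`, `anova.csv`, one `model_<genotype>.json`
#' per stepwise report, and `provenance.json`. Output is byte-stable: the
#' same design and seed reproduce identical files.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 15, trim = TRUE),
                     file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(result$fits, "fits.csv")
  wcsv(result$metrics, "metrics.csv")
  wcsv(result$anova, "anova.csv")
  for (g in names(result$models)) {
    m <- result$models[[g]]
    if (is.null(m)) next
    obj <- list(genotype = g, predictors = m$predictors,
                coefficients = as.list(m$coefficients),
                p_values = as.list(m$p_values),
                vif = as.list(m$vif), r2 = m$r2, adj_r2 = m$adj_r2,
                contributions = as.list(m$contributions),
                random_variance = m$random_variance, mixed = m$mixed,
                n = m$n)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"),
               file.path(out_dir, paste0("model_", g, ".json")))
  }
  writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d samples (%d outliers excluded)\n",
              nrow(x$fits), sum(x$fits$outlier)))
  for (g in names(x$models)) {
    m <- x$models[[g]]
    if (is.null(m)) next
    cat(sprintf("  %s model: %s (adj R^2 = %.3f)\n", g,
                if (length(m$predictors)) paste(m$predictors, collapse = " + ")
                else "(empty)", m$adj_r2))
  }
  invisible(x)
}
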