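#' Unloaded (traction-free) ring geometry
#'
#' Dimensions of the aortic segment in its unloaded reference configuration,
#' measured from cut rings after mechanical testing.
#'
#' @param D_i unloaded inner diameter, mm.
#' @param D_o unloaded outer diameter, mm.
#' @param L unloaded length, mm.
#' @return an object of class `unloaded_geometry`.
#' @export
unloaded_geometry <- function(D_i, D_o, L) {
  stopifnot(is.numeric(D_i), is.numeric(D_o), is.numeric(L),
            length(D_i) == 1, length(D_o) == 1, length(L) == 1)
  if (!is.finite(D_i) || !is.finite(D_o) || !is.finite(L)) {
    stop("geometry dimensions must be finite", call. = FALSE)
  }
  if (!(D_i > 0 && D_i < D_o)) {
    stop("require 0 < D_i < D_o, got D_i = ", D_i, ", D_o = ", D_o,
         call. = FALSE)
  }
  if (L <= 0) stop("unloaded length L must be positive", call. = FALSE)
  structure(list(D_i = D_i, D_o = D_o, L = L), class = "unloaded_geometry")
}

#' @export
print.unloaded_geometry <- function(x, ...) {
  cat(sprintf("Unloaded geometry: D_i = %.4g mm, D_o = %.4g mm, L = %.4g mm\n",
              x$D_i, x$D_o, x$L))
  invisible(x)
}

#' Per-sample metadata
#'
#' @param sample_id unique sample identifier.
#' @param animal_id animal identifier; the ascending (ASC) and descending
#'   (DSC) segments of one animal share it, which defines the repeated-
#'   measures structure used by the mixed models.
#' @param genotype `"WT"` (wildtype) or `"MU"` (Fbn1 mgR/mgR Marfan model).
#' @param vessel `"ASC"` or `"DSC"`.
#' @param age age in months, one of 1, 2, 3, 4.
#' @param sex `"M"` or `"F"`.
#' @param in_vivo_axial_stretch optional known in vivo axial stretch; `NA`
#'   means it is to be estimated from the force-pressure data.
#' @return an object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, animal_id, genotype, vessel, age, sex,
                        in_vivo_axial_stretch = NA_real_) {
  genotype <- match.arg(as.character(genotype), c("WT", "MU"))
  vessel <- match.arg(as.character(vessel), c("ASC", "DSC"))
  sex <- match.arg(as.character(sex), c("M", "F"))
  age <- as.integer(age)
  if (!age %in% 1:4) stop("age must be one of 1, 2, 3, 4 months", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 animal_id = as.character(animal_id),
                 genotype = genotype, vessel = vessel, age = age, sex = sex,
                 in_vivo_axial_stretch = as.numeric(in_vivo_axial_stretch)),
            class = "sample_meta")
}

trace_columns <- c("t", "P", "d_o", "lambda_z", "f")

#' A single test-protocol trace
#'
#' One protocol's time series of luminal pressure, outer diameter, axial
#' stretch and axial force. Six protocols are acquired per sample: three
#' inflation protocols (pressure ramps at fixed axial stretch) and three
#' axial protocols (stretch sweeps at fixed pressure).
#'
#' @param data data.frame with columns `t` (s), `P` (kPa), `d_o` (mm),
#'   `lambda_z` (dimensionless axial stretch), `f` (mN).
#' @param kind `"inflation"` or `"axial"`; determines which of (`P`,
#'   `lambda_z`) is the driven variable.
#' @param fixed_value the held variable: the fixed axial stretch for an
#'   inflation protocol, the fixed pressure (kPa) for an axial protocol.
#' @param sample_id sample the trace belongs to.
#' @param protocol_id short label, e.g. `"inflation_2"`.
#' @param cycle optional integer vector (same length as `data` rows)
#'   annotating detected cycles after segmentation.
#' @return an object of class `protocol_trace`.
#' @export
protocol_trace <- function(data, kind, fixed_value, sample_id = NA_character_,
                           protocol_id = NA_character_, cycle = NULL) {
  kind <- match.arg(kind, c("inflation", "axial"))
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(trace_columns, names(data))
  if (length(missing_cols)) {
    stop("trace data missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("trace has no records", call. = FALSE)
  for (col in trace_columns) {
    if (!is.numeric(data[[col]]) || any(!is.finite(data[[col]]))) {
      stop("trace column '", col, "' must be finite numeric", call. = FALSE)
    }
  }
  if (any(data$P < 0)) stop("pressures must be non-negative", call. = FALSE)
  if (any(data$d_o <= 0)) stop("outer diameters must be positive", call. = FALSE)
  if (any(data$lambda_z <= 0)) stop("axial stretches must be positive", call. = FALSE)
  structure(list(data = data[trace_columns], kind = kind,
                 fixed_value = as.numeric(fixed_value),
                 sample_id = as.character(sample_id),
                 protocol_id = as.character(protocol_id),
                 cycle = cycle),
            class = "protocol_trace")
}

#' @export
print.protocol_trace <- function(x, ...) {
  cat(sprintf("Protocol trace [%s] %s: %d records, fixed %s = %.4g\n",
              x$protocol_id, x$kind, nrow(x$data),
              if (x$kind == "inflation") "lambda_z" else "P (kPa)",
              x$fixed_value))
  invisible(x)
}

# driven variable name for a protocol kind
driven_variable <- function(trace) {
  if (trace$kind == "inflation") "P" else "lambda_z"
}

#' Constitutive parameters of the two-fiber-family HGO model
#'
#' The strain-energy density is W = Wiso + Wani with a Neo-Hookean matrix
#' Wiso = (c/2)(I1 - 3) and two symmetric exponential fiber families at
#' +/- alpha from the circumferential direction,
#' Wani = sum_j (k1 / 2 k2) (exp(k2 (I4j - 1)^2) - 1).
#'
#' @param c isotropic elastic modulus-like parameter, kPa.
#' @param k1 anisotropic elastic modulus-like parameter, kPa.
#' @param k2 dimensionless fiber nonlinearity parameter.
#' @param alpha fiber-family angle from the circumferential direction,
#'   degrees, in `[0, 90]`.
#' @param strict if `TRUE` (default) enforce strictly positive `c`, `k1`,
#'   `k2`; `strict = FALSE` additionally admits `k1 = 0` / `k2 = 0`
#'   (pure Neo-Hookean limits) for closed-form checks.
#' @return an object of class `hgo_parameters`.
#' @export
hgo_parameters <- function(c, k1, k2, alpha, strict = TRUE) {
  vals <- c(c = c, k1 = k1, k2 = k2, alpha = alpha)
  if (any(!is.finite(vals))) stop("parameters must be finite", call. = FALSE)
  lower_ok <- if (strict) all(c > 0, k1 > 0, k2 > 0) else all(c > 0, k1 >= 0, k2 >= 0)
  if (!lower_ok) {
    stop("require c > 0, k1 > 0, k2 > 0 (k1, k2 >= 0 when strict = FALSE)",
         call. = FALSE)
  }
  if (alpha < 0 || alpha > 90) {
    stop("alpha must lie in [0, 90] degrees", call. = FALSE)
  }
  structure(list(c = as.numeric(c), k1 = as.numeric(k1), k2 = as.numeric(k2),
                 alpha = as.numeric(alpha)),
            class = "hgo_parameters")
}

#' @export
print.hgo_parameters <- function(x, ...) {
  cat(sprintf("HGO parameters: c = %.4g kPa, k1 = %.4g kPa, k2 = %.4g, alpha = %.4g deg\n",
              x$c, x$k1, x$k2, x$alpha))
  invisible(x)
}

#' Serialize HGO parameters to JSON (with units)
#'
#' @param params an `hgo_parameters` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
hgo_params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "hgo_parameters"))
  obj <- list(model = "HGO-2-fiber-family",
              parameters = list(c = params$c, k1 = params$k1,
                                k2 = params$k2, alpha = params$alpha),
              units = list(c = "kPa", k1 = "kPa", k2 = "dimensionless",
                           alpha = "degrees"))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @rdname hgo_params_to_json
#' @param json a JSON string or file path produced by [hgo_params_to_json()].
#' @export
hgo_params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  p <- obj$parameters
  hgo_parameters(c = p$c, k1 = p$k1, k2 = p$k2, alpha = p$alpha)
}
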