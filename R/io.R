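#' Trace file schema
#'
#' Describes the CSV dialect of raw myograph exports: column names and the
#' units they are recorded in. The reader normalizes everything to internal
#' units (kPa, mm, mN, s); the writer emits the same dialect so that
#' write-then-read round-trips exactly.
#'
#' The axial coordinate may be recorded either as a loaded length (mm), in
#' which case the unloaded length `L` must be supplied to the reader to form
#' the stretch, or directly as a stretch ratio.
#'
#' @param time_col,pressure_col,diameter_col,axial_col,force_col column names.
#' @param pressure_unit `"mmHg"` or `"kPa"`.
#' @param diameter_unit `"mm"` or `"um"`.
#' @param axial_kind `"stretch"` (dimensionless ratio) or `"length"` (mm).
#' @return an object of class `trace_schema`.
#' @export
trace_schema <- function(time_col = "time_s", pressure_col = "pressure",
                         diameter_col = "outer_diameter", axial_col = "axial",
                         force_col = "force_mN",
                         pressure_unit = c("mmHg", "kPa"),
                         diameter_unit = c("mm", "um"),
                         axial_kind = c("stretch", "length")) {
  structure(list(time_col = time_col, pressure_col = pressure_col,
                 diameter_col = diameter_col, axial_col = axial_col,
                 force_col = force_col,
                 pressure_unit = match.arg(pressure_unit),
                 diameter_unit = match.arg(diameter_unit),
                 axial_kind = match.arg(axial_kind)),
            class = "trace_schema")
}

#' Read or write a trace schema as YAML
#' @param path file path.
#' @export
read_trace_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(trace_schema, cfg)
}

#' @rdname read_trace_schema
#' @param schema a `trace_schema` object.
#' @export
write_trace_schema <- function(schema, path) {
  yaml::write_yaml(unclass(schema), path)
  invisible(path)
}

#' Read one protocol trace from a delimited text file
#'
#' @param path CSV file with a header row matching the schema's column names.
#' @param kind `"inflation"` or `"axial"`.
#' @param fixed_value the protocol's held variable (axial stretch for
#'   inflation, pressure for axial protocols, in the schema's pressure unit).
#' @param schema a [trace_schema()] describing the dialect.
#' @param L unloaded length (mm), required when `axial_kind = "length"`.
#' @param sample_id,protocol_id identifiers attached to the trace.
#' @return a [protocol_trace()].
#' @export
read_protocol_trace <- function(path, kind, fixed_value,
                                schema = trace_schema(), L = NULL,
                                sample_id = NA_character_,
                                protocol_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty trace file: ", path, call. = FALSE)
  needed <- c(schema$time_col, schema$pressure_col, schema$diameter_col,
              schema$axial_col, schema$force_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("trace file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- lapply(needed, function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      # +1 for header row: report the file line number of the first offender
      stop("non-numeric value in column '", col, "' of ", path,
           " at line ", bad[1] + 1L, ": '", x[bad[1]], "'", call. = FALSE)
    }
    v
  })
  names(num) <- c("t", "P", "d_o", "axial", "f")
  P <- if (schema$pressure_unit == "mmHg") mmhg_to_kpa(num$P) else num$P
  d_o <- if (schema$diameter_unit == "um") um_to_mm(num$d_o) else num$d_o
  lambda_z <- if (schema$axial_kind == "stretch") {
    num$axial
  } else {
    if (is.null(L)) {
      stop("schema records loaded length; supply the unloaded length L",
           call. = FALSE)
    }
    num$axial / L
  }
  fixed <- if (kind == "axial" && schema$pressure_unit == "mmHg") {
    mmhg_to_kpa(fixed_value)
  } else {
    fixed_value
  }
  protocol_trace(data.frame(t = num$t, P = P, d_o = d_o,
                            lambda_z = lambda_z, f = num$f),
                 kind = kind, fixed_value = fixed,
                 sample_id = sample_id, protocol_id = protocol_id)
}

#' Write a protocol trace in a given CSV dialect
#'
#' Inverse of [read_protocol_trace()]: units are converted back to the
#' schema's units so that write-then-read reproduces the trace.
#'
#' @param trace a [protocol_trace()].
#' @param path output CSV path.
#' @param schema a [trace_schema()].
#' @param L unloaded length (mm), required when `axial_kind = "length"`.
#' @export
write_protocol_trace <- function(trace, path, schema = trace_schema(),
                                 L = NULL) {
  stopifnot(inherits(trace, "protocol_trace"))
  d <- trace$data
  out <- data.frame(
    a = d$t,
    b = if (schema$pressure_unit == "mmHg") kpa_to_mmhg(d$P) else d$P,
    c = if (schema$diameter_unit == "um") d$d_o * 1000 else d$d_o,
    d = if (schema$axial_kind == "stretch") d$lambda_z else {
      if (is.null(L)) stop("supply L to write loaded lengths", call. = FALSE)
      d$lambda_z * L
    },
    e = d$f)
  names(out) <- c(schema$time_col, schema$pressure_col, schema$diameter_col,
                  schema$axial_col, schema$force_col)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' One row per sample with metadata, unloaded geometry, and the six trace
#' file paths (columns `trace_1` .. `trace_6` relative to the manifest's
#' directory, with matching `kind_1..6` and `fixed_1..6` columns).
#'
#' @param path manifest CSV path.
#' @return data.frame with one row per sample.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  # sex codes "F"/"T" must not be parsed as logicals
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character",
                                      animal_id = "character",
                                      sex = "character"))
  needed <- c("sample_id", "animal_id", "genotype", "vessel", "age", "sex",
              "D_i", "D_o", "L")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m
}
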