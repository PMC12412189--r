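#' Pressure unit conversion
#'
#' Internal units throughout the package are mm, mN, kPa and seconds, so that
#' mN/mm^2 = kPa and stresses, moduli and strain-energy densities share one
#' unit (1 kPa = 1 kJ/m^3). Myograph hardware reports luminal pressure in
#' mmHg; these helpers convert at ingest using the standard definition
#' 1 mmHg = 101.325/760 kPa.
#'
#' @param p numeric vector of pressures.
#' @return numeric vector of converted pressures.
#' @examples
#' mmhg_to_kpa(100)           # 13.33224
#' kpa_to_mmhg(mmhg_to_kpa(150))  # 150, to machine precision
#' @export
mmhg_to_kpa <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("pressure must be finite numeric", call. = FALSE)
  }
  p * (101.325 / 760)
}

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("pressure must be finite numeric", call. = FALSE)
  }
  p * (760 / 101.325)
}

#' General pressure conversion between mmHg and kPa
#'
#' @param p numeric vector of pressures.
#' @param from,to unit names, each one of `"mmHg"` or `"kPa"`.
#' @return numeric vector in the `to` unit.
#' @export
convert_pressure <- function(p, from = "mmHg", to = "kPa") {
  from <- match.arg(from, c("mmHg", "kPa"))
  to <- match.arg(to, c("mmHg", "kPa"))
  if (from == to) {
    if (!is.numeric(p) || any(!is.finite(p))) {
      stop("pressure must be finite numeric", call. = FALSE)
    }
    return(p)
  }
  if (from == "mmHg") mmhg_to_kpa(p) else kpa_to_mmhg(p)
}

# micrometre -> millimetre, for diameter columns recorded in um
um_to_mm <- function(x) x / 1000
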