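#' Unit conversion: mmHg to MPa
#'
#' The model works in a consistent mm--N--MPa unit system. Clinical
#' intraocular pressure (IOP) is quoted in mmHg; internally it is applied as
#' a pressure in MPa. One mmHg is 101325/760 Pa = 133.3224 Pa, i.e.
#' 1.333224e-4 MPa, so 20 mmHg corresponds to 2.66645 kPa.
#'
#' @param mmhg pressure in millimetres of mercury
#' @return pressure in MPa
#' @examples
#' mmhg_to_mpa(20) * 1e3  # kPa
#' @export
mmhg_to_mpa <- function(mmhg) {
  stopifnot(is.numeric(mmhg))
  mmhg * 1.333224e-4
}

#' @rdname mmhg_to_mpa
#' @param mpa pressure in MPa
#' @export
mpa_to_mmhg <- function(mpa) mpa / 1.333224e-4
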