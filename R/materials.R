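#' Isotropic linear-elastic material
#'
#' Small-strain isotropic material described by Young's modulus and Poisson's
#' ratio, with derived bulk and shear moduli. Density is carried for
#' completeness but unused in the static analysis.
#'
#' @param young_modulus Young's modulus E in MPa (> 0)
#' @param poisson_ratio Poisson's ratio, in (0, 0.5)
#' @param density density in kg/mm^3 (informational only)
#' @param name optional label
#' @return an object of class `isotropic_material` with fields
#'   `young_modulus`, `poisson_ratio`, `bulk_modulus` (= E/(3(1-2v))),
#'   `shear_modulus` (= E/(2(1+v))), `lambda` and `mu` (Lame constants),
#'   `density`, `name`
#' @examples
#' isotropic_material(0.2, 0.43)$shear_modulus  # 0.06993 MPa
#' @export
isotropic_material <- function(young_modulus, poisson_ratio,
                               density = NA_real_, name = NULL) {
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1L,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1L)
  if (!(young_modulus > 0))
    stop("young_modulus must be > 0")
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5))
    stop("poisson_ratio must lie in (0, 0.5)")
  E <- young_modulus; nu <- poisson_ratio
  out <- list(
    young_modulus = E,
    poisson_ratio = nu,
    bulk_modulus  = E / (3 * (1 - 2 * nu)),
    shear_modulus = E / (2 * (1 + nu)),
    lambda        = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu            = E / (2 * (1 + nu)),
    density       = density,
    name          = if (is.null(name)) NA_character_ else name
  )
  class(out) <- "isotropic_material"
  out
}

#' @export
print.isotropic_material <- function(x, ...) {
  cat(sprintf("<isotropic_material%s> E = %g MPa, nu = %g, K = %g MPa, G = %g MPa\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$young_modulus, x$poisson_ratio, x$bulk_modulus, x$shear_modulus))
  invisible(x)
}

#' Ocular tissue material presets
#'
#' Literature values for the two modelled tissues: cornea E = 0.2 MPa,
#' nu = 0.43; sclera E = 2 MPa, nu = 0.4. Densities 9.6e-7 kg/mm^3 are
#' carried but unused (static analysis). The corneoscleral junction band is
#' given scleral material by default.
#'
#' @return an `isotropic_material`
#' @export
cornea_material <- function()
  isotropic_material(0.2, 0.43, density = 9.6e-7, name = "cornea")

#' @rdname cornea_material
#' @export
sclera_material <- function()
  isotropic_material(2, 0.4, density = 9.6e-7, name = "sclera")

#' Region-to-material map for the default eye
#'
#' Maps the nine mesh region tags (1 cornea, 4 sclera quadrants, 4 junction
#' quadrants) to materials. Junction regions default to scleral material;
#' only two tissue property sets are modelled.
#'
#' @param cornea,sclera,junction `isotropic_material` objects
#' @return named list region tag -> material
#' @export
eye_materials <- function(cornea = cornea_material(),
                          sclera = sclera_material(),
                          junction = sclera) {
  quads <- c("superior", "inferior", "nasal", "temporal")
  out <- c(list(cornea = cornea),
           stats::setNames(rep(list(sclera), 4), paste0("sclera-", quads)),
           stats::setNames(rep(list(junction), 4), paste0("junction-", quads)))
  out
}
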