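# Closed-form oracles and the convergence suite that gate the FEM and
# contact implementations independently of any reference simulation
# numbers: a pressurized spherical shell (thin-wall and Lame forms) and the
# Boussinesq rigid flat punch on an elastic half-space.

#' Pressurized spherical shell closed forms
#'
#' Thin-wall membrane solution: hoop stress sigma = pR/(2t) and radial
#' expansion u = pR^2(1-nu)/(2tE); for t >= R/5 (or on request) the exact
#' Lame thick-shell solution is used, evaluated at the inner surface.
#'
#' @param R mid-surface radius (mm)
#' @param t wall thickness (mm)
#' @param p internal pressure (MPa)
#' @param material an [isotropic_material()] (needed for the expansion)
#' @param form "auto", "thin" or "lame"
#' @return list with `hoop_stress` (MPa), `radial_expansion` (mm), `form`
#' @export
sphere_pressure_oracle <- function(R, t, p, material = sclera_material(),
                                   form = c("auto", "thin", "lame")) {
  form <- match.arg(form)
  stopifnot(t > 0, R > t / 2)
  if (form == "auto") form <- if (t < R / 5) "thin" else "lame"
  E <- material$young_modulus; nu <- material$poisson_ratio
  if (form == "thin") {
    list(hoop_stress = p * R / (2 * t),
         radial_expansion = p * R^2 * (1 - nu) / (2 * t * E),
         form = "thin")
  } else {
    a <- R - t / 2; b <- R + t / 2
    # Lame: tangential stress and radial displacement at the inner surface
    sig <- p * a^3 * (b^3 + 2 * a^3) / (2 * a^3 * (b^3 - a^3))
    u <- p * a^3 * a / (E * (b^3 - a^3)) *
      ((1 - 2 * nu) + (1 + nu) * b^3 / (2 * a^3))
    list(hoop_stress = sig, radial_expansion = u, form = "lame")
  }
}

#' Boussinesq rigid flat-punch force
#'
#' Closed-form indentation force of a rigid flat-ended cylinder of radius
#' `a` pressed a depth `depth` into an elastic half-space:
#' F = 2 a E depth / (1 - nu^2).
#'
#' @param a punch radius (mm)
#' @param E Young's modulus (MPa)
#' @param nu Poisson's ratio
#' @param depth indentation depth (mm)
#' @return force in N
#' @export
flat_punch_oracle <- function(a, E, nu, depth) {
  stopifnot(a > 0, depth >= 0)
  2 * a * E * depth / (1 - nu^2)
}

# FE hoop stress of a meshed pressurized sphere: element tangential stresses
# averaged per through-thickness layer and linearly extrapolated to the
# inner surface (surface stress recovery)
fe_sphere_hoop <- function(mesh, rec, R, t) {
  el <- mesh$elems
  ne <- nrow(el)
  ctr <- cbind(rowMeans(matrix(mesh$nodes[el, 1], ne, 8)),
               rowMeans(matrix(mesh$nodes[el, 2], ne, 8)),
               rowMeans(matrix(mesh$nodes[el, 3], ne, 8)))
  C <- c(R + t / 2, 0, 0)
  rv <- sweep(ctr, 2, C)
  rn <- sqrt(rowSums(rv^2)); rh <- rv / rn
  S <- rec$stress
  srr <- rh[, 1]^2 * S[, 1] + rh[, 2]^2 * S[, 2] + rh[, 3]^2 * S[, 3] +
    2 * (rh[, 1] * rh[, 2] * S[, 4] + rh[, 2] * rh[, 3] * S[, 5] +
         rh[, 1] * rh[, 3] * S[, 6])
  hoop <- (S[, 1] + S[, 2] + S[, 3] - srr) / 2
  nT <- mesh$resolution$n_thickness
  lay <- cut(rn, breaks = seq(R - t / 2, R + t / 2, length.out = nT + 1),
             include.lowest = TRUE)
  mh <- as.vector(tapply(hoop, lay, mean))
  mr <- as.vector(tapply(rn, lay, mean))
  cf <- stats::coef(stats::lm(mh ~ mr))
  unname(cf[1] + cf[2] * (R - t / 2))
}

#' Run the verification suite
#'
#' Solves the two oracle cases at each listed resolution and tabulates the
#' observed vs closed-form values. The suite is the pre-gate of the
#' pipeline: tonometry results are only meaningful when every oracle passes
#' at the preset resolution. Default tolerances: 2% for the sphere hoop
#' stress (vs the thin-wall value pR/(2t)), 5% for the flat-punch force.
#'
#' @param sphere_resolutions list of c(n_azimuth, n_meridian, n_thickness)
#' @param block_resolution c(n_side, n_depth) for the punch fixture
#' @param sphere_tol,punch_tol relative tolerances
#' @return data.frame of class `verification_report` with one row per case
#'   and resolution: case, resolution, observed, expected, rel_error, tol,
#'   pass
#' @export
run_verification_suite <- function(sphere_resolutions = list(c(16, 16, 2),
                                                             c(24, 24, 2),
                                                             c(48, 48, 3)),
                                   block_resolution = c(28, 12),
                                   sphere_tol = 0.02, punch_tol = 0.05) {
  R <- 11.2; t <- 0.317; p <- mmhg_to_mpa(20)
  mat <- sclera_material()
  rows <- list()
  shell <- make_sphere_fixture(R, t)
  exp_sphere <- sphere_pressure_oracle(R, t, p, mat, "thin")$hoop_stress
  for (i in seq_along(sphere_resolutions)) {
    res <- sphere_resolutions[[i]]
    mesh <- sweep_shell_mesh(shell, res[1], res[2], res[3])
    sys <- assemble_stiffness(mesh, list(sphere = mat))
    f <- apply_internal_pressure(mesh, p)
    sys <- apply_remote_displacement_zero(sys, mesh, "remote-rigid-body")
    u <- solve_displacement(sys, f)
    rec <- recover_stress(mesh, list(sphere = mat), u)
    obs <- fe_sphere_hoop(mesh, rec, R, t)
    gate <- i == length(sphere_resolutions) # tolerance applies at the
    # finest listed resolution; coarser rows document convergence
    rows[[length(rows) + 1L]] <- data.frame(
      case = "sphere_pressure_hoop",
      resolution = paste(res, collapse = "x"),
      observed = obs, expected = exp_sphere,
      rel_error = abs(obs / exp_sphere - 1),
      tol = if (gate) sphere_tol else NA_real_,
      pass = if (gate) abs(obs / exp_sphere - 1) < sphere_tol else NA)
  }

  E <- 0.2; nu <- 0.43; a <- 0.85; depth <- 0.1
  fx <- make_block_fixture(20, 20)
  bm <- block_mesh(fx, block_resolution[1], block_resolution[2])
  lc <- load_case(iop = 0, probe = probe_spec(2 * a), target_depth = depth,
                  n_increments = 1)
  res_p <- solve_indentation(bm, list(block = isotropic_material(E, nu)), lc)
  exp_punch <- flat_punch_oracle(a, E, nu, depth)
  rows[[length(rows) + 1L]] <- data.frame(
    case = "flat_punch_force",
    resolution = paste(block_resolution, collapse = "x"),
    observed = res_p$reaction_force, expected = exp_punch,
    rel_error = abs(res_p$reaction_force / exp_punch - 1), tol = punch_tol,
    pass = abs(res_p$reaction_force / exp_punch - 1) < punch_tol)

  out <- do.call(rbind, rows)
  class(out) <- c("verification_report", "data.frame")
  out
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report>\n")
  df <- as.data.frame(x)
  df$observed <- signif(df$observed, 5)
  df$expected <- signif(df$expected, 5)
  df$rel_error <- sprintf("%.2f%%", 100 * df$rel_error)
  print(df, row.names = FALSE)
  if (all(x$pass, na.rm = TRUE)) cat("all oracle gates PASS\n")
  else cat(sprintf("%d gate(s) FAIL\n", sum(!x$pass, na.rm = TRUE)))
  invisible(x)
}
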