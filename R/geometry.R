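# Parametric construction of the asymmetric cornea-sclera shell and of the
# simplified analytic verification fixtures. Coordinate convention: origin at
# the corneal apex (outer surface), +X toward the posterior pole, lengths mm.
# Azimuth: nasal 0 deg (+Y), superior 90 deg (+Z), temporal 180, inferior 270.

QUADRANTS <- c("superior", "inferior", "nasal", "temporal")
QUADRANT_AZIMUTH <- c(superior = pi / 2, inferior = 3 * pi / 2,
                      nasal = 0, temporal = pi)

#' Ocular geometry parameters
#'
#' All dimensions of the parametric eye model, in mm (angles in degrees).
#' Defaults are literature values for the adult human eye. The four
#' corneoscleral junction angles give the model its quadrant asymmetry.
#'
#' @param corneal_anterior_radius anterior corneal radius of curvature (mm)
#' @param corneal_central_thickness corneal thickness at the apex (mm)
#' @param corneal_peripheral_thickness corneal thickness at the limbus (mm)
#' @param scleral_radius scleral radius of curvature (mm)
#' @param scleral_thickness scleral wall thickness (mm)
#' @param choroidal_thickness choroid thickness (mm), only used when
#'   `include_choroid_in_wall` is TRUE
#' @param axial_length apex-to-posterior-pole outer distance (mm)
#' @param corneal_base_radius semi-diameter of the corneal base (limbus
#'   ring) in mm; the default 5.85 is the anatomical white-to-white corneal
#'   semi-diameter. Must be smaller than the corneal radius of curvature.
#' @param junction_angle_superior,junction_angle_inferior,junction_angle_nasal,junction_angle_temporal
#'   interior corneoscleral junction angle per quadrant (degrees, in
#'   (160, 180])
#' @param include_choroid_in_wall add the choroidal thickness to the scleral
#'   wall (scleral material)? Default FALSE: the wall is cornea and sclera
#'   only.
#' @return an object of class `ocular_geometry_params`
#' @export
ocular_geometry_params <- function(corneal_anterior_radius = 7.75,
                                   corneal_central_thickness = 0.52,
                                   corneal_peripheral_thickness = 0.67,
                                   scleral_radius = 11.2,
                                   scleral_thickness = 0.317,
                                   choroidal_thickness = 0.298,
                                   axial_length = 22.7,
                                   corneal_base_radius = 5.85,
                                   junction_angle_superior = 178.1,
                                   junction_angle_inferior = 177.7,
                                   junction_angle_nasal = 173.9,
                                   junction_angle_temporal = 177.0,
                                   include_choroid_in_wall = FALSE) {
  p <- list(corneal_anterior_radius = corneal_anterior_radius,
            corneal_central_thickness = corneal_central_thickness,
            corneal_peripheral_thickness = corneal_peripheral_thickness,
            scleral_radius = scleral_radius,
            scleral_thickness = scleral_thickness,
            choroidal_thickness = choroidal_thickness,
            axial_length = axial_length,
            corneal_base_radius = corneal_base_radius,
            junction_angle_superior = junction_angle_superior,
            junction_angle_inferior = junction_angle_inferior,
            junction_angle_nasal = junction_angle_nasal,
            junction_angle_temporal = junction_angle_temporal,
            include_choroid_in_wall = isTRUE(include_choroid_in_wall))
  lens <- c("corneal_anterior_radius", "corneal_central_thickness",
            "corneal_peripheral_thickness", "scleral_radius",
            "scleral_thickness", "choroidal_thickness", "axial_length")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !(p[[nm]] > 0))
      stop(sprintf("'%s' must be a single positive length", nm))
  angs <- paste0("junction_angle_", QUADRANTS)
  for (nm in angs)
    if (!(p[[nm]] > 160 && p[[nm]] <= 180))
      stop(sprintf("'%s' must lie in (160, 180] degrees", nm))
  if (p$corneal_peripheral_thickness < p$corneal_central_thickness)
    stop("corneal_peripheral_thickness must be >= corneal_central_thickness")
  if (p$axial_length <= p$corneal_anterior_radius)
    stop("axial_length must exceed corneal_anterior_radius")
  if (!(p$corneal_base_radius > 0 &&
        p$corneal_base_radius < p$corneal_anterior_radius))
    stop("corneal_base_radius must lie in (0, corneal_anterior_radius)")
  class(p) <- "ocular_geometry_params"
  p
}

#' @export
print.ocular_geometry_params <- function(x, ...) {
  cat("<ocular_geometry_params>\n")
  cat(sprintf("  cornea: R = %g mm, thickness %g (central) - %g (peripheral) mm\n",
              x$corneal_anterior_radius, x$corneal_central_thickness,
              x$corneal_peripheral_thickness))
  cat(sprintf("  sclera: R = %g mm, thickness %g mm; axial length %g mm\n",
              x$scleral_radius, x$scleral_thickness, x$axial_length))
  cat(sprintf("  junction angles (deg): S %g, I %g, N %g, T %g\n",
              x$junction_angle_superior, x$junction_angle_inferior,
              x$junction_angle_nasal, x$junction_angle_temporal))
  cat(sprintf("  choroid in wall: %s\n", x$include_choroid_in_wall))
  invisible(x)
}

#' Rigid tonometer probe specification
#'
#' A rigid flat-ended cylindrical probe advanced along the apex axis (+X,
#' from the cornea centre toward the sclera). The probe is never meshed: it
#' is an analytic contact surface (its modulus is ~1e6 times the corneal
#' modulus, so treating it as rigid is exact to rounding).
#'
#' @param diameter probe diameter in mm (default 1.7, the standard probe;
#'   Goldmann applanation uses 3.06)
#' @param edge_fillet_radius optional rim fillet radius in mm (< diameter/2);
#'   0 gives the ideal sharp-rimmed flat punch
#' @param axis unit vector of probe travel (only the +X default is exercised
#'   by the pipeline)
#' @param tip_shape only "flat" is supported
#' @return an object of class `probe_spec`
#' @export
probe_spec <- function(diameter = 1.7, edge_fillet_radius = 0,
                       axis = c(1, 0, 0), tip_shape = "flat") {
  if (!(is.numeric(diameter) && length(diameter) == 1L && diameter > 0))
    stop("probe diameter must be a single positive number")
  if (!(edge_fillet_radius >= 0 && edge_fillet_radius < diameter / 2))
    stop("edge_fillet_radius must be in [0, diameter/2)")
  tip_shape <- match.arg(tip_shape, "flat")
  axis <- as.numeric(axis)
  if (length(axis) != 3L || abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("axis must be a 3-component unit vector")
  structure(list(diameter = diameter, radius = diameter / 2,
                 edge_fillet_radius = edge_fillet_radius,
                 axis = axis, tip_shape = tip_shape),
            class = "probe_spec")
}

#' @rdname probe_spec
#' @param name one of "standard" (1.7 mm), "goldmann" (3.06 mm),
#'   "validation" (2.0 mm)
#' @export
probe_preset <- function(name = c("standard", "goldmann", "validation")) {
  name <- match.arg(name)
  probe_spec(diameter = switch(name, standard = 1.7, goldmann = 3.06,
                               validation = 2.0))
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> flat cylinder, diameter %g mm, fillet %g mm\n",
              x$diameter, x$edge_fillet_radius))
  invisible(x)
}

# Canonical meridian parameter: u in [0,1], junction kink at u = U_JUNCTION
# (cornea gets 45% of the parameter range so that a structured sweep puts
# enough meridional divisions under the probe).
U_JUNCTION <- 0.45
JUNCTION_BAND_HALF_WIDTH <- 0.75 # mm of arc length either side of the kink

#' Build one meridian (quadrant) profile of the eye shell
#'
#' Constructs the 2-D outer and inner wall polylines of the eye in the
#' meridian plane of one quadrant. The anterior cornea is a circular arc of
#' the given radius; it meets the sclera at the limbus with the quadrant's
#' printed interior junction angle, imposed as a tangent kink; the scleral
#' curve is the nominal scleral sphere (closing the globe to the axial
#' length, pole on the axis) carrying a smooth cubic polar-radius
#' perturbation that realises the kink angle exactly while keeping the
#' posterior pole position and its perpendicular tangent. The radii, axial
#' length and the four junction angles over-determine a two-arc meridian, so
#' the perturbation (at most a few percent of the scleral radius) is what
#' absorbs the quadrant asymmetry.
#'
#' @param params an [ocular_geometry_params()] object
#' @param quadrant one of "superior", "inferior", "nasal", "temporal"
#' @return an object of class `meridian_profile` with sampled `outer` and
#'   `inner` polylines (columns x, r in mm), `junction_index` into them, and
#'   analytic evaluators used by [loft_eye_surface()]
#' @export
build_meridian_profile <- function(params, quadrant = QUADRANTS) {
  stopifnot(inherits(params, "ocular_geometry_params"))
  quadrant <- match.arg(quadrant)
  Ra <- params$corneal_anterior_radius
  AL <- params$axial_length
  r_L <- params$corneal_base_radius
  A_deg <- params[[paste0("junction_angle_", quadrant)]]

  # limbus point on the corneal arc
  phi_L <- asin(r_L / Ra)
  x_P <- Ra * (1 - cos(phi_L))
  r_P <- r_L
  if (AL <= x_P + r_P / 4)
    stop(sprintf(paste0("geometric infeasibility in quadrant '%s': axial ",
                        "length does not clear the corneal cap"), quadrant))
  # convex kink of (180 - angle) at the limbus, then an ellipse arc with
  # its vertex on the axis at the posterior pole (smooth pole, exact axial
  # length), tangent-matched to the post-kink direction at the limbus.
  delta_q <- (180 - A_deg) * pi / 180
  theta_c <- pi / 2 - phi_L            # corneal tangent angle at the limbus
  theta_s <- theta_c - delta_q         # post-kink tangent angle
  if (theta_s <= 0.02)
    stop(sprintf(paste0("geometric infeasibility in quadrant '%s': junction ",
                        "angle %g deg leaves no room for the scleral arc"),
                 quadrant, A_deg))
  D <- AL - x_P
  m <- tan(theta_s)
  # ellipse x = x0 + a cos(t), r = b sin(t), vertex t = 0 at the pole,
  # limbus at t = t_P in (pi/2, pi); tangent condition:
  # -r_P cos(t) (1 - cos(t)) / (D sin(t)^2) = tan(theta_s)
  fwt <- function(t) -r_P * cos(t) * (1 - cos(t)) / (D * sin(t)^2) - m
  lo <- pi / 2 + 1e-9; hi <- pi - 1e-6
  if (fwt(lo) * fwt(hi) > 0)
    stop(sprintf(paste0("geometric infeasibility in quadrant '%s': no ",
                        "scleral closure reaches the posterior pole at ",
                        "junction angle %g deg"), quadrant, A_deg))
  t_P <- stats::uniroot(fwt, c(lo, hi), tol = 1e-12)$root
  a_s <- D / (1 - cos(t_P))
  b_s <- r_P / sin(t_P)
  x0 <- AL - a_s
  if (abs(a_s - params$scleral_radius) > 0.2 * params$scleral_radius)
    stop(sprintf(paste0("geometric infeasibility in quadrant '%s': closure ",
                        "needs a scleral semi-axis of %.2f mm, more than ",
                        "20%% from the nominal scleral radius %.2f mm"),
                 quadrant, a_s, params$scleral_radius))

  uj <- U_JUNCTION
  grade_exp <- 1.5 # corneal meridian grading: finer parameter spacing at the apex
  outer_xr <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    cor <- u <= uj
    x <- r <- numeric(length(u))
    if (any(cor)) {
      phi <- (u[cor] / uj)^grade_exp * phi_L
      x[cor] <- Ra * (1 - cos(phi)); r[cor] <- Ra * sin(phi)
    }
    if (any(!cor)) {
      t <- t_P * (1 - (u[!cor] - uj) / (1 - uj))
      x[!cor] <- x0 + a_s * cos(t); r[!cor] <- b_s * sin(t)
    }
    cbind(x = x, r = r)
  }
  tangent_xr <- function(u, side = c("auto", "cornea", "sclera")) {
    side <- match.arg(side)
    u <- pmin(pmax(u, 0), 1)
    cor <- if (side == "cornea") rep(TRUE, length(u))
           else if (side == "sclera") rep(FALSE, length(u))
           else u <= uj
    tx <- tr <- numeric(length(u))
    if (any(cor)) {
      phi <- (pmin(u[cor], uj) / uj)^grade_exp * phi_L
      tx[cor] <- sin(phi); tr[cor] <- cos(phi)
    }
    if (any(!cor)) {
      t <- t_P * (1 - (pmax(u[!cor], uj) - uj) / (1 - uj))
      # traversal direction is decreasing t
      vx <- a_s * sin(t); vr <- -b_s * cos(t)
      nv <- sqrt(vx^2 + vr^2)
      tx[!cor] <- vx / nv; tr[!cor] <- vr / nv
    }
    cbind(tx = tx, tr = tr)
  }

  # arc length lookup on a dense grid
  ug <- seq(0, 1, length.out = 2001)
  pg <- outer_xr(ug)
  sg <- c(0, cumsum(sqrt(diff(pg[, 1])^2 + diff(pg[, 2])^2)))
  arc_of_u <- stats::approxfun(ug, sg, rule = 2)
  u_of_arc <- stats::approxfun(sg, ug, rule = 2)
  s_P <- arc_of_u(uj)
  s_total <- sg[length(sg)]
  bw <- JUNCTION_BAND_HALF_WIDTH

  t_scl <- params$scleral_thickness +
    if (params$include_choroid_in_wall) params$choroidal_thickness else 0
  tc0 <- params$corneal_central_thickness
  tc1 <- params$corneal_peripheral_thickness
  thickness_of_arc <- function(s) {
    s0 <- s_P - bw; s1 <- s_P + bw
    out <- numeric(length(s))
    a <- s <= s0
    out[a] <- tc0 + (tc1 - tc0) * pmax(s[a], 0) / s0
    b <- s > s0 & s < s1
    w <- (s[b] - s0) / (s1 - s0)
    out[b] <- tc1 + (t_scl - tc1) * (3 * w^2 - 2 * w^3)
    out[!a & !b] <- t_scl
    out
  }

  inner_xr <- function(u) {
    po <- outer_xr(u)
    th <- tangent_xr(u)
    tau <- thickness_of_arc(arc_of_u(u))
    # inward offset: material lies on -n_out side, n_out = rot90ccw(tangent)
    cbind(x = po[, 1] + tau * th[, 2], r = po[, 2] - tau * th[, 1])
  }

  # sampled polylines with the junction as an explicit vertex
  u_samp <- unique(c(seq(0, uj, length.out = 181),
                     seq(uj, 1, length.out = 221)))
  prof <- list(quadrant = quadrant,
               angle_deg = A_deg,
               outer = outer_xr(u_samp),
               inner = inner_xr(u_samp),
               u = u_samp,
               junction_index = 181L,
               outer_xr = outer_xr,
               inner_xr = inner_xr,
               tangent_xr = tangent_xr,
               arc_of_u = arc_of_u,
               u_of_arc = u_of_arc,
               thickness_of_arc = thickness_of_arc,
               phi_L = phi_L, t_limbus = t_P,
               scleral_semi_axes = c(axial = a_s, equatorial = b_s),
               scleral_centre_x = x0, s_junction = s_P,
               band_half_width = bw, arc_total = s_total,
               u_junction = uj, params = params)
  class(prof) <- "meridian_profile"
  prof
}

#' @export
print.meridian_profile <- function(x, ...) {
  cat(sprintf("<meridian_profile> %s quadrant, junction angle %g deg at arc %0.3f mm (of %0.3f mm)\n",
              x$quadrant, x$angle_deg, x$s_junction, x$arc_total))
  invisible(x)
}

#' Measured junction angle of a profile or lofted meridian
#'
#' Interior angle (degrees) between the outer-surface tangents just before
#' and just after the corneoscleral kink.
#'
#' @param outer_xr function(u) -> cbind(x, r) outer meridian evaluator
#' @param u_junction kink parameter
#' @param eps one-sided finite-difference offset in u
#' @return interior angle in degrees
#' @export
junction_angle <- function(outer_xr, u_junction = U_JUNCTION, eps = 1e-4) {
  p0 <- outer_xr(u_junction - eps); p1 <- outer_xr(u_junction)
  p2 <- outer_xr(u_junction + eps)
  t1 <- (p1 - p0); t2 <- (p2 - p1)
  t1 <- t1 / sqrt(sum(t1^2)); t2 <- t2 / sqrt(sum(t2^2))
  jump <- acos(pmin(1, pmax(-1, sum(t1 * t2))))
  180 - jump * 180 / pi
}

# trigonometric interpolation through values at azimuths 0, 90, 180, 270 deg
# (nasal, superior, temporal, inferior); exact at the key azimuths, smooth
# and periodic in between.
trig_weights <- function(theta) {
  cbind(nasal    = 0.25 + 0.5 * cos(theta) + 0.25 * cos(2 * theta),
        superior = 0.25 + 0.5 * sin(theta) - 0.25 * cos(2 * theta),
        temporal = 0.25 - 0.5 * cos(theta) + 0.25 * cos(2 * theta),
        inferior = 0.25 - 0.5 * sin(theta) - 0.25 * cos(2 * theta))
}

quadrant_of_theta <- function(theta) {
  th <- theta %% (2 * pi)
  ifelse(th < pi / 4, "nasal",
         ifelse(th < 3 * pi / 4, "superior",
                ifelse(th < 5 * pi / 4, "temporal",
                       ifelse(th < 7 * pi / 4, "inferior", "nasal"))))
}

#' Loft the four meridian profiles into a closed parametric shell
#'
#' Periodic trigonometric interpolation of the four quadrant profiles across
#' azimuth: the surface at each key azimuth reproduces its profile exactly,
#' and four identical profiles give a surface of revolution. The result is a
#' closed, watertight parametric shell evaluated by azimuth theta and
#' meridian parameter u (0 = anterior pole, 1 = posterior pole, kink at
#' u = 0.45).
#'
#' @param profiles list of the four [build_meridian_profile()] outputs
#'   (any order; quadrants must be complete)
#' @return an object of class `parametric_shell`
#' @export
loft_eye_surface <- function(profiles) {
  if (length(profiles) != 4L || !all(vapply(profiles, inherits, TRUE,
                                            "meridian_profile")))
    stop("need a list of four meridian_profile objects")
  quads <- vapply(profiles, function(p) p$quadrant, "")
  if (!setequal(quads, QUADRANTS))
    stop("profiles must cover superior, inferior, nasal, temporal")
  names(profiles) <- quads
  profiles <- profiles[c("nasal", "superior", "temporal", "inferior")]
  params <- profiles[[1]]$params

  eval_xr <- function(theta, u, surface = c("outer", "inner")) {
    surface <- match.arg(surface)
    stopifnot(length(theta) == length(u) || length(theta) == 1L ||
              length(u) == 1L)
    n <- max(length(theta), length(u))
    theta <- rep_len(theta, n); u <- rep_len(u, n)
    W <- trig_weights(theta)
    x <- r <- numeric(n)
    for (q in colnames(W)) {
      f <- if (surface == "outer") profiles[[q]]$outer_xr
           else profiles[[q]]$inner_xr
      pq <- f(u)
      x <- x + W[, q] * pq[, 1]
      r <- r + W[, q] * pq[, 2]
    }
    cbind(x = x, r = r)
  }
  eval_3d <- function(theta, u, surface = c("outer", "inner")) {
    pr <- eval_xr(theta, u, surface)
    cbind(x = pr[, 1], y = pr[, 2] * cos(theta), z = pr[, 2] * sin(theta))
  }

  # self-intersection / degeneracy scan
  thg <- seq(0, 2 * pi, length.out = 73)[-73]
  ugr <- seq(0, 1, length.out = 101)
  for (th in thg) {
    po <- eval_xr(rep(th, length(ugr)), ugr, "outer")
    pi_ <- eval_xr(rep(th, length(ugr)), ugr, "inner")
    thick <- sqrt(rowSums((po - pi_)^2))
    if (any(po[, 2] < -1e-9) || any(thick[-c(1, length(ugr))] < 0.05))
      stop(sprintf("self-intersecting loft at azimuth %.1f deg",
                   th * 180 / pi))
  }

  # region boundaries in u (cornea | junction band | sclera), per quadrant
  uj <- profiles[[1]]$u_junction
  u_cb <- profiles[[1]]$u_of_arc(profiles[[1]]$s_junction -
                                 profiles[[1]]$band_half_width)
  u_jb <- vapply(profiles, function(p)
    p$u_of_arc(p$s_junction + p$band_half_width), 0)

  region <- function(theta, u) {
    n <- max(length(theta), length(u))
    theta <- rep_len(theta, n); u <- rep_len(u, n)
    q <- quadrant_of_theta(theta)
    out <- character(n)
    cor <- u < u_cb
    out[cor] <- "cornea"
    jb <- u_jb[q]
    jn <- !cor & u <= jb
    out[jn] <- paste0("junction-", q[jn])
    scl <- !cor & !jn
    out[scl] <- paste0("sclera-", q[scl])
    out
  }
  surface_class <- function(theta, u) {
    r <- region(theta, u)
    ifelse(r == "cornea", "contact",
           ifelse(startsWith(r, "sclera"), "constraint", "none"))
  }

  shell <- list(type = "eye", profiles = profiles, params = params,
                eval_xr = eval_xr, eval_3d = eval_3d,
                region = region, surface_class = surface_class,
                u_junction = uj, u_cornea_band = u_cb, u_band_sclera = u_jb)
  class(shell) <- "parametric_shell"
  shell
}

#' @export
print.parametric_shell <- function(x, ...) {
  cat(sprintf("<parametric_shell> type '%s'\n", x$type))
  invisible(x)
}

#' Spherical-shell verification fixture
#'
#' Uniform-thickness spherical shell with the same parametric layout as the
#' eye shell (anterior outer pole at the origin, +X through the centre);
#' used to verify the pressure-vessel response against the thin-wall and
#' Lame closed forms.
#'
#' @param radius mid-surface radius (mm)
#' @param thickness wall thickness (mm), < radius
#' @return a `parametric_shell` of type "sphere"
#' @export
make_sphere_fixture <- function(radius, thickness) {
  stopifnot(radius > 0, thickness > 0)
  if (!(thickness < radius)) stop("thickness must be smaller than radius")
  Rout <- radius + thickness / 2
  Rin <- radius - thickness / 2
  cx <- Rout # centre on axis; outer anterior pole at x = 0
  eval_xr <- function(theta, u, surface = c("outer", "inner")) {
    surface <- match.arg(surface)
    n <- max(length(theta), length(u))
    u <- rep_len(u, n)
    a <- pi * pmin(pmax(u, 0), 1)
    R <- if (surface == "outer") Rout else Rin
    cbind(x = cx - R * cos(a), r = R * sin(a))
  }
  eval_3d <- function(theta, u, surface = c("outer", "inner")) {
    n <- max(length(theta), length(u))
    theta <- rep_len(theta, n)
    pr <- eval_xr(theta, u, surface)
    cbind(x = pr[, 1], y = pr[, 2] * cos(theta), z = pr[, 2] * sin(theta))
  }
  region <- function(theta, u) rep_len("sphere", max(length(theta), length(u)))
  surface_class <- function(theta, u) {
    n <- max(length(theta), length(u))
    ifelse(rep_len(u, n) < 0.5, "contact", "constraint")
  }
  shell <- list(type = "sphere", radius = radius, thickness = thickness,
                eval_xr = eval_xr, eval_3d = eval_3d, region = region,
                surface_class = surface_class, u_junction = NA_real_)
  class(shell) <- "parametric_shell"
  shell
}

#' Elastic-block verification fixture
#'
#' Rectangular solid with one free face (the contact face, at x = 0, facing
#' the probe) and the five far faces tagged for full constraint. Used as the
#' half-space fixture for the Boussinesq flat-punch contact oracle; the
#' block should be at least ~10 probe radii wide for the half-space
#' approximation to hold.
#'
#' @param side side length of the free face (mm)
#' @param depth block depth along +X (mm)
#' @return an object of class `block_fixture`
#' @export
make_block_fixture <- function(side, depth) {
  if (!(is.numeric(side) && length(side) == 1L && side > 0))
    stop("side must be a single positive length")
  if (!(is.numeric(depth) && length(depth) == 1L && depth > 0))
    stop("depth must be a single positive length")
  faces <- data.frame(
    name = c("contact", "xmax", "ymin", "ymax", "zmin", "zmax"),
    role = c("contact", rep("fixed", 5)),
    stringsAsFactors = FALSE)
  structure(list(type = "block", side = side, depth = depth, faces = faces),
            class = "block_fixture")
}

#' @export
print.block_fixture <- function(x, ...) {
  cat(sprintf("<block_fixture> %g x %g x %g mm, contact face at x = 0\n",
              x$side, x$side, x$depth))
  invisible(x)
}

#' Export a parametric shell surface as ASCII STL
#'
#' Triangulates the outer or inner surface on a structured azimuth-meridian
#' grid and writes an ASCII STL file for inspection in standard viewers.
#'
#' @param shell a `parametric_shell`
#' @param path output file path
#' @param surface "outer" or "inner"
#' @param n_azimuth,n_meridian sampling resolution
#' @return the path, invisibly
#' @export
write_stl <- function(shell, path, surface = c("outer", "inner"),
                      n_azimuth = 72, n_meridian = 60) {
  stopifnot(inherits(shell, "parametric_shell"))
  surface <- match.arg(surface)
  th <- seq(0, 2 * pi, length.out = n_azimuth + 1)
  uu <- seq(0, 1, length.out = n_meridian + 1)
  grid <- array(NA_real_, c(n_azimuth + 1, n_meridian + 1, 3))
  for (j in seq_along(uu))
    grid[, j, ] <- shell$eval_3d(th, rep(uu[j], length(th)), surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid shell", con)
  tri <- function(p1, p2, p3) {
    n <- pracma_cross(p2 - p1, p3 - p1)
    nn <- sqrt(sum(n^2)); if (nn < 1e-14) return(invisible(NULL))
    n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", p1[1], p1[2], p1[3]),
                 sprintf("    vertex %g %g %g", p2[1], p2[2], p2[3]),
                 sprintf("    vertex %g %g %g", p3[1], p3[2], p3[3]),
                 "  endloop", "endfacet"), con)
  }
  for (i in seq_len(n_azimuth))
    for (j in seq_len(n_meridian)) {
      p00 <- grid[i, j, ]; p10 <- grid[i + 1, j, ]
      p11 <- grid[i + 1, j + 1, ]; p01 <- grid[i, j + 1, ]
      tri(p00, p10, p11); tri(p00, p11, p01)
    }
  writeLines("endsolid shell", con)
  invisible(path)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
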