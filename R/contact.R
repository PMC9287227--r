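# Displacement-driven frictionless contact between the rigid flat-ended
# cylindrical probe and the corneal outer surface. The probe is an analytic
# surface (node-to-rigid-surface discretization, penalty regularization).
# Because the structure is linear(ized), each active-set re-solve is carried
# out exactly on the condensed flexibility of the candidate contact degrees
# of freedom (Woodbury identity), which is algebraically identical to
# re-solving the full penalized system at a fraction of the cost.

#' Load case for an indentation solve
#'
#' @param iop intraocular pressure in mmHg (>= 0); converted internally at
#'   1 mmHg = 1.333224e-4 MPa
#' @param probe a [probe_spec()]
#' @param target_depth plunging depth in mm (>= 0), measured as probe
#'   advance beyond first touch of the pressurized eye (so zero depth gives
#'   zero force at any IOP)
#' @param n_increments number of equal displacement increments (>= 1)
#' @param constraint_mode "remote-rigid-body" or "posterior-patch"
#' @return an object of class `load_case`
#' @export
load_case <- function(iop = 20, probe = probe_spec(), target_depth = 0.5,
                      n_increments = 10,
                      constraint_mode = c("remote-rigid-body",
                                          "posterior-patch")) {
  stopifnot(iop >= 0, target_depth >= 0, n_increments >= 1)
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(inherits(probe, "probe_spec"))
  structure(list(iop = iop, pressure = mmhg_to_mpa(iop), probe = probe,
                 target_depth = target_depth,
                 n_increments = as.integer(n_increments),
                 constraint_mode = constraint_mode),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("<load_case> IOP %g mmHg (%.4g kPa), probe %g mm, depth %g mm in %d increments, %s\n",
              x$iop, x$pressure * 1e3, x$probe$diameter, x$target_depth,
              x$n_increments, x$constraint_mode))
  invisible(x)
}

#' Signed gap between a surface point and the probe face
#'
#' Axial distance from a (displaced) point to the probe face, for points
#' within the probe radius of the axis; points outside the radius are not
#' contact candidates and get +Inf. Negative gap means the point lies
#' behind the face (penetration demand). The probe face sits at
#' x = probe_depth (plus the rim recession when a fillet is set).
#'
#' @param probe a [probe_spec()]
#' @param probe_depth face position along the axis (mm)
#' @param point n x 3 matrix (or length-3 vector) of point coordinates
#' @return signed gap(s) in mm
#' @export
probe_gap <- function(probe, probe_depth, point) {
  stopifnot(inherits(probe, "probe_spec"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  rad <- sqrt(point[, 2]^2 + point[, 3]^2)
  face <- probe_face_x(probe, probe_depth, rad)
  ifelse(is.na(face), Inf, point[, 1] - face)
}

# face axial position at radial offset rad; NA outside the probe radius
probe_face_x <- function(probe, probe_depth, rad) {
  a <- probe$radius; fr <- probe$edge_fillet_radius
  face <- rep(probe_depth, length(rad))
  if (fr > 0) {
    rim <- rad > (a - fr) & rad <= a
    face[rim] <- probe_depth -
      (fr - sqrt(pmax(fr^2 - (rad[rim] - (a - fr))^2, 0)))
  }
  face[rad > a] <- NA_real_
  face
}

# dense LCP with penalty regularization on the candidate flexibility:
# solve p >= 0, gap(p) = g0 + A p = -p/kp on the active set
contact_lcp <- function(A, g0, kp, active = NULL, tol = 1e-12,
                        max_iter = 100L) {
  m <- length(g0)
  if (is.null(active)) active <- which(g0 < 0)
  p <- numeric(m)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    if (iters > max_iter)
      stop(sprintf(paste0("contact active set failed to stabilize after %d ",
                          "iterations (last active set %d nodes, worst ",
                          "penetration %.3e mm)"),
                   max_iter, length(active), max(0, -min(g0 + A %*% p))))
    if (!length(active)) {
      p <- numeric(m)
      g <- g0
      if (all(g >= -tol)) return(list(p = p, gap = g, iterations = iters,
                                      active = integer(0)))
      active <- which(g < -tol)
      next
    }
    Aaa <- A[active, active, drop = FALSE]
    diag(Aaa) <- diag(Aaa) + 1 / kp[active]
    pa <- solve(Aaa, -g0[active])
    p <- numeric(m)
    p[active] <- pa
    g <- g0 + as.vector(A %*% p)
    drop_ <- active[pa < 0]
    add_ <- setdiff(which(g < -tol), active)
    if (!length(drop_) && !length(add_))
      return(list(p = p, gap = g, iterations = iters, active = active))
    active <- sort(union(setdiff(active, drop_), add_))
  }
}

# build (or fetch from a model cache) the full solution machinery for a
# mesh + materials + constraint mode
indentation_operator <- function(mesh, materials, lc, formulation,
                                 stress_stiffening = TRUE, cache = NULL) {
  key <- paste(lc$constraint_mode, formulation, signif(lc$pressure, 12),
               stress_stiffening, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])

  base_key <- paste("sys", lc$constraint_mode, formulation, sep = "|")
  if (!is.null(cache) && !is.null(cache[[base_key]])) {
    sys <- cache[[base_key]]
  } else {
    sys <- assemble_stiffness(mesh, materials, formulation)
    if (mesh$type == "block") {
      dofs <- as.vector(t(outer(3L * (mesh$sets$fixed_nodes - 1L), 1:3, `+`)))
      sys <- fix_dofs(sys, dofs, 0)
    } else {
      sys <- apply_remote_displacement_zero(sys, mesh, lc$constraint_mode)
    }
    if (!is.null(cache)) cache[[base_key]] <- sys
  }
  f_p <- if (!is.null(mesh$sets$inner_surface) && lc$pressure > 0)
    apply_internal_pressure(mesh, lc$pressure) else numeric(sys$ndof)
  u0 <- if (any(f_p != 0)) as.vector(solve_displacement(sys, f_p))
        else numeric(sys$ndof)

  sys_t <- sys
  if (stress_stiffening && any(f_p != 0)) {
    rec0 <- recover_stress(mesh, materials, u0, formulation)
    Ks <- assemble_geometric_stiffness(mesh, rec0$stress)
    sys_t$K <- Matrix::forceSymmetric(sys$K + Ks)
    sys_t$cache <- new.env(parent = emptyenv())
  }
  op <- list(sys = sys, sys_t = sys_t, f_p = f_p, u0 = u0,
             probe_cache = new.env(parent = emptyenv()))
  if (!is.null(cache)) cache[[key]] <- op
  op
}

# updated-geometry variant: after the IOP ramp the probe-phase tangent is
# re-assembled on the pressure-inflated configuration (plus the
# initial-stress stiffness of the prestate). Experimental; not cached.
indentation_operator_updated <- function(mesh, materials, lc, formulation) {
  sys <- assemble_stiffness(mesh, materials, formulation)
  if (mesh$type == "block") {
    dofs <- as.vector(t(outer(3L * (mesh$sets$fixed_nodes - 1L), 1:3, `+`)))
    sys <- fix_dofs(sys, dofs, 0)
  } else {
    sys <- apply_remote_displacement_zero(sys, mesh, lc$constraint_mode)
  }
  f_p <- if (!is.null(mesh$sets$inner_surface) && lc$pressure > 0)
    apply_internal_pressure(mesh, lc$pressure) else numeric(sys$ndof)
  u0 <- if (any(f_p != 0)) as.vector(solve_displacement(sys, f_p))
        else numeric(sys$ndof)
  mesh1 <- mesh
  mesh1$nodes <- mesh$nodes + matrix(u0, ncol = 3, byrow = TRUE)
  sys1 <- assemble_stiffness(mesh1, materials, formulation)
  if (mesh$type == "block") {
    sys1 <- fix_dofs(sys1, sys$constraints$fixed$dofs, 0)
  } else {
    sys1 <- apply_remote_displacement_zero(sys1, mesh1, lc$constraint_mode)
  }
  if (any(f_p != 0)) {
    rec0 <- recover_stress(mesh, materials, u0, formulation)
    sys1$K <- Matrix::forceSymmetric(sys1$K +
      assemble_geometric_stiffness(mesh1, rec0$stress))
    sys1$cache <- new.env(parent = emptyenv())
  }
  list(sys = sys, sys_t = sys1, f_p = f_p, u0 = u0,
       probe_cache = new.env(parent = emptyenv()))
}

probe_operator <- function(op, mesh, probe) {
  key <- sprintf("probe-%g-%g", probe$diameter, probe$edge_fillet_radius)
  if (!is.null(op$probe_cache[[key]])) return(op$probe_cache[[key]])
  cand_nodes <- mesh$sets$corneal_outer$nodes
  rad <- sqrt(mesh$nodes[cand_nodes, 2]^2 + mesh$nodes[cand_nodes, 3]^2)
  keep <- rad <= probe$radius
  cand_nodes <- cand_nodes[keep]
  if (!length(cand_nodes))
    stop("no contact candidate nodes under the probe face")
  rad <- rad[keep]
  dofs_x <- 3L * (cand_nodes - 1L) + 1L
  E <- matrix(0, op$sys$ndof, length(cand_nodes))
  E[cbind(dofs_x, seq_along(cand_nodes))] <- 1
  W <- solve_displacement(op$sys_t, E)
  A <- W[dofs_x, , drop = FALSE]
  A <- (A + t(A)) / 2
  res <- list(nodes = cand_nodes, rad = rad, dofs_x = dofs_x, W = W, A = A)
  op$probe_cache[[key]] <- res
  res
}

#' Solve a displacement-driven probe indentation
#'
#' Applies the intraocular pressure in one linear step, then advances the
#' rigid probe along +X in equal displacement increments to the target
#' plunging depth, at constant IOP, resolving frictionless penalty contact
#' (active-set iteration with exact re-solves) at each increment. By
#' default the probe-phase stiffness is linearized about the pressurized
#' state (initial-stress geometric stiffness), which carries the
#' membrane-tension part of the applanation response; set
#' `stress_stiffening = FALSE` for the plain small-strain operator.
#'
#' @param mesh a `shell_mesh` (eye, sphere or block fixture)
#' @param materials named region-to-material list
#' @param lc a [load_case()]
#' @param formulation element formulation, as in [assemble_stiffness()]
#' @param penalty_scale contact penalty stiffness scale; the per-node
#'   penalty is `penalty_scale * E_contact * tributary_area /
#'   reference_thickness`
#' @param stress_stiffening linearize the probe phase about the pressurized
#'   state (default TRUE)
#' @param updated_geometry also re-assemble the probe-phase tangent on the
#'   pressure-inflated configuration (experimental; default FALSE)
#' @param model optional environment used to cache assembled operators
#'   across solves on the same mesh
#' @return an object of class `solve_result`
#' @export
solve_indentation <- function(mesh, materials, lc,
                              formulation = c("incompatible", "standard"),
                              penalty_scale = 1e3,
                              stress_stiffening = TRUE,
                              updated_geometry = FALSE,
                              model = NULL) {
  stopifnot(inherits(mesh, "shell_mesh"), inherits(lc, "load_case"))
  formulation <- match.arg(formulation)
  op <- if (updated_geometry)
    indentation_operator_updated(mesh, materials, lc, formulation)
  else indentation_operator(mesh, materials, lc, formulation,
                            stress_stiffening, cache = model)
  pr <- probe_operator(op, mesh, lc$probe)
  m <- length(pr$nodes)

  X_x <- mesh$nodes[pr$nodes, 1]
  u0_x <- op$u0[pr$dofs_x]
  face0 <- probe_face_x(lc$probe, 0, pr$rad) # rim recession if filleted
  # first-touch face position on the pressurized surface
  x_touch <- min(X_x + u0_x - face0)

  Ec <- if (!is.null(materials[["cornea"]])) materials[["cornea"]]$young_modulus
        else materials[[1]]$young_modulus
  h_ref <- if (mesh$type == "eye") 0.52 else max(diff(range(mesh$nodes[, 1])) / 10, 1)
  a_trib <- pi * lc$probe$radius^2 / m
  kp <- rep(penalty_scale * Ec * a_trib / h_ref, m)

  depths <- lc$target_depth * seq_len(lc$n_increments) / lc$n_increments
  if (lc$target_depth == 0) depths <- 0
  # increment loop, restarted with a 10x stiffer penalty if the residual
  # penetration exceeds the 1e-4 mm gap tolerance
  for (try_ in 1:4) {
    history <- data.frame(increment = integer(0), depth = numeric(0),
                          force = numeric(0), active_nodes = integer(0),
                          iterations = integer(0))
    p <- numeric(m)
    active <- NULL
    sol <- list(gap = numeric(m))
    for (inc in seq_along(depths)) {
      d <- depths[inc]
      g0 <- (X_x + u0_x - face0) - (x_touch + d)
      sol <- contact_lcp(pr$A, g0, kp, active = active)
      p <- sol$p
      active <- sol$active
      history <- rbind(history,
                       data.frame(increment = inc, depth = d,
                                  force = sum(p),
                                  active_nodes = length(sol$active),
                                  iterations = sol$iterations))
    }
    pen <- if (length(active)) max(0, -min(sol$gap[active])) else 0
    if (pen < 1e-4) break
    kp <- kp * 10
  }
  converged <- pen < 1e-4

  u <- op$u0 + as.vector(pr$W %*% p)
  rec <- recover_stress(mesh, materials, u, formulation)
  imax_d <- which.max(rec$total_deformation)
  imax_s <- which.max(rec$von_mises)
  contact_status <- numeric(nrow(mesh$nodes))
  contact_status[pr$nodes[p > 0]] <- 1

  res <- list(u = matrix(u, ncol = 3, byrow = TRUE),
              stress = rec$stress, von_mises = rec$von_mises,
              total_deformation = rec$total_deformation,
              contact_status = contact_status,
              reaction_force = sum(p),
              contact_forces = p, contact_nodes = pr$nodes,
              history = history,
              max_total_deformation = rec$total_deformation[imax_d],
              max_deformation_node = imax_d,
              max_deformation_location = mesh$nodes[imax_d, ],
              max_von_mises = rec$von_mises[imax_s],
              max_stress_element = imax_s,
              max_stress_region = mesh$region[imax_s],
              active_nodes = pr$nodes[p > 0],
              max_penetration = pen,
              converged = converged,
              load_case = lc, mesh = mesh)
  class(res) <- "solve_result"
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> depth %g mm, IOP %g mmHg, probe %g mm\n",
              x$load_case$target_depth, x$load_case$iop,
              x$load_case$probe$diameter))
  cat(sprintf("  reaction force %.5g N (%d active contact nodes, converged: %s)\n",
              x$reaction_force, length(x$active_nodes), x$converged))
  cat(sprintf("  max total deformation %.4g mm; max von Mises %.4g MPa in '%s'\n",
              x$max_total_deformation, x$max_von_mises, x$max_stress_region))
  invisible(x)
}

#' Applanation (reaction) force of a converged indentation
#'
#' The axial component of the total contact force on the probe: equal (by
#' the penalty constitutive definition) to the sum of the nodal penalty
#' forces along the probe axis, and equal to the negative of the
#' constraint-consistent nodal force sum over the active set.
#'
#' @param result a `solve_result`
#' @return force in N
#' @export
reaction_force <- function(result) {
  stopifnot(inherits(result, "solve_result"))
  result$reaction_force
}
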