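# Small-strain isotropic linear elasticity on hexahedral meshes.
# Displacement-based trilinear hexahedra with 2x2x2 Gauss quadrature; the
# default formulation augments each element with nine incompatible bending
# modes (Wilson/Taylor, with the centroid-Jacobian correction that preserves
# the patch test on distorted elements), statically condensed at element
# level. Collapsed (wedge) elements at the sweep poles fall back to the
# plain trilinear formulation.

HEX_XI <- c(-1, 1, 1, -1, -1, 1, 1, -1)
HEX_ETA <- c(-1, -1, 1, 1, -1, -1, 1, 1)
HEX_ZETA <- c(-1, -1, -1, -1, 1, 1, 1, 1)

hex_shape_derivs <- function(p) {
  # 8 x 3 matrix of dN/dxi at natural point p
  cbind(HEX_XI * (1 + p[2] * HEX_ETA) * (1 + p[3] * HEX_ZETA),
        HEX_ETA * (1 + p[1] * HEX_XI) * (1 + p[3] * HEX_ZETA),
        HEX_ZETA * (1 + p[1] * HEX_XI) * (1 + p[2] * HEX_ETA)) / 8
}

gauss_points_2 <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
}

# per-element kinematic arrays at a set of natural points (defaults to the
# 2x2x2 Gauss rule): physical shape-function gradients, Jacobian
# determinant, Jacobian column norms, and the corrected incompatible-mode
# gradients.
element_kinematics <- function(mesh, points = NULL) {
  if (is.null(points)) points <- gauss_points_2()
  el <- mesh$elems
  ne <- nrow(el)
  X <- mesh$nodes
  Xe <- lapply(1:3, function(i) {
    m <- matrix(X[el, i], ne, 8)
    m
  })
  degenerate <- rowSums(matrix(vapply(1:7, function(a)
    rowSums(el[, (a + 1):8, drop = FALSE] == el[, a]) > 0,
    logical(ne)), ne, 7)) > 0

  jac_at <- function(dN) {
    J <- vector("list", 9) # J[[3*(j-1)+i]] = dx_i/dxi_j
    for (i in 1:3) for (j in 1:3)
      J[[3 * (j - 1) + i]] <- as.vector(Xe[[i]] %*% dN[, j])
    J
  }
  inv_det <- function(J) {
    a <- J[[1]]; d <- J[[2]]; g <- J[[3]]
    b <- J[[4]]; e <- J[[5]]; h <- J[[6]]
    c <- J[[7]]; f <- J[[8]]; i <- J[[9]]
    # matrix M = [a b c; d e f; g h i] with M[r,s] = dx_r/dxi_s
    det <- a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g)
    iJ <- list(e * i - f * h, -(d * i - f * g), d * h - e * g,
               -(b * i - c * h), a * i - c * g, -(a * h - b * g),
               b * f - c * e, -(a * f - c * d), a * e - b * d)
    # iJ[[3*(s-1)+r]] = (M^-1)[r,s] * det
    list(det = det, iJ = iJ)
  }

  dN0 <- hex_shape_derivs(c(0, 0, 0))
  J0 <- jac_at(dN0)
  id0 <- inv_det(J0)

  gps <- vector("list", nrow(points))
  for (gp in seq_len(nrow(points))) {
    p <- points[gp, ]
    dN <- hex_shape_derivs(p)
    J <- jac_at(dN)
    id <- inv_det(J)
    det <- id$det
    # physical gradients: grad_x N_a = J^-T grad_xi N_a
    gx <- gy <- gz <- matrix(0, ne, 8)
    for (a in 1:8) {
      gx[, a] <- (id$iJ[[1]] * dN[a, 1] + id$iJ[[2]] * dN[a, 2] +
                  id$iJ[[3]] * dN[a, 3]) / det
      gy[, a] <- (id$iJ[[4]] * dN[a, 1] + id$iJ[[5]] * dN[a, 2] +
                  id$iJ[[6]] * dN[a, 3]) / det
      gz[, a] <- (id$iJ[[7]] * dN[a, 1] + id$iJ[[8]] * dN[a, 2] +
                  id$iJ[[9]] * dN[a, 3]) / det
    }
    # incompatible-mode gradients with the centroid correction:
    # grad_x M_alpha = (detJ0/detJ) J0^-T grad_xi M_alpha,
    # grad_xi M_alpha = -2 xi_alpha e_alpha; adj(J0) = iJ0 absorbs 1/detJ0
    mgx <- mgy <- mgz <- matrix(0, ne, 3)
    for (al in 1:3) {
      fac <- (-2 * p[al]) / det
      mgx[, al] <- fac * id0$iJ[[3 * (1 - 1) + al]]
      mgy[, al] <- fac * id0$iJ[[3 * (2 - 1) + al]]
      mgz[, al] <- fac * id0$iJ[[3 * (3 - 1) + al]]
    }
    # zero the modes on degenerate (collapsed) elements
    if (any(degenerate)) {
      mgx[degenerate, ] <- 0; mgy[degenerate, ] <- 0; mgz[degenerate, ] <- 0
    }
    cn1 <- sqrt(J[[1]]^2 + J[[2]]^2 + J[[3]]^2)
    cn2 <- sqrt(J[[4]]^2 + J[[5]]^2 + J[[6]]^2)
    cn3 <- sqrt(J[[7]]^2 + J[[8]]^2 + J[[9]]^2)
    gps[[gp]] <- list(gx = gx, gy = gy, gz = gz,
                      mgx = mgx, mgy = mgy, mgz = mgz,
                      detJ = det, cn1 = cn1, cn2 = cn2, cn3 = cn3)
  }
  list(gp = gps, degenerate = degenerate, ne = ne)
}

material_vectors <- function(mesh, materials) {
  tags <- unique(mesh$region)
  missing_tags <- setdiff(tags, names(materials))
  if (length(missing_tags))
    stop(sprintf("no material mapped for region tag(s): %s",
                 paste(missing_tags, collapse = ", ")))
  lam <- mu <- numeric(nrow(mesh$elems))
  for (tg in tags) {
    m <- materials[[tg]]
    stopifnot(inherits(m, "isotropic_material"))
    idx <- mesh$region == tg
    lam[idx] <- m$lambda; mu[idx] <- m$mu
  }
  list(lambda = lam, mu = mu)
}

# element stiffness matrices (condensed if incompatible) and the
# condensation operator used for stress recovery
element_matrices <- function(mesh, materials, formulation, kin = NULL) {
  if (is.null(kin)) kin <- element_kinematics(mesh)
  mv <- material_vectors(mesh, materials)
  lam <- mv$lambda; mu <- mv$mu
  ne <- kin$ne
  nsh <- if (formulation == "incompatible") 11L else 8L
  ndl <- 3L * nsh
  Kbig <- array(0, c(ne, ndl, ndl))
  for (g in kin$gp) {
    w <- g$detJ # unit Gauss weights
    G <- vector("list", nsh)
    for (a in 1:8) G[[a]] <- list(g$gx[, a], g$gy[, a], g$gz[, a])
    if (nsh == 11L)
      for (al in 1:3) G[[8 + al]] <- list(g$mgx[, al], g$mgy[, al],
                                          g$mgz[, al])
    for (a in seq_len(nsh)) {
      ga <- G[[a]]
      for (b in a:nsh) {
        gb <- G[[b]]
        dots <- ga[[1]] * gb[[1]] + ga[[2]] * gb[[2]] + ga[[3]] * gb[[3]]
        for (i in 1:3) for (j in 1:3) {
          v <- w * (lam * ga[[i]] * gb[[j]] + mu * ga[[j]] * gb[[i]] +
                    if (i == j) mu * dots else 0)
          Kbig[, 3 * (a - 1) + i, 3 * (b - 1) + j] <-
            Kbig[, 3 * (a - 1) + i, 3 * (b - 1) + j] + v
          if (a != b)
            Kbig[, 3 * (b - 1) + j, 3 * (a - 1) + i] <-
              Kbig[, 3 * (b - 1) + j, 3 * (a - 1) + i] + v
        }
      }
    }
  }
  if (nsh == 8L)
    return(list(Ke = Kbig, Cond = NULL, kin = kin))
  Ke <- Kbig[, 1:24, 1:24, drop = FALSE]
  Cond <- array(0, c(ne, 9, 24))
  for (e in seq_len(ne)) {
    if (kin$degenerate[e]) next
    Kaa <- Kbig[e, 25:33, 25:33]
    Kau <- Kbig[e, 25:33, 1:24]
    Ce <- solve(Kaa, Kau)
    Cond[e, , ] <- Ce
    Ke[e, , ] <- Ke[e, , ] - crossprod(Kau, Ce)
  }
  list(Ke = Ke, Cond = Cond, kin = kin)
}

element_dof_matrix <- function(elems) {
  ne <- nrow(elems)
  edof <- matrix(0L, ne, 24)
  for (a in 1:8) for (i in 1:3)
    edof[, 3L * (a - 1L) + i] <- 3L * (elems[, a] - 1L) + i
  edof
}

sparse_from_element <- function(Ke, edof, ndof) {
  ne <- dim(Ke)[1]
  p <- rep(1:24, times = 24)
  q <- rep(1:24, each = 24)
  ii <- as.vector(edof[, p])
  jj <- as.vector(edof[, q])
  xx <- as.vector(Ke)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Assemble the global elasticity stiffness matrix
#'
#' Standard displacement-based finite-element stiffness for homogeneous,
#' isotropic, linearly elastic regions, integrated with 2x2x2 Gauss
#' quadrature. The default "incompatible" formulation adds Wilson/Taylor
#' incompatible bending modes (condensed at element level), which removes
#' the parasitic shear stiffness of trilinear hexahedra in thin-shell
#' bending while retaining exact patch-test behaviour.
#'
#' @param mesh a `shell_mesh`
#' @param materials named list mapping every region tag of `mesh` to an
#'   [isotropic_material()]
#' @param formulation "incompatible" (default) or "standard"
#' @return an object of class `fem_system` holding the symmetric sparse
#'   stiffness `K` (MPa mm), a zero load vector `f`, and the mesh/material
#'   references. Before constraints are applied `K` is positive
#'   semi-definite with nullity 6 (the rigid-body modes).
#' @export
assemble_stiffness <- function(mesh, materials,
                               formulation = c("incompatible", "standard")) {
  stopifnot(inherits(mesh, "shell_mesh"))
  formulation <- match.arg(formulation)
  em <- element_matrices(mesh, materials, formulation)
  ndof <- 3L * nrow(mesh$nodes)
  K <- sparse_from_element(em$Ke, element_dof_matrix(mesh$elems), ndof)
  sys <- list(K = K, f = numeric(ndof), ndof = ndof,
              n_nodes = nrow(mesh$nodes), mesh = mesh,
              materials = materials, formulation = formulation,
              constraints = NULL, cache = new.env(parent = emptyenv()))
  class(sys) <- "fem_system"
  sys
}

#' @export
print.fem_system <- function(x, ...) {
  cons <- if (is.null(x$constraints)) "none"
          else x$constraints$mode
  cat(sprintf("<fem_system> %d dof, %s formulation, constraints: %s\n",
              x$ndof, x$formulation, cons))
  invisible(x)
}

#' Geometric (initial-stress) stiffness
#'
#' Assembles the symmetric initial-stress stiffness for a given element
#' stress state (element-mean Cauchy stress). Adding it to the material
#' stiffness linearises the response about a prestressed state; for the
#' pressurized eye this supplies the membrane-tension resistance of the
#' inflated wall, through which the intraocular pressure is transferred to
#' the applanating probe.
#'
#' @param mesh a `shell_mesh`
#' @param stress ne x 6 matrix of element stresses
#'   (xx, yy, zz, xy, yz, xz) in MPa, e.g. from [recover_stress()]
#' @return sparse symmetric matrix of the same dimension as the stiffness
#' @export
assemble_geometric_stiffness <- function(mesh, stress) {
  stopifnot(inherits(mesh, "shell_mesh"), nrow(stress) == nrow(mesh$elems))
  kin <- element_kinematics(mesh)
  ne <- kin$ne
  s11 <- stress[, 1]; s22 <- stress[, 2]; s33 <- stress[, 3]
  s12 <- stress[, 4]; s23 <- stress[, 5]; s13 <- stress[, 6]
  Ke <- array(0, c(ne, 24, 24))
  for (g in kin$gp) {
    w <- g$detJ
    for (a in 1:8) {
      gax <- g$gx[, a]; gay <- g$gy[, a]; gaz <- g$gz[, a]
      for (b in a:8) {
        gbx <- g$gx[, b]; gby <- g$gy[, b]; gbz <- g$gz[, b]
        sab <- w * (gax * (s11 * gbx + s12 * gby + s13 * gbz) +
                    gay * (s12 * gbx + s22 * gby + s23 * gbz) +
                    gaz * (s13 * gbx + s23 * gby + s33 * gbz))
        for (i in 1:3) {
          Ke[, 3 * (a - 1) + i, 3 * (b - 1) + i] <-
            Ke[, 3 * (a - 1) + i, 3 * (b - 1) + i] + sab
          if (a != b)
            Ke[, 3 * (b - 1) + i, 3 * (a - 1) + i] <-
              Ke[, 3 * (b - 1) + i, 3 * (a - 1) + i] + sab
        }
      }
    }
  }
  sparse_from_element(Ke, element_dof_matrix(mesh$elems),
                      3L * nrow(mesh$nodes))
}

quad_gauss_2 <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g)))
}

face_edge_closed <- function(faces) {
  e1 <- as.vector(faces[, c(1, 2, 3, 4)])
  e2 <- as.vector(faces[, c(2, 3, 4, 1)])
  keep <- e1 != e2
  key <- paste(pmin(e1, e2)[keep], pmax(e1, e2)[keep])
  all(table(key) == 2)
}

#' Consistent nodal forces from uniform internal pressure
#'
#' Integrates a uniform normal pressure over the mesh's closed inner
#' surface, oriented outward from the cavity (the pressure "diverges
#' outward" into the wall). The load is a dead load on the reference
#' configuration. For a closed surface the resultant force and moment are
#' zero to rounding.
#'
#' @param mesh a `shell_mesh` with an `inner_surface` set
#' @param pressure pressure in MPa (use [mmhg_to_mpa()] for IOP)
#' @return load vector (N), length 3 * n_nodes
#' @export
apply_internal_pressure <- function(mesh, pressure) {
  stopifnot(inherits(mesh, "shell_mesh"))
  set <- mesh$sets$inner_surface
  if (is.null(set) || nrow(set$faces) == 0L)
    stop("mesh has no inner_surface set to carry the pressure")
  faces <- set$faces
  if (!face_edge_closed(faces))
    stop("inner pressure surface is not closed")
  ndof <- 3L * nrow(mesh$nodes)
  if (pressure == 0) return(numeric(ndof))

  nf <- nrow(faces)
  Xf <- lapply(1:3, function(i) matrix(mesh$nodes[faces, i], nf, 4))
  cav <- colMeans(mesh$nodes[set$nodes, , drop = FALSE])

  xi_a <- c(-1, 1, 1, -1); eta_a <- c(-1, -1, 1, 1)
  # orientation: face-centre normal must point away from the cavity
  dN_c <- cbind(xi_a / 4, eta_a / 4)
  t1c <- sapply(1:3, function(i) Xf[[i]] %*% dN_c[, 1])
  t2c <- sapply(1:3, function(i) Xf[[i]] %*% dN_c[, 2])
  nc <- cbind(t1c[, 2] * t2c[, 3] - t1c[, 3] * t2c[, 2],
              t1c[, 3] * t2c[, 1] - t1c[, 1] * t2c[, 3],
              t1c[, 1] * t2c[, 2] - t1c[, 2] * t2c[, 1])
  ctr <- sapply(1:3, function(i) rowMeans(Xf[[i]]))
  sgn <- sign(rowSums(nc * sweep(ctr, 2, cav)))
  sgn[sgn == 0] <- 1

  idx_all <- val_all <- vector("list", 0)
  for (gp_row in seq_len(4)) {
    p <- quad_gauss_2()[gp_row, ]
    N <- (1 + p[1] * xi_a) * (1 + p[2] * eta_a) / 4
    dN <- cbind(xi_a * (1 + p[2] * eta_a) / 4, eta_a * (1 + p[1] * xi_a) / 4)
    t1 <- sapply(1:3, function(i) Xf[[i]] %*% dN[, 1])
    t2 <- sapply(1:3, function(i) Xf[[i]] %*% dN[, 2])
    nv <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
    for (a in 1:4) for (i in 1:3) {
      idx_all[[length(idx_all) + 1L]] <- 3L * (faces[, a] - 1L) + i
      val_all[[length(val_all) + 1L]] <- pressure * sgn * N[a] * nv[, i]
    }
  }
  idx <- unlist(idx_all); val <- unlist(val_all)
  agg <- rowsum(val, idx)
  f <- numeric(ndof)
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}

# consistent nodal forces for a constant traction vector on a face set
apply_face_traction <- function(mesh, faces, traction) {
  nf <- nrow(faces)
  Xf <- lapply(1:3, function(i) matrix(mesh$nodes[faces, i], nf, 4))
  xi_a <- c(-1, 1, 1, -1); eta_a <- c(-1, -1, 1, 1)
  ndof <- 3L * nrow(mesh$nodes)
  idx_all <- val_all <- vector("list", 0)
  for (gp_row in 1:4) {
    p <- quad_gauss_2()[gp_row, ]
    N <- (1 + p[1] * xi_a) * (1 + p[2] * eta_a) / 4
    dN <- cbind(xi_a * (1 + p[2] * eta_a) / 4, eta_a * (1 + p[1] * xi_a) / 4)
    t1 <- sapply(1:3, function(i) Xf[[i]] %*% dN[, 1])
    t2 <- sapply(1:3, function(i) Xf[[i]] %*% dN[, 2])
    dA <- sqrt(rowSums(cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                             t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                             t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])^2))
    for (a in 1:4) for (i in 1:3) {
      idx_all[[length(idx_all) + 1L]] <- 3L * (faces[, a] - 1L) + i
      val_all[[length(val_all) + 1L]] <- traction[i] * N[a] * dA
    }
  }
  idx <- unlist(idx_all); val <- unlist(val_all)
  agg <- rowsum(val, idx)
  f <- numeric(ndof)
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}

#' Remove rigid-body motion: the "remote displacement zero" condition
#'
#' In "remote-rigid-body" mode (the default, mirroring a deformable
#' attachment of the globe in the orbit), six averaged constraints -- zero
#' mean translation and zero mean infinitesimal rotation of the
#' `scleral_outer` node set about its centroid -- are imposed with Lagrange
#' multipliers: the sclera may deform freely but the globe cannot move as a
#' rigid body. In "posterior-patch" mode all degrees of freedom are fixed on
#' nodes whose polar angle from the apex direction (about the mesh centroid)
#' exceeds 140 degrees.
#'
#' @param system a `fem_system`
#' @param mesh its mesh (defaults to `system$mesh`)
#' @param mode "remote-rigid-body" or "posterior-patch"
#' @return the constrained system
#' @export
apply_remote_displacement_zero <- function(system, mesh = system$mesh,
                                           mode = c("remote-rigid-body",
                                                    "posterior-patch")) {
  stopifnot(inherits(system, "fem_system"))
  mode <- match.arg(mode)
  set <- mesh$sets$scleral_outer
  if (is.null(set) || length(set$nodes) == 0L)
    stop("mesh has no scleral_outer set to constrain")
  if (mode == "remote-rigid-body") {
    nd <- set$nodes
    ns <- length(nd)
    ct <- colMeans(mesh$nodes[nd, , drop = FALSE])
    r <- sweep(mesh$nodes[nd, , drop = FALSE], 2, ct)
    ii <- jj <- xx <- list()
    add <- function(row, dofs, vals) {
      ii[[length(ii) + 1L]] <<- rep(row, length(dofs))
      jj[[length(jj) + 1L]] <<- dofs
      xx[[length(xx) + 1L]] <<- vals
    }
    dof <- function(i) 3L * (nd - 1L) + i
    for (i in 1:3) add(i, dof(i), rep(1 / ns, ns))
    add(4L, dof(3L), r[, 2] / ns); add(4L, dof(2L), -r[, 3] / ns)
    add(5L, dof(1L), r[, 3] / ns); add(5L, dof(3L), -r[, 1] / ns)
    add(6L, dof(2L), r[, 1] / ns); add(6L, dof(1L), -r[, 2] / ns)
    C <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(6L, system$ndof))
    system$constraints <- list(mode = mode, C = C)
  } else {
    ct <- colMeans(mesh$nodes)
    v <- sweep(mesh$nodes, 2, ct)
    # apex direction: from centroid toward the anterior pole (-X)
    cosang <- -v[, 1] / pmax(sqrt(rowSums(v^2)), 1e-12)
    fixed_nodes <- which(acos(pmin(pmax(cosang, -1), 1)) > 140 * pi / 180)
    if (!length(fixed_nodes))
      stop("posterior-patch constraint selected no nodes")
    dofs <- as.vector(t(outer(3L * (fixed_nodes - 1L), 1:3, `+`)))
    system$constraints <- list(mode = mode, fixed = list(
      dofs = dofs, values = numeric(length(dofs))))
  }
  system$cache <- new.env(parent = emptyenv())
  system
}

# fix arbitrary dofs (possibly to prescribed nonzero values)
fix_dofs <- function(system, dofs, values = 0) {
  system$constraints <- list(mode = "fixed",
                             fixed = list(dofs = as.integer(dofs),
                                          values = rep_len(values,
                                                           length(dofs))))
  system$cache <- new.env(parent = emptyenv())
  system
}

fem_factorize <- function(system) {
  if (!is.null(system$cache$solver)) return(system$cache$solver)
  K <- system$K
  cons <- system$constraints
  if (is.null(cons))
    stop(paste("system is unconstrained: the stiffness has six rigid-body",
               "modes; apply constraints first"))
  if (!is.null(cons$fixed)) {
    fixed <- cons$fixed$dofs
    vals <- cons$fixed$values
    free <- setdiff(seq_len(system$ndof), fixed)
    Kff <- K[free, free, drop = FALSE]
    ch <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, perm = TRUE),
      error = function(e)
        stop(sprintf("singular constrained system (%s): an unconstrained mode remains",
                     conditionMessage(e))))
    Kfp <- K[free, fixed, drop = FALSE]
    solver <- function(f) {
      f <- as.matrix(f)
      rhs <- f[free, , drop = FALSE] -
        matrix(as.vector(Kfp %*% vals), length(free), ncol(f))
      uf <- as.matrix(Matrix::solve(ch, rhs, system = "A"))
      u <- matrix(0, system$ndof, ncol(f))
      u[free, ] <- uf
      u[fixed, ] <- vals
      u
    }
  } else {
    # multiplier (bordered) system [K C'; C 0], solved with a shifted
    # Cholesky of K plus the 6x6 Schur complement of the constraints, and
    # iterative refinement to remove the shift: exact saddle-point solve
    # at Cholesky cost.
    C <- cons$C
    Ct <- Matrix::t(C)
    q <- nrow(C)
    dK <- mean(abs(Matrix::diag(K)))
    s <- 1e-6 * dK
    Ks <- Matrix::forceSymmetric(K + s * Matrix::Diagonal(system$ndof))
    ch <- tryCatch(Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE),
                   error = function(e)
      stop(sprintf("singular constrained system (%s): an unconstrained mode remains",
                   conditionMessage(e))))
    Y <- as.matrix(Matrix::solve(ch, as.matrix(Ct), system = "A"))
    S <- as.matrix(C %*% Y)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("singular constrained system: the constraints do not remove all rigid-body modes"))
    base_solve <- function(b, g) {
      tt <- as.matrix(Matrix::solve(ch, b, system = "A"))
      lam <- Sinv %*% (as.matrix(C %*% tt) - g)
      list(u = tt - Y %*% lam, lam = lam)
    }
    solver <- function(f) {
      f <- as.matrix(f)
      nc <- ncol(f)
      z6 <- matrix(0, q, nc)
      sol <- base_solve(f, z6)
      u <- sol$u; lam <- sol$lam
      fn <- pmax(sqrt(colSums(f^2)), 1e-300)
      for (it in 1:20) {
        r1 <- f - as.matrix(K %*% u) - as.matrix(Ct %*% lam)
        r2 <- z6 - as.matrix(C %*% u)
        if (max(sqrt(colSums(r1^2)) / fn) < 1e-12 &&
            max(abs(r2)) < 1e-12 * max(fn)) break
        cor <- base_solve(r1, r2)
        u <- u + cor$u; lam <- lam + cor$lam
      }
      u
    }
  }
  system$cache$solver <- solver
  solver
}

#' Solve the constrained linear system for the displacement field
#'
#' Direct sparse solve (Cholesky for eliminated constraints, LU of the
#' bordered system for multiplier constraints). The relative residual of
#' the solution is checked against 1e-9.
#'
#' @param system a constrained `fem_system`
#' @param f load vector (defaults to `system$f`); a matrix of load columns
#'   is also accepted
#' @return displacement vector (mm) with attribute "residual"; matrix input
#'   gives matrix output
#' @export
solve_displacement <- function(system, f = NULL) {
  stopifnot(inherits(system, "fem_system"))
  if (is.null(f)) f <- system$f
  solver <- fem_factorize(system)
  u <- solver(f)
  fm <- as.matrix(f)
  nf <- sqrt(colSums(fm^2))
  # residual in the constrained subspace (projecting out multiplier forces)
  r <- as.matrix(system$K %*% u) - fm
  if (!is.null(system$constraints$fixed)) {
    r[system$constraints$fixed$dofs, ] <- 0
    res <- ifelse(nf > 0, sqrt(colSums(r^2)) / pmax(nf, 1e-300), 0)
  } else {
    C <- system$constraints$C
    # remove the multiplier reaction: r should lie in span(C^T)
    Ct <- Matrix::t(C)
    lam <- solve(as.matrix(C %*% Ct), as.matrix(C %*% r))
    r <- r - as.matrix(Ct %*% lam)
    res <- ifelse(nf > 0, sqrt(colSums(r^2)) / pmax(nf, 1e-300), 0)
  }
  if (any(nf > 0 & res > 1e-9))
    warning(sprintf("solver residual %.2e exceeds 1e-9", max(res)))
  if (ncol(fm) == 1L) {
    u <- drop(u)
  }
  attr(u, "residual") <- max(res)
  u
}

#' Recover element stresses and nodal deformation from a displacement field
#'
#' Quadrature-point stresses are volume-averaged per element; the von Mises
#' scalar is computed from the deviatoric invariant; the nodal total
#' deformation is the Euclidean norm of the displacement vector. With the
#' incompatible formulation the condensed internal modes are recovered per
#' element and contribute to the strain.
#'
#' @param mesh a `shell_mesh`
#' @param materials named region-to-material list
#' @param u displacement vector (length 3 * n_nodes) or n x 3 matrix
#' @param formulation must match the assembly formulation
#' @return list with `stress` (ne x 6: xx, yy, zz, xy, yz, xz, MPa),
#'   `von_mises` (ne), `total_deformation` (n_nodes, mm)
#' @export
recover_stress <- function(mesh, materials, u,
                           formulation = c("incompatible", "standard")) {
  stopifnot(inherits(mesh, "shell_mesh"))
  formulation <- match.arg(formulation)
  if (is.matrix(u)) u <- as.vector(t(u))
  ne <- nrow(mesh$elems)
  mv <- material_vectors(mesh, materials)
  kin <- element_kinematics(mesh)
  ue <- lapply(1:3, function(i)
    matrix(u[3L * (as.vector(mesh$elems) - 1L) + i], ne, 8))

  alpha <- NULL
  if (formulation == "incompatible") {
    em <- element_matrices(mesh, materials, formulation, kin)
    uel <- matrix(0, ne, 24)
    for (a in 1:8) for (i in 1:3)
      uel[, 3L * (a - 1L) + i] <- ue[[i]][, a]
    alpha <- array(0, c(ne, 3, 3)) # [e, mode, component]
    for (e in seq_len(ne)) {
      if (kin$degenerate[e]) next
      av <- -em$Cond[e, , ] %*% uel[e, ]
      # av is ordered (mode1 xyz, mode2 xyz, mode3 xyz)
      alpha[e, , ] <- t(matrix(av, 3, 3))
    }
  }

  sig_sum <- matrix(0, ne, 6)
  vol <- numeric(ne)
  lam <- mv$lambda; mu <- mv$mu
  for (g in kin$gp) {
    H <- array(0, c(ne, 3, 3)) # H[e,i,j] = du_i/dx_j
    gl <- list(g$gx, g$gy, g$gz)
    for (i in 1:3) for (j in 1:3)
      H[, i, j] <- rowSums(ue[[i]] * gl[[j]])
    if (!is.null(alpha)) {
      mgl <- list(g$mgx, g$mgy, g$mgz)
      for (i in 1:3) for (j in 1:3)
        H[, i, j] <- H[, i, j] + rowSums(alpha[, , i] * mgl[[j]])
    }
    e11 <- H[, 1, 1]; e22 <- H[, 2, 2]; e33 <- H[, 3, 3]
    e12 <- (H[, 1, 2] + H[, 2, 1]) / 2
    e23 <- (H[, 2, 3] + H[, 3, 2]) / 2
    e13 <- (H[, 1, 3] + H[, 3, 1]) / 2
    tr <- e11 + e22 + e33
    w <- g$detJ
    sig_sum[, 1] <- sig_sum[, 1] + w * (lam * tr + 2 * mu * e11)
    sig_sum[, 2] <- sig_sum[, 2] + w * (lam * tr + 2 * mu * e22)
    sig_sum[, 3] <- sig_sum[, 3] + w * (lam * tr + 2 * mu * e33)
    sig_sum[, 4] <- sig_sum[, 4] + w * (2 * mu * e12)
    sig_sum[, 5] <- sig_sum[, 5] + w * (2 * mu * e23)
    sig_sum[, 6] <- sig_sum[, 6] + w * (2 * mu * e13)
    vol <- vol + w
  }
  stress <- sig_sum / vol
  vm <- sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 +
                    (stress[, 2] - stress[, 3])^2 +
                    (stress[, 3] - stress[, 1])^2) +
             3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
  um <- matrix(u, ncol = 3, byrow = TRUE)
  list(stress = stress, von_mises = vm,
       total_deformation = sqrt(rowSums(um^2)))
}
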