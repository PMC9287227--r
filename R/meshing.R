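# Structured hexahedral sweep meshing of parametric shells, plus the graded
# block mesh used by the flat-punch oracle. Hexahedra collapse to wedges
# (repeated nodes) at the two poles; the collapsed elements keep positive
# Jacobians at the interior quadrature points.

#' Mesh resolution presets
#'
#' Named azimuth/meridian/through-thickness division presets for the eye
#' shell. The "reference" preset is the reference resolution used for the
#' tonometry results: its average in-plane element size is within a factor
#' of two of the ~2 mm element size of the reference study (exact node and
#' element counts are not reproducible across meshers and are not a
#' contract).
#'
#' @param name "coarse", "reference" or "fine"
#' @return list with n_azimuth, n_meridian, n_thickness
#' @export
mesh_preset <- function(name = c("reference", "coarse", "fine")) {
  name <- match.arg(name)
  switch(name,
         coarse = list(n_azimuth = 24, n_meridian = 16, n_thickness = 2),
         reference = list(n_azimuth = 32, n_meridian = 24, n_thickness = 2),
         fine   = list(n_azimuth = 48, n_meridian = 40, n_thickness = 3))
}

#' Sweep a parametric shell into a tagged hexahedral solid mesh
#'
#' Structured sweep over azimuth x meridian x thickness. Node count is
#' `n_azimuth*(n_meridian-1)*(n_thickness+1) + 2*(n_thickness+1)` (the two
#' pole columns are shared), element count is
#' `n_azimuth*n_meridian*n_thickness` (the pole rows are wedges stored as
#' collapsed hexahedra). Elements are tagged by the shell's region function
#' evaluated at their centroid (9 regions for the default eye: cornea, 4
#' sclera and 4 junction quadrants); the mesh carries the named surface sets
#' `inner_surface` (pressure), `corneal_outer` (contact candidates) and
#' `scleral_outer` (constraint).
#'
#' @param shell a `parametric_shell` from [loft_eye_surface()] or
#'   [make_sphere_fixture()]
#' @param n_azimuth azimuthal divisions (even, >= 8)
#' @param n_meridian meridional divisions (>= 8)
#' @param n_thickness through-thickness divisions (>= 2)
#' @return an object of class `shell_mesh` with fields `nodes` (n x 3 mm),
#'   `elems` (ne x 8 node indices, VTK hexahedron ordering), `region`
#'   (character per element), `sets`, `resolution`
#' @export
sweep_shell_mesh <- function(shell, n_azimuth, n_meridian, n_thickness) {
  stopifnot(inherits(shell, "parametric_shell"))
  nA <- as.integer(n_azimuth); nM <- as.integer(n_meridian)
  nT <- as.integer(n_thickness)
  if (nA < 8L || nA %% 2L != 0L) stop("n_azimuth must be even and >= 8")
  if (nM < 8L) stop("n_meridian must be >= 8")
  if (nT < 2L) stop("n_thickness must be >= 2")

  th <- 2 * pi * (0:(nA - 1)) / nA
  uu <- (0:nM) / nM
  nlay <- nT + 1L

  # node ids: 1..nlay anterior pole (k=0..nT), then interior rows, then
  # posterior pole
  n_interior <- nA * (nM - 1L) * nlay
  nid <- function(i, j, k) {
    # i azimuth index (any integer, wrapped), j in 0..nM, k in 0..nT
    n <- max(length(i), length(j), length(k))
    i <- rep_len(i, n) %% nA; j <- rep_len(j, n); k <- rep_len(k, n)
    out <- integer(n)
    ant <- j == 0L; post <- j == nM; mid <- !ant & !post
    out[ant] <- k[ant] + 1L
    out[post] <- nlay + n_interior + k[post] + 1L
    out[mid] <- nlay + ((j[mid] - 1L) * nA + i[mid]) * nlay + k[mid] + 1L
    out
  }
  nn <- 2L * nlay + n_interior
  nodes <- matrix(NA_real_, nn, 3L)

  kk <- (0:nT) / nT
  # poles
  for (jj in c(0L, nM)) {
    po <- shell$eval_3d(0, uu[jj + 1L], "outer")
    pi_ <- shell$eval_3d(0, uu[jj + 1L], "inner")
    for (k in 0:nT)
      nodes[nid(0L, jj, k), ] <- pi_ + kk[k + 1L] * (po - pi_)
  }
  # interior rows
  for (j in 1:(nM - 1L)) {
    po <- shell$eval_3d(th, rep(uu[j + 1L], nA), "outer")
    pi_ <- shell$eval_3d(th, rep(uu[j + 1L], nA), "inner")
    for (k in 0:nT)
      nodes[nid(0:(nA - 1L), j, k), ] <- pi_ + kk[k + 1L] * (po - pi_)
  }

  # connectivity: VTK hex ordering, bottom face at layer k, top at k+1;
  # local axes (azimuth, meridian, thickness) form a right-handed triad
  ii <- rep(0:(nA - 1L), times = nM * nT)
  jj <- rep(rep(0:(nM - 1L), each = nA), times = nT)
  kk_e <- rep(0:(nT - 1L), each = nA * nM)
  elems <- cbind(nid(ii, jj, kk_e),     nid(ii + 1L, jj, kk_e),
                 nid(ii + 1L, jj + 1L, kk_e), nid(ii, jj + 1L, kk_e),
                 nid(ii, jj, kk_e + 1L), nid(ii + 1L, jj, kk_e + 1L),
                 nid(ii + 1L, jj + 1L, kk_e + 1L), nid(ii, jj + 1L, kk_e + 1L))
  storage.mode(elems) <- "integer"

  theta_c <- th[ii + 1L] + pi / nA
  u_c <- (jj + 0.5) / nM
  region <- shell$region(theta_c, u_c)
  # the junction band must tag at least one element row even when it is
  # thinner than an element: elements containing the kink itself are
  # always tagged junction (centroid tagging handles the rest)
  if (!is.null(shell$u_junction) && !is.na(shell$u_junction)) {
    q <- quadrant_of_theta(theta_c)
    u0 <- jj / nM; u1 <- (jj + 1L) / nM
    jn <- u0 <= shell$u_junction & u1 > shell$u_junction
    region[jn] <- paste0("junction-", q[jn])
  }

  # named surface sets (quad faces; degenerate edges at the poles allowed)
  inner_idx <- which(kk_e == 0L)
  inner_faces <- cbind(nid(ii, jj, 0L), nid(ii + 1L, jj, 0L),
                       nid(ii + 1L, jj + 1L, 0L), nid(ii, jj + 1L, 0L))[inner_idx, ]
  storage.mode(inner_faces) <- "integer"
  outer_idx <- which(kk_e == nT - 1L)
  outer_faces <- cbind(nid(ii, jj, nT), nid(ii + 1L, jj, nT),
                       nid(ii + 1L, jj + 1L, nT), nid(ii, jj + 1L, nT))[outer_idx, ]
  storage.mode(outer_faces) <- "integer"
  oclass <- shell$surface_class(theta_c[outer_idx], u_c[outer_idx])

  make_set <- function(faces, elem) {
    list(faces = faces, elem = as.integer(elem),
         nodes = sort(unique(as.integer(faces))))
  }
  sets <- list(
    inner_surface = make_set(inner_faces, inner_idx),
    corneal_outer = make_set(outer_faces[oclass == "contact", , drop = FALSE],
                             outer_idx[oclass == "contact"]),
    scleral_outer = make_set(outer_faces[oclass == "constraint", , drop = FALSE],
                             outer_idx[oclass == "constraint"]))

  mesh <- list(nodes = nodes, elems = elems, region = region, sets = sets,
               type = shell$type,
               resolution = list(n_azimuth = nA, n_meridian = nM,
                                 n_thickness = nT))
  class(mesh) <- "shell_mesh"
  jmin <- min(min_scaled_jacobian(mesh))
  if (jmin <= 0) {
    w <- which.min(min_scaled_jacobian(mesh))
    stop(sprintf("meshing produced an inverted element (worst element %d near x=%.2f, y=%.2f, z=%.2f)",
                 w, mean(nodes[elems[w, ], 1]), mean(nodes[elems[w, ], 2]),
                 mean(nodes[elems[w, ], 3])))
  }
  mesh
}

#' @export
print.shell_mesh <- function(x, ...) {
  cat(sprintf("<shell_mesh> type '%s': %d nodes, %d elements, %d region tag(s)\n",
              x$type, nrow(x$nodes), nrow(x$elems),
              length(unique(x$region))))
  if (!is.null(x$resolution$n_azimuth))
    cat(sprintf("  resolution %d x %d x %d (azimuth x meridian x thickness)\n",
                x$resolution$n_azimuth, x$resolution$n_meridian,
                x$resolution$n_thickness))
  invisible(x)
}

#' Mesh the block fixture with grading toward the contact face centre
#'
#' Power-law grading concentrates nodes near the centre of the free face
#' (where the punch acts) and near the free surface, which the flat-punch
#' oracle needs to resolve the contact-edge stress gradient.
#'
#' @param fixture a [make_block_fixture()] object
#' @param n_side divisions per lateral direction (even)
#' @param n_depth divisions through the depth
#' @param grade_side,grade_depth grading exponents (1 = uniform)
#' @return a `shell_mesh`-compatible mesh with sets `corneal_outer` (the
#'   contact face) and `fixed_nodes`
#' @export
block_mesh <- function(fixture, n_side = 24, n_depth = 12,
                       grade_side = 2, grade_depth = 2) {
  stopifnot(inherits(fixture, "block_fixture"))
  ns <- as.integer(n_side); nd <- as.integer(n_depth)
  if (ns < 4L || ns %% 2L != 0L) stop("n_side must be even and >= 4")
  if (nd < 2L) stop("n_depth must be >= 2")
  s <- seq(-1, 1, length.out = ns + 1L)
  yz <- fixture$side / 2 * sign(s) * abs(s)^grade_side
  t <- seq(0, 1, length.out = nd + 1L)
  xs <- fixture$depth * t^grade_depth

  nid <- function(i, j, k) # i over y, j over z, k over x; 0-based
    (k * (ns + 1L) + j) * (ns + 1L) + i + 1L
  nn <- (ns + 1L)^2 * (nd + 1L)
  grid <- expand.grid(y = yz, z = yz, x = xs)
  nodes <- cbind(grid$x, grid$y, grid$z)

  ii <- rep(0:(ns - 1L), times = ns * nd)
  jj <- rep(rep(0:(ns - 1L), each = ns), times = nd)
  kk <- rep(0:(nd - 1L), each = ns * ns)
  elems <- cbind(nid(ii, jj, kk), nid(ii + 1L, jj, kk),
                 nid(ii + 1L, jj + 1L, kk), nid(ii, jj + 1L, kk),
                 nid(ii, jj, kk + 1L), nid(ii + 1L, jj, kk + 1L),
                 nid(ii + 1L, jj + 1L, kk + 1L), nid(ii, jj + 1L, kk + 1L))
  storage.mode(elems) <- "integer"

  top_idx <- which(kk == 0L)
  top_faces <- cbind(nid(ii, jj, 0L), nid(ii + 1L, jj, 0L),
                     nid(ii + 1L, jj + 1L, 0L), nid(ii, jj + 1L, 0L))[top_idx, ]
  storage.mode(top_faces) <- "integer"
  half <- fixture$side / 2
  fixed_nodes <- which(abs(nodes[, 1] - fixture$depth) < 1e-12 |
                       abs(abs(nodes[, 2]) - half) < 1e-12 |
                       abs(abs(nodes[, 3]) - half) < 1e-12)

  mesh <- list(nodes = nodes, elems = elems,
               region = rep("block", nrow(elems)),
               sets = list(inner_surface = NULL,
                           corneal_outer = list(faces = top_faces,
                                                elem = as.integer(top_idx),
                                                nodes = sort(unique(as.integer(top_faces)))),
                           scleral_outer = NULL,
                           fixed_nodes = as.integer(fixed_nodes)),
               type = "block",
               resolution = list(n_side = ns, n_depth = nd,
                                 grade_side = grade_side,
                                 grade_depth = grade_depth))
  class(mesh) <- "shell_mesh"
  if (min(min_scaled_jacobian(mesh)) <= 0)
    stop("block meshing produced an inverted element")
  mesh
}

# scaled Jacobian per element: minimum over the 2x2x2 Gauss points of
# det(J) normalised by the product of the column norms of J
min_scaled_jacobian <- function(mesh) {
  kin <- element_kinematics(mesh)
  out <- rep(Inf, nrow(mesh$elems))
  for (gp in seq_along(kin$gp)) {
    g <- kin$gp[[gp]]
    out <- pmin(out, g$detJ / (g$cn1 * g$cn2 * g$cn3))
  }
  out
}

#' Mesh quality report
#'
#' Deterministic quality metrics: minimum and median scaled Jacobian over
#' the quadrature points, maximum aspect ratio (ratio of Jacobian column
#' norms at the element centroid), node/element counts, the average element
#' edge length over all unique edges, and -- for swept shell meshes -- the
#' average in-plane element size (azimuthal and meridional edges only; the
#' through-thickness edge length is dictated by the wall thinness and is
#' reported separately by the overall average).
#'
#' @param mesh a `shell_mesh`
#' @return an object of class `mesh_quality_report`
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "shell_mesh"))
  sj <- min_scaled_jacobian(mesh)
  # aspect ratio at centroid
  kin <- element_kinematics(mesh, points = matrix(0, 1, 3))
  g <- kin$gp[[1]]
  cn <- cbind(g$cn1, g$cn2, g$cn3)
  aspect <- apply(cn, 1, max) / apply(cn, 1, min)

  edge_pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                      c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                      c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  el <- mesh$elems
  ne <- nrow(el)
  e_from <- as.vector(el[, edge_pairs[, 1]])
  e_to <- as.vector(el[, edge_pairs[, 2]])
  elen <- sqrt(rowSums((mesh$nodes[e_from, , drop = FALSE] -
                        mesh$nodes[e_to, , drop = FALSE])^2))
  elen <- matrix(elen, ne, 12)
  key <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  keep <- !duplicated(key) & e_from != e_to
  avg_edge <- mean(elen[matrix(keep, ne, 12)])
  # characteristic in-plane size per element: geometric mean of the mean
  # azimuthal (local 1-2/3-4 direction) and meridional (2-3/4-1) edge
  # lengths of the swept hex; for a block mesh all edges count
  az <- rowMeans(elen[, c(1, 3, 5, 7), drop = FALSE])
  me <- rowMeans(elen[, c(2, 4, 6, 8), drop = FALSE])
  az[az < 1e-12] <- me[az < 1e-12] # collapsed pole edges
  inplane_size <- mean(sqrt(az * me))

  rep_ <- list(n_nodes = nrow(mesh$nodes),
               n_elements = nrow(mesh$elems),
               min_scaled_jacobian = min(sj),
               median_scaled_jacobian = stats::median(sj),
               max_aspect_ratio = max(aspect),
               avg_edge_length = avg_edge,
               avg_inplane_size = if (mesh$type == "block") avg_edge
                                  else inplane_size)
  class(rep_) <- "mesh_quality_report"
  rep_
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat("<mesh_quality_report>\n")
  cat(sprintf("  nodes %d, elements %d\n", x$n_nodes, x$n_elements))
  cat(sprintf("  scaled Jacobian: min %.3g, median %.3g; max aspect %.3g\n",
              x$min_scaled_jacobian, x$median_scaled_jacobian,
              x$max_aspect_ratio))
  cat(sprintf("  avg edge length %.3g mm; avg in-plane size %.3g mm\n",
              x$avg_edge_length, x$avg_inplane_size))
  invisible(x)
}

#' Total mesh volume
#'
#' Sum of element volumes by Gauss quadrature; used to check watertight
#' closure of swept fixtures against closed-form volumes.
#'
#' @param mesh a `shell_mesh`
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  kin <- element_kinematics(mesh)
  sum(vapply(kin$gp, function(g) sum(g$detJ), 0))
}
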