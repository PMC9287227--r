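mat1 <- list(block = isotropic_material(1, 0.25))

test_that("single-hex stiffness matches an independent numerical-integration oracle entrywise", {
  msh <- unit_hex_mesh()
  K <- as.matrix(assemble_stiffness(msh, mat1, "standard")$K)
  Ko <- brute_force_hex_stiffness(msh$nodes, 1, 0.25)
  expect_lt(max(abs(K - Ko)), 1e-12)
})

test_that("the assembled stiffness has exactly six rigid-body modes spanned by translations and rotations", {
  sph <- make_sphere_fixture(10, 1)
  msh <- sweep_shell_mesh(sph, 8, 8, 2)
  for (form in c("standard", "incompatible")) {
    K <- as.matrix(assemble_stiffness(msh, list(sphere = mat1$block),
                                      form)$K)
    ev <- eigen(K, symmetric = TRUE)
    nzero <- sum(abs(ev$values) < 1e-8 * max(ev$values))
    expect_equal(nzero, 6L)
    # null vectors reproduced by rigid translations/rotations
    X <- msh$nodes
    R <- cbind(
      rep(c(1, 0, 0), nrow(X)), rep(c(0, 1, 0), nrow(X)),
      rep(c(0, 0, 1), nrow(X)),
      as.vector(t(cbind(0, -X[, 3], X[, 2]))),
      as.vector(t(cbind(X[, 3], 0, -X[, 1]))),
      as.vector(t(cbind(-X[, 2], X[, 1], 0))))
    null_vecs <- ev$vectors[, order(abs(ev$values))[1:6]]
    # each null vector lies in span(R)
    proj <- R %*% solve(crossprod(R), crossprod(R, null_vecs))
    expect_lt(max(abs(proj - null_vecs)), 1e-6)
  }
})

test_that("a distorted mesh under a prescribed linear field recovers constant stress exactly (patch test)", {
  bm <- distorted_block_mesh()
  interior <- attr(bm, "interior_nodes")
  mats <- list(block = isotropic_material(1.7, 0.3))
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 4e-4, 6e-4),
              3, 3)
  ub <- bm$nodes %*% t(A)
  boundary <- setdiff(seq_len(nrow(bm$nodes)), interior)
  dofs <- as.vector(t(outer(3L * (boundary - 1L), 1:3, `+`)))
  for (form in c("standard", "incompatible")) {
    sys <- assemble_stiffness(bm, mats, form)
    sys <- tonofem:::fix_dofs(sys, dofs, as.vector(t(ub[boundary, ])))
    u <- solve_displacement(sys, numeric(sys$ndof))
    expect_lt(max(abs(matrix(u, ncol = 3, byrow = TRUE) - ub)), 1e-12)
    rec <- recover_stress(bm, mats, u, form)
    eps <- (A + t(A)) / 2
    lam <- 1.7 * 0.3 / (1.3 * 0.4); mu <- 1.7 / 2.6
    sig <- lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
    expected <- c(sig[1, 1], sig[2, 2], sig[3, 3],
                  sig[1, 2], sig[2, 3], sig[1, 3])
    expect_lt(max(abs(sweep(rec$stress, 2, expected))), 1e-12)
  }
})

test_that("uniform internal pressure on a closed shell has zero resultant force and moment", {
  sph <- make_sphere_fixture(11.2, 0.317)
  msh <- sweep_shell_mesh(sph, 16, 16, 2)
  f <- apply_internal_pressure(msh, mmhg_to_mpa(20))
  fm <- matrix(f, ncol = 3, byrow = TRUE)
  tot <- sqrt(sum(f^2))
  expect_lt(sqrt(sum(colSums(fm)^2)), 1e-10 * tot)
  mom <- colSums(cbind(
    msh$nodes[, 2] * fm[, 3] - msh$nodes[, 3] * fm[, 2],
    msh$nodes[, 3] * fm[, 1] - msh$nodes[, 1] * fm[, 3],
    msh$nodes[, 1] * fm[, 2] - msh$nodes[, 2] * fm[, 1]))
  expect_lt(sqrt(sum(mom^2)), 1e-9 * tot * max(abs(msh$nodes)))
  expect_identical(apply_internal_pressure(msh, 0), numeric(3 * nrow(msh$nodes)))
})

test_that("an open pressure surface is rejected", {
  sph <- make_sphere_fixture(11.2, 0.317)
  msh <- sweep_shell_mesh(sph, 16, 16, 2)
  msh$sets$inner_surface$faces <- msh$sets$inner_surface$faces[-1, ]
  expect_error(apply_internal_pressure(msh, 1e-3), "not closed")
})

test_that("remote-rigid-body constraints let the sphere inflate freely with zero mean motion", {
  sph <- make_sphere_fixture(11.2, 0.317)
  msh <- sweep_shell_mesh(sph, 16, 16, 2)
  mats <- list(sphere = sclera_material())
  sys <- assemble_stiffness(msh, mats)
  expect_error(solve_displacement(sys, numeric(sys$ndof) + 1), "rigid-body")
  f <- apply_internal_pressure(msh, mmhg_to_mpa(20))
  sys <- apply_remote_displacement_zero(sys, msh, "remote-rigid-body")
  u <- solve_displacement(sys, f)
  expect_lt(attr(u, "residual"), 1e-9)
  disp <- matrix(u, ncol = 3, byrow = TRUE)
  cons <- msh$sets$scleral_outer$nodes
  expect_lt(max(abs(colMeans(disp[cons, ]))), 1e-10)
  # radial expansion close to the thin-wall closed form; averaging over the
  # full closed inner surface cancels the stress-free rigid shift that the
  # averaged constraint legitimately superposes
  allnd <- msh$sets$inner_surface$nodes
  C <- c(11.2 + 0.317 / 2, 0, 0)
  rv <- sweep(msh$nodes[allnd, ], 2, C)
  rh <- rv / sqrt(rowSums(rv^2))
  ur <- mean(rowSums(disp[allnd, ] * rh))
  oracle <- sphere_pressure_oracle(11.2, 0.317, mmhg_to_mpa(20),
                                   sclera_material(), "thin")
  expect_equal(ur, oracle$radial_expansion, tolerance = 0.02)
})

test_that("solution is linear in the load and zero for zero load", {
  sph <- make_sphere_fixture(11.2, 0.317)
  msh <- sweep_shell_mesh(sph, 12, 12, 2)
  mats <- list(sphere = sclera_material())
  sys <- assemble_stiffness(msh, mats)
  sys <- apply_remote_displacement_zero(sys, msh)
  u0 <- solve_displacement(sys, numeric(sys$ndof))
  expect_equal(max(abs(u0)), 0)
  f <- apply_internal_pressure(msh, 1e-3)
  u1 <- solve_displacement(sys, f)
  u2 <- solve_displacement(sys, 2 * f)
  expect_lt(max(abs(2 * as.vector(u1) - as.vector(u2))),
            1e-12 * max(abs(u2)) * 10)
})

test_that("work balance holds: external work equals strain energy", {
  sph <- make_sphere_fixture(11.2, 0.317)
  msh <- sweep_shell_mesh(sph, 12, 12, 2)
  mats <- list(sphere = sclera_material())
  sys <- assemble_stiffness(msh, mats)
  sys <- apply_remote_displacement_zero(sys, msh)
  f <- apply_internal_pressure(msh, mmhg_to_mpa(20))
  u <- as.vector(solve_displacement(sys, f))
  W_ext <- sum(u * f)
  W_int <- as.numeric(t(u) %*% (sys$K %*% u))
  expect_equal(W_ext, W_int, tolerance = 1e-9)
})

test_that("a rigidly translated mesh yields identical stresses (frame objectivity)", {
  sph <- make_sphere_fixture(11.2, 0.317)
  mats <- list(sphere = sclera_material())
  run <- function(shift) {
    msh <- sweep_shell_mesh(sph, 12, 12, 2)
    msh$nodes <- sweep(msh$nodes, 2, -shift)
    sys <- assemble_stiffness(msh, mats)
    f <- apply_internal_pressure(msh, mmhg_to_mpa(20))
    sys <- apply_remote_displacement_zero(sys, msh)
    recover_stress(msh, mats, as.vector(solve_displacement(sys, f)))
  }
  r0 <- run(c(0, 0, 0))
  r1 <- run(c(-5, 3, 2))
  expect_equal(r1$stress, r0$stress, tolerance = 1e-7)
})

test_that("a block under uniaxial traction matches the Hooke's-law closed form", {
  fx <- make_block_fixture(4, 8)
  bm <- block_mesh(fx, n_side = 4, n_depth = 4, grade_side = 1,
                   grade_depth = 1)
  E <- 1.3; nu <- 0.31; sig <- 0.02
  mats <- list(block = isotropic_material(E, nu))
  sys <- assemble_stiffness(bm, mats)
  far <- which(abs(bm$nodes[, 1] - 8) < 1e-12)
  dofs <- 3L * (far - 1L) + 1L
  n0 <- far[which.min(abs(bm$nodes[far, 2]) + abs(bm$nodes[far, 3]))]
  ny <- far[which.min(abs(bm$nodes[far, 2]) + abs(bm$nodes[far, 3] - 2))]
  dofs <- c(dofs, 3L * (n0 - 1L) + 2L, 3L * (n0 - 1L) + 3L,
            3L * (ny - 1L) + 2L)
  sys <- tonofem:::fix_dofs(sys, dofs, 0)
  f <- tonofem:::apply_face_traction(bm, bm$sets$corneal_outer$faces,
                                     c(-sig, 0, 0))
  u <- matrix(as.vector(solve_displacement(sys, f)), ncol = 3, byrow = TRUE)
  tip <- mean(u[abs(bm$nodes[, 1]) < 1e-12, 1])
  expect_equal(tip, -sig * 8 / E, tolerance = 0.01)
  rec <- recover_stress(bm, mats, as.vector(t(u)))
  expect_equal(mean(rec$stress[, 1]), sig, tolerance = 0.01)
  expect_equal(mean(rec$von_mises), sig, tolerance = 0.01)
})

test_that("von Mises stress is |sigma| for uniaxial states and zero for hydrostatic states", {
  msh <- unit_hex_mesh()
  E <- 1; nu <- 0.25
  # uniaxial stress: eps_xx = s, lateral = -nu s
  s <- 1e-3
  u_uni <- cbind(msh$nodes[, 1] * s, -nu * s * msh$nodes[, 2],
                 -nu * s * msh$nodes[, 3])
  rec <- recover_stress(msh, mat1, as.vector(t(u_uni)), "standard")
  expect_equal(rec$von_mises, E * s, tolerance = 1e-10)
  expect_equal(rec$stress[1, 2], 0, tolerance = 1e-15)
  # hydrostatic strain
  u_hyd <- msh$nodes * s
  rec2 <- recover_stress(msh, mat1, as.vector(t(u_hyd)), "standard")
  expect_lt(rec2$von_mises, 1e-15)
  # total deformation is the Euclidean displacement norm
  expect_equal(rec$total_deformation,
               sqrt(rowSums(u_uni^2)))
})

test_that("posterior-patch constraints give a nonsingular system", {
  msh <- coarse_eye_model()$mesh
  mats <- eye_materials()
  sys <- assemble_stiffness(msh, mats)
  sys <- apply_remote_displacement_zero(sys, msh, "posterior-patch")
  f <- apply_internal_pressure(msh, mmhg_to_mpa(10))
  u <- solve_displacement(sys, f)
  expect_lt(attr(u, "residual"), 1e-9)
  expect_gt(max(abs(u)), 0)
})
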