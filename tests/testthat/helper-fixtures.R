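# Shared fixtures, memoized across test files (everything is generated in
# code; nothing random enters the pipeline itself).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# one-element unit-cube mesh (for element-level oracles)
unit_hex_mesh <- function() {
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  nodes <- nodes[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  dimnames(nodes) <- NULL
  m <- list(nodes = nodes, elems = matrix(1:8, 1, 8), region = "block",
            sets = list(), type = "block", resolution = list())
  class(m) <- "shell_mesh"
  m
}

# small block mesh with randomly distorted interior nodes (fixed seed)
distorted_block_mesh <- function(seed = 42) {
  fx <- make_block_fixture(2, 2)
  bm <- block_mesh(fx, n_side = 4, n_depth = 2, grade_side = 1,
                   grade_depth = 1)
  interior <- which(apply(bm$nodes, 1, function(x)
    all(abs(x[2:3]) < 0.99) && x[1] > 0.01 && x[1] < 1.99))
  set.seed(seed)
  bm$nodes[interior, ] <- bm$nodes[interior, ] +
    matrix(runif(length(interior) * 3, -0.12, 0.12), ncol = 3)
  attr(bm, "interior_nodes") <- interior
  bm
}

# brute-force trilinear hex stiffness by independent 4x4x4 Gauss-Legendre
# integration (independent shape-derivative code path)
brute_force_hex_stiffness <- function(nodes, E, nu) {
  gl_x <- c(-0.861136311594052575, -0.339981043584856265,
            0.339981043584856265, 0.861136311594052575)
  gl_w <- c(0.347854845137453857, 0.652145154862546143,
            0.652145154862546143, 0.347854845137453857)
  xi <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  et <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  ze <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  K <- matrix(0, 24, 24)
  for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
    p <- c(gl_x[i1], gl_x[i2], gl_x[i3])
    w <- gl_w[i1] * gl_w[i2] * gl_w[i3]
    dN <- cbind(xi * (1 + p[2] * et) * (1 + p[3] * ze),
                et * (1 + p[1] * xi) * (1 + p[3] * ze),
                ze * (1 + p[1] * xi) * (1 + p[2] * et)) / 8
    J <- t(dN) %*% nodes
    dNx <- dN %*% solve(J)
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      B[1, 3 * a - 2] <- dNx[a, 1]; B[2, 3 * a - 1] <- dNx[a, 2]
      B[3, 3 * a] <- dNx[a, 3]
      B[4, 3 * a - 2] <- dNx[a, 2]; B[4, 3 * a - 1] <- dNx[a, 1]
      B[5, 3 * a - 1] <- dNx[a, 3]; B[5, 3 * a] <- dNx[a, 2]
      B[6, 3 * a - 2] <- dNx[a, 3]; B[6, 3 * a] <- dNx[a, 1]
    }
    K <- K + w * det(J) * t(B) %*% D %*% B
  }
  K
}

# default eye model at the reference resolution, shared by contact and
# acceptance tests
reference_eye_model <- function() fixture("reference_eye_model", function()
  build_eye_model(resolution = "reference"))

coarse_eye_model <- function() fixture("coarse_eye_model", function()
  build_eye_model(resolution = "coarse"))

solve_eye <- function(model, iop, probe, depth, n_increments = 10, ...) {
  lc <- load_case(iop = iop, probe = probe, target_depth = depth,
                  n_increments = n_increments)
  solve_indentation(model$mesh, model$materials, lc, model = model$cache,
                    ...)
}

# the default 15-point study sweep (1.7 mm probe) at reference resolution
default_sweep <- function() fixture("default_sweep", function() {
  cfg <- sweep_config()
  run_sweep(cfg, model = reference_eye_model())
})

# Goldmann 3.06 mm probe force series at 20 mmHg, depths 0.3-0.7
goldmann_sweep <- function() fixture("goldmann_sweep", function() {
  cfg <- sweep_config(probes = list(probe_preset("goldmann")), iops = 20)
  run_sweep(cfg, model = reference_eye_model())
})

verification_suite <- function() fixture("verification_suite",
                                         run_verification_suite)
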