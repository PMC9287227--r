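test_that("the default eye mesh carries exactly nine region tags and the named surface sets", {
  msh <- coarse_eye_model()$mesh
  tags <- unique(msh$region)
  expect_length(tags, 9L)
  expect_setequal(tags, c("cornea",
                          paste0("sclera-", c("superior", "inferior",
                                              "nasal", "temporal")),
                          paste0("junction-", c("superior", "inferior",
                                                "nasal", "temporal"))))
  expect_true(tonofem:::face_edge_closed(msh$sets$inner_surface$faces))
  # contact and constraint sets are disjoint element sets
  expect_length(intersect(msh$sets$corneal_outer$elem,
                          msh$sets$scleral_outer$elem), 0L)
})

test_that("node and element counts follow the closed-form sweep formulas", {
  sph <- make_sphere_fixture(11.2, 0.317)
  nA <- 16L; nM <- 16L; nT <- 2L
  msh <- sweep_shell_mesh(sph, nA, nM, nT)
  expect_equal(nrow(msh$elems), nA * nM * nT)
  expect_equal(nrow(msh$nodes), nA * (nM - 1L) * (nT + 1L) + 2L * (nT + 1L))
  expect_gt(min(tonofem:::min_scaled_jacobian(msh)), 0)
})

test_that("the 9-region partition is a function of geometry, not resolution", {
  shell <- coarse_eye_model()$shell
  for (res in list(c(24, 16, 2), c(32, 20, 3))) {
    m <- sweep_shell_mesh(shell, res[1], res[2], res[3])
    expect_length(unique(m$region), 9L)
    expect_setequal(names(m$sets),
                    c("inner_surface", "corneal_outer", "scleral_outer"))
  }
})

test_that("resolution preconditions are enforced", {
  sph <- make_sphere_fixture(10, 1)
  expect_error(sweep_shell_mesh(sph, 7, 16, 2), "n_azimuth")
  expect_error(sweep_shell_mesh(sph, 10, 4, 2), "n_meridian")
  expect_error(sweep_shell_mesh(sph, 10, 8, 1), "n_thickness")
})

test_that("a unit cube element reports ideal quality metrics", {
  q <- mesh_quality(unit_hex_mesh())
  expect_equal(q$min_scaled_jacobian, 1, tolerance = 1e-12)
  expect_equal(q$max_aspect_ratio, 1, tolerance = 1e-12)
  expect_equal(q$avg_edge_length, 1, tolerance = 1e-12)
  expect_equal(q$n_elements, 1L)
  expect_equal(q$n_nodes, 8L)
})

test_that("the reference eye mesh matches the reference average element size within a factor of two", {
  q <- mesh_quality(reference_eye_model()$mesh)
  expect_gt(q$avg_inplane_size, 1.9816 / 2)
  expect_lt(q$avg_inplane_size, 1.9816 * 2)
  expect_gt(q$min_scaled_jacobian, 0)
})

test_that("doubling the surface divisions halves the average in-plane element size", {
  sph <- make_sphere_fixture(11.2, 0.317)
  q1 <- mesh_quality(sweep_shell_mesh(sph, 16, 16, 2))
  q2 <- mesh_quality(sweep_shell_mesh(sph, 32, 32, 2))
  expect_equal(q2$avg_inplane_size / q1$avg_inplane_size, 0.5,
               tolerance = 0.1)
})

test_that("block meshes grade toward the contact face and tag the far faces", {
  fx <- make_block_fixture(20, 20)
  bm <- block_mesh(fx, n_side = 8, n_depth = 4)
  expect_equal(nrow(bm$elems), 8L * 8L * 4L)
  # graded: spacing near the centre of the free face much finer than side/n
  ys <- sort(unique(bm$nodes[abs(bm$nodes[, 1]) < 1e-9 &
                             abs(bm$nodes[, 3]) < 1e-9, 2]))
  expect_lt(min(diff(ys)), 20 / 8 / 2)
  expect_gt(length(bm$sets$fixed_nodes), 0)
  expect_true(all(bm$nodes[bm$sets$corneal_outer$nodes, 1] < 1e-12))
})
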