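test_that("probe gap geometry: face contact, radius cutoff and penetration demand", {
  pb <- probe_spec(1.7)
  expect_equal(probe_gap(pb, 0, c(0, 0, 0)), 0)
  expect_identical(probe_gap(pb, 0, c(0, 1.2, 0)), Inf)
  expect_equal(probe_gap(pb, 0.3, c(0, 0.5, 0)), -0.3)
  # a rim fillet recedes the face near the edge
  pbf <- probe_spec(1.7, edge_fillet_radius = 0.2)
  expect_gt(probe_gap(pbf, 0.3, c(0, 0.8, 0)),
            probe_gap(pb, 0.3, c(0, 0.8, 0)))
})

test_that("zero plunging depth produces zero reaction force at any IOP", {
  model <- coarse_eye_model()
  for (iop in c(0, 20)) {
    res <- solve_eye(model, iop, probe_spec(1.7), 0, n_increments = 1)
    expect_equal(reaction_force(res), 0)
    expect_true(res$converged)
  }
})

test_that("flat-punch force on the elastic block matches the Boussinesq closed form within 5%", {
  rep <- verification_suite()
  punch <- rep[rep$case == "flat_punch_force", ]
  expect_equal(punch$observed, flat_punch_oracle(0.85, 0.2, 0.43, 0.1),
               tolerance = 0.05)
  expect_true(punch$pass)
})

test_that("reaction force equals the penalty force sum, is nonnegative, and the history starts near zero", {
  model <- coarse_eye_model()
  res <- solve_eye(model, 20, probe_spec(1.7), 0.4, n_increments = 8)
  expect_equal(reaction_force(res), sum(res$contact_forces),
               tolerance = 1e-10)
  expect_true(all(res$contact_forces >= 0)) # no adhesive contact
  expect_gte(res$reaction_force, 0)
  expect_lt(res$history$force[1], 0.25 * res$reaction_force)
  expect_true(all(diff(res$history$force) > -1e-12))
  expect_lt(res$max_penetration, 1e-4)
  expect_true(res$converged)
})

test_that("the reaction force is insensitive to the penalty stiffness (adequately stiff penalty)", {
  model <- coarse_eye_model()
  r1 <- solve_eye(model, 20, probe_spec(1.7), 0.4, penalty_scale = 1e3)
  r2 <- solve_eye(model, 20, probe_spec(1.7), 0.4, penalty_scale = 1e4)
  expect_equal(r2$reaction_force, r1$reaction_force, tolerance = 0.01)
})

test_that("both rigid-body-removal modes give contact forces within 5% (Saint-Venant insensitivity)", {
  model <- coarse_eye_model()
  lc1 <- load_case(iop = 20, probe = probe_spec(1.7), target_depth = 0.4,
                   constraint_mode = "remote-rigid-body")
  lc2 <- load_case(iop = 20, probe = probe_spec(1.7), target_depth = 0.4,
                   constraint_mode = "posterior-patch")
  r1 <- solve_indentation(model$mesh, model$materials, lc1,
                          model = model$cache)
  r2 <- solve_indentation(model$mesh, model$materials, lc2,
                          model = model$cache)
  expect_equal(r2$reaction_force, r1$reaction_force, tolerance = 0.05)
})

test_that("applanation force exceeds the Imbert-Fick bound pressure x contact area for the stiff cornea", {
  model <- reference_eye_model()
  res <- solve_eye(model, 20, probe_spec(1.7), 0.5)
  cand <- res$contact_nodes[res$contact_forces > 0]
  # active contact area approximated by the tributary share of the face
  area <- pi * 0.85^2 * length(cand) / length(res$contact_nodes)
  expect_gt(res$reaction_force, mmhg_to_mpa(20) * area)
})

test_that("probe-induced deformation localizes at the contact patch rim", {
  model <- coarse_eye_model()
  res0 <- solve_eye(model, 20, probe_spec(1.7), 0, n_increments = 1)
  res <- solve_eye(model, 20, probe_spec(1.7), 0.5)
  du <- sqrt(rowSums((res$u - res0$u)^2))
  node <- which.max(du)
  rad <- sqrt(sum(model$mesh$nodes[node, 2:3]^2))
  expect_lt(abs(rad - 0.85), 1.5 * 0.85)
})

test_that("probe sizes 1.7 and 3.06 mm give comparable forces at shallow depth", {
  model <- reference_eye_model()
  r1 <- solve_eye(model, 20, probe_spec(1.7), 0.3)
  r2 <- solve_eye(model, 20, probe_preset("goldmann"), 0.3)
  expect_lt(abs(r2$reaction_force / r1$reaction_force - 1), 0.35)
})

test_that("the updated-geometry mode runs and stiffens the response", {
  model <- coarse_eye_model()
  lc <- load_case(iop = 20, probe = probe_spec(1.7), target_depth = 0.4,
                  n_increments = 4)
  r_lin <- solve_indentation(model$mesh, model$materials, lc,
                             model = model$cache)
  r_upd <- solve_indentation(model$mesh, model$materials, lc,
                             updated_geometry = TRUE)
  expect_true(r_upd$converged)
  expect_gt(r_upd$reaction_force, 0.8 * r_lin$reaction_force)
})
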