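test_that("sphere pressure closed forms evaluate correctly and scale linearly", {
  o <- sphere_pressure_oracle(11.2, 0.317, mmhg_to_mpa(20),
                              sclera_material(), "thin")
  expect_equal(o$hoop_stress, 0.04711, tolerance = 1e-3)
  expect_equal(sphere_pressure_oracle(11.2, 0.317, 0)$hoop_stress, 0)
  o2 <- sphere_pressure_oracle(11.2, 0.317, 2 * mmhg_to_mpa(20))
  expect_equal(o2$hoop_stress, 2 * o$hoop_stress)
  # thick shell auto-switches to the Lame form
  thick <- sphere_pressure_oracle(10, 4, 1e-3)
  expect_identical(thick$form, "lame")
  # Lame inner-surface stress exceeds... differs from thin-wall by O(t/R)
  lame <- sphere_pressure_oracle(11.2, 0.317, mmhg_to_mpa(20),
                                 sclera_material(), "lame")
  expect_lt(abs(lame$hoop_stress / o$hoop_stress - 1), 0.03)
})

test_that("flat punch closed form is linear in radius and depth", {
  expect_equal(flat_punch_oracle(0.85, 0.2, 0.43, 0.1), 4.171e-2,
               tolerance = 1e-3)
  expect_equal(flat_punch_oracle(0.85, 0.2, 0.43, 0), 0)
  expect_equal(flat_punch_oracle(1.7, 0.2, 0.43, 0.1),
               2 * flat_punch_oracle(0.85, 0.2, 0.43, 0.1))
})

test_that("the verification suite passes all oracle cases at the preset resolutions", {
  rep <- verification_suite()
  expect_s3_class(rep, "verification_report")
  expect_true(all(rep$pass, na.rm = TRUE))
  expect_true(all(!is.na(rep$pass[rep$case == "flat_punch_force"])))
  # refinement convergence of the sphere case: error decreases with mesh
  sph <- rep[rep$case == "sphere_pressure_hoop", ]
  expect_true(all(diff(sph$rel_error) < 0))
})
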