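test_that("pressure unit conversion reproduces the clinical reference value", {
  expect_equal(mmhg_to_mpa(20) * 1e3, 2.66645, tolerance = 1e-5)
  expect_equal(mpa_to_mmhg(mmhg_to_mpa(c(0, 10, 15, 20))), c(0, 10, 15, 20))
})

test_that("derived bulk and shear moduli match the tissue property table to 4 significant digits", {
  cornea <- cornea_material()
  sclera <- sclera_material()
  expect_equal(signif(cornea$bulk_modulus, 5), 0.47619)
  expect_equal(signif(cornea$shear_modulus, 4), 0.06993)
  expect_equal(signif(sclera$bulk_modulus, 5), 3.3333)
  expect_equal(signif(sclera$shear_modulus, 5), 0.71429)
})

test_that("material validation rejects non-physical inputs", {
  expect_error(isotropic_material(-1, 0.3), "young_modulus")
  expect_error(isotropic_material(1, 0.5), "poisson_ratio")
  expect_error(isotropic_material(1, 0), "poisson_ratio")
})

test_that("the eye material map covers all nine regions, junction defaulting to sclera", {
  m <- eye_materials()
  expect_length(m, 9L)
  expect_identical(m[["junction-nasal"]]$young_modulus,
                   sclera_material()$young_modulus)
  expect_identical(m[["cornea"]]$poisson_ratio, 0.43)
})
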