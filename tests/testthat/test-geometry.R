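quads <- c("superior", "inferior", "nasal", "temporal")

test_that("geometry parameter validation enforces the documented invariants", {
  expect_s3_class(ocular_geometry_params(), "ocular_geometry_params")
  expect_error(ocular_geometry_params(corneal_central_thickness = -1),
               "positive")
  expect_error(ocular_geometry_params(junction_angle_nasal = 150),
               "160")
  expect_error(ocular_geometry_params(corneal_peripheral_thickness = 0.4),
               "peripheral")
  expect_error(ocular_geometry_params(axial_length = 7), "axial_length")
  expect_error(ocular_geometry_params(corneal_base_radius = 8),
               "corneal_base_radius")
})

test_that("meridian profiles reproduce the printed junction angles and thickness values", {
  p <- ocular_geometry_params()
  targets <- c(superior = 178.1, inferior = 177.7, nasal = 173.9,
               temporal = 177.0)
  for (q in quads) {
    pr <- build_meridian_profile(p, q)
    expect_equal(junction_angle(pr$outer_xr), targets[[q]], tolerance = 0.1)
    # apex wall thickness equals the central corneal thickness
    d_apex <- sqrt(sum((pr$outer_xr(0) - pr$inner_xr(0))^2))
    expect_equal(d_apex, 0.52, tolerance = 1e-9)
    # inner polyline strictly inside outer
    expect_true(all(pr$inner[, 1] > pr$outer[, 1] - 1e-12 |
                    pr$inner[, 2] < pr$outer[, 2] + 1e-12))
  }
})

test_that("wall thickness stays within the printed bounds outside the junction blend", {
  p <- ocular_geometry_params()
  pr <- build_meridian_profile(p, "nasal")
  u <- seq(0, 1, length.out = 400)
  s <- pr$arc_of_u(u)
  th <- sqrt(rowSums((pr$outer_xr(u) - pr$inner_xr(u))^2))
  in_band <- abs(s - pr$s_junction) <= pr$band_half_width + 0.05
  expect_true(all(th[!in_band] >= 0.317 - 1e-6))
  expect_true(all(th[!in_band] <= 0.67 + 1e-6))
  # the blend itself is monotone and bounded by the same limits
  expect_true(all(th >= 0.317 - 1e-6 & th <= 0.67 + 1e-6))
})

test_that("junction angles of 180 degrees give a tangent, inflection-free meridian", {
  p <- ocular_geometry_params(junction_angle_superior = 180,
                              junction_angle_inferior = 180,
                              junction_angle_nasal = 180,
                              junction_angle_temporal = 180)
  pr <- build_meridian_profile(p, "nasal")
  expect_equal(junction_angle(pr$outer_xr), 180, tolerance = 0.05)
  # discrete curvature sign (turn direction) constant around the junction
  u <- seq(pr$u_junction - 0.1, pr$u_junction + 0.1, length.out = 81)
  pts <- pr$outer_xr(u)
  v <- diff(pts)
  cross <- v[-nrow(v), 1] * v[-1, 2] - v[-nrow(v), 2] * v[-1, 1]
  cross <- cross[abs(cross) > 1e-14]
  expect_true(all(cross > 0) || all(cross < 0))
})

test_that("infeasible closures raise a geometric error naming the quadrant", {
  p <- ocular_geometry_params(axial_length = 15)
  expect_error(build_meridian_profile(p, "temporal"),
               "infeasibility in quadrant 'temporal'")
})

test_that("the loft reproduces each profile at its key azimuth and varies continuously between", {
  p <- ocular_geometry_params()
  shell <- loft_eye_surface(lapply(quads, function(q)
    build_meridian_profile(p, q)))
  az <- c(nasal = 0, superior = pi / 2, temporal = pi, inferior = 3 * pi / 2)
  targets <- c(superior = 178.1, inferior = 177.7, nasal = 173.9,
               temporal = 177.0)
  for (q in quads) {
    f <- function(u) shell$eval_xr(rep(az[[q]], length(u)), u, "outer")
    expect_equal(junction_angle(f), targets[[q]], tolerance = 0.1)
  }
  th_ring <- seq(0, 2 * pi, length.out = 181)[-181]
  angs <- vapply(th_ring, function(t0)
    junction_angle(function(u) shell$eval_xr(rep(t0, length(u)), u,
                                             "outer")), 0)
  expect_true(all(angs > 173.9 - 0.5 & angs < 178.1 + 0.5))
  expect_lt(max(abs(diff(angs))), 0.5) # continuous variation
})

test_that("equal junction angles produce an axisymmetric lofted shell", {
  p <- ocular_geometry_params(junction_angle_superior = 176,
                              junction_angle_inferior = 176,
                              junction_angle_nasal = 176,
                              junction_angle_temporal = 176)
  shell <- loft_eye_surface(lapply(quads, function(q)
    build_meridian_profile(p, q)))
  u <- seq(0.05, 0.95, length.out = 40)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ref <- shell$eval_xr(rep(0, length(u)), u, "outer")
  for (t0 in th) {
    dev <- max(abs(shell$eval_xr(rep(t0, length(u)), u, "outer") - ref))
    expect_lt(dev, 1e-9)
  }
})

test_that("sphere fixture is a uniform shell with the closed-form volume", {
  sph <- make_sphere_fixture(10, 1)
  msh <- sweep_shell_mesh(sph, 64, 64, 2)
  vol <- mesh_volume(msh)
  exact <- 4 / 3 * pi * (10.5^3 - 9.5^3)
  expect_equal(vol, exact, tolerance = 0.005)
  # azimuthal slices identical
  u <- seq(0, 1, length.out = 21)
  ref <- sph$eval_xr(rep(0, 21), u, "outer")
  expect_equal(sph$eval_xr(rep(1.1, 21), u, "outer"), ref)
  expect_error(make_sphere_fixture(5, 6), "thickness")
})

test_that("block fixture tags six faces with one contact face and rejects degenerate sides", {
  fx <- make_block_fixture(20, 20)
  expect_equal(nrow(fx$faces), 6L)
  expect_equal(sum(fx$faces$role == "contact"), 1L)
  # >= 10 probe radii wide for the half-space approximation with a 1.7 mm probe
  expect_gte(fx$side / 2, 10 * 0.85)
  expect_error(make_block_fixture(0, 20), "side")
})

test_that("probe specification validates and provides the clinical presets", {
  expect_equal(probe_preset("goldmann")$diameter, 3.06)
  expect_equal(probe_preset("validation")$diameter, 2.0)
  expect_equal(probe_spec()$radius, 0.85)
  expect_error(probe_spec(-1), "diameter")
  expect_error(probe_spec(1.7, edge_fillet_radius = 1), "fillet")
})

test_that("shell surfaces export as ASCII STL", {
  sph <- make_sphere_fixture(11.2, 0.317)
  path <- tempfile(fileext = ".stl")
  write_stl(sph, path, n_azimuth = 16, n_meridian = 12)
  lines <- readLines(path)
  expect_match(lines[1], "^solid")
  expect_gt(sum(grepl("^facet normal", lines)), 100)
  unlink(path)
})
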