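# Synthetic anatomy: phantom geometry, target band, conductivity assignment.

test_that("slab dimensions follow extent and spacing", {
  g <- build_phantom("slab", list(extent_mm = c(40, 40, 20)), 0.5)
  expect_identical(dim(g$labels), c(80L, 80L, 40L))
  # label conservation: every voxel has exactly one declared class
  counts <- table(g$labels)
  expect_identical(sum(counts), length(g$labels))
  expect_true(all(as.integer(names(counts)) %in% g$label_names))
})

test_that("build_phantom rejects unresolvable or undersized grids", {
  expect_error(build_phantom("slab", spacing_mm = 2), "spacing_mm")
  expect_error(build_phantom("slab", list(wall_mm = 1.5), spacing_mm = 1),
               "resolve the wall")
  expect_error(build_phantom("antrum", list(extent_mm = c(50, 64, 72)),
                             spacing_mm = 0.5), "60 mm")
})

test_that("antrum wall is 2.5 mm thick along surface normals", {
  g <- antrum_half()
  p <- g$params
  # probe radial normals through the cylindrical vein wall around the band
  for (alpha in seq(-2, 2, length.out = 7)) {
    for (z in p$band_z_mm + c(-2, 0, 2)) {
      thick <- pfafield:::probe_wall_thickness(g, alpha, z)
      expect_true(abs(thick - 2.5) <= g$spacing_mm,
                  label = sprintf("wall thickness at alpha=%.2f z=%.1f: %.2f mm",
                                  alpha, z, thick))
    }
  }
})

test_that("antrum phantom is mirror-symmetric about its construction plane", {
  g <- antrum_coarse()
  expect_identical(g$labels, g$labels[dim(g$labels)[1]:1, , ])
  t <- target_coarse()
  left <- sum(t$mask[seq_len(dim(t$mask)[1] / 2), , ])
  right <- sum(t$mask) - left
  expect_identical(left, right)
})

test_that("myocardial and target volumes converge under grid refinement", {
  vol_myo <- function(g) sum(g$labels == g$label_names[["myocardium"]]) *
    g$spacing_mm^3
  v_half <- vol_myo(antrum_half())
  v_quarter <- vol_myo(build_phantom("antrum", spacing_mm = 0.25))
  expect_lt(abs(v_quarter - v_half) / v_half, 0.05)

  # target volume approaches the analytic 6 x 47 x 2.5 product
  v1 <- define_target(antrum_coarse())$volume_mm3
  v05 <- define_target(antrum_half())$volume_mm3
  expect_lt(abs(v05 - 705), abs(v1 - 705))
})

test_that("target band has the nominal volume and stays inside the wall", {
  t <- define_target(antrum_half())
  # one voxel-layer tolerance on each bounding dimension at 0.5 mm
  tol <- 705 * ((1 + 0.5 / 2.5) * (1 + 0.5 / 6) * (1 + 0.5 / 47) - 1)
  expect_lt(abs(t$volume_mm3 - 705), tol)
  g <- antrum_half()
  expect_false(any(g$labels[t$idx] == g$label_names[["blood"]]))
  expect_true(all(g$labels[t$idx] == g$label_names[["myocardium"]]))
})

test_that("degenerate target bands are rejected", {
  g <- antrum_coarse()
  expect_error(define_target(g, band_width_mm = 0), "width")
  expect_error(define_target(g, band_length_mm = 500), "circumference")
})

test_that("conductivity assignment maps classes and flags missing entries", {
  g <- antrum_coarse()
  cond <- assign_conductivity(g, default_conductivity_table())
  blood_idx <- g$labels == g$label_names[["blood"]]
  expect_true(all(cond$sigma0[blood_idx] == 0.70))
  expect_true(all(cond$sigma0 > 0))

  tab <- default_conductivity_table()
  tab$blood <- NULL
  expect_error(assign_conductivity(g, tab), "blood")

  # single-label slab gives a uniform map
  allmyo <- build_phantom("slab", list(extent_mm = c(10, 10, 10), base_mm = 0,
                                       wall_mm = 10), 0.5)
  cu <- assign_conductivity(allmyo, default_conductivity_table())
  expect_equal(unique(as.vector(cu$sigma0)), 0.20)
})

test_that("sigmoid conductivity has the stated asymptotes and monotonicity", {
  m <- nonlinear_conductivity(sigma0 = 0.2, A = 2, E_mid = 500, k = 80)
  expect_equal(sigma_of_E(m, 0), 0.2, tolerance = exp(-500 / 80) * 3)
  expect_equal(sigma_of_E(m, 500), 0.2 * 2, tolerance = 1e-12)
  expect_equal(sigma_of_E(m, 1e6), 0.2 * 3, tolerance = 1e-12)
  e <- seq(0, 2000, by = 10)
  expect_true(all(diff(sigma_of_E(m, e)) > 0))
  # signed fold change: a conductivity decrease is also monotone
  md <- nonlinear_conductivity(sigma0 = 0.2, A = -0.5)
  expect_true(all(diff(sigma_of_E(md, e)) < 0))
  expect_error(sigma_of_E(m, -1), "negative")
})
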