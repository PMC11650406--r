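# Catheter electrode sets and vectoring schemes.

fig_counts <- c(oneshot_sphere = 3L, focal_sphere_9mm = 7L, penta_spline = 6L,
                circular = 3L, flex_splines = 8L, balloon = 8L)

test_that("every design builds disjoint blood-side electrodes with the published vector counts", {
  g <- antrum_coarse()
  t <- target_coarse()
  for (d in names(fig_counts)) {
    es <- build_catheter(d, g, t)
    idx <- unlist(lapply(es$electrodes, `[[`, "idx"))
    expect_false(anyDuplicated(idx) > 0, label = paste(d, "disjoint"))
    expect_true(all(g$labels[idx] == g$label_names[["blood"]]),
                label = paste(d, "electrodes in blood"))
    sc <- make_vector_scheme(d, es)
    expect_identical(sc$n_counted_vectors, fig_counts[[d]],
                     label = paste(d, "counted vectors"))
    for (dv in sc$deliveries) {
      expect_gte(sum(dv$polarity > 0), 1)
      expect_gte(sum(dv$polarity < 0), 1)
    }
    monopolar <- d %in% c("focal_sphere_9mm", "oneshot_sphere")
    expect_identical(!is.null(es$return_patch), monopolar,
                     label = paste(d, "return patch"))
  }
})

test_that("building a design twice yields identical masks", {
  g <- antrum_coarse()
  t <- target_coarse()
  a <- build_catheter("penta_spline", g, t)
  b <- build_catheter("penta_spline", g, t)
  expect_identical(a$electrodes, b$electrodes)
})

test_that("circular rings are evenly pitched around the closed loop", {
  g <- antrum_coarse()
  es <- build_catheter("circular", g, target_coarse())
  expect_length(es$electrodes, 10L)
  cs <- sort(vapply(es$electrodes, `[[`, numeric(1), "center_s"))
  gaps <- diff(cs)
  # uniform pitch: the loop circumference over 10 electrodes (the nominal
  # 6.7 mm pitch does not fit the default vein circumference)
  expect_equal(unname(gaps), rep(2 * pi * 10 / 10, 9), tolerance = 1e-6)
})

test_that("penta-spline splines are single electrical nodes of four rings", {
  g <- antrum_half()
  t <- define_target(g)
  es <- build_catheter("penta_spline", g, t)
  expect_length(es$electrodes, 10L)  # 5 splines x 2 rotated applications
  e1 <- es$electrodes[[1]]
  co <- pfafield:::grid_coordinates(dim(g$labels), g$spacing_mm, g$origin_mm)
  z <- co$z[e1$idx]
  clusters <- cutree(hclust(dist(unique(round(z, 3))), method = "single"), h = 1)
  expect_identical(length(unique(clusters)), 4L)
})

test_that("oneshot diamond openings are not electrode voxels", {
  g <- slab_half()
  t <- define_target(g, 20, 6)
  es <- build_catheter("oneshot_sphere", g, t,
                       list(n_panels = 1L, panel_width_mm = 12,
                            panel_height_mm = 12, diamond_pitch_mm = 4))
  pitch <- 4  # panel_width / 3
  fr <- pfafield:::surface_frame(g)
  panel <- es$electrodes[[1]]
  # opening centre: ds = pitch/2, a = 0, first blood layer
  open_idx <- which(abs(fr$S - pitch / 2) <= 0.26 & abs(fr$A) <= 0.26 &
                      fr$D >= 0 & fr$D <= 0.51)
  expect_gt(length(open_idx), 0)
  expect_false(any(open_idx %in% panel$idx))
  # strut crossing at the panel centre is metal
  cross_idx <- which(abs(fr$S) <= 0.26 & abs(fr$A) <= 0.26 &
                       fr$D >= 0 & fr$D <= 0.51)
  expect_true(all(cross_idx %in% panel$idx))
})

test_that("analytic ECD-denominator areas follow the per-design conventions", {
  g <- antrum_coarse()
  t <- target_coarse()
  areas <- c(circular = pi * 0.16 * 0.3,
             penta_spline = 4 * pi * 0.13 * 0.3,
             flex_splines = 0.36^2,
             balloon = 0.36^2)
  for (d in names(areas)) {
    es <- build_catheter(d, g, t)
    expect_equal(electrode_metal_area(d, es), unname(areas[d]),
                 tolerance = 1e-9, label = d)
  }
})

test_that("rasterized metal agrees with the analytic formulas at 0.25 mm", {
  g <- build_phantom("slab", list(extent_mm = c(40, 40, 16), base_mm = 3),
                     spacing_mm = 0.25)
  t <- define_target(g, 20, 6)
  h <- g$spacing_mm
  # flat flex electrode: plate area from the rasterized volume over the
  # 1 mm contact-layer thickness
  esf <- build_catheter("flex_splines", g, t,
                        list(n_splines = 1L, electrodes_per_spline = 3L))
  nv <- length(esf$electrodes[[2]]$idx)
  area_rast <- nv * h^3 / 1.0 / 100  # cm^2
  expect_lt(abs(area_rast - 0.1296) / 0.1296, 0.15)
  # circular ring electrode: rasterized volume vs the solid cylinder
  esc <- build_catheter("circular", g, t, list(n_electrodes = 4L))
  vol <- length(esc$electrodes[[2]]$idx) * h^3
  vol_exact <- pi * 0.8^2 * 3
  expect_lt(abs(vol - vol_exact) / vol_exact, 0.15)
})

test_that("balloon adds an insulating interior behind the flex layout", {
  g <- antrum_coarse()
  t <- target_coarse()
  ef <- build_catheter("flex_splines", g, t)
  eb <- build_catheter("balloon", g, t)
  expect_identical(lapply(ef$electrodes, `[[`, "idx"),
                   lapply(eb$electrodes, `[[`, "idx"))
  expect_gt(length(eb$insulator_idx), 1000)
  expect_null(ef$insulator_idx)
  g2 <- apply_insulators(g, eb)
  expect_true(all(g2$labels[eb$insulator_idx] ==
                    g2$label_names[["balloon_insulator"]]))
  # insulator never displaces wall or electrodes
  expect_false(any(eb$insulator_idx %in% unlist(lapply(eb$electrodes, `[[`, "idx"))))
})

test_that("focal sphere placements reposition along the band", {
  g <- antrum_coarse()
  t <- target_coarse()
  es <- build_catheter("focal_sphere_9mm", g, t)
  sc <- make_vector_scheme("focal_sphere_9mm", es)
  offs <- vapply(sc$deliveries, `[[`, numeric(1), "placement_offset_mm")
  expect_equal(offs, seq(-18, 18, by = 6))
  es3 <- pfafield:::electrodes_for_delivery(es, g, t, sc$deliveries[[1]])
  expect_false(identical(es3$electrodes$cage$idx, es$electrodes$cage$idx))
  expect_equal(es3$electrodes$cage$center_s, -18)
})

test_that("unknown designs and empty rasterizations are rejected", {
  g <- antrum_coarse()
  t <- target_coarse()
  expect_error(build_catheter("laser", g, t), "unknown catheter design")
  expect_error(make_vector_scheme("laser", build_catheter("circular", g, t)),
               "unknown catheter design")
})
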