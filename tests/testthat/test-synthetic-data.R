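# Synthetic-data generators: parametric stems, rasterized label volumes,
# trait tables, spectra.

test_that("generated geometry has the requested structure", {
  geo <- generate_stem_geometry(stem_params(n_outer_bundles = 27,
                                            n_inner_bundles = 11, seed = 3))
  rings <- vapply(geo$fibres, function(f) f$ring, character(1))
  expect_length(geo$fibres, 38L)
  expect_identical(sum(rings == "outer"), 27L)
  expect_identical(sum(rings == "inner"), 11L)
  # every centerline point inside the culm wall annulus and z range
  for (f in geo$fibres) {
    r <- sqrt(f$points[, 1]^2 + f$points[, 2]^2)
    expect_true(all(r >= geo$params$inner_radius_Ri - 1e-9))
    expect_true(all(r <= geo$params$outer_radius_Ro + 1e-9))
    expect_true(all(diff(f$points[, 3]) > 0))
  }
})

test_that("vertical-fibre limit: constant (x, y), tangents parallel to z", {
  geo <- generate_stem_geometry(stem_params(incline_mean_deg = 90,
                                            incline_sd_deg = 0, seed = 1))
  for (f in geo$fibres) {
    expect_equal(diff(range(f$points[, 1])), 0)
    expect_equal(diff(range(f$points[, 2])), 0)
    expect_equal(compute_incline(f), 90)
  }
})

test_that("45-degree incline drifts one z-step per step, exactly", {
  geo <- generate_stem_geometry(small_stem(incline = 45, z_step = 1,
                                           length_L = 10))
  for (f in geo$fibres) {
    steps <- diff(f$points)
    drift <- sqrt(steps[, 1]^2 + steps[, 2]^2)
    expect_equal(drift, steps[, 3], tolerance = 1e-12) # tan(90 - 45) = 1
    expect_equal(compute_incline(f), 45, tolerance = 1e-9)
  }
})

test_that("incline of noiseless parametric fibres is recovered exactly", {
  for (inc in c(55, 70, 84)) {
    geo <- generate_stem_geometry(small_stem(incline = inc, sd = 3, seed = 9))
    for (f in geo$fibres) {
      expect_equal(compute_incline(f), f$incline_delta, tolerance = 1e-9)
    }
  }
})

test_that("geometry generation is deterministic per seed", {
  g1 <- generate_stem_geometry(stem_params(seed = 7))
  g2 <- generate_stem_geometry(stem_params(seed = 7))
  g3 <- generate_stem_geometry(stem_params(seed = 8))
  expect_identical(g1$fibres, g2$fibres)
  expect_false(identical(g1$fibres[[1]]$points, g3$fibres[[1]]$points))
})

test_that("invalid parameters and bundle collisions raise classed errors", {
  expect_error(stem_params(inner_radius_Ri = 2.0), class = "cf_parameter_error")
  expect_error(stem_params(ring_radius_outer = 2.5), class = "cf_parameter_error")
  expect_error(stem_params(incline_mean_deg = 0), class = "cf_parameter_error")
  expect_error(stem_params(bundle_radius = 0.5), class = "cf_parameter_error")
  # too many bundles for the ring circumference -> colliding pair named
  err <- tryCatch(
    generate_stem_geometry(stem_params(n_outer_bundles = 45,
                                       azimuth_jitter_deg = 0)),
    error = function(e) e
  )
  expect_s3_class(err, "cf_geometry_error")
  expect_match(conditionMessage(err), "overlap")
})

test_that("rasterization labels and trivial cases behave", {
  geo0 <- generate_stem_geometry(stem_params(n_outer_bundles = 0,
                                             n_inner_bundles = 0))
  vol0 <- rasterize_label_volume(geo0, volume_spec(c(64, 64, 8)))
  expect_setequal(unique(as.vector(vol0)), c(0L, 1L))
  # matrix voxels form an annulus in every slice
  spec <- attr(vol0, "spec")
  xs <- (seq_len(64) - 0.5) * spec$voxel_size[1] - spec$field_of_view[1] / 2
  r <- sqrt(outer(xs^2, xs^2, `+`))
  ann <- r >= geo0$params$inner_radius_Ri & r <= geo0$params$outer_radius_Ro
  for (iz in c(1, 4, 8)) expect_identical(vol0[, , iz] == 1L, ann)
  # stem wider than the field of view
  wide <- generate_stem_geometry(stem_params(outer_radius_Ro = 2.5,
                                             inner_radius_Ri = 1.2,
                                             ring_radius_outer = 2.2,
                                             ring_radius_inner = 1.5))
  expect_error(rasterize_label_volume(wide), class = "cf_spatial_error")
})

test_that("per-slice bundle component counts are resolution invariant", {
  geo <- generate_stem_geometry(small_stem(seed = 5))
  v1 <- rasterize_label_volume(geo, volume_spec(c(168, 168, 8),
                                                c(4.2, 4.2, 4)))
  v2 <- rasterize_label_volume(geo, volume_spec(c(336, 336, 8),
                                                c(4.2, 4.2, 4)))
  n1 <- count_bundles(extract_bundle_centerlines(v1))$counts
  n2 <- count_bundles(extract_bundle_centerlines(v2))$counts
  expect_identical(n1, c(outer = 8L, inner = 4L))
  expect_identical(n1, n2)
})

test_that("label volumes survive an NRRD round trip in both encodings", {
  geo <- generate_stem_geometry(small_stem())
  vol <- rasterize_label_volume(geo, volume_spec(c(64, 64, 6), c(4.2, 4.2, 3)))
  for (enc in c("ascii", "raw")) {
    path <- tempfile(fileext = ".nrrd")
    write_nrrd(vol, path, encoding = enc)
    back <- read_nrrd(path)
    expect_equal(unclass(back)[seq_along(vol)], as.integer(vol))
    expect_equal(attr(back, "spec")$voxel_size, attr(vol, "spec")$voxel_size,
                 tolerance = 1e-9)
    unlink(path)
  }
  expect_error(read_nrrd(tempfile()), class = "cf_io_error")
})

test_that("trait tables follow the additive F2 model", {
  # target_H2 = 0: F2 variance is the environmental variance only
  m0 <- trait_gen_model(100, 4, 80, 9, target_H2 = 0, n_per_parent = 50,
                        n_f2 = 4000, seed = 21)
  tab0 <- generate_trait_table(m0)
  v_f2 <- var(tab0$trait[tab0$generation == "F2"])
  expect_equal(v_f2, 4 * 9, tolerance = 0.1 * 36)
  expect_identical(levels(tab0$generation), c("P1", "P2", "F2"))
  expect_error(trait_gen_model(1, 1, 1, 1, target_H2 = 1),
               class = "cf_parameter_error")
  expect_error(trait_gen_model(1, 0, 1, 1), class = "cf_parameter_error")
  # determinism
  expect_identical(generate_trait_table(m0), generate_trait_table(m0))
})

test_that("plant-height preset reproduces the parental distributions", {
  # published parental plant heights: 110.7 +- 6.9 vs 95 +- 15.2 cm
  m <- trait_preset("PH", n_per_parent = 100, seed = 4)
  tab <- generate_trait_table(m)
  p1 <- tab$PH[tab$generation == "P1"]
  p2 <- tab$PH[tab$generation == "P2"]
  expect_lt(abs(mean(p1) - 110.7), 2 * 6.9 / sqrt(100))
  expect_lt(abs(mean(p2) - 95), 2 * 15.2 / sqrt(100))
})

test_that("heritability is recovered from generated tables", {
  m <- trait_gen_model(110.7, 6.9, 95, 15.2, target_H2 = 0.6,
                       n_per_parent = 500, n_f2 = 2000, seed = 13)
  expect_equal(heritability_h2(generate_trait_table(m))$H2, 0.6,
               tolerance = 0.05)
})

test_that("spectrum generation is an exact linear mixture", {
  lib <- component_library()
  z <- generate_spectra(lib, rep(0, 7), noise_sd = 0, baseline_sd = 0)
  expect_true(all(z$A == 0))
  expect_error(generate_spectra(lib, c(-1, rep(0, 6))),
               class = "cf_parameter_error")
  expect_error(generate_spectra(lib, rep(1, 5)), class = "cf_parameter_error")
  # noiseless weights recovered exactly by the decomposition
  w <- c(0.5, 0.3, 0.2, 0, 0, 0, 0)
  s <- generate_spectra(lib, w, noise_sd = 0, baseline_sd = 0)
  dec <- emsc_decompose(spectrum(s$wavenumber, s$A[1, ]), lib)
  expect_equal(unname(dec$loadings), w, tolerance = 1e-10)
  expect_lt(dec$residual_rms, 1e-10)
  # determinism under a fixed seed
  a <- generate_spectra(lib, w, noise_sd = 0.01, seed = 5)
  b <- generate_spectra(lib, w, noise_sd = 0.01, seed = 5)
  expect_identical(a$A, b$A)
})
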