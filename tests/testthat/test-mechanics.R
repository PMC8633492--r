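# Force-redistribution model: surface loading, propagation, per-fibre
# partitioning, attack sweep, optimal angle, rendering.

test_that("surface load matches the projected-area integral", {
  geo <- generate_stem_geometry(stem_params(seed = 2))
  g <- build_cylindrical_grid(geo)
  fld <- surface_load(g, impact_condition(attack_azimuth_deg = 137))
  # p * 2 Ro L with mm^2 -> m^2 conversion
  expect_equal(fld$total_load_N, 1 * 2 * 1.8e-3 * 15e-3, tolerance = 0.01)
  expect_equal(sum(fld$magnitude), fld$total_load_N, tolerance = 1e-12)
  # leeward half carries nothing
  leeward <- which(cospi((g$alpha_deg - 137) / 180) <= 0)
  expect_true(all(fld$magnitude[leeward, , ] == 0))
  # linearity in pressure
  fld2 <- surface_load(g, impact_condition(137, pressure_Nm2 = 2))
  expect_equal(fld2$Fin, 2 * fld$Fin, tolerance = 1e-12)
  # azimuth outside 1..360 wraps with a warning
  expect_warning(impact_condition(400), class = "cf_angle_wrap_warning")
})

test_that("propagation conserves magnitude and fibre-free stems stay planar", {
  geo0 <- generate_stem_geometry(stem_params(n_outer_bundles = 0,
                                             n_inner_bundles = 0))
  g0 <- build_cylindrical_grid(geo0)
  pr0 <- propagate_forces(surface_load(g0, impact_condition(90)), g0)
  expect_true(all(pr0$warp$warp == 0))
  # matrix voxels never generate an axial component
  expect_true(all(pr0$field$Fout[, , , 3] == 0))
  # full magnitude reaches the inner wall
  expect_equal(sum(pr0$field$inner_residual), pr0$field$total_load_N,
               tolerance = 1e-12)
  expect_lt(pr0$field$conservation_residual, 1e-9)
})

test_that("vertical fibres deflect nothing", {
  geo <- generate_stem_geometry(stem_params(n_outer_bundles = 6,
                                            n_inner_bundles = 0,
                                            incline_mean_deg = 90,
                                            incline_sd_deg = 0))
  g <- build_cylindrical_grid(geo)
  expect_gt(sum(g$is_fibre), 0)
  pr <- propagate_forces(surface_load(g, impact_condition(45)), g)
  expect_equal(max(abs(pr$warp$warp)), 0)
})

test_that("an aligned inclined fibre deflects cos(delta) of the load", {
  # straight fibre at azimuth 0 drifting toward the axis (phi = 180);
  # attack from azimuth 180 pushes along +x, so dir . t = -cos(60)
  geo <- generate_stem_geometry(stem_params(n_outer_bundles = 0,
                                            n_inner_bundles = 0))
  geo$fibres <- list(straight_fibre(1.55, 0, 60, 180, z_step = 0.1))
  g <- build_cylindrical_grid(geo)
  expect_gt(sum(g$is_fibre), 0)
  fld <- surface_load(g, impact_condition(180))
  pr <- propagate_forces(fld, g)
  # per loaded column crossing the fibre: residual = sqrt(1 - cos^2(60)) M0
  # and the summed signed warp of the column is -cos(60) M0
  crossed <- apply(g$is_fibre, c(1, 3), any)
  M0 <- fld$magnitude[, dim(g$is_fibre)[2], ]
  sel <- crossed & M0 > 0
  expect_gt(sum(sel), 0)
  expect_equal(pr$field$inner_residual[sel] / M0[sel],
               rep(sqrt(1 - 0.25), sum(sel)), tolerance = 1e-9)
  expect_equal(sum(pr$warp$warp), -0.5 * sum(M0[sel]), tolerance = 1e-9)
})

test_that("fibre force partitioning matches the beam trigonometry", {
  f90 <- beam_fibre(90, 0)
  for (az in c(1, 90, 213)) {
    ff <- fibre_force_partition(f90, impact_condition(az))
    expect_equal(ff$F_N, 0)
    expect_equal(ff$F_b, 1)
  }
  # delta = 0 limit: fibre lying along the attack direction
  f0 <- beam_fibre(1e-12, 0)
  ff <- fibre_force_partition(f0, impact_condition(180)) # direction az 0
  expect_equal(ff$F_N, 1, tolerance = 1e-9)
  expect_equal(ff$F_b, 0, tolerance = 1e-4)
  # delta = 60 aligned: F_N = cos(60), F_b = sqrt(1 - 0.25)
  ff60 <- fibre_force_partition(beam_fibre(60, 0), impact_condition(180))
  expect_equal(ff60$F_N, 0.5, tolerance = 1e-9)
  expect_equal(ff60$F_b, sqrt(0.75), tolerance = 1e-3)
  # Pythagorean closure with a non-unit impact force
  ff2 <- fibre_force_partition(beam_fibre(71, 123),
                               impact_condition(40, F_I = 2.5))
  expect_equal(ff2$F_N^2 + ff2$F_b^2, 2.5^2, tolerance = 1e-9)
  expect_error(fibre_force_partition(beam_fibre(NA, NA)),
               class = "cf_degenerate_error")
})

test_that("sweep equals the closed form and closure holds for all angles", {
  set.seed(7)
  fibres <- lapply(1:5, function(i) {
    beam_fibre(runif(1, 40, 90), runif(1, 0, 360), id = i)
  })
  fs <- do.call(beam_fibre_set, fibres)
  prof <- sweep_attack_angles(fs)
  expect_identical(nrow(prof), 360L)
  # oracle: closed-form F_N averaged over fibres
  oracle <- rowMeans(vapply(fibres, function(f) {
    closed_form_FN(1:360, f$incline_delta, f$tilt_azimuth_phi)
  }, numeric(360)))
  expect_equal(prof$mean_FN_over_FI, oracle, tolerance = 1e-9)
  # per-fibre Pythagorean closure across every angle
  for (f in fibres) {
    fn <- closed_form_FN(1:360, f$incline_delta, f$tilt_azimuth_phi)
    fb <- vapply(1:360, function(a) {
      fibre_force_partition(f, impact_condition(a))$F_b
    }, numeric(1))
    expect_equal(fn^2 + fb^2, rep(1, 360), tolerance = 1e-9)
  }
  expect_error(sweep_attack_angles(beam_fibre_set()),
               class = "cf_parameter_error")
})

test_that("sweep profiles are periodic and symmetric layouts are flat", {
  # all-vertical: F_b = 1 and F_N = 0 at every angle
  fsv <- do.call(beam_fibre_set,
                 lapply(1:4, function(i) beam_fibre(90, 90 * i, id = i)))
  pv <- sweep_attack_angles(fsv)
  expect_true(all(pv$mean_Fb_over_FI == 1))
  expect_true(all(pv$mean_FN_over_FI == 0))
  # rotationally symmetric layout with identical inclines: flat profiles
  n <- 12
  fss <- do.call(beam_fibre_set, lapply(seq_len(n), function(i) {
    beam_fibre(70, (i - 1) * 360 / n + 90, id = i)
  }))
  ps <- sweep_attack_angles(fss)
  expect_lt(sweep_amplitude(ps, "FN"), 1e-12)
  expect_lt(sweep_amplitude(ps, "Fb"), 1e-9) # sqrt roundoff

  # periodicity: angle alpha and alpha + 360 give identical partitions
  f <- beam_fibre(63, 10)
  suppressWarnings({
    a <- fibre_force_partition(f, impact_condition(45))
    b <- fibre_force_partition(f, impact_condition(45 + 360))
  })
  expect_equal(a$F_N, b$F_N, tolerance = 1e-12)
})

test_that("worst-case axial redistribution grows as fibres tilt", {
  # monotonicity: max |F_N| over alpha increases as delta drops from 90
  worst <- vapply(c(90, 80, 70, 60, 45), function(d) {
    prof <- sweep_attack_angles(beam_fibre_set(beam_fibre(d, 0)))
    max(abs(prof$mean_FN_over_FI))
  }, numeric(1))
  expect_true(all(diff(worst) > 0))
})

test_that("optimal attack identification honours criterion and tie-breaks", {
  pv <- sweep_attack_angles(beam_fibre_set(beam_fibre(90, 0)))
  expect_identical(find_optimal_attack(pv), 1L) # constant profile -> first
  p80 <- sweep_attack_angles(beam_fibre_set(beam_fibre(80, 0)))
  # bending maximal where axial vanishes: 90 or 270, smallest returned
  expect_identical(find_optimal_attack(p80), 90L)
  expect_identical(find_optimal_attack(p80, criterion = "axial"), 180L)
})

test_that("field rendering writes images and flags bad paths", {
  geo <- generate_stem_geometry(small_stem())
  g <- build_cylindrical_grid(geo)
  pr <- propagate_forces(surface_load(g, impact_condition(180)), g)
  out <- tempfile("render_")
  paths <- render_fields(pr$field, pr$warp, g, out)
  expect_true(all(file.exists(paths)))
  blocker <- tempfile()
  file.create(blocker) # a plain file: nothing can be created beneath it
  expect_error(render_fields(pr$field, pr$warp, g, file.path(blocker, "sub")),
               class = "cf_io_error")
  unlink(blocker)
  unlink(out, recursive = TRUE)
})
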