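# FTIR chemotyping: preprocessing, EMSC decomposition, PCA, effect screen.

lib <- component_library()

test_that("preprocessing truncates and normalizes as requested", {
  wn <- seq(4000, 400, by = -2)
  raw <- spectrum(wn, abs(sin(wn / 300)) + 0.1)
  pp <- preprocess_spectrum(raw, mode = "vector")
  expect_identical(range(pp$wavenumber), c(800, 1800))
  expect_equal(sum(pp$absorbance^2), 1, tolerance = 1e-9)
  expect_true(pp$flags$truncated && pp$flags$vector_normalized)
  # idempotence on an already unit-norm spectrum
  pp2 <- preprocess_spectrum(pp, mode = "vector")
  expect_equal(pp2$absorbance, pp$absorbance, tolerance = 1e-12)
  # min-max lands on [0, 1]
  mm <- preprocess_spectrum(raw, mode = "minmax")
  expect_equal(range(mm$absorbance), c(0, 1))
  # constant spectrum: degenerate min-max, zeros + warning
  const <- spectrum(wn, rep(2, length(wn)))
  expect_warning(z <- preprocess_spectrum(const, mode = "minmax"),
                 class = "cf_degenerate_warning")
  expect_true(all(z$absorbance == 0) && z$flags$degenerate)
  # window not covered
  short <- spectrum(seq(1500, 900, by = -2), rep(1, 301))
  expect_error(preprocess_spectrum(short), class = "cf_range_error")
})

test_that("decomposition is exact on noiseless in-span spectra", {
  s <- spectrum(lib$wavenumber, 0.7 * lib$K[, "cellulose"])
  dec <- emsc_decompose(s, lib)
  expect_equal(unname(dec$loadings["cellulose"]), 0.7, tolerance = 1e-10)
  expect_true(all(abs(dec$loadings[names(dec$loadings) != "cellulose"]) < 1e-10))
  expect_lt(dec$residual_rms, 1e-10)
  z <- emsc_decompose(spectrum(lib$wavenumber, rep(0, length(lib$wavenumber))),
                      lib)
  expect_true(all(abs(z$loadings) < 1e-12))
  # grid mismatch
  off <- spectrum(seq(1700, 900, by = -2), rep(1, 401))
  expect_error(emsc_decompose(off, lib), class = "cf_alignment_error")
})

test_that("vector normalization makes loadings scale invariant (up to norm)", {
  w <- c(0.4, 0.2, 0.1, 0.2, 0.05, 0.1, 0.02)
  s1 <- spectrum(lib$wavenumber, as.vector(lib$K %*% w))
  s5 <- spectrum(lib$wavenumber, 5 * as.vector(lib$K %*% w))
  n1 <- preprocess_spectrum(s1, mode = "vector")
  n5 <- preprocess_spectrum(s5, mode = "vector")
  d1 <- emsc_decompose(n1, lib)
  d5 <- emsc_decompose(n5, lib)
  expect_equal(d1$loadings, d5$loadings, tolerance = 1e-9)
})

test_that("noisy mixtures are recovered within Monte-Carlo tolerance", {
  # 50 samples at noise 0.01: mean absolute loading error < 0.02
  set.seed(31)
  W <- matrix(runif(50 * 7, 0, 0.6), 50, 7)
  ss <- generate_spectra(lib, W, noise_sd = 0.01, seed = 17)
  dec <- decompose_set(ss, lib)
  est <- as.matrix(dec[lib$components])
  expect_lt(mean(abs(est - W)), 0.02)
  # lignin S/G ratio 2.0 recovered to 0.1 across seeds
  w <- c(0.5, 0.3, 0.2, 0.4, 0.1, 0.1, 0.05) # lignin_S / lignin_G = 2
  ratios <- vapply(1:50, function(k) {
    s <- generate_spectra(lib, w, noise_sd = 0.01, seed = 100 + k)
    emsc_decompose(spectrum(s$wavenumber, s$A[1, ]), lib)$ratios["lnS_lnG"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.1)
  # xylan is the only hemicellulose-class component in the default library
  dd <- emsc_decompose(spectrum(lib$wavenumber, as.vector(lib$K %*% w)), lib)
  expect_equal(unname(dd$ratios["xylan_share_hemicellulose"]), 1)
})

test_that("nonnegative fit clips what plain least squares leaves negative", {
  y <- 0.5 * lib$K[, "cellulose"] - 0.03 * lib$K[, "pectin"]
  s <- spectrum(lib$wavenumber, as.vector(y))
  plain <- emsc_decompose(s, lib)
  expect_lt(plain$loadings["pectin"], 0)
  expect_true(plain$negative_loadings)
  nn <- emsc_decompose(s, lib, nonneg = TRUE)
  expect_true(all(nn$loadings >= -1e-12))
  expect_equal(unname(nn$loadings["cellulose"]), 0.5, tolerance = 0.05)
})

test_that("PCA scores are deterministic, normalized and reconstructive", {
  set.seed(5)
  W <- matrix(runif(12 * 7, 0, 1), 12, 7)
  ss <- generate_spectra(lib, W, noise_sd = 0.02, seed = 6)
  pca <- pca_chemotype(ss, n_components = 4L)
  expect_false(pca$degenerate)
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
  # full-rank reconstruction reproduces the centered data
  full <- pca_chemotype(ss, n_components = 11L)
  Xc <- scale(ss$A, center = TRUE, scale = FALSE)
  expect_equal(full$scores %*% t(full$loadings), unclass(Xc)[, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated spectra: zero variance flagged
  dup <- spectrum_set(lib$wavenumber,
                      matrix(rep(ss$A[1, ], 4), 4, byrow = TRUE))
  expect_true(pca_chemotype(dup)$degenerate)
  expect_error(pca_chemotype(dup, n_components = 10L),
               class = "cf_parameter_error")
})

test_that("PC1 separates lignin-contrasted mixture clusters", {
  set.seed(9)
  base <- c(0.5, 0.3, 0.15, 0.2, 0.1, 0.1, 0.05)
  hi <- base; hi[3:4] <- hi[3:4] + 0.3 # lignin-rich cluster
  W <- rbind(
    t(replicate(15, pmax(0, base + rnorm(7, 0, 0.01)))),
    t(replicate(15, pmax(0, hi + rnorm(7, 0, 0.01))))
  )
  ss <- generate_spectra(lib, W, noise_sd = 0.005, seed = 8,
                         group = rep(c("lo", "hi"), each = 15))
  pca <- pca_chemotype(ss, 2L)
  expect_gt(mean_silhouette(pca$scores[, 1, drop = FALSE], ss$meta$group), 0.5)
})

test_that("effect screen classifies component contrasts", {
  set.seed(77)
  same <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  scr0 <- effect_screen(rbind(same, same),
                        rep(c("g1", "g2"), each = 20))
  expect_true(all(scr0$D == 0))
  # standardized difference 0.98 on cellulose, n = 200 per group; the
  # single-draw estimator sd is ~0.11, so average 10 replicates
  n <- 200
  Ds <- replicate(10, {
    load_tab <- data.frame(cellulose = c(rnorm(n, 0.98), rnorm(n, 0)),
                           pectin = rnorm(2 * n))
    scr <- effect_screen(load_tab, rep(c("res", "pro"), each = n))
    scr$D[scr$component == "cellulose"]
  })
  expect_equal(mean(Ds), 0.98, tolerance = 0.15)
  load_tab <- data.frame(cellulose = c(rnorm(n, 0.98), rnorm(n, 0)),
                         pectin = rnorm(2 * n))
  expect_identical(classify_effect(0.69), "medium")
  expect_error(effect_screen(load_tab, rep("one", 2 * n)),
               class = "cf_parameter_error")
})
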