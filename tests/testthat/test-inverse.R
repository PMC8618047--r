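ref_q <- 4 * pi * 8.77 * 0.01^2 * 12

test_that("closed-form depth and intensity invert the forward model", {
  T_a <- forward_temperature_point(0.0168, 0.01, ref_q)
  expect_equal(dir_depth(T_a, 34, 22, 0.0168), 0.01, tolerance = 1e-12)
  expect_equal(dir_intensity(T_a, 34, 22, 0.0168), ref_q, tolerance = 1e-12)
  # the intensity equals 4*pi*h0*d^2*(Tmax - Te) with the inverted depth
  expect_equal(dir_intensity(T_a, 34, 22, 0.0168),
               4 * pi * 8.77 * dir_depth(T_a, 34, 22, 0.0168)^2 * 12)
  # midpoint temperature implies d = a exactly
  expect_equal(dir_depth(28, 34, 22, 0.005), 0.005)
  # doubling both contrasts at fixed shape doubles the intensity
  expect_equal(dir_intensity(28, 34, 22, 0.01),
               dir_intensity(34, 46, 22, 0.01) / 2)
})

test_that("degenerate and inconsistent profile points are flagged", {
  expect_warning(d0 <- dir_depth(22, 34, 22, 0.01), "flat profile")
  expect_equal(d0, 0)
  expect_equal(dir_intensity(22, 34, 22, 0.01), 0)
  expect_error(dir_depth(34, 34, 22, 0.01), "singular")
  expect_error(dir_depth(35, 34, 22, 0.01), "singular")
  expect_error(dir_depth(21, 34, 22, 0.01), "below ambient")
  expect_error(dir_depth(25, 34, 22, 0), "'a' must be > 0")
})

test_that("closed forms agree with brute-force numeric inversion", {
  # independent oracle: root-find the depth in the forward model, then
  # derive the intensity from the hotspot equation
  set.seed(31)
  for (i in 1:200) {
    d <- runif(1, 0.002, 0.02)
    dT <- runif(1, 2, 12)
    q <- 4 * pi * 8.77 * d^2 * dT
    a <- runif(1, 0.001, 0.018)
    T_a <- forward_temperature_point(a, d, q)
    d_num <- uniroot(function(dd)
      22 + dd^2 * dT / (dd^2 + a^2) - T_a,
      c(1e-6, 0.1), tol = 1e-14)$root
    expect_equal(dir_depth(T_a, 22 + dT, 22, a), d_num, tolerance = 1e-9)
    expect_equal(dir_intensity(T_a, 22 + dT, 22, a),
                 4 * pi * 8.77 * d_num^2 * dT, tolerance = 1e-9)
  }
})

test_that("radius feature is a monotone scale-covariant transform of intensity", {
  cst <- model_constants()
  expect_equal(source_radius(418.6, cst), 1)   # q = Qm * At
  expect_equal(source_radius(0, cst), 0)
  expect_equal(source_radius(0.13224, cst), (0.13224 / 418.6)^(1 / 3))
  expect_equal(round(source_radius(0.13224, cst), 4), 0.0681)
  q <- c(0.01, 0.1, 0.5, 2)
  expect_true(all(diff(source_radius(q, cst)) > 0))
  expect_equal(source_radius(8 * q, cst), 2 * source_radius(q, cst))
  expect_error(source_radius(-1, cst), "q")
  # sphere-volume alternative algebra
  sph <- model_constants(radius_form = "sphere")
  expect_equal(source_radius(1, sph), (3 / (4 * pi * 418.6))^(1 / 3))
})

test_that("inclination angle behaves across the quadrant", {
  expect_equal(theta_angle(0, 0.01), 0)
  expect_equal(theta_angle(0.01, 0.01), 45)
  expect_equal(round(theta_angle(0.13224, 0.0168), 2), 82.76)
  expect_equal(theta_angle(1, 0), 90)
  expect_equal(theta_angle(0, 0), 0)
})

test_that("coefficient of determination matches its definition", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), obs), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("Lorentz least squares recovers planted curve parameters", {
  # profile generated exactly as A/(a^2 + w^2) + y0 on the 31-offset grid
  offs <- (0:30) * 6e-4
  pr <- make_profile(d = 0.01, q = 0.0012 * 4 * pi * 8.77, Te = 22)
  # equivalently A = 0.0012, w = 0.01, y0 = 22
  lf <- lorentz_fit(pr)
  expect_equal(lf$A, 0.0012, tolerance = 1e-6)
  expect_equal(lf$w, 0.01, tolerance = 1e-6)
  expect_equal(lf$y0, 22, tolerance = 1e-6)
  expect_gt(lf$fit_r_squared, 1 - 1e-9)
  expect_gt(lf$w, 0)  # width reported positive (enters only squared)
  expect_equal(lorentz_params(lf$A, lf$w),
               list(d = lf$w, q = lf$A))
  expect_equal(lorentz_params(0.5, -0.01)$d, 0.01)  # sign fold
  expect_equal(lorentz_params(0, 0.01)$q, 0)
  # degenerate constant profile is a fit failure
  prc <- make_profile(d = 0.01, q = 0)
  expect_error(lorentz_fit(prc), "fit failure")
  pr4 <- make_profile(d = 0.01, q = 0.1, n_offsets = 3L)
  expect_error(lorentz_fit(pr4), ">= 4")
})

test_that("noiseless round trip recovers depth and intensity by both methods", {
  for (d in c(0.002, 0.005, 0.01, 0.02)) {
    for (dT in c(2, 6, 12)) {
      q <- 4 * pi * 8.77 * d^2 * dT
      pr <- make_profile(d, q)
      # D-I-R is exact at every positive offset
      for (k in c(1L, 7L, 30L)) {
        a <- k * 6e-4
        fit <- heat_source_fit(pr, "dir", a = a)
        expect_equal(coef(fit)[["d"]], d, tolerance = 1e-9)
        expect_equal(coef(fit)[["q"]], q, tolerance = 1e-9)
      }
      # Lorentz recovers the same depth; intensity under 4*pi*h0 = 1
      fl <- heat_source_fit(pr, "lorentz", a = 0.0168)
      expect_equal(coef(fl)[["d"]], d, tolerance = 1e-6)
      expect_equal(coef(fl)[["q"]] * 4 * pi * 8.77, q, tolerance = 1e-5)
      expect_gt(fl$r_squared, 1 - 1e-9)
    }
  }
})

test_that("Lorentz depth stays within 10% under sensor noise", {
  set.seed(123)
  rel_err <- replicate(200, {
    d <- runif(1, 0.004, 0.015)
    dT <- runif(1, 2, 12)
    pr <- make_profile(d, 4 * pi * 8.77 * d^2 * dT, noise_sd = 0.04)
    lf <- tryCatch(lorentz_fit(pr), error = function(e) NULL)
    if (is.null(lf)) NA_real_ else abs(lf$w - d) / d
  })
  expect_lt(median(rel_err, na.rm = TRUE), 0.10)
})

test_that("fit quality is perfect without noise and degrades with it", {
  rsq_at <- function(sd) {
    set.seed(55)
    mean(replicate(30, {
      pr <- make_profile(runif(1, 0.005, 0.015),
                         4 * pi * 8.77 * 0.01^2 * runif(1, 4, 12),
                         noise_sd = sd)
      lorentz_fit(pr)$fit_r_squared
    }))
  }
  r0 <- rsq_at(0); r1 <- rsq_at(0.1); r2 <- rsq_at(0.5)
  expect_equal(r0, 1, tolerance = 1e-9)
  expect_gt(r0, r1)
  expect_gt(r1, r2)
})

test_that("pattern vectors assemble the five features consistently", {
  d <- 0.01; q <- 4 * pi * 8.77 * d^2 * 12
  pr <- make_profile(d, q)
  v <- pattern_vector(pr, "dir", a = 0.0168)
  expect_named(v, c("Tmax", "d", "q", "R", "theta"))
  expect_equal(v[["Tmax"]], 34)
  expect_equal(v[["theta"]], theta_angle(v[["q"]], 0.0168))
  expect_equal(v[["R"]], source_radius(v[["q"]]))
  # D-I-R (d, q) are position-independent on an exact model profile
  v2 <- pattern_vector(pr, "dir", a = 0.006)
  expect_equal(v[c("d", "q")], v2[c("d", "q")], tolerance = 1e-9)
  # zero source: flat vector (with an indeterminate-depth warning)
  pr0 <- make_profile(0.01, 0)
  expect_warning(v0 <- pattern_vector(pr0, "dir", a = 0.0168), "flat")
  expect_equal(unname(v0), c(22, 0, 0, 0, 0))
  # off-grid and zero positions are rejected (no interpolation)
  expect_error(pattern_vector(pr, "dir", a = 0.00123), "offset grid")
  expect_error(pattern_vector(pr, "dir", a = 0), "> 0")
})

test_that("model-object methods expose fitted curve, residuals and predictions", {
  pr <- make_profile(0.01, ref_q, noise_sd = 0.02)
  fit <- heat_source_fit(pr, "lorentz", a = 0.0168)
  expect_s3_class(fit, "heat_source_fit")
  expect_length(fitted(fit), length(pr$offsets))
  expect_equal(residuals(fit), pr$mean_temp - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, a = pr$offsets), fitted(fit), tolerance = 1e-12)
  expect_output(print(fit), "Lorentz")
  expect_output(print(summary(fit)), "residual sd")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(pr$offsets), 3L))
  fd <- heat_source_fit(pr, "dir", a = 0.0168)
  expect_equal(predict(fd, a = 0),
               pr$Te + coef(fd)[["q"]] / (4 * pi * 8.77 * coef(fd)[["d"]]^2))
})
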