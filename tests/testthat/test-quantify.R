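# Conjugate-view quantification: ROI rates, attenuation, thickness,
# calibration, recovery coefficients, and the geometric-mean formula.

test_that("roi_counts implements background-corrected mean x pixel count / duration", {
  img <- img_of(rbind(c(5, 5, 2), c(5, 5, 2), c(5, 5, 2)))
  # 6-pixel ROI of mean 5; 3-pixel background of mean 2 -> wait: use exact shapes
  roi <- mask_of(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0)))
  bg <- mask_of(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), "background")
  expect_equal(roi_counts(img, roi, bg), (5 - 2) * 6 / 1)
  # background >= ROI floors at zero
  hot_bg <- img_of(rbind(c(1, 1, 9), c(1, 1, 9), c(1, 1, 9)))
  expect_equal(roi_counts(hot_bg, roi, bg), 0)
  # no background: ROI sum / duration
  img20 <- planar_image(matrix(10, 2, 5), duration_s = 20)
  expect_equal(roi_counts(img20, mask_of(matrix(1, 2, 5))), 100 / 20)
  expect_error(roi_counts(img, mask_of(matrix(1, 2, 2))), "shape")
})

test_that("effective_mu is the arithmetic mean, kept separate per region", {
  expect_equal(effective_mu(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(effective_mu(0.11), 0.11)
  # lung thirds each get their own coefficient - never pooled
  thirds <- list(lung_upper = c(0.14, 0.16), lung_middle = c(0.10, 0.12),
                 lung_lower = c(0.08, 0.10))
  mus <- vapply(thirds, effective_mu, numeric(1))
  expect_equal(unname(mus), c(0.15, 0.11, 0.09))
  expect_error(effective_mu(numeric(0)), "empty")
  expect_error(effective_mu(c(0.1, -0.1)), ">= 0")
})

test_that("oblique thickness follows distance x pixel size x obliquity / 10", {
  t1 <- thickness_from_oblique(c(0, 0), c(0, 100), pixel_size_mm = 2.3976)
  expect_equal(t1$thickness_cm, 23.976)
  t2 <- thickness_from_oblique(c(0, 0), c(30, 40), pixel_size_mm = 2.0)
  expect_equal(t2$thickness_cm, 10.0)
  # high-precision check of the sqrt(2) obliquity factor
  t3 <- thickness_from_oblique(c(0, 0), c(0, 100), pixel_size_mm = 2.3976,
                               obliquity_factor = sqrt(2))
  expect_equal(t3$thickness_cm, 100 * 2.3976 * sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(t3$thickness_cm, 33.9073, tolerance = 1e-4)
  expect_error(thickness_from_oblique(c(1, 1), c(1, 1)), "degenerate")
})

test_that("conjugate-view formula matches hand and high-precision evaluations", {
  C1 <- calibration_factor(1)
  expect_equal(conjugate_view_activity(1, 1, 0, 17, C1)$activity_MBq, 1)
  expect_equal(conjugate_view_activity(400, 900, 0, 0, 2)$activity_MBq, 300)
  # sqrt(I_A I_B exp(mu T)): 100 * exp(0.11 * 20 / 2) = 100 * e^1.1
  a <- conjugate_view_activity(100, 100, 0.11, 20, C1)
  expect_equal(a$activity_MBq, 100 * exp(1.1), tolerance = 1e-12)
  expect_equal(a$activity_MBq, 300.41660239, tolerance = 1e-8)
  # recovery-coefficient division
  expect_equal(conjugate_view_activity(100, 100, 0, 0, 1, rc = 0.8)$activity_MBq,
               125)
  expect_error(conjugate_view_activity(-1, 1, 0, 1, C1), ">= 0")
})

test_that("activity is monotone nondecreasing in I_A, I_B, mu_e and T", {
  set.seed(42)
  base <- list(ia = 200, ib = 300, mu = 0.1, t = 20)
  f <- function(ia, ib, mu, t)
    conjugate_view_activity(ia, ib, mu, t, 1)$activity_MBq
  for (i in 1:50) {
    d <- runif(1, 0.01, 2)
    expect_gte(f(base$ia + d, base$ib, base$mu, base$t), f(base$ia, base$ib, base$mu, base$t))
    expect_gte(f(base$ia, base$ib + d, base$mu, base$t), f(base$ia, base$ib, base$mu, base$t))
    expect_gte(f(base$ia, base$ib, base$mu + d / 100, base$t), f(base$ia, base$ib, base$mu, base$t))
    expect_gte(f(base$ia, base$ib, base$mu, base$t + d), f(base$ia, base$ib, base$mu, base$t))
    base <- list(ia = runif(1, 1, 1000), ib = runif(1, 1, 1000),
                 mu = runif(1, 0, 0.2), t = runif(1, 5, 35))
  }
})

test_that("calibration factor is counts/(MBq s), linear, and closes the loop", {
  C <- calibration_from_scan(40.7, 2442000, 60)
  expect_equal(C$value, 1000)
  expect_equal(calibration_from_scan(40.7, 2 * 2442000, 60)$value, 2000)
  # quantifying the calibration scan itself recovers the known activity
  rate <- 2442000 / 60
  est <- conjugate_view_activity(rate, rate, 0, 0, C)
  expect_equal(est$activity_MBq, 40.7, tolerance = 1e-12)
  expect_error(calibration_from_scan(0, 100, 1), "> 0")
})

test_that("recovery coefficients interpolate linearly and clamp at the ends", {
  cur <- recovery_curve(c(10, 20), c(0.8, 1.0))
  expect_equal(recovery_coefficient(cur, 15), 0.9)
  expect_equal(recovery_coefficient(cur, 10), 0.8)
  expect_warning(rc5 <- recovery_coefficient(cur, 5), "clamping")
  expect_equal(rc5, 0.8)
  # sphere-phantom curve: interpolation stays inside [min(rc), max(rc)]
  sph <- recovery_curve(c(7.3, 9.2, 11.4, 14.3, 17.9, 22.4, 29.9),
                        c(0.78, 0.82, 0.88, 0.95, 1.02, 1.06, 1.09))
  set.seed(7)
  for (d in runif(30, 7.3, 29.9)) {
    rc <- recovery_coefficient(sph, d)
    expect_gte(rc, 0.78); expect_lte(rc, 1.09)
  }
  expect_error(recovery_curve(c(10, 10), c(1, 1)), "increasing")
})

test_that("decay correction uses the I-131 physical constant and is off-chain", {
  lam <- log(2) / 192.5
  expect_equal(decay_correct(100, t_h = 192.5), 200)
  expect_equal(decay_correct(100, t_h = 24, t_ref_h = 24), 100)
  expect_equal(decay_correct(1, 10), exp(lam * 10))
})

test_that("quantify_organs runs the full chain per organ", {
  ph <- suppressWarnings(project_phantom(phantom_config()))
  res <- quantify_organs(ph$anterior, ph$posterior, ph$masks,
                         mu_e = ph$truth$mu_cm1,
                         thickness_cm = ph$truth$thickness_cm,
                         C = ph$truth$C,
                         background_mask = ph$background_mask)
  expect_setequal(res$organ, names(ph$masks))
  expect_true(all(c("I_A_cps", "I_B_cps", "mu_e_cm1", "T_cm", "C", "RC",
                    "activity_MBq") %in% names(res)))
  expect_error(quantify_organs(ph$anterior, ph$posterior, ph$masks,
                               mu_e = c(liver = 0.1),
                               thickness_cm = 20, C = 1),
               "no mu_e")
})
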