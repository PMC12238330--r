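# Synthetic phantom generators: forward projections, kernels, TACs, cohorts.

test_that("noiseless forward-then-inverse chain recovers every organ activity", {
  ph <- suppressWarnings(project_phantom(phantom_config()))
  res <- quantify_organs(ph$anterior, ph$posterior, ph$masks,
                         mu_e = ph$truth$mu_cm1,
                         thickness_cm = ph$truth$thickness_cm,
                         C = ph$truth$C,
                         background_mask = ph$background_mask)
  rel <- abs(res$activity_MBq - ph$truth$activities_MBq[res$organ]) /
    ph$truth$activities_MBq[res$organ]
  expect_lt(max(rel), 0.01)
  # background subtraction removes a uniform background exactly
  cfgb <- phantom_config(background_cps_per_px = 0.5)
  phb <- suppressWarnings(project_phantom(cfgb))
  resb <- quantify_organs(phb$anterior, phb$posterior, phb$masks,
                          mu_e = phb$truth$mu_cm1,
                          thickness_cm = phb$truth$thickness_cm,
                          C = phb$truth$C,
                          background_mask = phb$background_mask)
  relb <- abs(resb$activity_MBq - phb$truth$activities_MBq[resb$organ]) /
    phb$truth$activities_MBq[resb$organ]
  expect_lt(max(relb), 0.01)
})

test_that("with zero attenuation the anterior and flipped posterior agree", {
  org <- default_phantom_organs()
  org$mu_cm1 <- 0
  ph <- suppressWarnings(project_phantom(phantom_config(organs = org)))
  expect_equal(flip_posterior(ph$posterior)$pixels, ph$anterior$pixels,
               tolerance = 1e-12)
})

test_that("posterior view is rendered in the posterior detector frame", {
  # an off-center organ must appear mirrored on the posterior image
  org <- default_phantom_organs()[1, ]
  ph <- project_phantom(phantom_config(organs = org))
  sh <- dim(ph$anterior$pixels)
  ant_cm <- which(ph$anterior$pixels == max(ph$anterior$pixels), arr.ind = TRUE)[1, ]
  post_cm <- which(ph$posterior$pixels == max(ph$posterior$pixels), arr.ind = TRUE)
  expect_true(any(post_cm[, 1] == sh[1] + 1 - ant_cm[1]))
})

test_that("Poisson projections are seeded and reproducible", {
  cfg <- phantom_config(noise = "poisson", seed = 33)
  p1 <- suppressWarnings(project_phantom(cfg))
  p2 <- suppressWarnings(project_phantom(cfg))
  expect_identical(p1$anterior$pixels, p2$anterior$pixels)
  expect_identical(p1$posterior$pixels, p2$posterior$pixels)
  p3 <- suppressWarnings(project_phantom(phantom_config(noise = "poisson", seed = 34)))
  expect_false(identical(p1$anterior$pixels, p3$anterior$pixels))
  expect_error(phantom_config(noise = "poisson"), "seed")
})

test_that("overlapping organs are flagged as a warning listing the pair", {
  org <- data.frame(label = c("liver", "tumor"),
                    cy = c(20, 22), cx = c(20, 22), ry = c(6, 4), rx = c(6, 4),
                    activity_MBq = c(100, 10), mu_cm1 = c(0.11, 0.11),
                    thickness_cm = c(20, 20))
  expect_warning(project_phantom(phantom_config(organs = org)),
                 "liver/tumor")
})

test_that("oblique chord has the configured thickness as its ground truth", {
  ph <- suppressWarnings(project_phantom(phantom_config()))
  tm <- thickness_from_oblique(ph$truth$chord_p1, ph$truth$chord_p2,
                               pixel_size_mm = ph$oblique45$pixel_size_mm[1])
  expect_equal(tm$thickness_cm, default_phantom_organs()$thickness_cm[1],
               tolerance = 1e-12)
  expect_equal(ph$oblique45$view, "oblique45")
})

test_that("generated radial kernels are valid and degenerate to a delta", {
  k <- make_kernel(kernel_size = 9, range_mm = 3)
  expect_s3_class(k, "dose_kernel")
  s <- validate_kernel(k)   # throws on any invariant violation
  expect_true(all(diff(s$coverage_by_size) > 0))
  c0 <- k$grid[5, 5]
  expect_true(all(k$grid[-(5 + (5 - 1) * 9)] < c0))
  # range much smaller than a pixel: numerically a delta
  kd <- make_kernel(kernel_size = 5, range_mm = 1e-4, amplitude = 1)
  expect_equal(unname(validate_kernel(kd)$coverage_by_size["1"]), 1,
               tolerance = 1e-12)
  expect_error(make_kernel(kernel_size = 8), "odd")
})

test_that("TAC sampling is exact at CV = 0 and reproducible under a seed", {
  truth <- exp_truth(50, 0.008)
  x0 <- make_tac(truth, noise_cv = 0)
  expect_equal(x0$times_h, c(24, 72, 168))
  expect_equal(x0$activities_MBq, 50 * exp(-0.008 * c(24, 72, 168)))
  xa <- make_tac(truth, noise_cv = 0.1, seed = 9)
  xb <- make_tac(truth, noise_cv = 0.1, seed = 9)
  expect_identical(xa$activities_MBq, xb$activities_MBq)
  expect_false(identical(xa$activities_MBq, x0$activities_MBq))
  expect_error(make_tac(truth, noise_cv = -1), ">= 0")
})

test_that("cohort generation is seeded, complete, and carries its generator", {
  co <- make_cohort(100, "linear", noise_sd = 0, seed = 3)
  expect_equal(nrow(co), 100)
  expect_false(anyNA(co))
  expect_identical(co, make_cohort(100, "linear", noise_sd = 0, seed = 3))
  gen <- attr(co, "generator")
  expect_equal(gen$kind, "linear")
  expect_true(all(co$age_y >= 20 & co$age_y <= 80))
  expect_true(all(co$bmi_kg_m2 >= 17 & co$bmi_kg_m2 <= 40))
  expect_true(all(co$thickness_cm >= 15 & co$thickness_cm <= 35))
  expect_true(all(co$mu_e_cm1 >= 0.09 & co$mu_e_cm1 <= 0.13))
  expect_error(make_cohort(4), "n >= 8")
})
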