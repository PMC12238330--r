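# Cohort preprocessing, splitting, and the four dose regressors.

test_that("z-scoring and min-max scaling hit their textbook values", {
  df <- data.frame(patient_id = c("a", "b", "c"), organ = "liver",
                   age_y = c(1, 2, 3), bmi_kg_m2 = c(20, 25, 30),
                   thickness_cm = c(20, 21, 22), s_value = c(1, 2, 3) * 1e-4,
                   mu_e_cm1 = c(0.1, 0.11, 0.12),
                   I_A_cps = c(10, 20, 30), I_B_cps = c(5, 10, 15),
                   target_dose_Gy = c(1, 2, 3))
  pp <- preprocess_cohort(df)
  expect_equal(mean(pp$age_y), 0)
  expect_equal(sd(pp$age_y), 1)
  expect_equal(pp$I_A_cps, c(0, 0.5, 1))
  expect_equal(pp$I_B_cps, c(0, 0.5, 1))
})

test_that("rows with missing target are dropped; missing features imputed", {
  co <- make_cohort(10, "linear", seed = 2)
  co$target_dose_Gy[4] <- NA
  co$bmi_kg_m2[7] <- NA
  pp <- preprocess_cohort(co)
  expect_equal(nrow(pp), 9)
  expect_false(anyNA(pp$bmi_kg_m2))
  expect_error(preprocess_cohort(co[0, ]), "empty")
})

test_that("outlier rows beyond |z| > 3 are removed when fitting constants", {
  co <- make_cohort(50, "linear", seed = 4)
  co$age_y[1] <- 1e4   # gross outlier
  pp <- preprocess_cohort(co)
  expect_equal(nrow(pp), 49)
  expect_false("P0001" %in% pp$patient_id)
})

test_that("constant features warn and pass through unscaled", {
  co <- make_cohort(20, "linear", seed = 5)
  co$thickness_cm <- 25
  expect_warning(pp <- preprocess_cohort(co), "zero variance|constant")
  expect_true(all(pp$thickness_cm == 25))
})

test_that("splits are 75/25, rounded, and deterministic under a seed", {
  co <- make_cohort(100, "linear", seed = 1)
  sp <- split_cohort(co, seed = 11)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  sp2 <- split_cohort(co, seed = 11)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  co8 <- make_cohort(8, "linear", seed = 1)
  sp8 <- split_cohort(co8, seed = 1)
  expect_equal(nrow(sp8$train), 6)
  expect_equal(nrow(sp8$test), 2)
  expect_error(split_cohort(co8[1:3, ], 1), "at least 4")
})

test_that("test-split transforms use only saved training constants", {
  co <- make_cohort(80, "linear", noise_sd = 0.5, seed = 6)
  sp <- split_cohort(co, seed = 21)
  tr <- preprocess_cohort(sp$train)
  params <- attr(tr, "preprocess_params")
  te <- preprocess_cohort(sp$test, params = params)
  # constants are the training ones, not refit on test
  expect_equal(attr(te, "preprocess_params"), params)
  expect_false(isTRUE(all.equal(mean(te$age_y), 0)))  # test mean != 0
  # re-applying the saved transform is a no-op (idempotence / leakage check)
  te2 <- preprocess_cohort(te, params = params)
  for (f in c("age_y", "bmi_kg_m2", "I_A_cps", "I_B_cps"))
    expect_identical(te2[[f]], te[[f]])
  # test rows are never dropped by the training outlier filter
  expect_equal(nrow(te), nrow(sp$test))
})

test_that("linear regression recovers generating coefficients exactly", {
  # direct closed-form check: target = 2*age + 3*bmi, no noise
  n <- 40
  set.seed(8)
  df <- data.frame(age_y = runif(n, 20, 80), bmi_kg_m2 = runif(n, 17, 40),
                   target_dose_Gy = NA)
  df$target_dose_Gy <- 2 * df$age_y + 3 * df$bmi_kg_m2
  m <- train_dose_model(df, "linreg")
  cf <- coef(m)
  expect_equal(unname(cf["age_y"]), 2, tolerance = 1e-8)
  expect_equal(unname(cf["bmi_kg_m2"]), 3, tolerance = 1e-8)
  expect_equal(unname(cf["(Intercept)"]), 0, tolerance = 1e-6)
  expect_lt(mean((predict(m, df) - df$target_dose_Gy)^2), 1e-12)
  # on the generated linear cohort: raw-feature fit recovers the recorded
  # generator coefficients
  co <- make_cohort(120, "linear", noise_sd = 0, seed = 9)
  mf <- train_dose_model(as.data.frame(co), "linreg")
  gen <- attr(co, "generator")$coefs
  cf2 <- coef(mf)
  for (f in c("age_y", "bmi_kg_m2", "thickness_cm", "mu_e_cm1",
              "I_A_cps", "I_B_cps", "s_value"))
    expect_equal(unname(cf2[f]), unname(gen[f]), tolerance = 1e-6)
  # BFGS path reaches the same solution
  mb <- train_dose_model(df, "linreg", hyper = list(method = "bfgs"))
  expect_equal(unname(coef(mb)), unname(cf), tolerance = 1e-4)
})

test_that("a tree that cannot split predicts the pooled mean", {
  df <- data.frame(age_y = rep(1, 10), bmi_kg_m2 = rep(2, 10),
                   target_dose_Gy = 1:10)
  m <- train_dose_model(df, "tree")
  expect_equal(unique(predict(m, df)), mean(1:10))
})

test_that("tree respects min leaf size and the split cap", {
  co <- preprocess_cohort(make_cohort(300, "nonlinear", noise_sd = 0.2, seed = 10))
  m <- train_dose_model(co, "tree")
  fr <- m$fit$frame
  leaves <- fr[fr$var == "<leaf>", ]
  expect_true(all(leaves$n >= 5))
  expect_lte(sum(fr$var != "<leaf>"), 20)
})

test_that("unknown hyperparameters and NaN features fail loudly", {
  co <- preprocess_cohort(make_cohort(40, "linear", seed = 11))
  expect_error(train_dose_model(co, "svr", hyper = list(bogus = 1)),
               "unknown svr hyperparameters")
  co$age_y[3] <- NaN
  expect_error(train_dose_model(co, "linreg"), "rows 3")
})

test_that("training is deterministic given a seed", {
  co <- preprocess_cohort(make_cohort(120, "nonlinear", noise_sd = 0.2, seed = 12))
  newd <- co[1:20, ]
  for (fam in c("tree", "linreg")) {
    p1 <- predict(train_dose_model(co, fam, seed = 5), newd)
    p2 <- predict(train_dose_model(co, fam, seed = 5), newd)
    expect_identical(p1, p2)
  }
  hp <- list(epochs = 60, patience = 20)
  p1 <- predict(train_dose_model(co, "mlp", hyper = hp, seed = 5), newd)
  p2 <- predict(train_dose_model(co, "mlp", hyper = hp, seed = 5), newd)
  expect_equal(p1, p2, tolerance = 1e-6)
  p3 <- predict(train_dose_model(co, "svr", seed = 5), newd)
  p4 <- predict(train_dose_model(co, "svr", seed = 5), newd)
  expect_equal(p3, p4, tolerance = 1e-6)
})

test_that("SVR uses the tuned radial configuration and fits its training data", {
  co <- preprocess_cohort(make_cohort(150, "nonlinear", noise_sd = 0.1, seed = 13))
  m <- train_dose_model(co, "svr")
  expect_equal(m$hyper$cost, 100)
  expect_equal(m$hyper$gamma, 10)
  r2 <- r_squared(co$target_dose_Gy, predict(m, co))
  expect_gt(r2, 0.5)
})
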