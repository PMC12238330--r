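# Synthetic phantom generators: attenuated conjugate-view projections of
# known 2D activity distributions, radial Monte-Carlo-like kernels,
# noisy time-activity samples, and feature cohorts with known generating
# functions. Everything is seeded and bit-reproducible.
#
# The forward projector is a 2D slab model: each organ is an ellipse with
# one activity, one anterior depth d and one body thickness T, so
#   anterior counts  = C * A_pix * exp(-mu d)       * duration
#   posterior counts = C * A_pix * exp(-mu (T - d)) * duration
# and the product of the two views satisfies I_A I_B = C^2 A^2 exp(-mu T)
# exactly in the noiseless case — the minimum physics under which the
# conjugate-view formula is exactly invertible.

#' Phantom configuration
#'
#' @param grid_shape (rows, cols) of the projection grids.
#' @param pixel_size_mm detector pixel size (mm).
#' @param organs data.frame with columns label, cy, cx (ellipse center,
#'   pixels), ry, rx (semi-axes, pixels), activity_MBq, mu_cm1,
#'   thickness_cm and optionally depth_cm (anterior depth of the organ
#'   plane; default thickness/2).
#' @param background_cps_per_px uniform background count rate per pixel
#'   (counts/s); 0 disables background.
#' @param C calibration factor (counts/(MBq s)).
#' @param duration_s acquisition duration (s).
#' @param noise "none" or "poisson".
#' @param seed RNG seed; mandatory when noise != "none".
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64), pixel_size_mm = 2.3976,
                           organs = default_phantom_organs(),
                           background_cps_per_px = 0,
                           C = 100, duration_s = 300,
                           noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  if (noise != "none" && is.null(seed))
    stop("phantom_config: seed is mandatory when noise is enabled")
  need <- c("label", "cy", "cx", "ry", "rx", "activity_MBq", "mu_cm1",
            "thickness_cm")
  if (!all(need %in% names(organs)))
    stop("phantom_config: organs must have columns ",
         paste(need, collapse = ", "))
  if (is.null(organs$depth_cm)) organs$depth_cm <- organs$thickness_cm / 2
  if (any(organs$activity_MBq < 0)) stop("phantom_config: activities must be >= 0")
  inside <- organs$cy - organs$ry >= 1 & organs$cy + organs$ry <= grid_shape[1] &
    organs$cx - organs$rx >= 1 & organs$cx + organs$rx <= grid_shape[2]
  if (!all(inside)) stop("phantom_config: organ ellipses must lie inside the grid")
  structure(list(grid_shape = grid_shape, pixel_size_mm = pixel_size_mm,
                 organs = organs,
                 background_cps_per_px = background_cps_per_px,
                 C = C, duration_s = duration_s, noise = noise, seed = seed),
            class = "phantom_config")
}

#' Default three-organ phantom layout
#'
#' Liver-, spleen- and kidney-like ellipses on a 64 x 64 grid with
#' activities, attenuation coefficients and thicknesses in the clinical
#' I-131 range.
#'
#' @return data.frame suitable for [phantom_config()].
#' @export
default_phantom_organs <- function() {
  data.frame(
    label = c("liver", "spleen", "kidney_left"),
    cy = c(24, 22, 42), cx = c(22, 46, 40),
    ry = c(9, 4, 5), rx = c(11, 4, 4),
    activity_MBq = c(120, 35, 60),
    mu_cm1 = c(0.11, 0.115, 0.12),
    thickness_cm = c(22, 20, 21),
    stringsAsFactors = FALSE)
}

.ellipse_mask <- function(shape, cy, cx, ry, rx) {
  rr <- outer(seq_len(shape[1]), rep(1, shape[2]))
  cc <- outer(rep(1, shape[1]), seq_len(shape[2]))
  (((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1) * 1
}

#' Project a phantom into conjugate planar views
#'
#' Renders noiseless (or Poisson-noisy) anterior, posterior and
#' 45-degree-oblique count images of the configured organ ellipses, plus
#' the matching organ masks, a background mask, and the ground truth.
#' The posterior image is returned in the posterior detector frame (i.e.
#' already rotated 180 degrees relative to the anterior view), so the
#' quantification chain must [flip_posterior()] it, as with real data.
#' The oblique view is the anterior geometry annotated with a body
#' chord whose endpoints are returned in the truth record, giving
#' [thickness_from_oblique()] a defined ground truth.
#'
#' Organ overlap is permitted but reported with a warning listing pairs.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `anterior`, `posterior`, `oblique45`
#'   (planar_images), `masks` (named list of organ_masks),
#'   `background_mask`, and `truth` (list: per-organ activities_MBq,
#'   mu_cm1, thickness_cm, C, chord endpoints p1/p2).
#' @export
project_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  sh <- cfg$grid_shape
  ant <- matrix(0, sh[1], sh[2])
  post <- matrix(0, sh[1], sh[2])
  masks <- list()
  org <- cfg$organs
  for (i in seq_len(nrow(org))) {
    m <- .ellipse_mask(sh, org$cy[i], org$cx[i], org$ry[i], org$rx[i])
    npix <- sum(m)
    a_pix <- org$activity_MBq[i] / npix
    ant <- ant + m * cfg$C * a_pix *
      exp(-org$mu_cm1[i] * org$depth_cm[i]) * cfg$duration_s
    post <- post + m * cfg$C * a_pix *
      exp(-org$mu_cm1[i] * (org$thickness_cm[i] - org$depth_cm[i])) *
      cfg$duration_s
    masks[[org$label[i]]] <- organ_mask(m, label = org$label[i])
  }
  # overlap report
  if (nrow(org) > 1) {
    pairs <- utils::combn(seq_len(nrow(org)), 2)
    ov <- apply(pairs, 2, function(p)
      sum(masks[[org$label[p[1]]]]$pixels * masks[[org$label[p[2]]]]$pixels) > 0)
    if (any(ov)) {
      lab <- apply(pairs[, ov, drop = FALSE], 2, function(p)
        paste(org$label[p], collapse = "/"))
      warning("project_phantom: overlapping organs: ",
              paste(lab, collapse = ", "))
    }
  }
  if (cfg$background_cps_per_px > 0) {
    bg <- cfg$background_cps_per_px * cfg$duration_s
    ant <- ant + bg
    post <- post + bg
  }
  if (cfg$noise == "poisson") {
    set.seed(cfg$seed)
    ant <- matrix(stats::rpois(length(ant), ant), nrow(ant), ncol(ant))
    post <- matrix(stats::rpois(length(post), post), nrow(post), ncol(post))
  }
  # background ROI: top-left corner patch kept clear of organs
  bgm <- matrix(0, sh[1], sh[2])
  bgm[1:3, 1:3] <- 1
  for (m in masks) bgm <- bgm * (1 - m$pixels)
  background_mask <- if (sum(bgm) > 0) organ_mask(bgm, "background") else NULL

  # body chord for the oblique thickness measurement: a horizontal segment
  # whose pixel length corresponds to the first organ's thickness
  t_cm <- org$thickness_cm[1]
  len_px <- t_cm * 10 / cfg$pixel_size_mm
  p1 <- c(2, 2)
  p2 <- c(2, 2 + len_px)
  obl <- ant

  mk_img <- function(px, view) planar_image(px, pixel_size_mm = cfg$pixel_size_mm,
                                            view = view,
                                            duration_s = cfg$duration_s)
  # posterior detector sees the patient mirrored: rotate the posterior
  # projection into its native frame
  post_native <- post[rev(seq_len(sh[1])), rev(seq_len(sh[2])), drop = FALSE]
  list(anterior = mk_img(ant, "anterior"),
       posterior = mk_img(post_native, "posterior"),
       oblique45 = mk_img(obl, "oblique45"),
       masks = masks,
       background_mask = background_mask,
       truth = list(activities_MBq = stats::setNames(org$activity_MBq, org$label),
                    mu_cm1 = stats::setNames(org$mu_cm1, org$label),
                    thickness_cm = stats::setNames(org$thickness_cm, org$label),
                    C = cfg$C, chord_p1 = p1, chord_p2 = p2))
}

#' Generate a Monte-Carlo-like radial dose kernel
#'
#' Exponential radial falloff k(r) = amplitude * exp(-r / range_mm)
#' evaluated at pixel-center distances: radially decreasing, symmetric,
#' maximal at the center, so it always passes [validate_kernel()]. In the
#' range << pixel limit it degenerates to a delta kernel.
#'
#' @param kernel_size odd grid size (default 9).
#' @param pixel_size_mm pixel size (mm), default 2.3976.
#' @param amplitude center value (Gy/(MBq s)).
#' @param range_mm exponential range (mm).
#' @param organ_or_medium label.
#' @return a `dose_kernel`.
#' @export
make_kernel <- function(kernel_size = 9, pixel_size_mm = 2.3976,
                        amplitude = 1e-4, range_mm = 3,
                        organ_or_medium = "synthetic_water") {
  if (kernel_size %% 2 == 0) stop("make_kernel: kernel_size must be odd")
  h <- (kernel_size - 1) / 2
  off <- (-h):h
  r <- sqrt(outer(off^2, rep(1, kernel_size)) +
              outer(rep(1, kernel_size), off^2)) * pixel_size_mm
  dose_kernel(amplitude * exp(-r / range_mm), pixel_size_mm = pixel_size_mm,
              organ_or_medium = organ_or_medium)
}

#' Sample a noisy time-activity curve from a known decay model
#'
#' Evaluates the fitted (or constructed) exponential model at the given
#' times and applies multiplicative lognormal noise of the stated
#' coefficient of variation. The default times are the clinical I-131
#' protocol scans at 24, 72 and 168 h.
#'
#' @param fit_truth a `tac_fit` (e.g. built via [exp_truth()]).
#' @param times_h sampling times (h), increasing.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact curve values).
#' @param seed RNG seed.
#' @param organ organ label for the curve.
#' @return a [tac()].
#' @export
make_tac <- function(fit_truth, times_h = c(24, 72, 168), noise_cv = 0,
                     seed = 1, organ = "organ") {
  stopifnot(inherits(fit_truth, "tac_fit"))
  if (noise_cv < 0) stop("make_tac: noise_cv must be >= 0")
  if (any(diff(times_h) <= 0)) stop("make_tac: times must be increasing")
  y <- predict(fit_truth, times_h)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    y <- y * stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tac(times_h, y, organ = organ)
}

#' Construct a ground-truth exponential model
#'
#' Convenience constructor of a `tac_fit` with known parameters, used as
#' the generating truth for [make_tac()] and recovery tests.
#'
#' @param A1_MBq,lambda1_per_h first (dominant) component.
#' @param A2_MBq,lambda2_per_h optional second component (biexp).
#' @return a `tac_fit`.
#' @export
exp_truth <- function(A1_MBq, lambda1_per_h, A2_MBq = NULL, lambda2_per_h = NULL) {
  biexp <- !is.null(A2_MBq)
  structure(list(model = if (biexp) "biexp" else "monoexp",
                 A1_MBq = A1_MBq, lambda1_per_h = lambda1_per_h,
                 A2_MBq = A2_MBq, lambda2_per_h = lambda2_per_h,
                 residual_ss = 0, fixed_lambda = NULL,
                 data = tac(c(0, 1), c(A1_MBq + (A2_MBq %||% 0),
                                       .exp_model(1, A1_MBq, lambda1_per_h,
                                                  A2_MBq %||% 0,
                                                  lambda2_per_h %||% 1)))),
            class = "tac_fit")
}

#' Generate a synthetic dosimetry cohort
#'
#' Feature table with the planar-dosimetry schema (anterior/posterior
#' counts, thickness, BMI, age, S-value, effective attenuation) and a
#' target organ dose produced by a known generating function plus
#' Gaussian noise. The generating coefficients are stored in
#' `attr(, "generator")` so regression tests can check recovery.
#'
#' Feature ranges reflect the clinical cohort: age 20-80 y, BMI 17-40,
#' thickness 15-35 cm, mu_e 0.09-0.13 /cm, lognormal count rates,
#' S-values around 1e-4 Gy/(MBq s).
#'
#' @param n number of rows (>= 8).
#' @param generator "linear" (dose = linear form of the features) or
#'   "nonlinear" (attenuation-style exponential interaction plus smooth
#'   nonlinearities).
#' @param noise_sd Gaussian noise SD added to the target (Gy).
#' @param seed RNG seed.
#' @return data.frame of class `cohort_table` with columns patient_id,
#'   age_y, bmi_kg_m2, organ, I_A_cps, I_B_cps, thickness_cm, s_value,
#'   mu_e_cm1, target_dose_Gy.
#' @export
make_cohort <- function(n = 200, generator = c("linear", "nonlinear"),
                        noise_sd = 0, seed = 1) {
  generator <- match.arg(generator)
  if (n < 8) stop("make_cohort: need n >= 8")
  set.seed(seed)
  organs <- c("heart", "liver", "spleen", "kidney_left", "kidney_right",
              "lung_upper", "lung_middle", "lung_lower", "thyroid",
              "salivary_glands")
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_y = stats::runif(n, 20, 80),
    bmi_kg_m2 = stats::runif(n, 17, 40),
    organ = sample(organs, n, replace = TRUE),
    I_A_cps = stats::rlnorm(n, meanlog = log(500), sdlog = 0.5),
    I_B_cps = stats::rlnorm(n, meanlog = log(400), sdlog = 0.5),
    thickness_cm = stats::runif(n, 15, 35),
    s_value = stats::rlnorm(n, meanlog = log(1e-4), sdlog = 0.3),
    mu_e_cm1 = stats::runif(n, 0.09, 0.13),
    stringsAsFactors = FALSE)
  if (generator == "linear") {
    coefs <- c(intercept = 1, age_y = 0.02, bmi_kg_m2 = 0.05,
               thickness_cm = 0.1, mu_e_cm1 = 10,
               I_A_cps = 0.001, I_B_cps = 0.001, s_value = 5000)
    y <- coefs["intercept"] + coefs["age_y"] * df$age_y +
      coefs["bmi_kg_m2"] * df$bmi_kg_m2 +
      coefs["thickness_cm"] * df$thickness_cm +
      coefs["mu_e_cm1"] * df$mu_e_cm1 +
      coefs["I_A_cps"] * df$I_A_cps + coefs["I_B_cps"] * df$I_B_cps +
      coefs["s_value"] * df$s_value
  } else {
    # dose scales like the conjugate-view activity estimate times the
    # S-value: geometric-mean counts, exponential attenuation recovery,
    # plus a smooth saturating age/BMI modifier
    coefs <- c(scale = 2e-2, sat_age = 0.01)
    gm <- sqrt(df$I_A_cps * df$I_B_cps)
    y <- coefs["scale"] * gm * exp(df$mu_e_cm1 * df$thickness_cm / 2) *
      df$s_value * 1e3 +
      2 / (1 + exp(-coefs["sat_age"] * (df$age_y - 50))) +
      0.02 * df$bmi_kg_m2
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  df$target_dose_Gy <- as.numeric(y)
  attr(df, "generator") <- list(kind = generator, coefs = coefs,
                                noise_sd = noise_sd, seed = seed)
  class(df) <- c("cohort_table", "data.frame")
  df
}
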