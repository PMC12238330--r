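# Cohort preprocessing and splitting for the dose-regression models.
# Feature columns follow the planar-dosimetry schema: imaging-derived
# count rates are min-max scaled, every other numeric feature is
# z-scored; constants are fitted on the training split only and saved so
# the test split is transformed without leakage.

.zscore_features <- c("age_y", "bmi_kg_m2", "thickness_cm", "s_value",
                      "mu_e_cm1")
.minmax_features <- c("I_A_cps", "I_B_cps")
.all_features <- c(.zscore_features, .minmax_features)

#' Deterministic train/test split
#'
#' Draws round(train_frac * n) training rows with a fixed seed; the same
#' seed always yields the same partition.
#'
#' @param cohort a cohort data.frame (>= 4 rows).
#' @param seed integer RNG seed.
#' @param train_frac training fraction, default 0.75.
#' @return list with `train` and `test` data.frames.
#' @export
split_cohort <- function(cohort, seed, train_frac = 0.75) {
  n <- nrow(cohort)
  if (n < 4) stop("split_cohort: need at least 4 records")
  n_train <- round(train_frac * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = cohort[sort(idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Fit preprocessing constants on a training cohort
#'
#' Computes, on the training split only: per-feature means/SDs for
#' z-scoring, per-feature min/max for the imaging-derived count features,
#' and imputation means. Zero-variance features trigger a warning and are
#' passed through unscaled.
#'
#' @param train training-split data.frame.
#' @param z_max outlier threshold: rows with any |z| > z_max on a z-scored
#'   feature are flagged for removal (default 3).
#' @return a `preprocess_params` object.
#' @export
fit_preprocess <- function(train, z_max = 3) {
  feats <- intersect(.all_features, names(train))
  p <- list(z_max = z_max, center = list(), scale = list(),
            min = list(), max = list(), impute = list())
  for (f in feats) {
    v <- train[[f]]
    p$impute[[f]] <- mean(v, na.rm = TRUE)
    if (f %in% .zscore_features) {
      m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        warning("fit_preprocess: feature '", f,
                "' has zero variance; passed through unscaled")
        m <- 0; s <- 1
      }
      p$center[[f]] <- m; p$scale[[f]] <- s
    } else {
      lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
      if (hi == lo) {
        warning("fit_preprocess: feature '", f,
                "' is constant; passed through unscaled")
        lo <- 0; hi <- 1
      }
      p$min[[f]] <- lo; p$max[[f]] <- hi
    }
  }
  structure(p, class = "preprocess_params")
}

#' Preprocess a cohort for model fitting
#'
#' The cleaning and normalization pipeline: rows with a missing target
#' dose are dropped; missing features are imputed (mean, or linear
#' interpolation along patient_id/organ order); rows with any |z| > z_max
#' on a z-scored feature are removed (outlier filter, applied only when
#' the constants are being fitted, i.e. on the training split); then
#' imaging-derived count features are min-max scaled and all other
#' features z-scored. When `params` is supplied (the saved training
#' constants) they are applied verbatim — no constant is recomputed — and
#' the transform is idempotent: an already-normalized table is returned
#' unchanged.
#'
#' @param cohort cohort data.frame.
#' @param params optional saved `preprocess_params`; NULL fits fresh
#'   constants on `cohort` (training use).
#' @param z_max outlier threshold used when fitting fresh constants.
#' @param impute "mean" or "interpolate".
#' @return the transformed data.frame, with the fitted or supplied
#'   constants in `attr(, "preprocess_params")`.
#' @export
preprocess_cohort <- function(cohort, params = NULL, z_max = 3,
                              impute = c("mean", "interpolate")) {
  impute <- match.arg(impute)
  df <- as.data.frame(cohort)
  if (isTRUE(attr(df, "normalized"))) return(df)   # idempotent re-application
  if (nrow(df) == 0) stop("preprocess_cohort: empty cohort")
  # drop rows with missing target
  if ("target_dose_Gy" %in% names(df))
    df <- df[!is.na(df$target_dose_Gy), , drop = FALSE]
  feats <- intersect(.all_features, names(df))
  # impute missing features
  fitting <- is.null(params)
  if (fitting) params <- fit_preprocess(df, z_max = z_max)
  for (f in feats) {
    miss <- is.na(df[[f]])
    if (!any(miss)) next
    if (impute == "interpolate") {
      ord <- order(df$patient_id, df$organ)
      v <- df[[f]][ord]
      v <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                         xout = seq_along(v), rule = 2)$y
      df[[f]][ord] <- v
    } else {
      df[[f]][miss] <- params$impute[[f]]
    }
  }
  if (fitting) {
    # outlier filter on the z-scored features (training split only)
    keep <- rep(TRUE, nrow(df))
    for (f in intersect(.zscore_features, feats)) {
      z <- (df[[f]] - params$center[[f]]) / params$scale[[f]]
      keep <- keep & abs(z) <= params$z_max
    }
    df <- df[keep, , drop = FALSE]
  }
  for (f in feats) {
    if (f %in% .zscore_features)
      df[[f]] <- (df[[f]] - params$center[[f]]) / params$scale[[f]]
    else
      df[[f]] <- (df[[f]] - params$min[[f]]) / (params$max[[f]] - params$min[[f]])
  }
  attr(df, "preprocess_params") <- params
  attr(df, "normalized") <- TRUE
  df
}
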