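# Conjugate-view activity quantification: ROI count rates, effective
# attenuation, oblique-view thickness, calibration, recovery coefficients,
# and the geometric-mean activity formula
#   A = sqrt(I_A * I_B * exp(+mu_e * T)) / C        [/ RC when applied]
# with I_A, I_B background-corrected ROI count rates (counts/s), mu_e the
# effective linear attenuation coefficient (1/cm), T the body thickness
# along the view (cm), and C the system calibration factor (counts/(MBq s)).

#' System calibration factor
#'
#' Counts recorded per MBq per second, measured from a planar scan of a
#' known activity (Petri dish in air, or a point-like source).
#'
#' @param value counts per (MBq s); must be > 0.
#' @param method "petri_dish" or "point_source".
#' @param source_activity_MBq activity of the calibration source (MBq).
#' @param distance_cm source-to-camera distance (cm).
#' @return an object of class `calibration_factor`.
#' @export
calibration_factor <- function(value, method = c("petri_dish", "point_source"),
                               source_activity_MBq = NA_real_,
                               distance_cm = NA_real_) {
  method <- match.arg(method)
  if (!is.finite(value) || value <= 0)
    stop("calibration_factor: value must be a positive number")
  structure(list(value = value, method = method,
                 source_activity_MBq = source_activity_MBq,
                 distance_cm = distance_cm),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %.6g counts/(MBq s) [%s]\n",
              x$value, x$method))
  invisible(x)
}

#' Calibration factor from a known-activity scan
#'
#' C = total counts / (known activity x duration). Linear in counts:
#' doubling the recorded counts doubles C.
#'
#' @param known_activity_MBq true source activity (MBq), > 0.
#' @param total_counts counts recorded over the scan, > 0.
#' @param duration_s scan duration (s), > 0.
#' @param method calibration geometry, see [calibration_factor()].
#' @return a `calibration_factor`.
#' @export
calibration_from_scan <- function(known_activity_MBq, total_counts, duration_s,
                                  method = "petri_dish") {
  if (known_activity_MBq <= 0 || total_counts <= 0 || duration_s <= 0)
    stop("calibration_from_scan: all inputs must be > 0")
  calibration_factor(total_counts / (known_activity_MBq * duration_s),
                     method = method,
                     source_activity_MBq = known_activity_MBq)
}

#' Background-corrected ROI count rate
#'
#' (mean in-ROI pixel counts - mean background pixel counts, floored at 0)
#' x number of ROI pixels / acquisition duration. Without a background mask
#' no subtraction is performed (the rate is then ROI sum / duration).
#'
#' @param img a `planar_image`.
#' @param mask an `organ_mask` congruent with `img`.
#' @param background_mask optional `organ_mask` of a background region.
#' @return count rate in counts/s (scalar).
#' @export
roi_counts <- function(img, mask, background_mask = NULL) {
  stopifnot(inherits(img, "planar_image"), inherits(mask, "organ_mask"))
  if (!identical(dim(img$pixels), dim(mask$pixels)))
    stop("roi_counts: mask shape does not match image")
  idx <- mask$pixels > 0
  npix <- sum(idx)
  if (npix == 0) stop("roi_counts: empty mask")
  m_roi <- mean(img$pixels[idx])
  m_bg <- 0
  if (!is.null(background_mask)) {
    if (!identical(dim(img$pixels), dim(background_mask$pixels)))
      stop("roi_counts: background mask shape does not match image")
    bidx <- background_mask$pixels > 0
    if (sum(bidx) == 0) stop("roi_counts: empty background mask")
    m_bg <- mean(img$pixels[bidx])
  }
  max(m_roi - m_bg, 0) * npix / img$duration_s
}

#' Effective attenuation coefficient of a region
#'
#' The arithmetic mean of the linear attenuation coefficients of the
#' tissues traversed between the organ and the detector. When the lung is
#' split into upper/middle/lower thirds, each third gets its own call —
#' values are never pooled across parts.
#'
#' @param mu_values numeric vector of attenuation coefficients (1/cm),
#'   all >= 0, non-empty.
#' @return mean coefficient (1/cm).
#' @export
effective_mu <- function(mu_values) {
  if (length(mu_values) == 0) stop("effective_mu: empty input")
  if (any(!is.finite(mu_values)) || any(mu_values < 0))
    stop("effective_mu: coefficients must be finite and >= 0")
  mean(mu_values)
}

#' Body thickness from the 45-degree oblique view
#'
#' The apparent thickness is the pixel distance between two cursor points
#' on the oblique image, scaled by the pixel size and an optional
#' obliquity correction factor (default 1: the apparent chord is taken as
#' the thickness T of the attenuation formula).
#'
#' @param p1,p2 (row, col) pixel coordinates; must differ.
#' @param pixel_size_mm pixel size (scalar, mm).
#' @param obliquity_factor positive geometric correction, default 1.
#' @return an object of class `thickness_measurement` with `$thickness_cm`.
#' @export
thickness_from_oblique <- function(p1, p2, pixel_size_mm = 2.3976,
                                   obliquity_factor = 1.0) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2 || length(p2) != 2)
    stop("thickness_from_oblique: points must be (row, col) pairs")
  if (all(p1 == p2))
    stop("thickness_from_oblique: coincident points give a degenerate measurement")
  if (obliquity_factor <= 0)
    stop("thickness_from_oblique: obliquity_factor must be > 0")
  d_px <- sqrt(sum((p2 - p1)^2))
  structure(list(p1 = p1, p2 = p2, pixel_size_mm = pixel_size_mm,
                 obliquity_factor = obliquity_factor,
                 thickness_cm = d_px * pixel_size_mm * obliquity_factor / 10),
            class = "thickness_measurement")
}

#' @export
print.thickness_measurement <- function(x, ...) {
  cat(sprintf("<thickness_measurement> %.3f cm (%.1f px at %.4f mm, factor %.3f)\n",
              x$thickness_cm, sqrt(sum((x$p2 - x$p1)^2)), x$pixel_size_mm,
              x$obliquity_factor))
  invisible(x)
}

#' Recovery-coefficient curve for partial-volume correction
#'
#' Apparent-to-true activity ratio measured on a sphere phantom as a
#' function of sphere diameter; used as a divisor to correct small-object
#' activity. Queries interpolate piecewise-linearly and clamp (with a
#' warning) outside the calibrated diameter range.
#'
#' @param diameters_mm strictly increasing sphere diameters (mm).
#' @param rc matching recovery coefficients, all > 0.
#' @param modality "planar" or "spect".
#' @return an object of class `recovery_curve`.
#' @export
recovery_curve <- function(diameters_mm, rc, modality = c("planar", "spect")) {
  modality <- match.arg(modality)
  if (length(diameters_mm) == 0 || length(diameters_mm) != length(rc))
    stop("recovery_curve: diameters and rc must be non-empty and match")
  if (any(diff(diameters_mm) <= 0))
    stop("recovery_curve: diameters must be strictly increasing")
  if (any(rc <= 0)) stop("recovery_curve: rc values must be > 0")
  structure(list(diameters_mm = as.numeric(diameters_mm),
                 rc = as.numeric(rc), modality = modality),
            class = "recovery_curve")
}

#' Interpolate a recovery coefficient
#'
#' @param curve a [recovery_curve()].
#' @param diameter_mm object diameter (mm); outside the calibrated range
#'   the nearest-end value is returned with a warning.
#' @return the recovery coefficient (scalar).
#' @export
recovery_coefficient <- function(curve, diameter_mm) {
  stopifnot(inherits(curve, "recovery_curve"))
  rng <- range(curve$diameters_mm)
  if (diameter_mm < rng[1] || diameter_mm > rng[2])
    warning(sprintf("diameter %.1f mm outside calibrated range [%.1f, %.1f]; clamping",
                    diameter_mm, rng[1], rng[2]))
  if (length(curve$diameters_mm) == 1L) return(curve$rc)
  stats::approx(curve$diameters_mm, curve$rc, xout = diameter_mm,
                rule = 2)$y
}

#' Conjugate-view activity estimate
#'
#' The geometric-mean activity formula: with anterior and posterior ROI
#' count rates I_A and I_B (counts/s), effective attenuation mu_e (1/cm),
#' body thickness T (cm) and calibration factor C (counts/(MBq s)),
#'
#'   A = sqrt(I_A * I_B / exp(-mu_e * T)) / C      (MBq)
#'
#' optionally divided by a recovery coefficient to correct partial-volume
#' losses. With mu_e = 0 the formula reduces to sqrt(I_A I_B)/C exactly,
#' and A is monotone nondecreasing in each of I_A, I_B, mu_e and T.
#'
#' @param I_A,I_B anterior / posterior ROI count rates (counts/s), >= 0.
#' @param mu_e effective attenuation coefficient (1/cm), >= 0.
#' @param T_cm body thickness along the view (cm), >= 0.
#' @param C a [calibration_factor()] or a positive scalar (counts/(MBq s)).
#' @param rc optional recovery coefficient (> 0) applied as a divisor.
#' @param organ organ label recorded in the estimate.
#' @return an object of class `activity_estimate` with `$activity_MBq` and
#'   a `$components` record of every input used.
#' @export
conjugate_view_activity <- function(I_A, I_B, mu_e, T_cm, C, rc = NULL,
                                    organ = NA_character_) {
  cval <- if (inherits(C, "calibration_factor")) C$value else C
  if (I_A < 0 || I_B < 0) stop("conjugate_view_activity: count rates must be >= 0")
  if (mu_e < 0) stop("conjugate_view_activity: mu_e must be >= 0")
  if (T_cm < 0) stop("conjugate_view_activity: thickness must be >= 0")
  if (!is.finite(cval) || cval <= 0)
    stop("conjugate_view_activity: calibration factor must be > 0")
  if (!is.null(rc) && rc <= 0) stop("conjugate_view_activity: rc must be > 0")
  A <- sqrt(I_A * I_B * exp(mu_e * T_cm)) / cval
  if (!is.null(rc)) A <- A / rc
  structure(list(activity_MBq = A, organ = organ,
                 components = list(I_A = I_A, I_B = I_B, mu_e = mu_e,
                                   T_cm = T_cm, C = cval,
                                   RC = if (is.null(rc)) NA_real_ else rc)),
            class = "activity_estimate")
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("<activity_estimate> %s: %.4g MBq\n",
              if (is.na(x$organ)) "(organ?)" else x$organ, x$activity_MBq))
  cmp <- x$components
  cat(sprintf("  I_A=%.4g cps, I_B=%.4g cps, mu_e=%.4g /cm, T=%.4g cm, C=%.4g, RC=%s\n",
              cmp$I_A, cmp$I_B, cmp$mu_e, cmp$T_cm, cmp$C,
              if (is.na(cmp$RC)) "-" else format(cmp$RC)))
  invisible(x)
}

# physical decay constant of I-131 (half-life 8.02 d = 192.5 h)
LAMBDA_PHYS_I131_PER_H <- log(2) / 192.5

#' Decay-correct a count rate to a reference time
#'
#' Off by default in the pipeline; multiplies by exp(+lambda_phys * dt)
#' to refer counts measured at `t_h` back to `t_ref_h`.
#'
#' @param rate count rate (counts/s).
#' @param t_h measurement time post-administration (h).
#' @param t_ref_h reference time (h), default 0.
#' @param lambda_per_h decay constant (1/h), default the I-131 physical
#'   constant ln(2)/192.5.
#' @return decay-corrected rate.
#' @export
decay_correct <- function(rate, t_h, t_ref_h = 0,
                          lambda_per_h = LAMBDA_PHYS_I131_PER_H) {
  rate * exp(lambda_per_h * (t_h - t_ref_h))
}

#' Quantify every organ of a conjugate-view study
#'
#' Full per-organ chain: background-corrected ROI rates on the anterior
#' and flipped-posterior images, then the conjugate-view formula with the
#' per-organ effective attenuation coefficient, per-organ (or global)
#' thickness, calibration factor, and optional recovery-coefficient
#' correction.
#'
#' @param anterior,posterior `planar_image`s (posterior unflipped; it is
#'   flipped internally).
#' @param masks named list of `organ_mask`s (names = organ labels); masks
#'   apply to the anterior frame.
#' @param mu_e named numeric vector or list: per-organ effective
#'   attenuation coefficients (1/cm).
#' @param thickness_cm per-organ named vector, or a single number used for
#'   all organs.
#' @param C a [calibration_factor()] or positive scalar.
#' @param background_mask optional background `organ_mask`.
#' @param rc_curve optional [recovery_curve()]; used with `diameters_mm`.
#' @param diameters_mm optional named per-organ equivalent diameters (mm)
#'   for recovery-coefficient lookup.
#' @return data.frame with columns organ, I_A_cps, I_B_cps, mu_e_cm1,
#'   T_cm, C, RC, activity_MBq.
#' @export
quantify_organs <- function(anterior, posterior, masks, mu_e, thickness_cm, C,
                            background_mask = NULL, rc_curve = NULL,
                            diameters_mm = NULL) {
  stopifnot(inherits(anterior, "planar_image"), inherits(posterior, "planar_image"))
  pflip <- if (posterior$view == "posterior") flip_posterior(posterior) else posterior
  organs <- names(masks)
  if (is.null(organs)) stop("quantify_organs: masks must be a named list")
  rows <- lapply(organs, function(org) {
    m <- masks[[org]]
    ia <- roi_counts(anterior, m, background_mask)
    ib <- roi_counts(pflip, m, background_mask)
    mu <- if (length(mu_e) == 1 && is.null(names(mu_e))) as.numeric(mu_e) else {
      if (!org %in% names(mu_e)) stop("quantify_organs: no mu_e for organ ", org)
      as.numeric(mu_e[[org]])
    }
    tt <- if (length(thickness_cm) == 1 && is.null(names(thickness_cm)))
      as.numeric(thickness_cm)
    else {
      if (!org %in% names(thickness_cm))
        stop("quantify_organs: no thickness for organ ", org)
      as.numeric(thickness_cm[[org]])
    }
    rc <- NULL
    if (!is.null(rc_curve) && !is.null(diameters_mm) && org %in% names(diameters_mm))
      rc <- recovery_coefficient(rc_curve, as.numeric(diameters_mm[[org]]))
    est <- conjugate_view_activity(ia, ib, mu, tt, C, rc = rc, organ = org)
    data.frame(organ = org, I_A_cps = ia, I_B_cps = ib, mu_e_cm1 = mu,
               T_cm = tt,
               C = if (inherits(C, "calibration_factor")) C$value else C,
               RC = if (is.null(rc)) NA_real_ else rc,
               activity_MBq = est$activity_MBq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
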