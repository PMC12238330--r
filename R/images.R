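#' Planar scintigraphy image
#'
#' Container for a single 2D planar count image: the raw count grid, the
#' detector pixel size, which projection it is (anterior, posterior or the
#' 45-degree oblique view), the acquisition time after administration, and
#' the acquisition duration. Pixels hold raw counts; count rates are derived
#' as counts / duration where needed.
#'
#' @param pixels numeric matrix of non-negative counts, indexed (row, col)
#'   with row = the image vertical (cranio-caudal) axis.
#' @param pixel_size_mm positive numeric of length 1 or 2: (row, col) pixel
#'   size in mm. A scalar is recycled to square pixels. Default 2.3976 mm,
#'   the pixel pitch of a 1024 x 256 whole-body matrix on a dual-head camera.
#' @param view one of "anterior", "posterior", "oblique45",
#'   "posterior_flipped".
#' @param time_post_admin_h non-negative scan time after administration (h).
#' @param duration_s positive acquisition duration (s).
#' @return an object of class `planar_image`.
#' @export
planar_image <- function(pixels, pixel_size_mm = 2.3976,
                         view = c("anterior", "posterior", "oblique45",
                                  "posterior_flipped"),
                         time_post_admin_h = 0, duration_s = 1) {
  view <- match.arg(view)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)))
    stop("planar_image: pixel values must be finite")
  if (any(pixels < 0))
    stop("planar_image: pixel values must be >= 0")
  if (length(pixel_size_mm) == 1L) pixel_size_mm <- rep(pixel_size_mm, 2L)
  if (length(pixel_size_mm) != 2L || any(pixel_size_mm <= 0))
    stop("planar_image: pixel_size_mm must be two positive reals (row, col)")
  if (time_post_admin_h < 0) stop("planar_image: time_post_admin_h must be >= 0")
  if (duration_s <= 0) stop("planar_image: duration_s must be > 0")
  structure(list(pixels = pixels,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 view = view,
                 time_post_admin_h = as.numeric(time_post_admin_h),
                 duration_s = as.numeric(duration_s)),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %s view, %d x %d pixels (%.4f x %.4f mm)\n",
              x$view, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_mm[1], x$pixel_size_mm[2]))
  cat(sprintf("  t = %.1f h post-admin, duration %.0f s, total %.4g counts\n",
              x$time_post_admin_h, x$duration_s, sum(x$pixels)))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$pixels)

#' Binary organ region-of-interest mask
#'
#' A 0/1 mask congruent with a planar image, labelled with the organ it
#' delineates. The lung is conventionally split into upper/middle/lower
#' thirds so that attenuation can be corrected separately for each part.
#'
#' @param pixels binary (0/1 or logical) matrix, same shape as the image it
#'   will be applied to; must contain at least one nonzero pixel.
#' @param label organ name, e.g. "heart", "kidney_left", "kidney_right",
#'   "liver", "lung_upper", "lung_middle", "lung_lower", "spleen",
#'   "thyroid", "salivary_glands", "tumor", or "background".
#' @return an object of class `organ_mask`.
#' @export
organ_mask <- function(pixels, label) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(pixels %in% c(0, 1)))
    stop("organ_mask: mask must be binary (0/1)")
  if (sum(pixels) < 1)
    stop("organ_mask: mask must contain at least one pixel")
  structure(list(pixels = pixels, label = as.character(label)),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("<organ_mask> '%s': %d pixels in a %d x %d grid\n",
              x$label, sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Rotate a posterior image 180 degrees in-plane
#'
#' The posterior detector views the patient from behind, so before the
#' geometric-mean combination the posterior image must be rotated 180
#' degrees in-plane (equivalently flipped along both axes) to register it
#' with the anterior view. Metadata is preserved; the view is annotated
#' `posterior_flipped`. Applying the flip twice returns the original grid.
#'
#' @param img a `planar_image` with view "posterior".
#' @return the flipped `planar_image` (view "posterior_flipped").
#' @export
flip_posterior <- function(img) {
  stopifnot(inherits(img, "planar_image"))
  if (!img$view %in% c("posterior", "posterior_flipped"))
    stop("flip_posterior: image view must be posterior (got '",
         img$view, "')")
  p <- img$pixels[rev(seq_len(nrow(img$pixels))),
                  rev(seq_len(ncol(img$pixels))), drop = FALSE]
  out <- img
  out$pixels <- p
  out$view <- if (img$view == "posterior") "posterior_flipped" else "posterior"
  out
}

#' Geometric-mean image of opposed views
#'
#' Per-pixel sqrt(anterior x flipped-posterior): the conjugate-view
#' combination that, for a source at depth d in a body of thickness T,
#' cancels the depth dependence of attenuation (exp(-mu d) and
#' exp(-mu (T - d)) combine to exp(-mu T / 2)).
#'
#' @param ant anterior `planar_image`.
#' @param post_flipped posterior image already flipped with
#'   [flip_posterior()]; same shape and pixel size as `ant`.
#' @return a `planar_image` holding the geometric-mean grid.
#' @export
geometric_mean_image <- function(ant, post_flipped) {
  stopifnot(inherits(ant, "planar_image"), inherits(post_flipped, "planar_image"))
  if (!identical(dim(ant$pixels), dim(post_flipped$pixels)))
    stop("geometric_mean_image: image shapes differ")
  if (max(abs(ant$pixel_size_mm - post_flipped$pixel_size_mm)) > 1e-9)
    stop("geometric_mean_image: pixel sizes differ")
  out <- ant
  out$pixels <- sqrt(ant$pixels * post_flipped$pixels)
  out$view <- "anterior"   # GM lives in the anterior frame
  out
}
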