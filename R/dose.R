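# Pixel dose maps by kernel convolution: D = A-tilde (x) DPK, plus organ
# mean dose, organ S-values, and kernel-size sufficiency analysis.

#' Cumulated-activity map
#'
#' Per-pixel time-integrated activity (MBq s). Its pixel size must match
#' the kernel it is convolved with.
#'
#' @param grid non-negative numeric matrix (MBq s per pixel).
#' @param pixel_size_mm pixel size (mm).
#' @return an object of class `activity_map`.
#' @export
activity_map <- function(grid, pixel_size_mm = 2.3976) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("activity_map: entries must be finite and >= 0")
  structure(list(grid = grid, pixel_size_mm = as.numeric(pixel_size_mm)),
            class = "activity_map")
}

#' Convolve a cumulated-activity map with a dose point kernel
#'
#' Discrete 2D convolution D = A (x) k with zero padding: the output has
#' the same shape as the input, and activity outside the field contributes
#' no dose. The operation is linear in both arguments, and when the
#' activity lies at least half a kernel away from every border the total
#' dose is conserved exactly: sum(D) = sum(A) x sum(k). True convolution
#' is implemented (the kernel is index-reversed), although for the
#' validated symmetric kernels convolution and correlation coincide.
#'
#' @param a an [activity_map()] (or bare matrix, MBq s).
#' @param k a [dose_kernel()].
#' @param edge edge rule; only "zero_pad" is defined.
#' @return an object of class `dose_map` (grid in Gy).
#' @export
convolve_dose <- function(a, k, edge = "zero_pad") {
  stopifnot(inherits(k, "dose_kernel"))
  if (!identical(edge, "zero_pad"))
    stop("convolve_dose: only edge = 'zero_pad' is supported")
  if (inherits(a, "activity_map")) {
    if (abs(a$pixel_size_mm[1] - k$pixel_size_mm[1]) > 1e-6)
      stop(sprintf("convolve_dose: pixel size mismatch (map %.6f mm, kernel %.6f mm)",
                   a$pixel_size_mm[1], k$pixel_size_mm[1]))
    A <- a$grid
    psz <- a$pixel_size_mm
  } else {
    A <- as.matrix(a)
    psz <- k$pixel_size_mm
  }
  kg <- k$grid
  K <- nrow(kg)
  h <- (K - 1) / 2
  nr <- nrow(A); nc <- ncol(A)
  # zero-pad the activity, then shift-and-add one kernel tap at a time:
  # D[x] = sum_u k[u] A[x - u], offsets u measured from the kernel center
  P <- matrix(0, nr + 2 * h, nc + 2 * h)
  P[(h + 1):(h + nr), (h + 1):(h + nc)] <- A
  D <- matrix(0, nr, nc)
  for (i in seq_len(K)) {
    di <- i - (h + 1)   # row offset u_r
    for (j in seq_len(K)) {
      w <- kg[i, j]
      if (w == 0) next
      dj <- j - (h + 1)
      # A[x - u] for all x: slice the padded grid shifted by -u
      D <- D + w * P[(h + 1 - di):(h + nr - di),
                     (h + 1 - dj):(h + nc - dj), drop = FALSE]
    }
  }
  structure(list(grid = D, pixel_size_mm = psz), class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d, total %.4g Gy-pixels, max %.4g Gy\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), max(x$grid)))
  invisible(x)
}

#' Mean absorbed dose over an organ mask
#'
#' @param d a `dose_map` (or bare matrix, Gy).
#' @param mask an `organ_mask` congruent with `d`.
#' @return mean dose over mask pixels (Gy).
#' @export
organ_mean_dose <- function(d, mask) {
  stopifnot(inherits(mask, "organ_mask"))
  g <- if (inherits(d, "dose_map")) d$grid else as.matrix(d)
  if (!identical(dim(g), dim(mask$pixels)))
    stop("organ_mean_dose: mask shape does not match dose map")
  idx <- mask$pixels > 0
  if (sum(idx) == 0) stop("organ_mean_dose: empty mask")
  mean(g[idx])
}

#' Organ self-dose S-value from a kernel
#'
#' Mean absorbed dose to the organ per unit total cumulated activity
#' distributed uniformly over the organ mask: a uniform activity map of
#' total 1 MBq s on the mask is convolved with the kernel and averaged
#' over the mask. For a single-pixel mask this is the kernel center value;
#' for a delta kernel of unit amplitude and an m-pixel mask it is 1/m.
#'
#' @param k a `dose_kernel`.
#' @param mask an `organ_mask`.
#' @return S-value in Gy/(MBq s).
#' @export
organ_s_value <- function(k, mask) {
  stopifnot(inherits(k, "dose_kernel"), inherits(mask, "organ_mask"))
  m <- sum(mask$pixels > 0)
  if (m == 0) stop("organ_s_value: empty mask")
  a <- mask$pixels / m   # unit total cumulated activity
  d <- convolve_dose(activity_map(a, pixel_size_mm = k$pixel_size_mm), k)
  organ_mean_dose(d, mask)
}

#' Central crop of a kernel
#'
#' @param k a `dose_kernel` of size K.
#' @param size odd size <= K.
#' @return the cropped `dose_kernel` (validation not re-run: a crop of a
#'   valid kernel keeps its invariants).
#' @export
crop_kernel <- function(k, size) {
  stopifnot(inherits(k, "dose_kernel"))
  K <- nrow(k$grid)
  if (size %% 2 == 0 || size > K)
    stop("crop_kernel: size must be odd and <= ", K)
  c0 <- (K + 1) / 2
  h <- (size - 1) / 2
  dose_kernel(k$grid[(c0 - h):(c0 + h), (c0 - h):(c0 + h), drop = FALSE],
              pixel_size_mm = k$pixel_size_mm,
              organ_or_medium = k$organ_or_medium, check = FALSE)
}

#' Kernel-size sufficiency study
#'
#' For each requested odd size n <= K: the coverage fraction of the full
#' kernel sum captured by the central n x n block, and the relative
#' total-dose deficit of the truncated kernel versus the full kernel on a
#' reference phantom (a uniform disc of activity in the map interior).
#' The deficit is nonincreasing with size and reaches 0 at n = K.
#'
#' @param k_full the full `dose_kernel` (size K).
#' @param sizes odd sizes <= K (default 3, 5, ..., K).
#' @param phantom_shape reference map dimensions (rows, cols).
#' @param disc_radius_px radius of the uniform activity disc (pixels).
#' @return data.frame with columns size, coverage, dose_deficit.
#' @export
kernel_size_study <- function(k_full, sizes = seq(3, nrow(k_full$grid), by = 2),
                              phantom_shape = c(41, 41), disc_radius_px = 10) {
  stopifnot(inherits(k_full, "dose_kernel"))
  K <- nrow(k_full$grid)
  if (any(sizes %% 2 == 0)) stop("kernel_size_study: sizes must be odd")
  if (any(sizes > K)) stop("kernel_size_study: sizes must be <= ", K)
  summ <- validate_kernel(k_full)
  # uniform disc phantom centered in the map
  nr <- phantom_shape[1]; nc <- phantom_shape[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rr <- outer(seq_len(nr), rep(1, nc)) - cr
  cc2 <- outer(rep(1, nr), seq_len(nc)) - cc
  disc <- (rr^2 + cc2^2 <= disc_radius_px^2) * 1
  a <- activity_map(disc / sum(disc), pixel_size_mm = k_full$pixel_size_mm)
  full_total <- sum(convolve_dose(a, k_full)$grid)
  out <- lapply(sizes, function(n) {
    kc <- crop_kernel(k_full, n)
    tot <- sum(convolve_dose(a, kc)$grid)
    data.frame(size = n,
               coverage = unname(summ$coverage_by_size[as.character(n)]),
               dose_deficit = (full_total - tot) / full_total)
  })
  do.call(rbind, out)
}
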