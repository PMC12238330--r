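# Dose point kernels: odd-sized square grids of absorbed dose per unit
# cumulated activity in the central source pixel (Gy per MBq s), exported
# from Monte-Carlo simulation per organ/medium. This file holds the
# container, validation, and the text/MetaImage kernel dialects.

#' Dose point kernel
#'
#' K x K grid (K odd) of dose deposited per unit cumulated activity in the
#' central source pixel, in Gy/(MBq s). A valid kernel is non-negative,
#' peaks at its center, and is symmetric under 90-degree rotation and
#' mirroring to within a tolerance (isotropic point source).
#'
#' @param grid numeric K x K matrix, K odd, entries >= 0.
#' @param pixel_size_mm pixel size (mm), default 2.3976.
#' @param organ_or_medium label of the organ/medium the kernel was
#'   simulated in.
#' @param check validate invariants on construction (default TRUE).
#' @param tol symmetry tolerance relative to the center value.
#' @return an object of class `dose_kernel`.
#' @export
dose_kernel <- function(grid, pixel_size_mm = 2.3976,
                        organ_or_medium = "water", check = TRUE,
                        tol = 1e-6) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  k <- structure(list(grid = grid, pixel_size_mm = as.numeric(pixel_size_mm),
                      organ_or_medium = as.character(organ_or_medium)),
                 class = "dose_kernel")
  if (check) validate_kernel(k, tol = tol)
  k
}

#' @export
print.dose_kernel <- function(x, ...) {
  K <- nrow(x$grid)
  cat(sprintf("<dose_kernel> %s: %d x %d at %.4f mm, center %.4g Gy/(MBq s), sum %.4g\n",
              x$organ_or_medium, K, K, x$pixel_size_mm,
              x$grid[(K + 1) / 2, (K + 1) / 2], sum(x$grid)))
  invisible(x)
}

#' Validate a dose point kernel and summarize its coverage
#'
#' Checks the kernel invariants (odd size, square, non-negative entries,
#' central maximum, rotational/mirror symmetry within `tol`) and computes
#' the coverage profile: for each odd n <= K, the fraction of the total
#' kernel sum inside the central n x n block. A kernel whose outer ring
#' still holds more than `1 - coverage_threshold` of the sum is rejected —
#' its support is too small to cover the dose range.
#'
#' @param k a `dose_kernel` (or bare matrix).
#' @param tol symmetry tolerance, relative to the center value.
#' @param coverage_threshold minimum coverage the (K-2) x (K-2) core must
#'   reach (default 0: disabled).
#' @return an object of class `kernel_summary` with `$s_value_center`
#'   (Gy/(MBq s)) and `$coverage_by_size` (named numeric, names = n).
#' @export
validate_kernel <- function(k, tol = 1e-6, coverage_threshold = 0) {
  g <- if (inherits(k, "dose_kernel")) k$grid else as.matrix(k)
  K <- nrow(g)
  if (ncol(g) != K) stop("validate_kernel: kernel must be square")
  if (K %% 2 == 0) stop("validate_kernel: kernel size must be odd (got ", K, ")")
  if (any(!is.finite(g))) stop("validate_kernel: non-finite entries")
  if (any(g < 0)) stop("validate_kernel: negative entries")
  c0 <- (K + 1) / 2
  if (g[c0, c0] < max(g)) stop("validate_kernel: center entry is not the maximum")
  ref <- max(g[c0, c0], .Machine$double.eps)
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m))), drop = FALSE]
  if (max(abs(g - rot90(g))) > tol * ref)
    stop("validate_kernel: kernel is not symmetric under 90-degree rotation")
  if (max(abs(g - g[, rev(seq_len(K)), drop = FALSE])) > tol * ref)
    stop("validate_kernel: kernel is not mirror-symmetric")
  tot <- sum(g)
  sizes <- seq(1, K, by = 2)
  cov <- vapply(sizes, function(n) {
    h <- (n - 1) / 2
    sum(g[(c0 - h):(c0 + h), (c0 - h):(c0 + h)]) / tot
  }, numeric(1))
  names(cov) <- sizes
  if (coverage_threshold > 0 && K >= 3) {
    core <- cov[as.character(K - 2)]
    if (core < coverage_threshold)
      stop(sprintf(
        "validate_kernel: outer ring holds %.3f of the kernel sum (> %.3f); support too small",
        1 - core, 1 - coverage_threshold))
  }
  structure(list(s_value_center = g[c0, c0], coverage_by_size = cov,
                 size = K, total = tot),
            class = "kernel_summary")
}

#' @export
print.kernel_summary <- function(x, ...) {
  cat(sprintf("<kernel_summary> K=%d, center S-value %.4g Gy/(MBq s)\n",
              x$size, x$s_value_center))
  cat("  coverage:",
      paste(sprintf("%sx%s %.3f", names(x$coverage_by_size),
                    names(x$coverage_by_size), x$coverage_by_size),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a dose kernel from its text dialect or MetaImage
#'
#' The text dialect is whitespace-delimited with a 3-line header:
#' line 1 `K <odd size>`, line 2 `pixel_size_mm <mm>`, line 3
#' `units <string>`, then K rows of K values. `.mhd` paths are read as
#' MetaImage.
#'
#' @param path kernel file path (`.txt`/`.dat` dialect or `.mhd`).
#' @param organ_or_medium label for the kernel.
#' @return a `dose_kernel`.
#' @export
read_kernel <- function(path, organ_or_medium = sub("\\.[^.]+$", "", basename(path))) {
  if (grepl("\\.mhd$", path)) {
    img <- read_metaimage(path)
    return(dose_kernel(img$pixels, pixel_size_mm = img$pixel_size_mm[1],
                       organ_or_medium = organ_or_medium))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1:3]), "\\s+")
  if (tolower(hdr[[1]][1]) != "k" || tolower(hdr[[2]][1]) != "pixel_size_mm")
    stop("read_kernel: malformed text-kernel header (expect 'K <n>' then 'pixel_size_mm <mm>' then 'units <u>')")
  K <- as.integer(hdr[[1]][2])
  psz <- as.numeric(hdr[[2]][2])
  vals <- scan(text = paste(lines[-(1:3)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != K * K)
    stop("read_kernel: expected ", K * K, " values, got ", length(vals))
  dose_kernel(matrix(vals, nrow = K, byrow = TRUE), pixel_size_mm = psz,
              organ_or_medium = organ_or_medium)
}

#' Write a dose kernel in the text dialect
#'
#' @param k a `dose_kernel`.
#' @param path output path.
#' @param units unit string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(k, path, units = "Gy_per_MBq_s") {
  stopifnot(inherits(k, "dose_kernel"))
  K <- nrow(k$grid)
  hdr <- c(sprintf("K %d", K),
           sprintf("pixel_size_mm %s", format(k$pixel_size_mm, digits = 15)),
           sprintf("units %s", units))
  body <- apply(k$grid, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
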