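# Time-activity curves, exponential decay fits, and time-integrated
# (cumulated) activity A-tilde = integral of A(t) dt, reported in MBq s.

#' Time-activity curve
#'
#' Organ activity sampled at increasing times post-administration. The
#' usual I-131 protocol scans at 24, 72 and 168 h.
#'
#' @param times_h strictly increasing non-negative times (h), >= 2 points.
#' @param activities_MBq matching non-negative activities (MBq).
#' @param organ organ label.
#' @return an object of class `tac`.
#' @export
tac <- function(times_h, activities_MBq, organ = NA_character_) {
  if (length(times_h) < 2) stop("tac: need at least two time points")
  if (length(times_h) != length(activities_MBq))
    stop("tac: times and activities lengths differ")
  if (any(diff(times_h) <= 0)) stop("tac: times must be strictly increasing")
  if (any(times_h < 0)) stop("tac: times must be >= 0")
  if (any(activities_MBq < 0)) stop("tac: activities must be >= 0")
  structure(list(times_h = as.numeric(times_h),
                 activities_MBq = as.numeric(activities_MBq),
                 organ = as.character(organ)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d points, t = %s h\n",
              x$organ, length(x$times_h),
              paste(format(x$times_h), collapse = ", ")))
  invisible(x)
}

.exp_model <- function(t, A1, l1, A2 = 0, l2 = 1) {
  A1 * exp(-l1 * t) + A2 * exp(-l2 * t)
}

# deterministic start: lambda from log-linear regression on the last two
# points, amplitude from the first point; rates floored at 1e-6 /h
.init_monoexp <- function(t, y) {
  n <- length(t)
  yp <- pmax(y, max(y) * 1e-9 + .Machine$double.xmin)
  l0 <- (log(yp[n - 1]) - log(yp[n])) / (t[n] - t[n - 1])
  l0 <- max(l0, 1e-6)
  A0 <- yp[1] * exp(l0 * t[1])
  c(A1 = A0, l1 = l0)
}

#' Fit an exponential decay model to a time-activity curve
#'
#' Ordinary (unweighted) least squares fit of a mono- or biexponential
#' decay A(t) = A1 exp(-l1 t) [+ A2 exp(-l2 t)] to the sampled
#' activities. A free biexponential has four parameters and therefore
#' requires at least four points; with only three scans (the common
#' clinical protocol) either fit a monoexponential or pin one rate via
#' `fixed_lambda` (e.g. to the physical decay constant). Underdetermined
#' requests fail loudly rather than silently.
#'
#' Initialization is deterministic: the slow rate comes from a log-linear
#' regression on the last two points and the amplitude from the first
#' point, so the fit is reproducible given the data.
#'
#' @param x a [tac()].
#' @param model "monoexp" or "biexp".
#' @param fixed_lambda optional: pin the second rate l2 (1/h) of a
#'   biexponential, reducing it to three free parameters.
#' @return an object of class `tac_fit` with components A1_MBq,
#'   lambda1_per_h (and A2_MBq, lambda2_per_h for biexp), residual_ss.
#' @export
fit_tac <- function(x, model = c("monoexp", "biexp"), fixed_lambda = NULL) {
  stopifnot(inherits(x, "tac"))
  model <- match.arg(model)
  t <- x$times_h; y <- x$activities_MBq; n <- length(t)

  if (model == "monoexp") {
    if (n < 2) stop("fit_tac: monoexp needs >= 2 points")
    if (n == 2) {
      # exact interpolation
      l1 <- log(y[1] / y[2]) / (t[2] - t[1])
      if (!is.finite(l1) || l1 <= 0)
        stop("fit_tac: two-point data are not a decaying exponential")
      A1 <- y[1] * exp(l1 * t[1])
      fit <- list(A1 = A1, l1 = l1, rss = 0)
    } else {
      st <- .init_monoexp(t, y)
      df <- data.frame(t = t, y = y)
      nls_fit <- tryCatch(
        stats::nls(y ~ A1 * exp(-l1 * t), data = df, start = as.list(st),
                   algorithm = "port", lower = c(A1 = 0, l1 = 1e-6),
                   control = list(maxiter = 500)),
        error = function(e)
          minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t), data = df,
                            start = as.list(st),
                            lower = c(0, 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 500)))
      cf <- stats::coef(nls_fit)
      fit <- list(A1 = cf[["A1"]], l1 = cf[["l1"]],
                  rss = sum(stats::resid(nls_fit)^2))
    }
    out <- list(model = "monoexp", A1_MBq = fit$A1,
                lambda1_per_h = fit$l1, A2_MBq = NULL, lambda2_per_h = NULL,
                residual_ss = fit$rss, fixed_lambda = NULL,
                data = x)
  } else {
    if (is.null(fixed_lambda)) {
      if (n < 4)
        stop("fit_tac: a free biexponential has 4 parameters and needs >= 4 ",
             "points (got ", n, "); fit monoexp or supply fixed_lambda")
      st <- .init_monoexp(t, y)
      # split amplitude between a fast and a slow component
      start <- list(A1 = st[["A1"]] * 0.5, l1 = max(st[["l1"]] * 5, 2e-6),
                    A2 = st[["A1"]] * 0.5, l2 = st[["l1"]])
      df <- data.frame(t = t, y = y)
      nls_fit <- tryCatch(
        stats::nls(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t), data = df,
                   start = start, algorithm = "port",
                   lower = c(0, 1e-6, 0, 1e-6),
                   control = list(maxiter = 1000)),
        error = function(e)
          minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                            data = df, start = start,
                            lower = c(0, 1e-6, 0, 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 1000)))
      cf <- stats::coef(nls_fit)
      out <- list(model = "biexp", A1_MBq = cf[["A1"]],
                  lambda1_per_h = cf[["l1"]], A2_MBq = cf[["A2"]],
                  lambda2_per_h = cf[["l2"]],
                  residual_ss = sum(stats::resid(nls_fit)^2),
                  fixed_lambda = NULL, data = x)
    } else {
      if (fixed_lambda <= 0) stop("fit_tac: fixed_lambda must be > 0")
      if (n < 3)
        stop("fit_tac: biexp with one rate fixed needs >= 3 points (got ", n, ")")
      st <- .init_monoexp(t, y)
      l2 <- fixed_lambda
      start <- list(A1 = st[["A1"]] * 0.5,
                    l1 = max(st[["l1"]], l2 * 2 + 1e-6),
                    A2 = st[["A1"]] * 0.5)
      df <- data.frame(t = t, y = y, l2 = l2)
      nls_fit <- tryCatch(
        stats::nls(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t), data = df,
                   start = start, algorithm = "port",
                   lower = c(0, 1e-6, 0), control = list(maxiter = 1000)),
        error = function(e)
          minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                            data = df, start = start, lower = c(0, 1e-6, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 1000)))
      cf <- stats::coef(nls_fit)
      out <- list(model = "biexp", A1_MBq = cf[["A1"]],
                  lambda1_per_h = cf[["l1"]], A2_MBq = cf[["A2"]],
                  lambda2_per_h = l2,
                  residual_ss = sum(stats::resid(nls_fit)^2),
                  fixed_lambda = l2, data = x)
    }
    if (isTRUE(all.equal(out$lambda1_per_h, out$lambda2_per_h)))
      warning("fit_tac: the two biexponential rates coincide; the model is ",
              "effectively monoexponential")
  }
  class(out) <- "tac_fit"
  out
}

#' @export
print.tac_fit <- function(x, ...) {
  if (x$model == "monoexp") {
    cat(sprintf("<tac_fit> monoexp: A(t) = %.4g exp(-%.5g t)  [MBq, t in h]\n",
                x$A1_MBq, x$lambda1_per_h))
  } else {
    cat(sprintf("<tac_fit> biexp: A(t) = %.4g exp(-%.5g t) + %.4g exp(-%.5g t)%s\n",
                x$A1_MBq, x$lambda1_per_h, x$A2_MBq, x$lambda2_per_h,
                if (!is.null(x$fixed_lambda)) " (l2 fixed)" else ""))
  }
  cat(sprintf("  residual SS = %.4g; half-life of slow term %.3g h\n",
              x$residual_ss,
              log(2) / min(x$lambda1_per_h,
                           x$lambda2_per_h %||% x$lambda1_per_h)))
  invisible(x)
}

#' @export
coef.tac_fit <- function(object, ...) {
  if (object$model == "monoexp")
    c(A1_MBq = object$A1_MBq, lambda1_per_h = object$lambda1_per_h)
  else
    c(A1_MBq = object$A1_MBq, lambda1_per_h = object$lambda1_per_h,
      A2_MBq = object$A2_MBq, lambda2_per_h = object$lambda2_per_h)
}

#' @export
predict.tac_fit <- function(object, times_h = NULL, ...) {
  if (is.null(times_h)) times_h <- object$data$times_h
  .exp_model(times_h, object$A1_MBq, object$lambda1_per_h,
             object$A2_MBq %||% 0, object$lambda2_per_h %||% 1)
}

#' @export
residuals.tac_fit <- function(object, ...) {
  object$data$activities_MBq - predict(object)
}

#' Time-integrated (cumulated) activity of a fitted decay model
#'
#' Closed-form integral of the fitted exponential sum over
#' [t_start, t_end]: sum_i (A_i / lambda_i)(exp(-lambda_i t_start) -
#' exp(-lambda_i t_end)), with t_end = Inf allowed, converted from MBq h
#' to MBq s (x 3600).
#'
#' @param fit a `tac_fit`.
#' @param t_start_h,t_end_h integration limits (h); t_end may be `Inf`.
#' @return cumulated activity in MBq s.
#' @export
time_integrated_activity <- function(fit, t_start_h = 0, t_end_h = Inf) {
  stopifnot(inherits(fit, "tac_fit"))
  if (t_end_h <= t_start_h)
    stop("time_integrated_activity: t_end must exceed t_start")
  term <- function(A, l) {
    e_end <- if (is.infinite(t_end_h)) 0 else exp(-l * t_end_h)
    (A / l) * (exp(-l * t_start_h) - e_end)
  }
  tia_h <- term(fit$A1_MBq, fit$lambda1_per_h)
  if (fit$model == "biexp")
    tia_h <- tia_h + term(fit$A2_MBq, fit$lambda2_per_h)
  tia_h * 3600
}

#' Trapezoidal cumulated activity (model-free fallback)
#'
#' Trapezoidal area under the observed points, optionally extended beyond
#' the last scan by an analytic physical-decay tail
#' A_last / lambda_phys with lambda_phys = ln(2)/192.5 /h for I-131.
#'
#' @param x a [tac()].
#' @param tail "none" or "physical_decay".
#' @param lambda_phys_per_h tail decay constant (1/h).
#' @return cumulated activity in MBq s.
#' @export
trapezoid_tia <- function(x, tail = c("none", "physical_decay"),
                          lambda_phys_per_h = LAMBDA_PHYS_I131_PER_H) {
  stopifnot(inherits(x, "tac"))
  tail <- match.arg(tail)
  t <- x$times_h; y <- x$activities_MBq
  area_h <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (tail == "physical_decay")
    area_h <- area_h + y[length(y)] / lambda_phys_per_h
  area_h * 3600
}
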