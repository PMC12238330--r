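# The four tabular dose regressors: multilayer perceptron (3 hidden
# layers of 6 neurons, leaky ReLU, Adam, L2 penalty), support vector
# regression (radial kernel, C = 100, gamma = 10), decision tree (min
# leaf 5, at most 20 splits), and linear regression (closed-form least
# squares, optional quasi-Newton path capped at 1000 iterations).
# One pooled model is fitted with the organ as a one-hot feature; metric
# reports break results down per organ.

.model_frame <- function(df) {
  feats <- intersect(.all_features, names(df))
  X <- as.matrix(df[feats])
  if ("organ" %in% names(df)) {
    organs <- sort(unique(df$organ))
    if (length(organs) > 1) {
      oh <- sapply(organs, function(o) as.numeric(df$organ == o))
      colnames(oh) <- paste0("organ_", organs)
      X <- cbind(X, oh)
    }
  }
  X
}

#' Train a dose-regression model
#'
#' Fits one of the four model families to a preprocessed cohort (see
#' [preprocess_cohort()]): "mlp", "svr", "tree" or "linreg". Defaults are
#' the tuned clinical configuration: MLP with hidden layers (6, 6, 6),
#' leaky-ReLU activation (alpha = 0.01), Adam optimizer at learning rate
#' 0.001, batch size 50, L2 weight penalty, early stopping on a held-out
#' quarter of the training data; SVR with radial kernel, C = 100,
#' gamma = 10; decision tree with minimum leaf size 5 and at most 20
#' splits; linear regression by exact least squares (set
#' `hyper$method = "bfgs"` for the quasi-Newton path, capped at 1000
#' iterations). Training is deterministic given `seed` (exactly for tree
#' and linreg; to numerical tolerance for MLP/SVR).
#'
#' @param train preprocessed training data.frame with `target_dose_Gy`.
#' @param family one of "mlp", "svr", "tree", "linreg".
#' @param hyper named list of family-specific hyperparameter overrides
#'   (unknown keys are an error).
#' @param seed integer seed for weight initialization / batch order.
#' @return an object of class `c("dose_model_<family>", "dose_model")`
#'   carrying the fit, the feature template, the hyperparameters, the
#'   seed and the saved preprocessing constants (if present on `train`).
#' @export
train_dose_model <- function(train, family = c("mlp", "svr", "tree", "linreg"),
                             hyper = list(), seed = 42) {
  family <- match.arg(family)
  if (!"target_dose_Gy" %in% names(train))
    stop("train_dose_model: training data must contain target_dose_Gy")
  X <- .model_frame(train)
  y <- train$target_dose_Gy
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    bad <- which(rowSums(!is.finite(cbind(X, y))) > 0)
    stop("train_dose_model: non-finite feature values in rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  defaults <- switch(family,
    mlp = list(hidden = c(6, 6, 6), alpha = 0.01, l2 = 1e-4, lr = 0.001,
               batch_size = 50, epochs = 2000, patience = 100,
               val_frac = 0.25),
    svr = list(cost = 100, gamma = 10, epsilon = 0.1),
    tree = list(min_leaf = 5, max_splits = 20),
    linreg = list(method = "ols", maxit = 1000))
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown))
    stop("train_dose_model: unknown ", family, " hyperparameters: ",
         paste(unknown, collapse = ", "))
  hp <- utils::modifyList(defaults, hyper)
  fit <- switch(family,
    mlp = .fit_mlp(X, y, hp, seed),
    svr = {
      set.seed(seed)
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = hp$cost, gamma = hp$gamma, epsilon = hp$epsilon,
                 scale = FALSE)
    },
    tree = .fit_tree(X, y, hp, seed),
    linreg = .fit_linreg(X, y, hp))
  structure(list(family = family, fit = fit, hyper = hp, seed = seed,
                 feature_names = colnames(X),
                 norm_params = attr(train, "preprocess_params")),
            class = c(paste0("dose_model_", family), "dose_model"))
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("<dose_model> family '%s', %d features, seed %d\n",
              x$family, length(x$feature_names), x$seed))
  invisible(x)
}

.align_features <- function(model, df) {
  X <- .model_frame(df)
  out <- matrix(0, nrow(X), length(model$feature_names),
                dimnames = list(NULL, model$feature_names))
  common <- intersect(colnames(X), model$feature_names)
  out[, common] <- X[, common]
  out
}

#' Predict organ doses with a trained model
#'
#' @param object a `dose_model`.
#' @param newdata preprocessed cohort data.frame.
#' @param ... unused.
#' @return numeric vector of predicted doses (Gy).
#' @export
predict.dose_model <- function(object, newdata, ...) {
  X <- .align_features(object, newdata)
  switch(object$family,
    mlp = as.numeric(.mlp_forward(object$fit, X)$out),
    svr = as.numeric(stats::predict(object$fit, X)),
    tree = as.numeric(stats::predict(object$fit,
                                     as.data.frame(X, check.names = FALSE))),
    linreg = as.numeric(cbind(1, X) %*% object$fit$coefficients))
}

# ---- linear regression ------------------------------------------------

.fit_linreg <- function(X, y, hp) {
  if (identical(hp$method, "bfgs")) {
    p <- ncol(X) + 1
    obj <- function(b) {
      r <- y - cbind(1, X) %*% b
      sum(r^2)
    }
    gr <- function(b) -2 * drop(crossprod(cbind(1, X), y - cbind(1, X) %*% b))
    o <- stats::optim(rep(0, p), obj, gr, method = "L-BFGS-B",
                      control = list(maxit = hp$maxit))
    list(coefficients = o$par, method = "bfgs", converged = o$convergence == 0)
  } else {
    f <- stats::lm.fit(cbind(1, X), y)
    cf <- f$coefficients
    cf[is.na(cf)] <- 0   # rank-deficient columns contribute nothing
    list(coefficients = cf, method = "ols", converged = TRUE)
  }
}

#' @export
coef.dose_model <- function(object, ...) {
  if (object$family != "linreg")
    stop("coef() is defined for linreg models only")
  cf <- object$fit$coefficients
  names(cf) <- c("(Intercept)", object$feature_names)
  cf
}

# ---- decision tree ----------------------------------------------------

.fit_tree <- function(X, y, hp, seed) {
  df <- as.data.frame(X, check.names = FALSE)
  df$.y <- y
  set.seed(seed)
  fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        minbucket = hp$min_leaf,
                        minsplit = max(2 * hp$min_leaf, 2),
                        cp = 0, xval = 0, maxsurrogate = 0,
                        maxcompete = 0))
  # cap the number of splits: prune back to the best subtree with at most
  # max_splits splits
  ct <- fit$cptable
  ok <- ct[, "nsplit"] <= hp$max_splits
  if (any(ok) && !utils::tail(ok, 1)) {
    cp_target <- ct[max(which(ok)), "CP"]
    fit <- rpart::prune(fit, cp = cp_target)
  }
  fit
}

# ---- multilayer perceptron --------------------------------------------

.lrelu <- function(z, a) ifelse(z > 0, z, a * z)
.lrelu_grad <- function(z, a) ifelse(z > 0, 1, a)

.mlp_forward <- function(net, X) {
  H <- X
  zs <- list(); hs <- list(H)
  L <- length(net$W)
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]] + matrix(net$b[[l]], nrow(H), length(net$b[[l]]),
                                   byrow = TRUE)
    if (l < L) H <- .lrelu(Z, net$alpha) else H <- Z   # linear output
    zs[[l]] <- Z; hs[[l + 1]] <- H
  }
  list(out = H, zs = zs, hs = hs)
}

.fit_mlp <- function(X, y, hp, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  # inner holdout for early stopping
  n_val <- max(1, round(hp$val_frac * n))
  vidx <- sample.int(n, n_val)
  Xtr <- X[-vidx, , drop = FALSE]; ytr <- y[-vidx]
  Xva <- X[vidx, , drop = FALSE]; yva <- y[vidx]
  sizes <- c(p, hp$hidden, 1L)
  L <- length(sizes) - 1
  W <- list(); b <- list()
  for (l in seq_len(L)) {   # He-style init scaled to fan-in
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  net <- list(W = W, b = b, alpha = hp$alpha)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  best <- list(err = Inf, net = net, since = 0)
  ntr <- nrow(Xtr)
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1, ntr, by = hp$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + hp$batch_size - 1, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      fw <- .mlp_forward(net, Xb)
      m <- length(idx)
      delta <- 2 * (fw$out - yb) / m          # dMSE/dout
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        gW[[l]] <- crossprod(fw$hs[[l]], delta) + 2 * hp$l2 * net$W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(net$W[[l]])) * .lrelu_grad(fw$zs[[l - 1]], net$alpha)
      }
      step <- step + 1
      for (l in seq_len(L)) {   # Adam update
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        net$W[[l]] <- net$W[[l]] - hp$lr * mhW / (sqrt(vhW) + eps)
        net$b[[l]] <- net$b[[l]] - hp$lr * mhb / (sqrt(vhb) + eps)
      }
    }
    val_err <- mean((.mlp_forward(net, Xva)$out - yva)^2)
    if (val_err < best$err - 1e-12) {
      best <- list(err = val_err, net = net, since = 0)
    } else {
      best$since <- best$since + 1
      if (best$since >= hp$patience) break
    }
  }
  out <- best$net
  out$val_mse <- best$err
  out$epochs_run <- epoch
  out
}
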