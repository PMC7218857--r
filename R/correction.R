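#' Min-max normalization to [-1, 1]
#'
#' Fits per-variable minima and maxima and affinely maps each variable so
#' its observed minimum goes to -1 and its maximum to +1. The inverse
#' transform restores the original scale exactly.
#'
#' @param x numeric vector, matrix or data frame of observations.
#' @return for `minmax_fit`, a `minmax_state` (per-variable `min`, `max`);
#'   for `minmax_fit_transform`, a list with elements `scaled` and `state`.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  if (any(!is.finite(mins)) || any(!is.finite(maxs))) {
    stop("non-finite values in normalization input", call. = FALSE)
  }
  if (any(maxs <= mins)) {
    stop("constant variable: min-max normalization undefined", call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "minmax_state")
}

#' @rdname minmax_fit
#' @param state a `minmax_state` from [minmax_fit()].
#' @export
minmax_transform <- function(x, state) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, state$min), 2L, (state$max - state$min) / 2, "/") - 1
}

#' @rdname minmax_fit
#' @param z scaled values in the [-1, 1] convention.
#' @export
minmax_inverse <- function(z, state) {
  z <- as.matrix(z)
  sweep(sweep(z + 1, 2L, (state$max - state$min) / 2, "*"), 2L, state$min, "+")
}

#' @rdname minmax_fit
#' @export
minmax_fit_transform <- function(x) {
  state <- minmax_fit(x)
  list(scaled = minmax_transform(x, state), state = state)
}

#' Regression model specification for drift correction
#'
#' Describes one of the three supported regressor families used to map a
#' fusion-derived joint angle (and optionally its angular velocity) to a
#' reference joint angle:
#' * `nn` — two-layer shallow network: one sigmoid hidden layer
#'   (5-20 neurons), one linear output neuron, trained by
#'   Levenberg-Marquardt least squares with four stopping rules
#'   (validation error rising for `val_fail_limit` consecutive iterations,
#'   MSE reaching `mse_goal`, gradient below `grad_min`, damping `mu`
#'   above `mu_max`);
#' * `tree` — binary regression tree splitting on maximal MSE reduction,
#'   with a minimum leaf size from \{4, 12, 36, 50, 100\} (fine, medium,
#'   coarse, and two pruned settings) and a 200-observation branch minimum;
#' * `svm` — epsilon-insensitive support vector regression with linear,
#'   quadratic, cubic or Gaussian kernel (Gaussian width sigma from
#'   \{0.35, 1.35, 2.35\}).
#'
#' @param kind `"nn"`, `"tree"` or `"svm"`.
#' @param nn_hidden hidden-layer size, integer in 5..20.
#' @param nn_stop list of stopping-rule parameters: `val_fail_limit`,
#'   `mse_goal`, `grad_min`, `mu_max`, `max_epochs`.
#' @param tree_min_leaf minimum observations per leaf node.
#' @param tree_min_branch minimum observations per branch node.
#' @param svm_kernel,svm_C,svm_eps,svm_sigma SVM hyperparameters.
#' @param seed integer seed; fixes the NN initialization and validation
#'   split so fits are reproducible.
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(kind = c("nn", "tree", "svm"),
                            nn_hidden = 5L,
                            nn_stop = list(),
                            tree_min_leaf = 12L,
                            tree_min_branch = 200L,
                            svm_kernel = c("gaussian", "linear", "quadratic", "cubic"),
                            svm_C = 1,
                            svm_eps = 0.01,
                            svm_sigma = 1.35,
                            seed = 1L) {
  kind <- match.arg(kind)
  svm_kernel <- match.arg(svm_kernel)
  nn_hidden <- as.integer(nn_hidden)
  if (nn_hidden < 5L || nn_hidden > 20L) {
    stop("nn_hidden must lie in 5..20", call. = FALSE)
  }
  if (!tree_min_leaf %in% c(4L, 12L, 36L, 50L, 100L)) {
    stop("tree_min_leaf must be one of 4, 12, 36, 50, 100", call. = FALSE)
  }
  if (!svm_sigma %in% c(0.35, 1.35, 2.35)) {
    stop("svm_sigma must be one of 0.35, 1.35, 2.35", call. = FALSE)
  }
  stop_defaults <- list(val_fail_limit = 10L, mse_goal = 0, grad_min = 1e-7,
                        mu_max = 1e10, max_epochs = 300L)
  nn_stop <- utils::modifyList(stop_defaults, nn_stop)
  structure(list(kind = kind, nn_hidden = nn_hidden, nn_stop = nn_stop,
                 tree_min_leaf = as.integer(tree_min_leaf),
                 tree_min_branch = as.integer(tree_min_branch),
                 svm_kernel = svm_kernel, svm_C = svm_C, svm_eps = svm_eps,
                 svm_sigma = svm_sigma, seed = as.integer(seed)),
            class = "regression_spec")
}

# ---- shallow NN trained by Levenberg-Marquardt -----------------------------

sigmoid <- function(u) 1 / (1 + exp(-u))

nn_unpack <- function(w, p, h) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- w[i + seq_len(h)]; i <- i + h
  w2 <- w[i + seq_len(h)]; i <- i + h
  b2 <- w[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

nn_forward <- function(X, wts) {
  A <- sigmoid(sweep(X %*% t(wts$W1), 2L, wts$b1, "+"))
  list(A = A, yhat = as.numeric(A %*% wts$w2 + wts$b2))
}

# Jacobian of predictions w.r.t. the packed weight vector
nn_jacobian <- function(X, wts) {
  fwd <- nn_forward(X, wts)
  A <- fwd$A
  G <- sweep(A * (1 - A), 2L, wts$w2, "*")   # n x h
  p <- ncol(X); h <- ncol(A); n <- nrow(X)
  J <- matrix(0, n, h * p + 2L * h + 1L)
  for (k in seq_len(p)) J[, (k - 1L) * h + seq_len(h)] <- G * X[, k]
  J[, h * p + seq_len(h)] <- G
  J[, h * p + h + seq_len(h)] <- A
  J[, h * p + 2L * h + 1L] <- 1
  list(J = J, yhat = fwd$yhat)
}

# Levenberg-Marquardt training with validation early stopping.
# Stops on: validation failures, MSE goal, gradient floor, mu ceiling,
# or the epoch budget; returns the weights at the best validation MSE.
nn_lm_fit <- function(X, y, hidden, stop_rules, seed, val_frac = 0.15) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); h <- hidden
  if (n < 2L) stop("too few observations for NN training", call. = FALSE)
  set.seed(seed)
  nw <- h * p + 2L * h + 1L
  w <- stats::runif(nw, -0.5, 0.5)

  n_val <- max(1L, floor(val_frac * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  mu <- 1e-3
  wts <- nn_unpack(w, p, h)
  sse <- sum((ytr - nn_forward(Xtr, wts)$yhat)^2)
  best_val <- Inf; best_w <- w; val_fails <- 0L
  stop_reason <- "max_epochs"

  for (epoch in seq_len(stop_rules$max_epochs)) {
    jac <- nn_jacobian(Xtr, wts)
    r <- ytr - jac$yhat
    JtJ <- crossprod(jac$J)
    Jtr <- crossprod(jac$J, r)

    if (max(abs(2 * Jtr)) / length(ytr) < stop_rules$grad_min) {
      stop_reason <- "grad_min"; break
    }

    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(JtJ + mu * diag(nw), Jtr),
        error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + as.numeric(step)
        wts_new <- nn_unpack(w_new, p, h)
        sse_new <- sum((ytr - nn_forward(Xtr, wts_new)$yhat)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          w <- w_new; wts <- wts_new; sse <- sse_new
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
        } else {
          mu <- mu * 10
        }
      } else {
        mu <- mu * 10
      }
      if (mu > stop_rules$mu_max) break
    }
    if (!accepted) { stop_reason <- "mu_max"; break }

    val_mse <- mean((yval - nn_forward(Xval, wts)$yhat)^2)
    if (val_mse < best_val) {
      best_val <- val_mse; best_w <- w; val_fails <- 0L
    } else {
      val_fails <- val_fails + 1L
      if (val_fails >= stop_rules$val_fail_limit) {
        stop_reason <- "val_fail"; break
      }
    }
    if (sse / length(ytr) <= stop_rules$mse_goal) {
      best_val <- val_mse; best_w <- w
      stop_reason <- "mse_goal"; break
    }
  }
  if (is.finite(best_val)) w <- best_w
  structure(list(weights = w, p = p, hidden = h, stop_reason = stop_reason),
            class = "nn_lm")
}

#' @export
predict.nn_lm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nn_forward(X, nn_unpack(object$weights, object$p, object$hidden))$yhat
}

# ---- unified regressor interface -------------------------------------------

#' Train a drift-correction regressor on normalized data
#'
#' @param spec a [regression_spec()].
#' @param X n-by-p matrix of normalized predictors (joint angle, optionally
#'   joint angular velocity), in `[-1, 1]`.
#' @param y normalized reference joint angle, length n.
#' @return a fitted model of class `joint_regressor` with a `predict`
#'   method.
#' @export
train_regressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "regression_spec"))
  X <- as.matrix(X)
  if (nrow(X) == 0L || length(y) != nrow(X)) {
    stop("empty data or predictor/target shape mismatch", call. = FALSE)
  }
  fit <- switch(spec$kind,
    nn = nn_lm_fit(X, y, hidden = spec$nn_hidden,
                   stop_rules = spec$nn_stop, seed = spec$seed),
    tree = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("V", seq_len(ncol(df)))
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     minbucket = spec$tree_min_leaf,
                     minsplit = spec$tree_min_branch,
                     cp = 0, xval = 0, maxsurrogate = 0, maxcompete = 0))
    },
    svm = {
      kern <- switch(spec$svm_kernel,
                     linear = list(kernel = "linear"),
                     quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1),
                     cubic = list(kernel = "polynomial", degree = 3, coef0 = 1),
                     gaussian = list(kernel = "radial",
                                     gamma = 1 / (2 * spec$svm_sigma^2)))
      do.call(e1071::svm, c(list(x = X, y = y, type = "eps-regression",
                                 cost = spec$svm_C, epsilon = spec$svm_eps,
                                 scale = FALSE), kern))
    })
  structure(list(spec = spec, fit = fit, p = ncol(X)),
            class = "joint_regressor")
}

#' @export
predict.joint_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) {
    stop("predictor count differs from training", call. = FALSE)
  }
  if (object$spec$kind == "tree") {
    df <- as.data.frame(X)
    colnames(df) <- paste0("V", seq_len(ncol(df)))
    as.numeric(stats::predict(object$fit, df))
  } else {
    as.numeric(stats::predict(object$fit, X))
  }
}

#' k-fold cross-validation of a drift-correction regressor
#'
#' Folds are contiguous by subject when subject labels are supplied (so the
#' fitted models are user-independent: every test subject is unseen during
#' training); otherwise samples are assigned to folds at random under the
#' spec's seed. Normalization is fitted on each training split only.
#' Reports per-fold and mean NRMSE (RMSE over the test fold divided by the
#' test-fold reference range) and the coefficient of determination R^2.
#'
#' @param spec a [regression_spec()].
#' @param X predictor matrix in original units.
#' @param y reference target, original units.
#' @param folds number of folds (default 5).
#' @param subjects optional subject label per row.
#' @return a `cv_report`: list with `fold_nrmse`, `fold_r2`, `mean_nrmse`,
#'   `mean_r2`, `folds`.
#' @export
cross_validate <- function(spec, X, y, folds = 5L, subjects = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("fewer observations than folds", call. = FALSE)
  if (!is.null(subjects)) {
    if (length(subjects) != n) stop("subject labels length mismatch", call. = FALSE)
    subj <- unique(subjects)
    fold_of_subj <- rep(seq_len(folds), length.out = length(subj))
    fold_id <- fold_of_subj[match(subjects, subj)]
  } else {
    set.seed(spec$seed)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
  }

  fold_nrmse <- numeric(folds)
  fold_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    nx <- minmax_fit(X[!te, , drop = FALSE])
    ny <- minmax_fit(y[!te])
    model <- train_regressor(spec,
                             minmax_transform(X[!te, , drop = FALSE], nx),
                             as.numeric(minmax_transform(y[!te], ny)))
    pred <- minmax_inverse(predict(model, minmax_transform(X[te, , drop = FALSE], nx)), ny)
    res <- y[te] - as.numeric(pred)
    rng <- diff(range(y[te]))
    fold_nrmse[f] <- sqrt(mean(res^2)) / rng
    fold_r2[f] <- 1 - sum(res^2) / sum((y[te] - mean(y[te]))^2)
  }
  structure(list(fold_nrmse = fold_nrmse, fold_r2 = fold_r2,
                 mean_nrmse = mean(fold_nrmse), mean_r2 = mean(fold_r2),
                 folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold: mean NRMSE %.4f, mean R^2 %.4f\n",
              x$folds, x$mean_nrmse, x$mean_r2))
  invisible(x)
}

#' Fit a drift-correction model for one joint
#'
#' Convenience wrapper: min-max normalizes the predictors (angle, and
#' optionally angular velocity) and the reference target into `[-1, 1]`,
#' trains the requested regressor, and stores the normalization states so
#' the model can be applied to new series in original units.
#'
#' @param angle fusion-derived joint angle series, deg.
#' @param ref reference joint angle series, deg (training target).
#' @param velocity optional joint angular velocity series, deg/s.
#' @param spec a [regression_spec()].
#' @return an object of class `drift_model`.
#' @export
fit_drift_model <- function(angle, ref, velocity = NULL,
                            spec = regression_spec("nn")) {
  X <- if (is.null(velocity)) cbind(angle = angle) else
    cbind(angle = angle, velocity = velocity)
  if (length(ref) != nrow(X)) stop("reference length mismatch", call. = FALSE)
  nx <- minmax_fit(X)
  ny <- minmax_fit(ref)
  model <- train_regressor(spec, minmax_transform(X, nx),
                           as.numeric(minmax_transform(ref, ny)))
  structure(list(model = model, norm_x = nx, norm_y = ny,
                 uses_velocity = !is.null(velocity)),
            class = "drift_model")
}

#' Apply a drift-correction model to a joint angle series
#'
#' Normalizes the inputs with the stored training normalization, predicts
#' the reference angle, and maps the prediction back to degrees. An empty
#' series returns an empty series.
#'
#' @param model a [fit_drift_model()] result.
#' @param angle joint angle series, deg.
#' @param velocity joint angular velocity, deg/s; required when the model
#'   was trained with a velocity input.
#' @return corrected joint angle series, deg, same length as `angle`.
#' @export
apply_correction <- function(model, angle, velocity = NULL) {
  stopifnot(inherits(model, "drift_model"))
  if (length(angle) == 0L) return(numeric(0))
  if (model$uses_velocity && is.null(velocity)) {
    stop("model was trained with a velocity input; supply 'velocity'",
         call. = FALSE)
  }
  X <- if (model$uses_velocity) cbind(angle = angle, velocity = velocity) else
    cbind(angle = angle)
  pred <- predict(model$model, minmax_transform(X, model$norm_x))
  as.numeric(minmax_inverse(pred, model$norm_y))
}
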