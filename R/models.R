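# QSAR model fitting on stepwise-selected, autoscaled descriptors, plus
# the paper-style validation suite: LOO Q2/PRESS, k-fold Q2, train/test
# R2 as squared Pearson correlation, SD and regression F.

#' Descending-activity train/test split
#'
#' Sorts peptides by activity in descending order (ties broken by
#' sequence, lexicographically) and sends every third record -- 1-based
#' ranks 1, 4, 7, ... -- to the test set; the rest form the training set.
#' On 91 records this yields 60 training and 31 test peptides.
#'
#' @param peptides Data frame with `sequence` and `activity` columns.
#' @return List with `train` and `test` data frames (each with `subset`
#'   filled in) and `all`, the full sorted table with labels.
#' @export
split_train_test <- function(peptides) {
  stopifnot(is.data.frame(peptides),
            all(c("sequence", "activity") %in% names(peptides)))
  if (anyNA(peptides$activity)) stop("all activities must be present to split")
  if (anyDuplicated(peptides$sequence)) stop("duplicate sequences in peptide table")
  if (nrow(peptides) < 3L) {
    warning("fewer than 3 records: all assigned to training set")
    peptides$subset <- "train"
    return(list(train = peptides, test = peptides[0, ], all = peptides))
  }
  ord <- order(-peptides$activity, peptides$sequence)
  sorted <- peptides[ord, , drop = FALSE]
  rank <- seq_len(nrow(sorted))
  sorted$subset <- ifelse((rank - 1L) %% 3L == 0L, "test", "train")
  rownames(sorted) <- NULL
  list(train = sorted[sorted$subset == "train", , drop = FALSE],
       test = sorted[sorted$subset == "test", , drop = FALSE],
       all = sorted)
}

new_qsar_model <- function(method, variables, coefficients = NULL,
                           hyperparameters = list(), scaling = NULL,
                           seed = NULL, fit = NULL, fitted_scaled = NULL) {
  structure(
    list(method = method, variables = variables,
         coefficients = coefficients, hyperparameters = hyperparameters,
         scaling = scaling, seed = seed, fit = fit,
         fitted_scaled = fitted_scaled, metrics = NULL),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model (%s), %d variable(s)\n", x$method, length(x$variables)))
  if (!is.null(x$coefficients)) {
    print(round(x$coefficients, 4))
  }
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("R2_train %.3f  SD %.3f  F %.2f  Q2_LOO %.3f  PRESS %.3f\n",
                m$R2_train, m$SD, m$F, m$Q2_loo, m$PRESS))
    if (!is.null(m$R2_test)) cat(sprintf("R2_test %.3f (n = %d)\n", m$R2_test, m$n_test))
  }
  invisible(x)
}

check_fit_inputs <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("response has zero variance")
  X
}

#' Fit multiple linear regression on standardized variables
#'
#' Ordinary least squares on autoscaled predictors and response. Because
#' both sides are centered, the intercept is zero by construction and the
#' stored coefficients are normalized regression coefficients.
#'
#' @param X Autoscaled predictor matrix restricted to selected variables.
#' @param y Autoscaled response.
#' @param scaling Optional `scaling_params` from [autoscale()]; when
#'   present, [predict.qsar_model()] accepts raw descriptor rows and
#'   returns activities in original units.
#' @return A `qsar_model` of method `"MLR"`.
#' @export
fit_mlr <- function(X, y, scaling = NULL) {
  X <- check_fit_inputs(X, y)
  if (nrow(X) <= ncol(X) + 1L) stop("MLR needs rows > variables + 1")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design; collinear variables: ", paste(dep, collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% coef)
  new_qsar_model("MLR", colnames(X), coefficients = coef,
                 scaling = scaling, fitted_scaled = fitted)
}

# NIPALS PLS1: orthogonal scores on (internally centered) X, collapsed
# regression vector B = W (P'W)^-1 q.
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- as.vector(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- as.vector(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - t * q
    W[, a] <- w; P[, a] <- pvec; qv[a] <- q
    used <- a
  }
  if (used == 0L) stop("PLS: response uncorrelated with predictors")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  B <- as.vector(W %*% solve(crossprod(P, W), qv))
  names(B) <- colnames(X)
  list(coef = B, intercept = ybar - sum(xbar * B), ncomp = used)
}

#' Fit partial least squares regression (NIPALS)
#'
#' PLS1 regression with orthogonal score deflation. When `ncomp` is not
#' supplied it is chosen by maximizing leave-one-out Q2 over 1 to
#' `ncol(X)` components. With as many components as (full-rank)
#' variables, the collapsed coefficients equal the OLS solution.
#'
#' @inheritParams fit_mlr
#' @param ncomp Number of latent components, or NULL to select by LOO Q2.
#' @return A `qsar_model` of method `"PLS"` with collapsed per-variable
#'   coefficients; `hyperparameters$ncomp` records the component count.
#' @export
fit_pls <- function(X, y, ncomp = NULL, scaling = NULL) {
  X <- check_fit_inputs(X, y)
  if (!is.null(ncomp) && (ncomp < 1L || ncomp > ncol(X))) {
    stop("ncomp must be between 1 and the number of variables")
  }
  if (is.null(ncomp)) {
    n <- nrow(X)
    sst <- sum((y - mean(y))^2)
    press_by_a <- vapply(seq_len(ncol(X)), function(a) {
      pe <- vapply(seq_len(n), function(i) {
        f <- tryCatch(nipals_pls(X[-i, , drop = FALSE], y[-i], a),
                      error = function(e) NULL)
        if (is.null(f)) return(NA_real_)
        y[i] - (sum(X[i, ] * f$coef) + f$intercept)
      }, 0)
      sum(pe^2)
    }, 0)
    ncomp <- which.max(1 - press_by_a / sst)
  }
  f <- nipals_pls(X, y, ncomp)
  fitted <- as.vector(X %*% f$coef) + f$intercept
  m <- new_qsar_model("PLS", colnames(X), coefficients = f$coef,
                      hyperparameters = list(ncomp = f$ncomp,
                                             intercept = f$intercept),
                      scaling = scaling, fitted_scaled = fitted)
  m
}

#' Fit epsilon support vector regression with an RBF kernel
#'
#' Hyperparameters (cost, gamma, epsilon) are chosen by grid search
#' maximizing Q2 on seeded internal cross-validation folds, then the
#' model is refit on all rows.
#'
#' @inheritParams fit_mlr
#' @param seed Integer seed for fold construction.
#' @param cost,gamma,epsilon Grid values searched.
#' @param nfold Internal folds for the grid search (default 5).
#' @return A `qsar_model` of method `"SVR"` (no coefficients).
#' @export
fit_svr <- function(X, y, seed = 1L, scaling = NULL,
                    cost = c(0.1, 1, 10, 100), gamma = c(0.01, 0.1, 1),
                    epsilon = c(0.01, 0.1), nfold = 5L) {
  X <- check_fit_inputs(X, y)
  grid <- expand.grid(cost = cost, gamma = gamma, epsilon = epsilon)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfold), n))
  sst <- sum((y - mean(y))^2)
  q2 <- vapply(seq_len(nrow(grid)), function(g) {
    pe <- numeric(n)
    for (k in seq_len(nfold)) {
      idx <- fold == k
      fit <- e1071::svm(X[!idx, , drop = FALSE], y[!idx], type = "eps-regression",
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], epsilon = grid$epsilon[g],
                        scale = FALSE)
      pe[idx] <- y[idx] - stats::predict(fit, X[idx, , drop = FALSE])
    }
    1 - sum(pe^2) / sst
  }, 0)
  best <- grid[which.max(q2), ]
  hyper <- list(cost = best$cost, gamma = best$gamma, epsilon = best$epsilon,
                kernel = "radial", cv_q2 = max(q2))
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = hyper$cost, gamma = hyper$gamma,
                    epsilon = hyper$epsilon, scale = FALSE)
  new_qsar_model("SVR", colnames(X), hyperparameters = hyper,
                 scaling = scaling, seed = seed, fit = fit,
                 fitted_scaled = as.vector(stats::predict(fit, X)))
}

#' Fit a random forest regression model
#'
#' @inheritParams fit_svr
#' @param ntree Number of trees (default 500).
#' @return A `qsar_model` of method `"RF"` (no coefficients).
#' @export
fit_rf <- function(X, y, seed = 1L, scaling = NULL, ntree = 500L) {
  X <- check_fit_inputs(X, y)
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = ntree)
  new_qsar_model("RF", colnames(X),
                 hyperparameters = list(ntree = ntree),
                 scaling = scaling, seed = seed, fit = fit,
                 fitted_scaled = as.vector(stats::predict(fit, X)))
}

# Predict on the scaled (model-internal) space.
predict_scaled <- function(object, Xs) {
  vars <- object$variables %||% names(object$coefficients)
  Xs <- as.matrix(Xs)[, vars, drop = FALSE]
  switch(object$method,
    MLR = as.vector(Xs %*% object$coefficients),
    PLS = as.vector(Xs %*% object$coefficients) +
      object$hyperparameters$intercept,
    SVR = as.vector(stats::predict(object$fit, Xs)),
    RF  = as.vector(stats::predict(object$fit, Xs)),
    stop("unknown method: ", object$method)
  )
}

#' Predict activities for new descriptor rows
#'
#' When the model carries scaling parameters, `newdata` is a raw
#' descriptor matrix (as from [encode_peptides()]); it is scaled with the
#' stored parameters and predictions are returned on the original
#' activity scale. Without scaling, `newdata` is assumed already scaled
#' and predictions stay on the standardized scale.
#'
#' @param object A `qsar_model`.
#' @param newdata Descriptor matrix containing the model's variables.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (!is.null(object$scaling)) {
    Xs <- apply_scaling(newdata, object$scaling)
    z <- predict_scaled(object, Xs)
    if (!is.null(object$scaling$y_center)) {
      return(unscale_response(z, object$scaling))
    }
    return(z)
  }
  predict_scaled(object, as.matrix(newdata))
}

# Refit a model with the same method and (already chosen) hyperparameters
# on a row subset of scaled data; used by the cross-validation loops so
# hyperparameter tuning is not repeated per fold.
refit_scaled <- function(model, Xs, ys) {
  switch(model$method,
    MLR = fit_mlr(Xs, ys),
    PLS = fit_pls(Xs, ys, ncomp = min(model$hyperparameters$ncomp,
                                      ncol(Xs), nrow(Xs) - 1L)),
    SVR = {
      h <- model$hyperparameters
      fit <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
                        cost = h$cost, gamma = h$gamma, epsilon = h$epsilon,
                        scale = FALSE)
      new_qsar_model("SVR", colnames(Xs), hyperparameters = h, fit = fit)
    },
    RF = {
      set.seed(model$seed %||% 1L)
      fit <- randomForest::randomForest(Xs, ys,
                                        ntree = model$hyperparameters$ntree)
      new_qsar_model("RF", colnames(Xs),
                     hyperparameters = model$hyperparameters, fit = fit)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map inputs to the model's scaled space (identity when no scaling).
to_scaled <- function(model, X, y = NULL) {
  if (is.null(model$scaling)) {
    list(X = as.matrix(X)[, model$variables, drop = FALSE], y = y)
  } else {
    ys <- if (is.null(y) || is.null(model$scaling$y_center)) y else
      (y - model$scaling$y_center) / model$scaling$y_scale
    list(X = apply_scaling(X, model$scaling)[, model$variables, drop = FALSE],
         y = ys)
  }
}

from_scaled_y <- function(model, z) {
  if (!is.null(model$scaling) && !is.null(model$scaling$y_center)) {
    unscale_response(z, model$scaling)
  } else z
}

cv_press <- function(model, X, y, fold) {
  sc <- to_scaled(model, X, y)
  pred <- numeric(length(y))
  for (k in unique(fold)) {
    idx <- fold == k
    refit <- refit_scaled(model, sc$X[!idx, , drop = FALSE], sc$y[!idx])
    pred[idx] <- predict_scaled(refit, sc$X[idx, , drop = FALSE])
  }
  pred_raw <- from_scaled_y(model, pred)
  press <- sum((y - pred_raw)^2)
  list(press = press, predictions = pred_raw)
}

#' Leave-one-out cross-validation Q2 and PRESS
#'
#' Each row is held out in turn, the model refit (same method and
#' hyperparameters) on the remainder and the held-out activity predicted.
#' PRESS is the sum of squared prediction errors and
#' Q2 = 1 - PRESS / SS_total with SS_total about the full-sample mean.
#' All quantities are on the original activity scale.
#'
#' @param model A fitted `qsar_model` (its hyperparameters are reused).
#' @param X Descriptor matrix of the training rows (raw scale when the
#'   model has scaling, otherwise scaled).
#' @param y Observed activities for those rows.
#' @return List with `q2` and `press`.
#' @export
loo_q2 <- function(model, X, y) {
  n <- length(y)
  stopifnot(n >= 3L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero total sum of squares")
  cv <- cv_press(model, X, y, seq_len(n))
  list(q2 = 1 - cv$press / sst, press = cv$press)
}

#' k-fold cross-validation Q2
#'
#' Rows are shuffled with `seed` and partitioned into k near-equal folds;
#' Q2 = 1 - sum of held-out squared errors / SS_total.
#'
#' @inheritParams loo_q2
#' @param k Number of folds (2 to `nrow(X)`); `k = nrow(X)` reproduces
#'   leave-one-out.
#' @param seed Integer seed for the fold shuffle.
#' @return List with `q2`, `press`, `k` and `seed`.
#' @export
kfold_q2 <- function(model, X, y, k, seed = 1L) {
  n <- length(y)
  stopifnot(k >= 2L, k <= n)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero total sum of squares")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  cv <- cv_press(model, X, y, fold)
  list(q2 = 1 - cv$press / sst, press = cv$press, k = k, seed = as.integer(seed))
}

#' Regression F statistic from R-squared
#'
#' F = (R^2 / m) / ((1 - R^2) / (n - m - 1)) for n observations and m
#' predictors.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param m Number of predictor variables.
#' @return The F statistic (Inf when `r2` is 1).
#' @export
f_statistic <- function(r2, n, m) {
  stopifnot(r2 >= 0, r2 <= 1, n > m + 1)
  if (r2 == 1) return(Inf)
  (r2 / m) / ((1 - r2) / (n - m - 1))
}

#' Full metric bundle for a fitted model
#'
#' Computes the training-set statistics (R2 as squared Pearson
#' correlation of fitted vs observed, residual SD, regression F), the
#' leave-one-out PRESS and Q2, k-fold Q2 for each requested k, and the
#' test-set R2 when a test set is supplied. The result is also stored in
#' `model$metrics` of the returned model.
#'
#' @param model Fitted `qsar_model`.
#' @param X_train,y_train Training descriptors and activities (raw scale
#'   when the model has scaling).
#' @param X_test,y_test Optional held-out set.
#' @param ks Fold counts for k-fold validation (default 4, 6, 10).
#' @param seed Seed for fold shuffles.
#' @return The model with a `metrics` list: `n`, `m`, `R2_train`, `SD`,
#'   `F`, `Q2_loo`, `Q2_kfold` (named by k), `PRESS`, `n_test`,
#'   `R2_test`.
#' @export
model_metrics <- function(model, X_train, y_train, X_test = NULL,
                          y_test = NULL, ks = c(4, 6, 10), seed = 1L) {
  n <- length(y_train)
  m <- length(model$variables)
  fitted_raw <- stats::predict(model, X_train)
  r2_train <- stats::cor(fitted_raw, y_train)^2
  rss <- sum((y_train - fitted_raw)^2)
  sd_res <- if (n - m - 1 > 0) sqrt(rss / (n - m - 1)) else NA_real_
  fstat <- f_statistic(min(r2_train, 1), n, m)
  loo <- loo_q2(model, X_train, y_train)
  q2k <- vapply(ks, function(k) kfold_q2(model, X_train, y_train, k, seed)$q2, 0)
  names(q2k) <- paste0("k", ks)
  metrics <- list(n = n, m = m, R2_train = r2_train, SD = sd_res, F = fstat,
                  Q2_loo = loo$q2, Q2_kfold = q2k, PRESS = loo$press,
                  n_test = NULL, R2_test = NULL)
  if (!is.null(X_test) && !is.null(y_test) && length(y_test) > 0L) {
    pred_test <- stats::predict(model, X_test)
    metrics$n_test <- length(y_test)
    metrics$R2_test <- stats::cor(pred_test, y_test)^2
  }
  model$metrics <- metrics
  model
}
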