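#' Build a sliding-window dataset for sequence forecasting
#'
#' Converts a multichannel feature frame and a target series into
#' paired (input-window, target-window) tensors. Feature and target
#' window lengths may differ; every target window starts exactly one
#' step after its input window ends. Windows are emitted in sliding
#' (chronological) order.
#'
#' @param features a `tcf` or numeric matrix (time x channels).
#' @param target numeric target series, same length as the feature
#'   rows.
#' @param in_len input window length (steps).
#' @param horizon target window length (steps).
#' @param stride step between consecutive window starts.
#' @return a `window_dataset`: list with `X` (n x in_len x channels
#'   array), `Y` (n x horizon), `starts`, `order = "sliding"`.
#' @export
make_windows <- function(features, target, in_len, horizon, stride = 1L) {
  M <- if (inherits(features, "tcf")) as.matrix(features$channels)
  else as.matrix(features)
  if (nrow(M) != length(target)) stop("feature/target lengths differ")
  if (in_len < 1 || horizon < 1 || stride < 1)
    stop("in_len, horizon and stride must be >= 1")
  n <- nrow(M)
  if (n < in_len + horizon)
    stop("series shorter than in_len + horizon")
  starts <- seq(1L, n - in_len - horizon + 1L, by = stride)
  X <- array(NA_real_, c(length(starts), in_len, ncol(M)),
             dimnames = list(NULL, NULL, colnames(M)))
  Y <- matrix(NA_real_, length(starts), horizon)
  for (i in seq_along(starts)) {
    s <- starts[i]
    X[i, , ] <- M[s:(s + in_len - 1L), , drop = FALSE]
    Y[i, ] <- target[(s + in_len):(s + in_len + horizon - 1L)]
  }
  structure(list(X = X, Y = Y, starts = starts, in_len = in_len,
                 horizon = horizon, stride = stride, order = "sliding",
                 seed = NULL),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset: %d windows (%s order), in %d x %d channels, horizon %d>\n",
              nrow(x$Y), x$order, x$in_len, dim(x$X)[3], x$horizon))
  invisible(x)
}

#' Shuffle the window order of a dataset
#'
#' Randomised training order (same windows, permuted), the alternative
#' to strict sliding order. Seeded and reproducible; the window
#' multiset is preserved.
#'
#' @param ds a sliding-ordered `window_dataset`.
#' @param seed RNG seed for the permutation.
#' @return the permuted dataset with `order = "shuffled"`.
#' @export
shuffle_windows <- function(ds, seed = 1L) {
  if (!inherits(ds, "window_dataset")) stop("not a window_dataset")
  perm <- with_seed(seed, sample.int(nrow(ds$Y)))
  ds$X <- ds$X[perm, , , drop = FALSE]
  ds$Y <- ds$Y[perm, , drop = FALSE]
  ds$starts <- ds$starts[perm]
  ds$order <- "shuffled"
  ds$seed <- as.integer(seed)
  ds
}

#' Root mean square error
#' @param pred,truth numeric vectors/matrices of equal shape.
#' @export
rmse <- function(pred, truth) sqrt(mean((as.numeric(pred) -
                                           as.numeric(truth))^2))

#' Coefficient of determination
#' @param pred,truth numeric vectors of equal length.
#' @export
r_squared <- function(pred, truth) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

# --- estimator contract -----------------------------------------------------
# An estimator_spec is a list(fit = function(X, Y) -> model,
#                             predict = function(model, X) -> matrix,
#                             importances = optional function(model)).
# X is n x p (flattened windows or tabular rows), Y is n x h.

#' Linear least-squares sequence estimator
#'
#' Deterministic multi-output linear regression on flattened input
#' windows: the bundled baseline estimator for the forecasting
#' harness (the recurrent network of the original application is
#' pluggable behind the same contract).
#' @return an estimator spec (list with `fit`/`predict`).
#' @export
estimator_linear <- function() {
  list(
    fit = function(X, Y) {
      Xd <- cbind(1, X)
      ## ridge-stabilised normal equations: exact for full-rank designs
      A <- crossprod(Xd) + diag(1e-8, ncol(Xd))
      list(B = solve(A, crossprod(Xd, Y)))
    },
    predict = function(model, X) cbind(1, X) %*% model$B,
    importances = function(model) rowSums(abs(model$B[-1, , drop = FALSE]))
  )
}

#' Sequential gradient-descent linear estimator
#'
#' A single-pass stochastic-gradient linear learner whose result
#' depends on the order in which training windows are presented -
#' the property that makes randomised window order outperform strict
#' sliding order for sequence learners trained incrementally.
#'
#' @param lr learning rate.
#' @param epochs passes over the training windows.
#' @return an estimator spec.
#' @export
estimator_sgd_linear <- function(lr = 0.05, epochs = 2L) {
  list(
    fit = function(X, Y) {
      p <- ncol(X) + 1L
      B <- matrix(0, p, ncol(Y))
      for (e in seq_len(epochs)) {
        for (i in seq_len(nrow(X))) {
          xi <- c(1, X[i, ])
          err <- drop(xi %*% B) - Y[i, ]
          B <- B - lr * outer(xi, err) / p
        }
      }
      list(B = B)
    },
    predict = function(model, X) cbind(1, X) %*% model$B
  )
}

#' Gradient-boosted tree estimator (per-horizon-step)
#'
#' Wraps xgboost regression behind the estimator contract (one booster
#' per target column); used for the tabular soft-sensor task.
#' @param nrounds,max_depth,learning_rate xgboost hyper-parameters.
#' @return an estimator spec.
#' @export
estimator_xgboost <- function(nrounds = 150, max_depth = 4,
                              learning_rate = 0.2) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the xgboost package is required for this estimator")
  list(
    fit = function(X, Y) {
      lapply(seq_len(ncol(Y)), function(j)
        xgboost::xgboost(x = X, y = Y[, j], nrounds = nrounds,
                         max_depth = max_depth,
                         learning_rate = learning_rate, nthreads = 1,
                         verbosity = 0, seed = 1L,
                         objective = "reg:squarederror"))
    },
    predict = function(model, X)
      vapply(model, function(m) stats::predict(m, X), numeric(nrow(X))),
    importances = function(model) {
      imp <- xgboost::xgb.importance(model = model[[1]])
      stats::setNames(imp$Gain, imp$Feature)
    }
  )
}

.flatten_windows <- function(ds, idx) {
  X <- ds$X[idx, , , drop = FALSE]
  dim(X) <- c(length(idx), ds$in_len * dim(ds$X)[3])
  X
}

## per-column min-max scaling fitted on the training span only
.fit_scaler <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- ifelse(hi - lo > 0, hi - lo, 1)
  list(lo = lo, rng = rng)
}
.apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$lo), 2, sc$rng, "/")

#' Train and evaluate a windowed multivariate forecaster
#'
#' Trains an estimator on the first `eval_split` fraction of windows in
#' the dataset's own order (sliding or shuffled) and forecasts the
#' remaining held-out windows. Inputs are min-max scaled with
#' parameters fitted on the training windows only.
#'
#' @param ds a `window_dataset`.
#' @param model_spec an estimator spec (see [estimator_linear()]).
#' @param eval_split fraction of windows used for training.
#' @return a `forecast_result`: list with `predictions`, `truth`,
#'   `rmse`, `horizon`, `train_span` (number of training windows).
#' @export
multivariate_forecast <- function(ds, model_spec = estimator_linear(),
                                  eval_split = 0.8) {
  if (!is.list(model_spec) || !is.function(model_spec$fit) ||
      !is.function(model_spec$predict))
    stop("model_spec does not implement the fit/predict contract")
  n <- nrow(ds$Y)
  n_train <- max(1L, floor(eval_split * n))
  if (n_train >= n) stop("no held-out windows left for evaluation")
  tr <- seq_len(n_train); te <- (n_train + 1L):n
  Xtr <- .flatten_windows(ds, tr); Xte <- .flatten_windows(ds, te)
  sc <- .fit_scaler(Xtr)
  model <- model_spec$fit(.apply_scaler(Xtr, sc), ds$Y[tr, , drop = FALSE])
  pred <- model_spec$predict(model, .apply_scaler(Xte, sc))
  truth <- ds$Y[te, , drop = FALSE]
  structure(list(predictions = pred, truth = truth,
                 rmse = rmse(pred, truth), r_squared = NA_real_,
                 horizon = ds$horizon, train_span = n_train,
                 order = ds$order),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result: RMSE %.4g over horizon %d (%s)>\n",
              x$rmse, x$horizon,
              if (is.na(x$r_squared)) sprintf("train span %d", x$train_span)
              else sprintf("R^2 %.3f", x$r_squared)))
  invisible(x)
}

#' Fit a tabular soft sensor for MRI/PTI
#'
#' Chronological split at `train_fraction`, estimator fitted on the
#' early rows; reports the coefficient of determination on the
#' training rows and the RMSE on the held-out later rows, plus native
#' feature importances when the estimator provides them.
#'
#' @param features a `tcf` or numeric matrix of predictor rows.
#' @param target numeric target series.
#' @param train_fraction fraction in (0, 1); 0.25/0.5/0.75 mirror the
#'   studied training-set sizes.
#' @param estimator_spec estimator contract (default
#'   [estimator_xgboost()] when available, else linear).
#' @return list with `model`, `result` (a `forecast_result` with
#'   `r_squared`), and `importances` (or `NULL`).
#' @export
soft_sensor_fit <- function(features, target, train_fraction = 0.75,
                            estimator_spec = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  if (is.null(estimator_spec)) {
    estimator_spec <- if (requireNamespace("xgboost", quietly = TRUE))
      estimator_xgboost() else estimator_linear()
  }
  M <- if (inherits(features, "tcf")) as.matrix(features$channels)
  else as.matrix(features)
  ok <- stats::complete.cases(M, target)
  M <- M[ok, , drop = FALSE]; target <- target[ok]
  n <- nrow(M)
  n_train <- floor(train_fraction * n)
  tr <- seq_len(n_train); te <- (n_train + 1L):n
  sc <- .fit_scaler(M[tr, , drop = FALSE])
  model <- estimator_spec$fit(.apply_scaler(M[tr, , drop = FALSE], sc),
                              matrix(target[tr], ncol = 1))
  pred_tr <- estimator_spec$predict(model,
                                    .apply_scaler(M[tr, , drop = FALSE], sc))
  pred_te <- estimator_spec$predict(model,
                                    .apply_scaler(M[te, , drop = FALSE], sc))
  res <- structure(list(predictions = pred_te, truth = target[te],
                        rmse = rmse(pred_te, target[te]),
                        r_squared = r_squared(pred_tr, target[tr]),
                        horizon = 1L, train_span = n_train,
                        order = "chronological"),
                   class = "forecast_result")
  imp <- if (is.function(estimator_spec$importances))
    tryCatch(estimator_spec$importances(model), error = function(e) NULL)
  list(model = model, result = res, importances = imp)
}

#' Univariate ARIMA forecast of a probe signal
#'
#' Fits an automatically order-selected ARIMA on a training hour of
#' data and forecasts the following hour, reporting RMSE against the
#' realised values.
#'
#' @param series numeric minutely series covering at least
#'   `train_minutes + horizon_minutes` samples; the first
#'   `train_minutes` are the training span.
#' @param train_minutes,horizon_minutes spans in minutes (samples).
#' @param max_order ARIMA order bound.
#' @return a `forecast_result`.
#' @export
univariate_forecast <- function(series, train_minutes = 60,
                                horizon_minutes = 60,
                                max_order = c(3, 2, 3)) {
  if (length(series) < train_minutes + horizon_minutes)
    stop("series shorter than training span plus horizon")
  tr <- series[seq_len(train_minutes)]
  truth <- series[(train_minutes + 1L):(train_minutes + horizon_minutes)]
  if (stats::var(tr) < 1e-24) {            # constant training data
    pred <- rep(tr[1], horizon_minutes)
  } else {
    fit <- auto_arima_fit(tr, max_order = max_order)
    pred <- as.numeric(stats::predict(fit$fit,
                                      n.ahead = horizon_minutes)$pred) +
      fit$mean
  }
  structure(list(predictions = pred, truth = truth,
                 rmse = rmse(pred, truth), r_squared = NA_real_,
                 horizon = horizon_minutes, train_span = train_minutes,
                 order = "sliding"),
            class = "forecast_result")
}

#' Expanding-window (stacked) cross-validation of a forecaster
#'
#' Splits the window sequence into `k` chronologically ordered folds:
#' fold i trains on all windows before its validation block, so
#' training always precedes validation in time and no fold leaks
#' future information.
#'
#' @param ds a sliding-ordered `window_dataset`.
#' @param k number of validation folds (>= 2).
#' @param model_spec estimator contract.
#' @return list of per-fold `forecast_result`s, each carrying
#'   `train_idx`/`val_idx` attributes.
#' @export
cross_validate_forecaster <- function(ds, k, model_spec = estimator_linear()) {
  if (k < 2) stop("k must be >= 2")
  n <- nrow(ds$Y)
  bounds <- floor(seq(0, n, length.out = k + 2L))
  if (bounds[2] < 1) stop("k too large for the number of windows")
  lapply(seq_len(k), function(i) {
    tr <- seq_len(bounds[i + 1L])
    va <- (bounds[i + 1L] + 1L):bounds[i + 2L]
    Xtr <- .flatten_windows(ds, tr); Xva <- .flatten_windows(ds, va)
    sc <- .fit_scaler(Xtr)
    model <- model_spec$fit(.apply_scaler(Xtr, sc),
                            ds$Y[tr, , drop = FALSE])
    pred <- model_spec$predict(model, .apply_scaler(Xva, sc))
    res <- structure(list(predictions = pred,
                          truth = ds$Y[va, , drop = FALSE],
                          rmse = rmse(pred, ds$Y[va, , drop = FALSE]),
                          r_squared = NA_real_, horizon = ds$horizon,
                          train_span = length(tr), order = ds$order),
                     class = "forecast_result")
    attr(res, "train_idx") <- tr
    attr(res, "val_idx") <- va
    res
  })
}
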