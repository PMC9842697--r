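#' Automatic ARIMA order selection
#'
#' Small bounded grid search: the differencing order is chosen first by
#' a variance-reduction heuristic (difference while it shrinks the
#' sample variance), then (p, q) by AIC at that order. Orders are
#' bounded for desk-scale runtime; missing values are tolerated (the
#' underlying state-space fit handles them).
#'
#' @param x numeric series (may contain `NA`).
#' @param max_order `c(max_p, max_d, max_q)`.
#' @return list with `fit` (an `Arima` object), `order`, and
#'   `mean` (the subtracted level when d = 0).
#' @export
auto_arima_fit <- function(x, max_order = c(3, 2, 3)) {
  stopifnot(length(max_order) == 3)
  d <- 0L
  v <- stats::var(x, na.rm = TRUE)
  xd <- x
  while (d < max_order[2]) {
    xd2 <- diff(xd)
    v2 <- stats::var(xd2, na.rm = TRUE)
    if (!is.finite(v2) || v2 >= v * 0.95) break
    d <- d + 1L; xd <- xd2; v <- v2
  }
  mu <- if (d == 0L) mean(x, na.rm = TRUE) else 0
  y <- if (d == 0L) x - mu else x
  best <- NULL
  for (p in 0:max_order[1]) for (q in 0:max_order[3]) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(y, order = c(p, d, q),
                                    include.mean = FALSE, method = "ML")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::AIC(fit) < stats::AIC(best$fit))
      best <- list(fit = fit, order = c(p, d, q), mean = mu)
  }
  if (is.null(best))
    stop("no ARIMA model could be fitted to the series")
  best
}

## Fill NA cells by Kalman smoothing on the state-space representation
## of an auto-selected ARIMA fit; falls back to linear interpolation if
## no ARIMA model can be fitted (degenerate series).
.kalman_impute <- function(x, max_order = c(2, 1, 2)) {
  miss <- which(is.na(x))
  fit <- tryCatch(auto_arima_fit(x, max_order = max_order),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    y <- if (fit$order[2] == 0L) x - fit$mean else x
    ks <- stats::KalmanSmooth(y, fit$fit$model, nit = -1)
    z <- as.matrix(fit$fit$model$Z)
    est <- as.numeric(ks$smooth %*% z) + fit$mean
    x[miss] <- est[miss]
    if (!anyNA(x))
      return(list(values = x, method = sprintf("kalman_arima(%d,%d,%d)",
                                               fit$order[1], fit$order[2],
                                               fit$order[3])))
  }
  obs <- which(!is.na(x))
  x[miss] <- stats::approx(obs, x[obs], xout = miss, rule = 2)$y
  list(values = x, method = "linear")
}
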