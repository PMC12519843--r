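#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y_i - \hat y_i)^2 / \sum(y_i - \bar y)^2}. Can be
#' negative for models worse than the mean; equals 1 for a perfect fit.
#'
#' @param observed numeric vector of observed values.
#' @param predicted numeric vector of predictions, same length.
#' @return scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  if (length(observed) < 2L)
    stop("r_squared() needs at least 2 observations", call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("r_squared() is undefined when all observed values are equal",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / tss
}

#' Root mean squared error with the n - 1 denominator
#'
#' Defined here as \eqn{\sqrt{\sum(y_i - \hat y_i)^2 / (n - 1)}}: the
#' denominator is n - 1, not n, matching the convention used throughout the
#' fit-accuracy tables this package reproduces. At n = 2 with unit residuals
#' this gives sqrt(2), which distinguishes it from the 1/n estimator.
#'
#' @inheritParams r_squared
#' @return scalar RMSE in the units of the response (kg here).
#' @export
rmse <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  n <- length(observed)
  if (n < 2L) stop("rmse() needs at least 2 observations", call. = FALSE)
  sqrt(sum((observed - predicted)^2) / (n - 1))
}

#' Total relative error
#'
#' \eqn{TRE = \sum|y_i - \hat y_i| / \sum y_i}: the absolute-deviation form.
#' A signed variant (\eqn{\sum(y_i - \hat y_i)/\sum y_i}) is available via
#' `signed = TRUE` for comparison with the conventional aggregate-bias TRE.
#' Returned as a fraction; multiply by 100 for the percent rendering.
#'
#' @inheritParams r_squared
#' @param signed use the signed (aggregate bias) variant instead of the
#'   absolute-value form. Default `FALSE`.
#' @return scalar fraction.
#' @export
tre <- function(observed, predicted, signed = FALSE) {
  check_obs_pred(observed, predicted)
  tot <- sum(observed)
  if (tot <= 0)
    stop("tre() requires a strictly positive observed total", call. = FALSE)
  if (signed) sum(observed - predicted) / tot
  else sum(abs(observed - predicted)) / tot
}

#' Information criteria for least-squares fits
#'
#' AIC = 2k - 2 ln L and BIC = k ln n - 2 ln L with L the Gaussian maximum
#' likelihood concentrated over the error variance,
#' \eqn{\ln L = -(n/2)(\ln(2\pi \cdot RSS/n) + 1)}. This is the standard
#' likelihood surrogate for nonlinear least squares; k counts mean-function
#' parameters (the concentrated variance is not counted, so AIC differences
#' between forms are unaffected).
#'
#' @param rss residual sum of squares, > 0.
#' @param n number of observations, > k.
#' @param k number of mean-function parameters.
#' @return scalar criterion value.
#' @export
aic_ls <- function(rss, n, k) {
  2 * k - 2 * loglik_ls(rss, n)
}

#' @rdname aic_ls
#' @export
bic_ls <- function(rss, n, k) {
  k * log(n) - 2 * loglik_ls(rss, n)
}

loglik_ls <- function(rss, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (rss <= 0)
    stop("degenerate fit: rss must be > 0 for the Gaussian likelihood ",
         "(an exact fit has unbounded likelihood)", call. = FALSE)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

#' All goodness-of-fit metrics for one model on one dataset
#'
#' @inheritParams r_squared
#' @param k parameter count of the model that produced `predicted` (needed
#'   for AIC/BIC; omit to get NA criteria).
#' @return one-row data.frame: n, k, r2, rmse, tre, aic, bic.
#' @export
fit_metrics <- function(observed, predicted, k = NA_integer_) {
  rss <- sum((observed - predicted)^2)
  n <- length(observed)
  data.frame(
    n = n, k = k,
    r2 = r_squared(observed, predicted),
    rmse = rmse(observed, predicted),
    tre = tre(observed, predicted),
    aic = if (is.na(k) || rss <= 0) NA_real_ else aic_ls(rss, n, k),
    bic = if (is.na(k) || rss <= 0) NA_real_ else bic_ls(rss, n, k)
  )
}

check_obs_pred <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("observed/predicted must not contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Compare fitted models on common train and test data
#'
#' Evaluates each fitted model (any object with a `predict` method taking the
#' tree table, e.g. [fit_base()], [fit_dummy()] results, or an NSUR system
#' restricted to one component) for one biomass component on the same
#' training and test tables, and reports pairwise relative changes in the
#' metrics. Relative change is (new - old)/old * 100 on the metric itself.
#'
#' @param fits named list of fitted models, all predicting the same component.
#' @param train,test tree tables (see [read_tree_csv()] for the schema).
#' @param component which mass column to evaluate (e.g. "trunk").
#' @return data.frame with one row per (model, sample) of metrics; pairwise
#'   percentage changes relative to the first model are attached as attribute
#'   `"changes"`.
#' @export
compare_report <- function(fits, train, test, component) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  col <- paste0("m_", component)
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    k <- n_params(f)
    for (sample in c("train", "test")) {
      dat <- if (sample == "train") train else test
      m <- fit_metrics(dat[[col]], predict(f, dat), k = k)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = nm, component = component, sample = sample), m)
    }
  }
  out <- do.call(rbind, rows)
  ref <- names(fits)[1L]
  chg <- lapply(setdiff(names(fits), ref), function(nm) {
    a <- out[out$model == ref, ]
    b <- out[out$model == nm, ]
    data.frame(model = nm, reference = ref, sample = a$sample,
               d_r2_pct = (b$r2 - a$r2) / a$r2 * 100,
               d_rmse_pct = (b$rmse - a$rmse) / a$rmse * 100,
               d_tre_pct = (b$tre - a$tre) / a$tre * 100)
  })
  attr(out, "changes") <- if (length(chg)) do.call(rbind, chg) else NULL
  out
}

n_params <- function(fit) {
  if (!is.null(fit$params)) sum(!is.na(unlist(fit$params))) else NA_integer_
}
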