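#' Candidate base model forms
#'
#' The four candidate allometric mean functions relating a biomass component
#' BM (kg) to LiDAR tree height LH (m) and LiDAR crown diameter LCD (m),
#' with the sign conventions exactly as published:
#' \describe{
#'   \item{logistic}{BM = a / (1 + b exp(-c LH - d LCD)), 4 parameters}
#'   \item{linear}{BM = a LH + b LCD - c, 3 parameters}
#'   \item{exponential}{BM = a exp(-b LH - c LCD), 3 parameters (fitted b, c
#'     are typically negative, making the effective exponents positive)}
#'   \item{power}{BM = a LH^b LCD^c, 3 parameters}
#' }
#'
#' @return character vector of form names.
#' @export
base_forms <- function() c("logistic", "linear", "exponential", "power")

base_form_spec <- function(form) {
  switch(form,
    logistic = list(
      par_names = c("a", "b", "c", "d"),
      mean = function(p, lh, lcd) p[1] / (1 + p[2] * exp(-p[3] * lh - p[4] * lcd)),
      jac = function(p, lh, lcd) {
        E <- exp(-p[3] * lh - p[4] * lcd)
        den <- 1 + p[2] * E
        cbind(a = 1 / den,
              b = -p[1] * E / den^2,
              c = p[1] * p[2] * E * lh / den^2,
              d = p[1] * p[2] * E * lcd / den^2)
      },
      init = function(y, lh, lcd) {
        a0 <- 1.05 * max(y)
        z <- log(a0 / y - 1)
        co <- coef(lm(z ~ lh + lcd))
        c(a = a0, b = exp(unname(co[1])),
          c = -unname(co[2]), d = -unname(co[3]))
      }),
    linear = list(
      par_names = c("a", "b", "c"),
      mean = function(p, lh, lcd) p[1] * lh + p[2] * lcd - p[3],
      jac = function(p, lh, lcd) cbind(a = lh, b = lcd, c = rep(-1, length(lh))),
      init = function(y, lh, lcd) {
        co <- coef(lm(y ~ lh + lcd))
        c(a = unname(co[2]), b = unname(co[3]), c = -unname(co[1]))
      }),
    exponential = list(
      par_names = c("a", "b", "c"),
      mean = function(p, lh, lcd) p[1] * exp(-p[2] * lh - p[3] * lcd),
      jac = function(p, lh, lcd) {
        E <- exp(-p[2] * lh - p[3] * lcd)
        cbind(a = E, b = -p[1] * E * lh, c = -p[1] * E * lcd)
      },
      init = function(y, lh, lcd) {
        co <- coef(lm(log(y) ~ lh + lcd))
        c(a = exp(unname(co[1])), b = -unname(co[2]), c = -unname(co[3]))
      }),
    power = list(
      par_names = c("a", "b", "c"),
      mean = function(p, lh, lcd) p[1] * lh^p[2] * lcd^p[3],
      jac = function(p, lh, lcd) {
        m <- p[1] * lh^p[2] * lcd^p[3]
        cbind(a = m / p[1], b = m * log(lh), c = m * log(lcd))
      },
      init = function(y, lh, lcd) {
        co <- coef(lm(log(y) ~ log(lh) + log(lcd)))
        c(a = exp(unname(co[1])), b = unname(co[2]), c = unname(co[3]))
      }),
    stop("unknown base form: ", form, call. = FALSE)
  )
}

#' Construct a base model from known parameters
#'
#' Wraps a parameter vector in a `base_fit` object so the package's
#' `predict` method can evaluate it; used for published parameter sets and
#' for simulation truths.
#'
#' @param form one of [base_forms()].
#' @param params named numeric vector matching the form's parameters.
#' @param component the biomass component the model predicts.
#' @return a `base_fit` object (no data, no standard errors).
#' @export
base_model <- function(form, params, component = NA_character_) {
  spec <- base_form_spec(form)
  params <- params[spec$par_names]
  if (anyNA(params))
    stop("params must supply ", paste(spec$par_names, collapse = ", "),
         call. = FALSE)
  structure(list(form = form, component = component,
                 params = setNames(as.numeric(params), spec$par_names),
                 se = NULL, n = NA_integer_, converged = NA,
                 iterations = NA_integer_, rss = NA_real_),
            class = "base_fit")
}

#' Fit one base form to one biomass component
#'
#' Nonlinear least squares by Levenberg-Marquardt with analytic Jacobians
#' and deterministic log-linear (or logit-linear, for the logistic form)
#' starting values. Standard errors come from the Jacobian-based covariance
#' \eqn{\hat\sigma^2 (J'J)^{-1}} evaluated via the SVD, so a rank-deficient
#' Jacobian (non-identifiable parameters) surfaces as huge or infinite SEs
#' rather than an error.
#'
#' @param train tree table with columns `lh`, `lcd` and the component mass.
#' @param form one of [base_forms()].
#' @param component biomass component: bark, trunk, branch, leaf or total.
#' @param start optional named start vector overriding the built-in
#'   initializer.
#' @param variance_power optional lambda for power-of-the-mean variance
#'   weighting, Var(y) proportional to mean^(2*lambda): residuals are
#'   weighted by 1/mean^lambda in a second IRLS stage. `NULL` (default) is
#'   ordinary unweighted least squares, the convention used for the headline
#'   fits; `lambda = 1` matches a constant-CV multiplicative error model and
#'   makes the reported standard errors appropriate under it.
#' @param control a [minpack.lm::nls.lm.control()] list; defaults to maxiter
#'   200, ftol 1e-12, ptol 1e-10.
#' @return a `base_fit`: form, component, `params`, `se`, `n`, `converged`,
#'   `iterations`, `rss`, and `rss_trace` (RSS after each accepted LM
#'   iteration).
#' @export
fit_base <- function(train, form = "power", component = "total",
                     start = NULL, variance_power = NULL, control = NULL) {
  form <- match.arg(form, base_forms())
  col <- paste0("m_", component)
  if (!col %in% names(train))
    stop("component column ", col, " not found", call. = FALSE)
  y <- train[[col]]; lh <- train$lh; lcd <- train$lcd
  if (length(y) == 0L) stop("fit_base(): empty training data", call. = FALSE)
  if (form %in% c("power", "exponential", "logistic") || is.null(start)) {
    bad <- which(lh <= 0 | lcd <= 0)
    if (form == "power" && length(bad))
      stop("fit_base(power): non-positive covariates in rows ",
           paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  spec <- base_form_spec(form)
  if (form %in% c("power", "exponential", "logistic")) {
    if (any(y <= 0))
      stop("fit_base(", form, "): requires strictly positive response for ",
           "the log/logit-linear initializer", call. = FALSE)
  }
  p0 <- if (is.null(start)) spec$init(y, lh, lcd)
        else setNames(as.numeric(start[spec$par_names]), spec$par_names)
  fn <- function(p) spec$mean(p, lh, lcd)
  jacfn <- function(p) spec$jac(p, lh, lcd)
  extra <- list(form = form, component = component)
  fit <- ls_fit(p0, y, fn, jacfn, control = control, extra = extra,
                class = "base_fit")
  if (!is.null(variance_power)) {
    w <- 1 / pmax(fn(fit$params), 1e-12)^variance_power
    fit <- ls_fit(fit$params, y, fn, jacfn, control = control, extra = extra,
                  weights = w, class = "base_fit")
    fit$variance_power <- variance_power
  }
  fit
}

# Shared LM driver: minimises sum(w^2 (y - fn(p))^2) (w = 1 unweighted);
# returns params, SEs from the SVD-based weighted (J'J)^{-1} covariance,
# convergence info and the RSS trace.
ls_fit <- function(p0, y, fn, jacfn, control = NULL, extra = list(),
                   weights = NULL, class = "base_fit") {
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  modifyList(list(maxiter = 200, ftol = 1e-12, ptol = 1e-10),
                             as.list(control %||% list())))
  w <- weights %||% rep(1, length(y))
  out <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) w * (y - fn(p)),
    jac = function(p) -w * jacfn(p),
    control = ctrl)
  p <- setNames(coef(out), names(p0))
  n <- length(y); k <- length(p)
  rss <- sum((y - fn(p))^2)
  J <- w * jacfn(p)
  sv <- svd(J)
  rss_w <- out$deviance   # equals rss when unweighted
  sigma2 <- if (n > k) rss_w / (n - k) else NA_real_
  # 1/s^2 blows up for near-zero singular values: non-identifiability shows
  # up as huge/Inf standard errors instead of a hard failure.
  inv_s2 <- ifelse(sv$d > 0, 1 / sv$d^2, Inf)
  se <- sqrt(sigma2 * rowSums(sweep(sv$v^2, 2L, inv_s2, `*`)))
  structure(c(extra, list(
    params = p,
    se = setNames(se, names(p0)),
    n = n,
    converged = out$info %in% 1:4,
    info = out$info, message = out$message,
    iterations = out$niter,
    rss = rss,
    rss_trace = out$rsstrace,
    vcov = {
      V <- sv$v %*% (inv_s2 * t(sv$v)) * sigma2
      dimnames(V) <- list(names(p0), names(p0)); V
    })), class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.base_fit <- function(object, newdata, ...) {
  spec <- base_form_spec(object$form)
  if (object$form == "power" && any(newdata$lh <= 0 | newdata$lcd <= 0))
    stop("predict: non-positive covariates under the power form",
         call. = FALSE)
  spec$mean(object$params, newdata$lh, newdata$lcd)
}

#' @export
print.base_fit <- function(x, ...) {
  cat("Base allometric model (", x$form, "), component: ", x$component, "\n",
      sep = "")
  print(round(x$params, 6))
  if (!is.null(x$se)) {
    cat("SE:\n"); print(signif(x$se, 4))
  }
  if (!is.na(x$rss))
    cat(sprintf("n = %d, RSS = %.6g, converged = %s (%d iterations)\n",
                x$n, x$rss, x$converged, x$iterations))
  invisible(x)
}

#' Stratified train/test split
#'
#' Partitions a tree table into training and test sets at the given fraction
#' (default 0.7, the 7:3 convention), stratified by age group so every group
#' appears in both partitions. Within each stratum the training count is
#' `round(frac * n)`, so the train share is within one tree of the target.
#' Deterministic given `seed`.
#'
#' @param records tree table (>= 10 rows).
#' @param frac training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @param stratify stratify by `age_group` (default) or split globally.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_records <- function(records, frac = 0.7, seed = 1L, stratify = TRUE) {
  if (nrow(records) < 10L)
    stop("split_records() needs at least 10 records", call. = FALSE)
  if (frac <= 0 || frac >= 1) stop("frac must be in (0,1)", call. = FALSE)
  strata <- if (stratify) records$age_group else rep(1L, nrow(records))
  idx_train <- integer(0)
  local_rng(seed)
  for (g in sort(unique(strata))) {
    idx <- which(strata == g)
    n_tr <- round(frac * length(idx))
    if (n_tr == length(idx) || n_tr == 0L) {
      warning("stratum ", g, " too small to split; placed wholly in train",
              call. = FALSE)
      idx_train <- c(idx_train, idx)
    } else {
      idx_train <- c(idx_train, sort(sample(idx, n_tr)))
    }
  }
  list(train = records[idx_train, , drop = FALSE],
       test = records[setdiff(seq_len(nrow(records)), idx_train), , drop = FALSE])
}

# All stochastic entry points seed explicitly through here; a single integer
# seed fully determines every draw downstream (documented draw order).
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j), with R^2_j from the OLS regression of predictor j
#' on the remaining predictors (with intercept). Exact collinearity gives
#' `Inf`, not an error. Predictors with VIF above 5 are conventionally
#' excluded here.
#'
#' @param records data.frame holding the predictor columns.
#' @param predictors character vector of >= 2 column names.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(records, predictors) {
  if (length(predictors) < 2L)
    stop("compute_vif() needs at least 2 predictors", call. = FALSE)
  X <- as.data.frame(records)[, predictors, drop = FALSE]
  if (nrow(X) <= length(predictors))
    stop("compute_vif() needs n > number of predictors", call. = FALSE)
  vapply(predictors, function(j) {
    # perfect-fit warnings from summary.lm are the collinearity signal we
    # convert to Inf, not a user-facing condition
    fit <- lm(reformulate(setdiff(predictors, j), response = j), data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise predictor selection on the log-linearised power model
#'
#' Forward-backward stepwise selection by AIC on
#' `log(y) ~ log(x1) + log(x2) + ...` (the log-linearisation of the power
#' form), followed by exclusion of predictors with VIF > `vif_cutoff`
#' computed on the log scale (dropping the worst offender iteratively).
#' All candidate columns and the response must be strictly positive.
#'
#' @param records tree table.
#' @param response mass column to model (e.g. `"m_total"`).
#' @param candidates candidate predictor column names (e.g. `c("lh","lcd")`).
#' @param vif_cutoff exclusion threshold, default 5.
#' @return character vector of selected predictor names (possibly empty,
#'   with a warning, when nothing beats the intercept).
#' @export
stepwise_select <- function(records, response, candidates, vif_cutoff = 5) {
  if (length(candidates) == 0L)
    stop("stepwise_select() needs candidates", call. = FALSE)
  dat <- data.frame(.y = log(records[[response]]))
  for (cc in candidates) {
    if (any(records[[cc]] <= 0))
      stop("candidate ", cc, " must be strictly positive for the log-linear ",
           "power screen", call. = FALSE)
    dat[[cc]] <- log(records[[cc]])
  }
  # VIF screen first so stepwise never sees an exactly collinear design
  keep <- candidates
  while (length(keep) >= 2L) {
    v <- compute_vif(dat, keep)
    if (max(v) <= vif_cutoff) break
    keep <- setdiff(keep, names(which.max(v)))
  }
  full <- reformulate(keep, response = ".y")
  scope <- list(lower = .y ~ 1, upper = full)
  fit0 <- lm(.y ~ 1, data = dat)
  sel <- step(fit0, scope = scope, direction = "both", trace = 0)
  chosen <- intersect(keep, attr(terms(sel), "term.labels"))
  if (length(chosen) == 0L)
    warning("no candidate predictor improves on the intercept-only model",
            call. = FALSE)
  chosen
}

#' Rank fitted base forms and select the parsimonious best
#'
#' Orders converged fits by training AIC (computed from each fit's RSS under
#' the Gaussian likelihood). If the top two differ by no more than
#' `delta_aic` (default 2), the form with fewer parameters is selected —
#' near-ties are resolved by parsimony. Non-converged fits are excluded with
#' a reason column.
#'
#' @param fits list of `base_fit` objects fitted on the same data.
#' @param delta_aic near-tie threshold on the AIC scale.
#' @return list with `table` (form, k, rss, aic, converged, reason, rank)
#'   ordered by AIC, and `selected` (the chosen form name).
#' @export
rank_models <- function(fits, delta_aic = 2) {
  if (length(fits) < 1L) stop("rank_models() needs fits", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f) {
    k <- length(f$params)
    data.frame(form = f$form, component = f$component, k = k, n = f$n,
               rss = f$rss,
               aic = if (isTRUE(f$converged)) aic_ls(f$rss, f$n, k) else NA_real_,
               converged = isTRUE(f$converged),
               reason = if (isTRUE(f$converged)) "" else
                 paste0("excluded: not converged (", f$message, ")"))
  }))
  ok <- tab[tab$converged, , drop = FALSE]
  if (nrow(ok) == 0L) stop("rank_models(): no converged fits", call. = FALSE)
  ok <- ok[order(ok$aic), , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  selected <- ok$form[1L]
  if (nrow(ok) >= 2L && (ok$aic[2L] - ok$aic[1L]) <= delta_aic &&
      ok$k[2L] < ok$k[1L])
    selected <- ok$form[2L]
  bad <- tab[!tab$converged, , drop = FALSE]
  if (nrow(bad)) bad$rank <- NA_integer_
  list(table = rbind(ok, bad), selected = selected)
}
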