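#' Age-group indicator encoding
#'
#' Encodes the five stand-development classes (1 young, 2 middle-aged,
#' 3 near-mature, 4 mature, 5 over-mature) as 0/1 indicator columns
#' AG1..AG5, exactly one of which is 1 per tree. All five indicators enter
#' the multiplicative dummy power model as group-specific scale
#' coefficients; no reference category is dropped because the model has no
#' separate intercept (the usual "n - 1 dummies" rule applies only to
#' additive encodings).
#'
#' @param age_group integer vector with values in 1..5.
#' @return integer matrix, one row per element, columns AG1..AG5.
#' @export
encode_age <- function(age_group) {
  bad <- which(!(age_group %in% 1:5))
  if (length(bad))
    stop("age_group outside 1..5 in rows ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  m <- matrix(0L, nrow = length(age_group), ncol = 5L,
              dimnames = list(NULL, paste0("AG", 1:5)))
  m[cbind(seq_along(age_group), age_group)] <- 1L
  m
}

#' Construct a dummy power model from known parameters
#'
#' The age-group dummy power model predicts a biomass component as
#' \eqn{(\sum_i b_{0i} S_i) \, LH^b \, LCD^c}: group-specific scale
#' coefficients with exponents shared across groups.
#'
#' @param scales numeric vector of 5 positive per-group scale coefficients
#'   (may contain NA for groups a fit never saw).
#' @param b,c shared exponents on LH and LCD.
#' @param component the biomass component modelled.
#' @return a `dummy_fit` object.
#' @export
dummy_model <- function(scales, b, c, component = NA_character_) {
  stopifnot(length(scales) == 5L)
  if (any(scales[!is.na(scales)] <= 0))
    stop("scale coefficients must be strictly positive", call. = FALSE)
  structure(list(component = component,
                 params = list(scales = setNames(as.numeric(scales),
                                                 paste0("b0", 1:5)),
                               b = as.numeric(b), c = as.numeric(c)),
                 se = NULL, n = NA_integer_, converged = NA,
                 rss = NA_real_),
            class = "dummy_fit")
}

#' @export
predict.dummy_fit <- function(object, newdata, ...) {
  if (any(newdata$lh <= 0 | newdata$lcd <= 0))
    stop("predict: lh and lcd must be strictly positive", call. = FALSE)
  sc <- object$params$scales[newdata$age_group]
  if (anyNA(sc))
    stop("prediction requested for an age group absent from the fit",
         call. = FALSE)
  unname(sc) * newdata$lh^object$params$b * newdata$lcd^object$params$c
}

#' Fit the age-group dummy power model
#'
#' Joint nonlinear least squares over the per-group scale coefficients and
#' the shared exponents (b on LH, c on LCD), by Levenberg-Marquardt with
#' analytic Jacobians. Initialisation: the base power fit on the same data,
#' with every group scale started at its `a`. Only the age groups present in
#' the data get a scale estimate; with a single group present the model
#' collapses to the base power form on that subset.
#'
#' @param train tree table; all modelled age groups must have observations.
#' @param component biomass component.
#' @param require_all_groups error if any of the five groups is absent
#'   (default FALSE: absent groups simply get `NA` scales).
#' @param start optional list with elements `scales` (length 5), `b`, `c`.
#' @param variance_power optional power-of-the-mean variance weighting
#'   exponent, as in [fit_base()] (`NULL` = unweighted, the default).
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return a `dummy_fit` with `params` (`scales` b01..b05, `b`, `c`), `se`
#'   on the same layout, `n`, `rss`, `rss_trace`, convergence info.
#' @export
fit_dummy <- function(train, component = "total", require_all_groups = FALSE,
                      start = NULL, variance_power = NULL, control = NULL) {
  col <- paste0("m_", component)
  y <- train[[col]]; lh <- train$lh; lcd <- train$lcd
  ag <- as.integer(train$age_group)
  encode_age(ag)  # validates the range
  groups <- sort(unique(ag))
  if (require_all_groups && length(groups) < 5L)
    stop("age group(s) ", paste(setdiff(1:5, groups), collapse = ", "),
         " absent from training data; use a stratified split ",
         "(split_records(stratify = TRUE))", call. = FALSE)
  k <- length(groups) + 2L
  if (length(y) < k)
    stop("fit_dummy(): ", length(y), " observations cannot identify ", k,
         " parameters", call. = FALSE)
  if (any(lh <= 0 | lcd <= 0) || any(y <= 0))
    stop("fit_dummy(): requires strictly positive response and covariates",
         call. = FALSE)
  if (is.null(start)) {
    base <- fit_base(train, "power", component, control = control)
    p0 <- c(rep(base$params["a"], length(groups)),
            base$params["b"], base$params["c"])
  } else {
    p0 <- c(start$scales[groups], start$b, start$c)
  }
  names(p0) <- c(paste0("b0", groups), "b", "c")
  gi <- match(ag, groups)
  fn <- function(p) p[gi] * lh^p[length(groups) + 1L] * lcd^p[length(groups) + 2L]
  jacfn <- function(p) {
    m <- fn(p)
    Js <- matrix(0, length(y), length(groups))
    Js[cbind(seq_along(y), gi)] <- m / p[gi]
    cbind(Js, m * log(lh), m * log(lcd))
  }
  extra <- list(component = component, groups = groups)
  fit <- ls_fit(p0, y, fn, jacfn, control = control, extra = extra,
                class = "dummy_fit")
  if (!is.null(variance_power)) {
    w <- 1 / pmax(fn(fit$params), 1e-12)^variance_power
    fit <- ls_fit(fit$params, y, fn, jacfn, control = control, extra = extra,
                  weights = w, class = "dummy_fit")
    fit$variance_power <- variance_power
  }
  # repackage the flat LM parameter vector into the scales/b/c layout
  sc <- se_sc <- setNames(rep(NA_real_, 5L), paste0("b0", 1:5))
  sc[groups] <- fit$params[seq_along(groups)]
  se_sc[groups] <- fit$se[seq_along(groups)]
  fit$params <- list(scales = sc,
                     b = unname(fit$params[length(groups) + 1L]),
                     c = unname(fit$params[length(groups) + 2L]))
  fit$se <- list(scales = se_sc,
                 b = unname(fit$se[length(groups) + 1L]),
                 c = unname(fit$se[length(groups) + 2L]))
  fit
}

#' @export
print.dummy_fit <- function(x, ...) {
  cat("Age-group dummy power model, component:", x$component, "\n")
  cat("scales (b01..b05):", paste(signif(x$params$scales, 5), collapse = " "),
      "\n")
  cat(sprintf("exponents: b (LH) = %.5g, c (LCD) = %.5g\n",
              x$params$b, x$params$c))
  if (!is.na(x$rss %||% NA))
    cat(sprintf("n = %d, RSS = %.6g, converged = %s\n",
                x$n, x$rss, x$converged))
  invisible(x)
}
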