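#' Construct an additive NSUR system from known parameters
#'
#' The compatible biomass system models the four components jointly,
#' \deqn{M_{comp} = (\sum_i s_{i,comp} AG_i) \, LH^{e_{comp}} \, LCD^{f_{comp}},}
#' for comp in (trunk, bark, branch, leaf), and defines the total as their
#' exact sum — an identity, never a fifth fitted equation. Component order
#' throughout is trunk, bark, branch, leaf.
#'
#' @param scales named list (trunk, bark, branch, leaf) of length-5 positive
#'   scale vectors (one per age group).
#' @param exponents named list of length-2 vectors `c(e, f)` (exponents on
#'   LH and LCD).
#' @return an `nsur_fit` object (no data; `Sigma`, SEs absent).
#' @export
nsur_system <- function(scales, exponents) {
  comps <- c("trunk", "bark", "branch", "leaf")
  stopifnot(all(comps %in% names(scales)), all(comps %in% names(exponents)))
  params <- lapply(comps, function(cc) {
    sc <- as.numeric(scales[[cc]])
    stopifnot(length(sc) == 5L)
    ef <- as.numeric(exponents[[cc]])
    list(scales = setNames(sc, paste0("s", 1:5)), e = ef[1], f = ef[2])
  })
  names(params) <- comps
  structure(list(params = params, Sigma = NULL, se = NULL,
                 converged = NA, outer_iterations = NA_integer_,
                 n = NA_integer_),
            class = "nsur_fit")
}

#' Predict all components and the total from an NSUR system
#'
#' Each component comes from its power equation; the total is the exact sum
#' of the four component predictions (structural additivity — compatibility
#' holds for every input by construction).
#'
#' @param object an `nsur_fit`.
#' @param newdata data.frame with `lh`, `lcd`, `age_group`.
#' @param ... unused.
#' @return data.frame with columns trunk, bark, branch, leaf, total (kg).
#' @export
predict.nsur_fit <- function(object, newdata, ...) {
  if (any(newdata$lh <= 0 | newdata$lcd <= 0))
    stop("predict: lh and lcd must be strictly positive", call. = FALSE)
  ag <- as.integer(newdata$age_group)
  encode_age(ag)
  out <- lapply(object$params, function(p)
    unname(p$scales[ag]) * newdata$lh^p$e * newdata$lcd^p$f)
  out <- as.data.frame(out)
  out$total <- out$trunk + out$bark + out$branch + out$leaf
  out
}

#' Residual cross-equation covariance
#'
#' \eqn{\hat\Sigma = R'R / n} from the n x 4 residual matrix (columns =
#' component equations). Symmetric positive semidefinite by construction;
#' the 1/n divisor (not 1/(n - p)) is the package default and is what the
#' iterated-GLS loop uses.
#'
#' @param residuals numeric n x 4 matrix of equation residuals, n >= 5.
#' @return 4 x 4 covariance matrix.
#' @export
estimate_sigma <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 5L)
    stop("estimate_sigma() needs at least 5 residual rows", call. = FALSE)
  crossprod(residuals) / nrow(residuals)
}

#' Fit the additivity-constrained NSUR system
#'
#' Iterated feasible generalized least squares for the four-equation
#' nonlinear system (5 age-group scales + 2 exponents per component, 28
#' parameters):
#' \enumerate{
#'   \item start from equationwise fits (age-group dummy power models per
#'     component, fitted here unless supplied via `start`);
#'   \item estimate \eqn{\hat\Sigma = R'R/n} from the current residual
#'     matrix;
#'   \item minimise the stacked GLS criterion
#'     \eqn{\sum_i r_i' \hat\Sigma^{-1} r_i} by Levenberg-Marquardt on
#'     residuals whitened with the Cholesky factor of
#'     \eqn{\hat\Sigma^{-1}};
#'   \item repeat 2-3 until the maximum relative parameter change falls
#'     below `outer_tol` (default 1e-8) or `max_outer` iterations.
#' }
#' The total-biomass equation is never estimated: it is the structural sum
#' of the component predictions (including it would make \eqn{\Sigma}
#' singular). A singular \eqn{\hat\Sigma} is ridge-regularised
#' (\eqn{\hat\Sigma + \lambda I}, \eqn{\lambda} = 1e-8 of the mean
#' diagonal) with a warning. Parameter covariance is the GLS expression
#' \eqn{(J' (\hat\Sigma^{-1} \otimes I_n) J)^{-1}} at the final iterate.
#'
#' @param train tree table with all five age groups present and >= 50 trees.
#' @param start optional named list of `dummy_fit` objects (trunk, bark,
#'   branch, leaf) used as equationwise starts.
#' @param outer_tol convergence threshold on the max relative parameter
#'   change between outer iterations.
#' @param max_outer maximum outer iterations.
#' @param sigma_structure `"full"` (default) uses the unrestricted residual
#'   covariance; `"diagonal"` zeroes the off-diagonal terms, which makes the
#'   GLS criterion separable so the system estimates coincide with
#'   equationwise NLS (the uncorrelated-error limit, useful as an oracle and
#'   for sensitivity analysis).
#' @param variance_power optional per-equation power-of-the-mean variance
#'   weighting exponent (as in [fit_base()]); weights 1/mean^lambda are
#'   computed from the equationwise starting fits and held fixed through the
#'   IFGLS loop. `NULL` (default) is unweighted, the headline convention.
#' @param control inner [minpack.lm::nls.lm.control()] list.
#' @return an `nsur_fit`: `params` (per component: `scales` s1..s5, `e`,
#'   `f`), `se` (same layout), `Sigma` (4 x 4, component order trunk, bark,
#'   branch, leaf), `vcov`, `converged`, `outer_iterations`, and `trace`
#'   (per outer iteration: GLS criterion before and after the inner step,
#'   and the parameter change).
#' @export
fit_nsur <- function(train, start = NULL, outer_tol = 1e-8, max_outer = 100L,
                     sigma_structure = c("full", "diagonal"),
                     variance_power = NULL, control = NULL) {
  sigma_structure <- match.arg(sigma_structure)
  comps <- c("trunk", "bark", "branch", "leaf")
  ag <- as.integer(train$age_group)
  if (!all(1:5 %in% ag))
    stop("fit_nsur() requires observations in all five age groups",
         call. = FALSE)
  n <- nrow(train)
  if (n < 50L) stop("fit_nsur() needs at least 50 trees", call. = FALSE)
  lh <- train$lh; lcd <- train$lcd
  if (any(lh <= 0 | lcd <= 0))
    stop("fit_nsur(): covariates must be strictly positive", call. = FALSE)
  Y <- as.matrix(train[, paste0("m_", comps)])

  if (is.null(start))
    start <- setNames(lapply(comps, function(cc)
      fit_dummy(train, cc, require_all_groups = TRUE,
                variance_power = variance_power, control = control)),
      comps)
  theta <- unlist(lapply(comps, function(cc) {
    p <- start[[cc]]$params
    c(p$scales, p$b, p$c)
  }))
  names(theta) <- paste(rep(comps, each = 7L),
                        rep(c(paste0("s", 1:5), "e", "f"), 4L), sep = ".")

  mean_mat <- function(th) {
    M <- matrix(0, n, 4L)
    for (j in 1:4) {
      p <- th[(j - 1L) * 7L + 1:7]
      M[, j] <- p[ag] * lh^p[6L] * lcd^p[7L]
    }
    M
  }
  # optional per-equation variance-power weights, fixed at the start values
  Wmat <- if (is.null(variance_power)) matrix(1, n, 4L)
          else 1 / pmax(mean_mat(theta), 1e-12)^variance_power
  res_mat <- function(th) Wmat * (Y - mean_mat(th))
  # Block-diagonal Jacobian of the (weighted) stacked residuals
  # (column-stacked): equation j's residuals depend only on its own 7
  # parameters.
  jac_blocks <- function(th) {
    lapply(1:4, function(j) {
      p <- th[(j - 1L) * 7L + 1:7]
      m <- p[ag] * lh^p[6L] * lcd^p[7L]
      Js <- matrix(0, n, 5L)
      Js[cbind(seq_len(n), ag)] <- m / p[ag]
      Wmat[, j] * cbind(Js, m * log(lh), m * log(lcd))
    })
  }
  whiten <- function(S) {
    ok <- tryCatch({chol(solve(S)); TRUE}, error = function(e) FALSE)
    if (!ok) {
      warning("singular residual covariance: applying ridge regularisation",
              call. = FALSE)
      S <- S + diag(mean(diag(S)) * 1e-8, nrow(S))
    }
    chol(solve(S))  # upper U with U'U = S^{-1}; ||U r||^2 = r' S^{-1} r
  }

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  modifyList(list(maxiter = 200, ftol = 1e-12, ptol = 1e-10),
                             as.list(control %||% list())))
  trace <- list()
  converged <- FALSE
  U <- NULL
  for (it in seq_len(max_outer)) {
    R <- res_mat(theta)
    Sigma <- estimate_sigma(R)
    if (sigma_structure == "diagonal") Sigma <- diag(diag(Sigma))
    U <- whiten(Sigma)
    crit <- function(th) {
      Rw <- res_mat(th) %*% t(U)
      sum(Rw * Rw)
    }
    crit_start <- crit(theta)
    inner <- minpack.lm::nls.lm(
      par = theta,
      fn = function(th) as.vector(res_mat(th) %*% t(U)),
      jac = function(th) {
        B <- jac_blocks(th)
        J <- matrix(0, 4L * n, length(th))
        for (k in 1:4) {        # whitened output stream k
          rows <- (k - 1L) * n + seq_len(n)
          for (j in 1:4) {      # source equation j
            if (U[k, j] != 0)
              J[rows, (j - 1L) * 7L + 1:7] <-
                J[rows, (j - 1L) * 7L + 1:7] - U[k, j] * B[[j]]
          }
        }
        J
      },
      control = ctrl)
    theta_new <- setNames(coef(inner), names(theta))
    delta <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-12))
    trace[[it]] <- data.frame(outer = it, crit_start = crit_start,
                              crit_end = crit(theta_new),
                              max_rel_change = delta)
    theta <- theta_new
    if (delta < outer_tol) { converged <- TRUE; break }
  }

  # GLS parameter covariance at the final iterate
  B <- jac_blocks(theta)
  Jw <- matrix(0, 4L * n, length(theta))
  for (k in 1:4) {
    rows <- (k - 1L) * n + seq_len(n)
    for (j in 1:4)
      if (U[k, j] != 0)
        Jw[rows, (j - 1L) * 7L + 1:7] <-
          Jw[rows, (j - 1L) * 7L + 1:7] + U[k, j] * B[[j]]
  }
  sv <- svd(Jw)
  inv_s2 <- ifelse(sv$d > 0, 1 / sv$d^2, Inf)
  V <- sv$v %*% (inv_s2 * t(sv$v))
  dimnames(V) <- list(names(theta), names(theta))
  se <- sqrt(diag(V))

  R <- res_mat(theta)
  Sigma <- estimate_sigma(R)
  if (sigma_structure == "diagonal") Sigma <- diag(diag(Sigma))
  dimnames(Sigma) <- list(comps, comps)
  pack <- function(v) {
    out <- lapply(1:4, function(j) {
      p <- v[(j - 1L) * 7L + 1:7]
      list(scales = setNames(unname(p[1:5]), paste0("s", 1:5)),
           e = unname(p[6L]), f = unname(p[7L]))
    })
    names(out) <- comps
    out
  }
  Rraw <- Y - mean_mat(theta)
  structure(list(params = pack(theta), se = pack(se), Sigma = Sigma,
                 vcov = V, n = n, converged = converged,
                 outer_iterations = length(trace),
                 trace = do.call(rbind, trace),
                 variance_power = variance_power,
                 rss = sum(Rraw * Rraw)),
            class = "nsur_fit")
}

#' @export
print.nsur_fit <- function(x, ...) {
  cat("Additive NSUR biomass system (trunk + bark + branch + leaf = total)\n")
  for (cc in names(x$params)) {
    p <- x$params[[cc]]
    cat(sprintf("  %-6s scales: %s | LH^%.4f LCD^%.4f\n", cc,
                paste(signif(p$scales, 4), collapse = " "), p$e, p$f))
  }
  if (!is.null(x$Sigma)) {
    cat(sprintf("n = %d, converged = %s after %d outer iteration(s)\n",
                x$n, x$converged, x$outer_iterations))
    cat("residual covariance (Sigma):\n")
    print(signif(x$Sigma, 4))
  }
  invisible(x)
}
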