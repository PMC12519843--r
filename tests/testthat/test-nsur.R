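test_that("system prediction follows the published coefficients and is additive", {
  sys <- published_sur_system()
  out <- predict(sys, data.frame(lh = 1, lcd = 1, age_group = 1))
  expect_equal(unname(unlist(out[, c("trunk", "bark", "branch", "leaf")])),
               c(0.2124, 0.1098, 0.2901, 0.3401))
  expect_equal(out$total, 0.9524)

  set.seed(91)
  nd <- data.frame(lh = runif(200, 3, 30), lcd = runif(200, 0.3, 8),
                   age_group = sample(1:5, 200, replace = TRUE))
  pr <- predict(sys, nd)
  expect_identical(pr$total, pr$trunk + pr$bark + pr$branch + pr$leaf)

  # linearity in the scale coefficients: doubling all scales doubles output
  sys2 <- sys
  for (cc in names(sys2$params))
    sys2$params[[cc]]$scales <- 2 * sys2$params[[cc]]$scales
  expect_equal(as.matrix(predict(sys2, nd)), 2 * as.matrix(pr))

  expect_error(predict(sys, data.frame(lh = -1, lcd = 1, age_group = 1)),
               "positive")
})

test_that("residual covariance estimation is R'R/n with guards", {
  Z <- matrix(0, 10, 4)
  expect_equal(estimate_sigma(Z), matrix(0, 4, 4))

  set.seed(92)
  a <- rnorm(2000); b <- rnorm(2000)
  b <- resid(lm(b ~ a)); a <- a / sd(a) * sqrt(1999 / 2000)
  b <- b / sd(b) * sqrt(1999 / 2000)
  R2 <- cbind(a, b, rnorm(2000), rnorm(2000))
  S <- estimate_sigma(R2)
  expect_equal(S[1, 1], 1, tolerance = 1e-3)
  expect_equal(S[1, 2], 0, tolerance = 1e-9)
  expect_true(isSymmetric(S))
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-12))

  # duplicated residual columns give a rank-deficient estimate
  Rd <- cbind(a, a, b, rnorm(2000))
  expect_lt(min(eigen(estimate_sigma(Rd), only.values = TRUE)$values), 1e-10)

  expect_error(estimate_sigma(matrix(0, 4, 4)), "at least 5")
})

test_that("noise-free data reproduces all 28 published coefficients to 1e-6", {
  s <- exact_stand(30L, seed = 111L)
  fit <- fit_nsur(s)
  truth <- published_sur_system()
  expect_true(fit$converged)
  for (cc in c("trunk", "bark", "branch", "leaf")) {
    expect_equal(unname(fit$params[[cc]]$scales),
                 unname(truth$params[[cc]]$scales), tolerance = 1e-6,
                 label = cc)
    expect_equal(fit$params[[cc]]$e, truth$params[[cc]]$e, tolerance = 1e-6)
    expect_equal(fit$params[[cc]]$f, truth$params[[cc]]$f, tolerance = 1e-6)
  }
})

test_that("with diagonal error covariance NSUR matches equationwise NLS", {
  for (seed in c(7L, 19L, 31L)) {
    s <- small_stand(60L, cv = 0.10, cor = 0, seed = seed)
    # the diagonal-Sigma structure makes the GLS criterion separable, so the
    # system estimator must reduce to equation-by-equation NLS
    fit <- fit_nsur(s, sigma_structure = "diagonal")
    expect_true(fit$converged)
    for (cc in c("trunk", "bark", "branch", "leaf")) {
      eqw <- fit_dummy(s, cc, require_all_groups = TRUE)
      th_sys <- c(fit$params[[cc]]$scales, fit$params[[cc]]$e,
                  fit$params[[cc]]$f)
      th_eqw <- c(eqw$params$scales, eqw$params$b, eqw$params$c)
      expect_equal(unname(th_sys), unname(th_eqw), tolerance = 1e-4,
                   label = paste("seed", seed, cc))
    }
  }
})

test_that("the GLS criterion does not increase within an outer iteration", {
  s <- small_stand(60L, cv = 0.15, cor = 0.6, seed = 121L)
  fit <- fit_nsur(s)
  expect_true(all(fit$trace$crit_end <= fit$trace$crit_start * (1 + 1e-10)))
  expect_true(fit$converged)
})

test_that("predictions from a fitted system remain exactly additive", {
  s <- small_stand(40L, seed = 131L)
  fit <- fit_nsur(s)
  pr <- predict(fit, s)
  expect_identical(pr$total, pr$trunk + pr$bark + pr$branch + pr$leaf)
})

test_that("joint estimation costs no efficiency despite correlated errors", {
  # Monte-Carlo sampling-variance comparison at pairwise error correlation
  # 0.7. All four equations share the same covariates (lh, lcd) and the same
  # indicator structure, so by the identical-regressor property of SUR the
  # GLS weighting can yield essentially no efficiency gain over equationwise
  # NLS here; the check is that the joint estimator tracks equationwise
  # efficiency (variance ratios near 1) while additionally delivering the
  # residual covariance and exact additivity.
  n_rep <- 50L
  est_sys <- matrix(NA_real_, n_rep, 28L)
  est_eqw <- matrix(NA_real_, n_rep, 28L)
  comps <- c("trunk", "bark", "branch", "leaf")
  for (r in seq_len(n_rep)) {
    s <- generate_stand(stand_config(n_per_age_group = rep(100L, 5L),
                                     cv = 0.25, error_cor = 0.7,
                                     seed = 9000L + r))
    starts <- lapply(setNames(comps, comps), function(cc)
      fit_dummy(s, cc, require_all_groups = TRUE, variance_power = 1))
    fit <- fit_nsur(s, start = starts, variance_power = 1)
    est_sys[r, ] <- unlist(lapply(fit$params, unlist))
    est_eqw[r, ] <- unlist(lapply(starts, function(f)
      c(f$params$scales, f$params$b, f$params$c)))
  }
  ratio <- apply(est_sys, 2L, var) / apply(est_eqw, 2L, var)
  expect_true(all(ratio < 1.15))
  expect_true(all(ratio > 0.85))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("correlated-error simulations recover the truth within 3 joint SEs", {
  truth <- published_sur_system()
  n_rep <- 50L
  hits <- 0L
  for (r in seq_len(n_rep)) {
    s <- generate_stand(stand_config(n_per_age_group = rep(400L, 5L),
                                     cv = 0.10, error_cor = 0.5,
                                     seed = 11000L + r))
    # lambda = 1 weighting matches the constant-CV error model, so the GLS
    # standard errors are on the right scale for the coverage check
    fit <- fit_nsur(s, variance_power = 1)
    if (!fit$converged) next
    ok <- TRUE
    for (cc in c("trunk", "bark", "branch", "leaf")) {
      th <- c(fit$params[[cc]]$scales, fit$params[[cc]]$e, fit$params[[cc]]$f)
      tr <- c(truth$params[[cc]]$scales, truth$params[[cc]]$e,
              truth$params[[cc]]$f)
      se <- c(fit$se[[cc]]$scales, fit$se[[cc]]$e, fit$se[[cc]]$f)
      if (!all(abs(th - tr) <= 3 * se)) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("preconditions are enforced", {
  s <- small_stand(40L, seed = 141L)
  expect_error(fit_nsur(s[s$age_group != 2L, ]), "five age groups")
  expect_error(fit_nsur(s[c(1:9, 41:49, 81:89, 121:129, 161:169), ]),
               "at least 50")
})
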