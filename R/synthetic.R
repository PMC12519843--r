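#' Synthetic stand generator configuration
#'
#' Configures the generator that emulates the tree-level data structure the
#' analysis assumes: five age groups; per-group LiDAR tree height `lh` drawn
#' from a truncated lognormal (group means increasing with age, pooled mean
#' near 13.1 m, envelope 2.7-31.7 m); crown diameter
#' `lcd = lcd_alpha * lh^lcd_beta * lognormal noise` (pooled mean near
#' 2.3 m); component biomass means from per-group power laws in (lh, lcd)
#' whose default truth is the published compatible-system coefficient set;
#' and multiplicative lognormal component errors (mean-one) with a Gaussian
#' copula across the four components. The total is always computed as the
#' exact component sum, never generated independently.
#'
#' @param n_per_age_group integer vector of 5 positive counts (default 400
#'   trees per group).
#' @param lh_mean per-group mean tree height (m), increasing with age.
#' @param lh_sdlog lognormal sdlog of `lh` within group.
#' @param lh_bounds truncation envelope for `lh` (m). `lh_bounds[1] ==
#'   lh_bounds[2]` degenerates to a fixed height (useful for exact checks).
#' @param lcd_alpha,lcd_beta,lcd_sdlog crown-diameter allometry and noise.
#' @param truth an `nsur_fit`-like object giving the per-component,
#'   per-group power-law means; default [published_sur_system()].
#' @param cv per-component coefficient of variation of the multiplicative
#'   error, named (trunk, bark, branch, leaf) or scalar; default 0.10.
#' @param error_cor 4 x 4 error correlation matrix (component order trunk,
#'   bark, branch, leaf) or a single off-diagonal value; default 0.5.
#' @param trees_per_plot synthetic plot size used to assign `plot_id`.
#' @param seed integer seed; every draw derives from it.
#' @return a `stand_config` object.
#' @export
stand_config <- function(n_per_age_group = rep(400L, 5L),
                         lh_mean = c(8, 11, 13.5, 16, 17.5),
                         lh_sdlog = 0.18,
                         lh_bounds = c(2.7, 31.7),
                         lcd_alpha = 0.23, lcd_beta = 0.9, lcd_sdlog = 0.4,
                         truth = published_sur_system(),
                         cv = 0.10,
                         error_cor = 0.5,
                         trees_per_plot = 150L,
                         seed = 1L) {
  if (length(n_per_age_group) != 5L || any(n_per_age_group < 0))
    stop("n_per_age_group must be 5 non-negative counts", call. = FALSE)
  if (length(lh_mean) != 5L || any(lh_mean <= 0))
    stop("lh_mean must be 5 positive values", call. = FALSE)
  if (lh_bounds[1] > lh_bounds[2] || lh_bounds[1] <= 0)
    stop("lh_bounds must be a positive, non-inverted range", call. = FALSE)
  if (lh_sdlog < 0 || lcd_sdlog < 0 || lcd_alpha <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  comps <- c("trunk", "bark", "branch", "leaf")
  if (length(cv) == 1L) cv <- setNames(rep(cv, 4L), comps)
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  if (length(error_cor) == 1L) {
    R <- matrix(error_cor, 4L, 4L); diag(R) <- 1
  } else R <- as.matrix(error_cor)
  if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-12))
    stop("error_cor must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("error_cor must be positive semidefinite", call. = FALSE)
  dimnames(R) <- list(comps, comps)
  structure(list(n_per_age_group = as.integer(n_per_age_group),
                 lh_mean = lh_mean, lh_sdlog = lh_sdlog,
                 lh_bounds = lh_bounds,
                 lcd_alpha = lcd_alpha, lcd_beta = lcd_beta,
                 lcd_sdlog = lcd_sdlog,
                 truth = truth, cv = cv[comps], error_cor = R,
                 trees_per_plot = as.integer(trees_per_plot),
                 seed = as.integer(seed)),
            class = "stand_config")
}

#' Generate a synthetic stand
#'
#' Draw order (the reproducibility contract, given `config$seed`): for each
#' age group 1..5 in turn — (1) `lh` via inverse-CDF truncated-lognormal
#' uniforms, (2) `lcd` noise normals, (3) the n x 4 error-copula normal
#' matrix (column order trunk, bark, branch, leaf). Component biomass is the
#' power-law mean times a mean-one multiplicative lognormal error; the total
#' is the exact sum, so additivity is structural. With `cv = 0` the masses
#' equal the deterministic means exactly.
#'
#' @param config a [stand_config()].
#' @return tree table (classed `tree_stand`), one row per tree.
#' @export
generate_stand <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  comps <- c("trunk", "bark", "branch", "leaf")
  local_rng(config$seed)
  L <- chol_psd(config$error_cor)
  sdlog_err <- sqrt(log(1 + config$cv^2))
  out <- list()
  for (g in 1:5) {
    n <- config$n_per_age_group[g]
    if (n == 0L) next
    lo <- config$lh_bounds[1]; hi <- config$lh_bounds[2]
    u <- runif(n)
    if (lo == hi) {
      lh <- rep(lo, n)
    } else {
      ml <- log(config$lh_mean[g]) - config$lh_sdlog^2 / 2
      plo <- plnorm(lo, ml, config$lh_sdlog)
      phi <- plnorm(hi, ml, config$lh_sdlog)
      lh <- qlnorm(plo + u * (phi - plo), ml, config$lh_sdlog)
    }
    zc <- rnorm(n)
    lcd <- config$lcd_alpha * lh^config$lcd_beta *
      exp(zc * config$lcd_sdlog - config$lcd_sdlog^2 / 2)
    Z <- matrix(rnorm(n * 4L), n, 4L) %*% L
    rec <- data.frame(
      tree_id = sprintf("t%d_%05d", g, seq_len(n)),
      plot_id = sprintf("p%d_%03d", g,
                        (seq_len(n) - 1L) %/% config$trees_per_plot + 1L),
      age_group = g, lh = lh, lcd = lcd)
    for (j in seq_along(comps)) {
      p <- config$truth$params[[comps[j]]]
      mu <- p$scales[g] * lh^p$e * lcd^p$f
      eps <- exp(Z[, j] * sdlog_err[j] - sdlog_err[j]^2 / 2)
      rec[[paste0("m_", comps[j])]] <- unname(mu * eps)
    }
    rec$m_total <- rec$m_bark + rec$m_trunk + rec$m_branch + rec$m_leaf
    out[[g]] <- rec
  }
  res <- do.call(rbind, out)[, .tree_csv_header]
  rownames(res) <- NULL
  class(res) <- unique(c("tree_stand", class(res)))
  res
}

# Cholesky-like factor for a PSD (possibly rank-deficient) correlation
# matrix, via the eigendecomposition with negative round-off clipped.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
}

#' Generate trees through the DBH/height allocation path
#'
#' Draws DBH (cm) and height (m) from a joint lognormal covariate model,
#' computes the total via the total allometry and the components via ratio
#' disaggregation (so additivity is exact), then attaches `lh`/`lcd` as
#' noisy proxies: `lh = height * lognormal`, `lcd = crown_alpha *
#' dbh^crown_beta * lognormal`. Draw order per tree batch: DBH normals,
#' height normals, lh-noise normals, lcd-noise normals. Non-positive draws
#' cannot occur under the lognormal covariate law; bounds violations (see
#' `dbh_range`/`height_range`) are redrawn up to `max_retry` batches, then
#' error.
#'
#' @param n number of trees.
#' @param alloc an [allocation_params()] object.
#' @param covariates list: `dbh_meanlog`, `dbh_sdlog`, `height_alpha`,
#'   `height_beta`, `height_sdlog` (height = alpha * dbh^beta * noise),
#'   `lh_sdlog`, `crown_alpha`, `crown_beta`, `lcd_sdlog`,
#'   `dbh_range`, `height_range`. Set the `*_sdlog` entries to 0 for
#'   noise-free proxies.
#' @param age_group age-group label(s) to assign (recycled).
#' @param seed integer seed.
#' @param max_retry redraw batches allowed for out-of-range covariates.
#' @return tree table with additional columns `dbh` and `height`.
#' @export
generate_from_allocation <- function(n, alloc,
                                     covariates = list(),
                                     age_group = 1L,
                                     seed = 1L, max_retry = 20L) {
  stopifnot(inherits(alloc, "allocation_params"), n >= 0)
  cfg <- modifyList(list(dbh_meanlog = log(15), dbh_sdlog = 0.35,
                         height_alpha = 1.6, height_beta = 0.75,
                         height_sdlog = 0.08,
                         lh_sdlog = 0.03, crown_alpha = 0.35,
                         crown_beta = 0.7, lcd_sdlog = 0.1,
                         dbh_range = c(1, 80), height_range = c(1.3, 40)),
                    covariates)
  if (n == 0L) {
    empty <- data.frame(tree_id = character(0), plot_id = character(0),
                        age_group = integer(0), lh = numeric(0),
                        lcd = numeric(0), m_bark = numeric(0),
                        m_trunk = numeric(0), m_branch = numeric(0),
                        m_leaf = numeric(0), m_total = numeric(0),
                        dbh = numeric(0), height = numeric(0))
    return(empty)
  }
  local_rng(seed)
  dbh <- height <- rep(NA_real_, n)
  need <- seq_len(n)
  for (try in seq_len(max_retry)) {
    m <- length(need)
    d <- exp(rnorm(m, cfg$dbh_meanlog, cfg$dbh_sdlog))
    h <- cfg$height_alpha * d^cfg$height_beta *
      exp(rnorm(m, 0, cfg$height_sdlog) - cfg$height_sdlog^2 / 2)
    ok <- d >= cfg$dbh_range[1] & d <= cfg$dbh_range[2] &
      h >= cfg$height_range[1] & h <= cfg$height_range[2]
    dbh[need[ok]] <- d[ok]; height[need[ok]] <- h[ok]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need))
    stop("covariate draws kept violating dbh/height bounds after ",
         max_retry, " redraw batches", call. = FALSE)
  m_total <- total_agb(dbh, height, alloc)
  parts <- disaggregate(m_total, alloc)
  lh <- height * exp(rnorm(n, 0, cfg$lh_sdlog) - cfg$lh_sdlog^2 / 2)
  lcd <- cfg$crown_alpha * dbh^cfg$crown_beta *
    exp(rnorm(n, 0, cfg$lcd_sdlog) - cfg$lcd_sdlog^2 / 2)
  res <- data.frame(
    tree_id = sprintf("t%05d", seq_len(n)),
    plot_id = "p1",
    age_group = rep_len(as.integer(age_group), n),
    lh = lh, lcd = lcd,
    m_bark = parts$bark, m_trunk = parts$stem, m_branch = parts$branch,
    m_leaf = parts$leaf,
    # summed in canonical column order so stored additivity is bit-exact
    m_total = parts$bark + parts$stem + parts$branch + parts$leaf,
    dbh = dbh, height = height)
  class(res) <- unique(c("tree_stand", class(res)))
  res
}
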