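# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a property explicitly needs more.

# A small noisy stand with all five age groups.
small_stand <- function(n_per_group = 40L, cv = 0.10, cor = 0.5, seed = 101L) {
  generate_stand(stand_config(n_per_age_group = rep(as.integer(n_per_group), 5L),
                              cv = cv, error_cor = cor, seed = seed))
}

# Exact (noise-free) stand: masses are the deterministic power-law means.
exact_stand <- function(n_per_group = 40L, seed = 101L) {
  small_stand(n_per_group, cv = 0, seed = seed)
}

# Single-component dataset lying exactly on a given base-form surface.
surface_data <- function(form, params, n = 200L, seed = 11L,
                         component = "total") {
  set.seed(seed)
  lh <- runif(n, 3, 30)
  lcd <- runif(n, 0.3, 8)
  fit <- base_model(form, params, component)
  y <- predict(fit, data.frame(lh = lh, lcd = lcd))
  df <- data.frame(tree_id = as.character(seq_len(n)), plot_id = "p1",
                   age_group = 1L, lh = lh, lcd = lcd)
  df[[paste0("m_", component)]] <- y
  df
}

# Brute-force RSS minimiser for the power form, independent of the LM path:
# for fixed exponents (b, c) the optimal scale has the closed form
# a = sum(y g) / sum(g^2) with g = lh^b lcd^c, so the oracle grids over
# (b, c) with nested refinement and profiles a out exactly.
grid_power_oracle <- function(y, lh, lcd, lower = c(0.2, -0.5),
                              upper = c(3, 1.5), levels = 12L, pts = 31L) {
  lo <- lower; hi <- upper
  best <- NULL
  prof <- function(b, c) {
    g <- lh^b * lcd^c
    a <- sum(y * g) / sum(g * g)
    c(a, sum((y - a * g)^2))
  }
  for (lev in seq_len(levels)) {
    gr <- expand.grid(b = seq(lo[1], hi[1], length.out = pts),
                      c = seq(lo[2], hi[2], length.out = pts))
    res <- vapply(seq_len(nrow(gr)),
                  function(i) prof(gr$b[i], gr$c[i]), numeric(2))
    i0 <- which.min(res[2, ])
    best <- c(res[1, i0], gr$b[i0], gr$c[i0])
    step <- (hi - lo) / (pts - 1)
    lo <- c(gr$b[i0], gr$c[i0]) - step
    hi <- c(gr$b[i0], gr$c[i0]) + step
  }
  setNames(best, c("a", "b", "c"))
}
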