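#' Total-allometry and ratio-disaggregation parameters
#'
#' Parameters of the national-standard-style allocation path: total
#' aboveground biomass \eqn{M_A = a_0 D^{a_1} H^{a_2}} from DBH (cm) and
#' height (m), then component shares proportional to (1, g1, g2, g3) for
#' (stem, bark, branch, leaf), where g1, g2, g3 are the bark-, branch- and
#' leaf-to-stem biomass ratios. The national standard's species-specific
#' coefficient values are not shipped: supply your own. The set returned by
#' [placeholder_allocation_params()] is synthetic, for tests and examples
#' only.
#'
#' @param a0,a1,a2 total-allometry coefficients; `a0 > 0`.
#' @param g1,g2,g3 non-negative component-to-stem biomass ratios
#'   (bark, branch, leaf).
#' @return an `allocation_params` object (a validated named list).
#' @export
allocation_params <- function(a0, a1, a2, g1, g2, g3) {
  stopifnot(is.numeric(a0), is.numeric(a1), is.numeric(a2),
            is.numeric(g1), is.numeric(g2), is.numeric(g3))
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  if (g1 < 0 || g2 < 0 || g3 < 0)
    stop("ratios g1, g2, g3 must be non-negative", call. = FALSE)
  structure(list(a0 = a0, a1 = a1, a2 = a2, g1 = g1, g2 = g2, g3 = g3),
            class = "allocation_params")
}

#' @rdname allocation_params
#' @export
placeholder_allocation_params <- function() {
  # Synthetic round-number values spanning a plausible conifer range.
  # NOT the national standard's coefficients (those are user-supplied).
  allocation_params(a0 = 0.06, a1 = 1.9, a2 = 0.9,
                    g1 = 0.18, g2 = 0.25, g3 = 0.12)
}

#' Total aboveground biomass from DBH and height
#'
#' \eqn{M_A = a_0 D^{a_1} H^{a_2}}, vectorised over `d` and `h`.
#'
#' @param d diameter at breast height, cm, > 0.
#' @param h tree height, m, > 0.
#' @param p an [allocation_params()] object.
#' @return biomass in kg.
#' @export
total_agb <- function(d, h, p) {
  stopifnot(inherits(p, "allocation_params"))
  if (any(d <= 0) || any(h <= 0))
    stop("total_agb(): d and h must be strictly positive", call. = FALSE)
  p$a0 * d^p$a1 * h^p$a2
}

#' Disaggregate total biomass into components
#'
#' Splits total aboveground biomass into (stem, bark, branch, leaf) with
#' weights (1, g1, g2, g3)/(1 + g1 + g2 + g3). The leaf share is computed as
#' the residual so that the four outputs sum to the input exactly in floating
#' point (conservation is structural, not approximate).
#'
#' @param m_a total aboveground biomass, kg, >= 0; vectorised.
#' @param p an [allocation_params()] object.
#' @return data.frame with columns stem, bark, branch, leaf (one row per
#'   element of `m_a`).
#' @export
disaggregate <- function(m_a, p) {
  stopifnot(inherits(p, "allocation_params"))
  if (any(m_a < 0))
    stop("disaggregate(): m_a must be non-negative", call. = FALSE)
  s <- 1 + p$g1 + p$g2 + p$g3
  stem <- m_a / s
  bark <- m_a * p$g1 / s
  branch <- m_a * p$g2 / s
  leaf <- m_a - stem - bark - branch
  # floating-point fix-up: nudge the residual component until the
  # left-associated sum stem + bark + branch + leaf reproduces m_a bit for
  # bit (at most a few one-ulp corrections)
  for (i in 1:5) {
    delta <- m_a - (stem + bark + branch + leaf)
    if (all(delta == 0)) break
    leaf <- leaf + delta
  }
  leaf <- pmax(leaf, 0)
  data.frame(stem = stem, bark = bark, branch = branch, leaf = leaf)
}
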