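## IPCC Tier-2 harvested-wood-product pool -----------------------------------
##
## Three product categories (sawn wood, wood-based panels, paper/paperboard)
## each decaying with first-order kinetics.  The annual recursion is
##   C_j(i+1) = exp(-k_j) C_j(i) + (1 - exp(-k_j))/k_j * Inflow_j(i)
## with k_j = ln(2) / HL_j and default half-lives 35 / 25 / 2 years.

DEFAULT_HALF_LIVES <- c(sawn = 35, panel = 25, paper = 2)

#' First-order decay constant from a half-life
#'
#' @param half_life_yr half-life in years (> 0).
#' @return decay constant `k = ln(2) / HL` per year.
#' @examples
#' decay_constant(35)
#' @export
decay_constant <- function(half_life_yr) {
  if (any(!is.numeric(half_life_yr)) || any(half_life_yr <= 0))
    stop_input("half_life_yr must be positive")
  log(2) / half_life_yr
}

#' One annual step of the product-pool recursion
#'
#' @param pools named numeric vector of category stocks (Tg C), names
#'   `sawn`, `panel`, `paper`.
#' @param inflow_total total harvested-carbon inflow this year (Tg C).
#' @param ratios named shares allocating the inflow to categories; must sum
#'   to 1 within 1e-9.
#' @param half_lives category half-lives in years (defaults 35/25/2).
#' @return the category stocks one year later.
#' @export
step_pool <- function(pools, inflow_total, ratios,
                      half_lives = DEFAULT_HALF_LIVES) {
  if (inflow_total < 0) stop_input("inflow must be nonnegative")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_input("product ratios must sum to 1 (got ", sum(ratios), ")")
  k <- decay_constant(half_lives)
  # -expm1(-k)/k = (1 - exp(-k))/k without cancellation for small k
  exp(-k) * pools + (-expm1(-k) / k) * (inflow_total * ratios)
}

#' Closed-form pool under constant inflow
#'
#' Analytic solution of the annual recursion for one category under
#' constant inflow `I`:
#' `C(n) = C0 exp(-k n) + (I/k)(1 - exp(-k n))`; the independent oracle for
#' [step_pool()], approaching the steady state `I/k` as `n` grows.
#'
#' @param C0 initial stock.
#' @param I constant annual inflow to the category.
#' @param k decay constant (> 0).
#' @param n_years number of annual steps.
#' @return stock after `n_years`.
#' @export
closed_form_constant_inflow <- function(C0, I, k, n_years) {
  if (any(k <= 0)) stop_input("k must be positive")
  C0 * exp(-k * n_years) + (I / k) * (1 - exp(-k * n_years))
}

#' Project the wood-product pool over an inflow series
#'
#' Iterates [step_pool()] over aligned annual inflow and ratio series and
#' reports per-category stocks, total stock and annual decay emissions.
#' The balance `inflow - decay - delta stock = 0` holds each year.
#'
#' @param inflow data.frame (year, inflow) in Tg C.
#' @param ratio_series data.frame (year, sawn, panel, paper); must cover
#'   the inflow years.
#' @param half_lives category half-lives (defaults 35/25/2 years).
#' @param C0 initial category stocks: named vector, a single 0, or the
#'   string `"steady_first_decade"` (default) which starts each category at
#'   the steady state implied by its mean inflow over the first ten years
#'   (a configurable stand-in for spinning the pool up from its historical
#'   inflow series, which is out of scope).
#' @return data.frame (year, sawn, panel, paper, total, decay_emission).
#' @export
project_pool <- function(inflow, ratio_series,
                         half_lives = DEFAULT_HALF_LIVES,
                         C0 = "steady_first_decade") {
  if (!all(inflow$year %in% ratio_series$year))
    stop_input("ratio series does not cover all inflow years")
  ridx <- match(inflow$year, ratio_series$year)
  k <- decay_constant(half_lives)
  cats <- names(DEFAULT_HALF_LIVES)
  if (identical(C0, "steady_first_decade")) {
    n0 <- min(10, nrow(inflow))
    Imean <- mean(inflow$inflow[seq_len(n0)])
    r0 <- as.numeric(ratio_series[ridx[1], cats])
    C0 <- Imean * r0 / k
  } else if (length(C0) == 1L && C0 == 0) {
    C0 <- stats::setNames(rep(0, 3), cats)
  }
  C0 <- stats::setNames(as.numeric(C0), cats)
  ny <- nrow(inflow)
  out <- matrix(0, ny, 3, dimnames = list(inflow$year, cats))
  decay <- numeric(ny)
  pools <- C0
  for (i in seq_len(ny)) {
    r <- stats::setNames(as.numeric(ratio_series[ridx[i], cats]), cats)
    new <- step_pool(pools, inflow$inflow[i], r, half_lives)
    decay[i] <- sum(pools) + inflow$inflow[i] - sum(new)
    out[i, ] <- new
    pools <- new
  }
  data.frame(year = inflow$year, out, total = rowSums(out),
             decay_emission = decay, row.names = NULL)
}
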