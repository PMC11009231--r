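## Age impacts on cohort growth ---------------------------------------------
##
## A logistic multiplier on a cohort's production capacity as a function of
## its age b:
##     F_age(b) = 1 - a / (1 + exp(3/Age1 * (b - Age1)))
## ranging from (1 - a) for very young stands to 1 for old ones, with the
## midpoint 1 - a/2 at b = Age1 (the age of peak instantaneous growth).

#' Age factor on forest growth
#'
#' @param a initial-age depression parameter, in `[0, 1)`; `a = 0.05` is the
#'   default for newly planted or regenerated stands, later calibrated per
#'   species against the statistical model's 2020 sink.
#' @param age1 age of the instantaneous growth-rate peak (years, > 0).
#' @param b cohort age(s), years, >= 0.
#' @return numeric vector of factors in `[1 - a, 1]`, nondecreasing in `b`.
#' @examples
#' age_factor(0.05, 30, 30)   # midpoint: 1 - a/2 = 0.975
#' @export
age_factor <- function(a, age1, b) {
  check_scalar_num(a, "a", lower = 0, upper = 1 - 1e-12)
  check_scalar_num(age1, "age1", lower = 0, strict_lower = TRUE)
  if (any(b < 0)) stop_input("cohort age b must be nonnegative")
  1 - a / (1 + exp(3 / age1 * (b - age1)))
}

#' Calibrate the age-factor parameter a for one species
#'
#' Scalar root-find on `a` in `[0, 0.95]` so that a simulator's species-level
#' sink in the calibration year matches the statistical model's within 0.1%
#' relative.  `sim_sink` must be a function of `a` returning that sink.
#' Starts from `a = 0.05`; if the start already matches, or no root is
#' bracketed in bounds, `a = 0.05` is kept (with a warning in the latter
#' case).
#'
#' @param sim_sink function(a) -> simulated sink for the species.
#' @param target_sink the statistical model's sink (same units).
#' @param a_init starting / fallback value (default 0.05).
#' @param bounds search interval (default `c(0, 0.95)`).
#' @param rel_tol relative matching tolerance (default 1e-3).
#' @return the calibrated `a`.
#' @export
calibrate_age_factor_a <- function(sim_sink, target_sink, a_init = 0.05,
                                   bounds = c(0, 0.95), rel_tol = 1e-3) {
  scale <- max(abs(target_sink), 1e-12)
  f <- function(a) sim_sink(a) - target_sink
  if (abs(f(a_init)) / scale <= rel_tol) return(a_init)
  lo <- f(bounds[1]); hi <- f(bounds[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
    warning("no age-factor root bracketed in [", bounds[1], ", ", bounds[2],
            "]; keeping a = ", a_init)
    return(a_init)
  }
  r <- stats::uniroot(f, bounds, tol = 1e-10)
  r$root
}
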