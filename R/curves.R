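## Stand-level carbon growth-curve families ---------------------------------
##
## Canonical forestry parameterizations:
##   richards     C(t) = A * (1 - exp(-k t))^m
##   korf         C(t) = A * exp(-k * t^(-m))
##   hossfeld     C(t) = t^c / (b + t^c / A)
##   logistic     C(t) = A / (1 + b * exp(-k t))
##   logarithmic  C(t) = p + q * log(t)
## The sigmoidal families approach the asymptote A as t -> Inf.

CURVE_FAMILIES <- c("richards", "korf", "hossfeld", "logistic", "logarithmic")

curve_param_names <- function(family) {
  switch(family,
         richards    = c("A", "k", "m"),
         korf        = c("A", "k", "m"),
         hossfeld    = c("A", "b", "c"),
         logistic    = c("A", "b", "k"),
         logarithmic = c("p", "q"),
         stop_input("unknown curve family: ", family))
}

curve_params_admissible <- function(family, params) {
  pn <- curve_param_names(family)
  if (is.null(names(params))) names(params) <- pn
  if (!all(pn %in% names(params)) || any(!is.finite(unlist(params[pn]))))
    return(FALSE)
  p <- as.list(params)
  if (family == "logarithmic") return(TRUE)
  all(unlist(p[pn]) > 0)  # asymptote, rate and shape strictly positive
}

#' Evaluate a stand carbon growth curve
#'
#' Computes carbon stock (Mg C/ha) at stand age `age_yr` for one of the five
#' curve families used throughout the package: the three theoretical growth
#' equations (Richards, Korf, Hossfeld) that drive the statistical projection
#' ensemble, plus the logistic and logarithmic stock--age forms used for the
#' inventory reference stocks.
#'
#' @param family one of `"richards"`, `"korf"`, `"hossfeld"`, `"logistic"`,
#'   `"logarithmic"`.
#' @param params named numeric vector of curve parameters
#'   (`A,k,m` / `A,b,c` / `A,b,k` / `p,q` depending on the family).
#' @param age_yr numeric vector of stand ages in years, must be > 0.
#' @return numeric vector of carbon stocks, same length as `age_yr`.
#' @examples
#' eval_curve("richards", c(A = 100, k = 0.1, m = 2), 10)
#' @export
eval_curve <- function(family, params, age_yr) {
  family <- match.arg(family, CURVE_FAMILIES)
  if (!is.numeric(age_yr) || any(!is.finite(age_yr)) || any(age_yr <= 0))
    stop_input("age_yr must be positive and finite")
  if (!curve_params_admissible(family, params))
    stop_input("inadmissible parameters for family '", family, "'")
  p <- as.list(params)
  t <- age_yr
  switch(family,
         richards    = p$A * (1 - exp(-p$k * t))^p$m,
         korf        = p$A * exp(-p$k * t^(-p$m)),
         hossfeld    = t^p$c / (p$b + t^p$c / p$A),
         logistic    = p$A / (1 + p$b * exp(-p$k * t)),
         logarithmic = p$p + p$q * log(t))
}

## annual increment of a species curve between integer ages; never negative
## for admissible sigmoidal parameters, clamped defensively for logarithmic
curve_increment <- function(family, params, age_yr) {
  a0 <- pmax(age_yr, 1e-9)
  pmax(eval_curve(family, params, a0 + 1) - eval_curve(family, params, a0), 0)
}
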