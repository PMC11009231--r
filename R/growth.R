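## Statistical growth-curve counterpart model --------------------------------
##
## Fits stand-level carbon stock ~ age curves per stratum with nonlinear
## least squares for the three theoretical growth equations (Richards, Korf,
## Hossfeld), validates each by ten-part held-out splitting, keeps the best
## candidate per family and predicts with an R2-weighted ensemble of the
## three winners.  This statistical model deliberately carries no harvest,
## climate or CO2 terms: its contrast with the process-emulating cohort
## simulator is the point.

curve_start_values <- function(family, age, stock) {
  A0 <- 1.2 * max(stock)
  t <- age; y <- pmin(stock, 0.999 * A0)
  safe_lm <- function(f) tryCatch(stats::coef(stats::lm(f)), error = function(e) NULL)
  switch(family,
    richards = {
      co <- safe_lm(log(pmax(1 - y / A0, 1e-6)) ~ 0 + t)
      k0 <- if (is.null(co) || !is.finite(co[1]) || co[1] >= 0) 3 / max(t)
            else -unname(co[1])
      c(A = A0, k = k0, m = 1)
    },
    korf = {
      k0 <- mean((log(A0) - log(pmax(y, 1e-6))) * t)
      c(A = A0, k = max(k0, 1e-3), m = 1)
    },
    hossfeld = {
      co <- safe_lm(I(1 / pmax(y, 1e-6)) ~ I(1 / t))
      b0 <- if (is.null(co) || !is.finite(co[2]) || co[2] <= 0) 1
            else unname(co[2])
      c(A = A0, b = b0, c = 1)
    },
    logistic = {
      z <- log(pmax(A0 / pmax(y, 1e-6) - 1, 1e-6))
      co <- safe_lm(z ~ t)
      if (is.null(co) || !is.finite(co[2]) || co[2] >= 0)
        c(A = A0, b = 5, k = 0.1)
      else c(A = A0, b = exp(unname(co[1])), k = -unname(co[2]))
    },
    stop_input("no nonlinear start values for family: ", family))
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(0)
  1 - sum((obs - pred)^2) / sst
}

#' Fit one growth-curve family by nonlinear least squares
#'
#' Levenberg-Marquardt least squares with log-linearised starting values,
#' positivity bounds on all parameters of the sigmoidal families, and a
#' tight convergence tolerance so that noise-free curve data are recovered
#' essentially exactly.  The logarithmic family is an ordinary linear model
#' in `log(age)`.
#'
#' @param data data.frame with columns `age` and `stock` (Mg C/ha).
#' @param family curve family, see [eval_curve()].
#' @return object of class `fc_growth_fit`: family, named `params`,
#'   training `r2`, `rmse`, logical `ok` (FALSE for non-convergence or
#'   degenerate data; such fits are excluded from ensembles).
#' @export
fit_curve <- function(data, family) {
  family <- match.arg(family, CURVE_FAMILIES)
  pn <- curve_param_names(family)
  if (nrow(data) < length(pn) + 1)
    stop_input("need at least ", length(pn) + 1, " points to fit ", family)
  age <- data$age; stock <- data$stock
  out <- list(family = family, params = stats::setNames(rep(NA_real_, length(pn)), pn),
              r2 = 0, rmse = NA_real_, ok = FALSE, n = nrow(data))
  class(out) <- "fc_growth_fit"
  if (family == "logarithmic") {
    fit <- stats::lm(stock ~ log(age))
    out$params <- c(p = unname(stats::coef(fit)[1]), q = unname(stats::coef(fit)[2]))
    pred <- stats::fitted(fit)
    out$r2 <- r_squared(stock, pred)
    out$rmse <- sqrt(mean((stock - pred)^2))
    out$ok <- all(is.finite(out$params)) && out$r2 > 0
    return(out)
  }
  start <- curve_start_values(family, age, stock)
  fml <- switch(family,
    richards = stock ~ A * (1 - exp(-k * age))^m,
    korf     = stock ~ A * exp(-k * age^(-m)),
    hossfeld = stock ~ age^c / (b + age^c / A),
    logistic = stock ~ A / (1 + b * exp(-k * age)))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(age = age, stock = stock),
                      start = as.list(start),
                      lower = rep(1e-8, length(start)),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  out$params <- stats::coef(fit)[pn]
  pred <- eval_curve(family, out$params, age)
  out$r2 <- r_squared(stock, pred)
  out$rmse <- sqrt(mean((stock - pred)^2))
  out$ok <- curve_params_admissible(family, out$params) && out$r2 > 0
  out
}

#' @export
print.fc_growth_fit <- function(x, ...) {
  cat(sprintf("Growth-curve fit (%s)%s\n", x$family,
              if (x$ok) "" else "  [flagged: not usable]"))
  print(round(x$params, 6))
  cat(sprintf("  n = %d, R2 = %.4f, RMSE = %.4g\n", x$n, x$r2, x$rmse))
  invisible(x)
}

#' @export
coef.fc_growth_fit <- function(object, ...) object$params

#' @export
predict.fc_growth_fit <- function(object, newdata, ...) {
  age <- if (is.data.frame(newdata)) newdata$age else newdata
  eval_curve(object$family, object$params, age)
}

#' Fit the per-stratum R2-weighted growth-curve ensemble
#'
#' The central fitting function.  For every stratum with at least 10 plots,
#' the plots are split into ten parts; for each part and each of the
#' Richards, Korf and Hossfeld families a model is trained on the remaining
#' nine parts and validated (R2) on the held-out part.  The best candidate
#' of each family is kept (ties broken by lower validation RMSE, then lower
#' part index) and predictions are the R2-weighted average of the (up to)
#' three winners, with negative validation R2 clamped to zero and dropped.
#'
#' @param data data.frame with columns `age`, `stock` and optionally
#'   `stratum` (a single stratum is assumed when absent).
#' @param n_parts number of validation parts (default 10).
#' @param fold_mode `"tenfold"` (each of the ten parts held out once) or
#'   `"ninefold"` (only the first nine parts are held out).
#' @return object of class `fc_growth_ensemble`: a list of per-stratum
#'   entries holding the winning `fc_growth_fit`s and their normalised
#'   weights.  Methods: [predict.fc_growth_ensemble()], `print`, `summary`,
#'   `coef`.
#' @export
fit_growth_ensemble <- function(data, n_parts = 10,
                                fold_mode = c("tenfold", "ninefold")) {
  fold_mode <- match.arg(fold_mode)
  if (is.null(data$stratum)) data$stratum <- "all"
  families <- c("richards", "korf", "hossfeld")
  strata <- unique(data$stratum)
  entries <- stats::setNames(vector("list", length(strata)), strata)
  for (s in strata) {
    d <- data[data$stratum == s, , drop = FALSE]
    if (nrow(d) < n_parts)
      stop_input("stratum '", s, "' has ", nrow(d), " plots; need >= ", n_parts)
    part <- rep_len(seq_len(n_parts), nrow(d))
    heldout <- if (fold_mode == "tenfold") seq_len(n_parts)
               else seq_len(n_parts - 1L)
    winners <- list()
    for (fam in families) {
      cand <- list()
      for (p in heldout) {
        train <- d[part != p, , drop = FALSE]
        valid <- d[part == p, , drop = FALSE]
        f <- tryCatch(fit_curve(train, fam), error = function(e) NULL)
        if (is.null(f) || !f$ok) next
        pv <- eval_curve(fam, f$params, valid$age)
        f$validation_part <- p
        f$r2 <- r_squared(valid$stock, pv)       # held-out R2
        f$rmse <- sqrt(mean((valid$stock - pv)^2))
        cand[[length(cand) + 1L]] <- f
      }
      if (length(cand) == 0) next
      o <- order(-vapply(cand, `[[`, 0, "r2"),
                 vapply(cand, `[[`, 0, "rmse"),
                 vapply(cand, `[[`, 0, "validation_part"))
      winners[[fam]] <- cand[[o[1]]]
    }
    w <- pmax(vapply(winners, `[[`, 0, "r2"), 0)
    keep <- w > 0
    if (!any(keep))
      stop("all growth-curve families failed in stratum '", s, "'")
    winners <- winners[keep]
    w <- w[keep] / sum(w[keep])
    entries[[s]] <- list(stratum = s, fits = winners, weights = w)
  }
  structure(list(strata = entries, n_parts = n_parts, fold_mode = fold_mode),
            class = "fc_growth_ensemble")
}

#' Predict from a growth-curve ensemble
#'
#' @param object an `fc_growth_ensemble`.
#' @param newdata data.frame with columns `age` and optionally `stratum`.
#' @param ... unused.
#' @return numeric vector of ensemble carbon stocks (Mg C/ha).
#' @export
predict.fc_growth_ensemble <- function(object, newdata, ...) {
  if (is.null(newdata$stratum)) newdata$stratum <- names(object$strata)[1]
  out <- numeric(nrow(newdata))
  for (s in unique(newdata$stratum)) {
    e <- object$strata[[s]]
    if (is.null(e)) stop_input("no predictor for stratum '", s, "'")
    i <- newdata$stratum == s
    pred <- 0
    for (j in seq_along(e$fits))
      pred <- pred + e$weights[j] *
        eval_curve(e$fits[[j]]$family, e$fits[[j]]$params, newdata$age[i])
    out[i] <- pred
  }
  out
}

#' @export
print.fc_growth_ensemble <- function(x, ...) {
  cat(sprintf("Growth-curve ensemble: %d strat%s, %d-part validation (%s)\n",
              length(x$strata), if (length(x$strata) == 1) "um" else "a",
              x$n_parts, x$fold_mode))
  for (e in x$strata)
    cat(sprintf("  %s: %s\n", e$stratum,
                paste(sprintf("%s (w=%.3f, R2=%.3f)", names(e$fits),
                              e$weights, vapply(e$fits, `[[`, 0, "r2")),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.fc_growth_ensemble <- function(object, ...) {
  rows <- list()
  for (e in object$strata)
    for (fam in names(e$fits)) {
      f <- e$fits[[fam]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = e$stratum, family = fam, weight = unname(e$weights[fam]),
        r2 = f$r2, rmse = f$rmse, validation_part = f$validation_part,
        t(f$params), stringsAsFactors = FALSE)
    }
  out <- do.call(function(...) rbind(..., make.row.names = FALSE),
                 lapply(rows, function(r) {
                   miss <- setdiff(c("A", "k", "m", "b", "c"), names(r))
                   for (m in miss) r[[m]] <- NA_real_
                   r[c("stratum", "family", "weight", "r2", "rmse",
                       "validation_part", "A", "k", "m", "b", "c")]
                 }))
  class(out) <- c("summary.fc_growth_ensemble", "data.frame")
  out
}

#' @export
coef.fc_growth_ensemble <- function(object, ...) {
  s <- summary(object)
  s[, c("stratum", "family", "A", "k", "m", "b", "c")]
}

#' Stock--age curve for inventory reference stocks
#'
#' Fits both the logistic and the logarithmic stock--age equations and
#' adopts the one with the higher R2.
#'
#' @param data data.frame with columns `age`, `stock`.
#' @return the winning `fc_growth_fit` (field `family` says which).
#' @export
fit_stock_age <- function(data) {
  f1 <- fit_curve(data, "logistic")
  f2 <- fit_curve(data, "logarithmic")
  if (f1$ok && (!f2$ok || f1$r2 >= f2$r2)) f1 else f2
}

#' Project stocks and sinks with the statistical model
#'
#' Ages every stratum by exactly +1 year per year along its ensemble curve
#' (no harvest, no mortality, no climate terms) and adds new plantations
#' entering at age 0 scaled by the tree survival rate.  The annual sink is
#' the first difference of the stock series.
#'
#' @param initial data.frame (stratum, area_ha, age0): initial states.
#' @param ensemble an `fc_growth_ensemble` covering all strata.
#' @param years integer vector of calendar years (default 2020:2100).
#' @param survival_rate fraction of planted area that establishes
#'   (baseline 0.47, improved management 0.85).
#' @param planting optional data.frame (year, stratum, area_ha) of planned
#'   new plantations (pre-survival areas).
#' @return object of class `fc_stat_proj`: data.frame (year, stock_Mg,
#'   sink_Mg) with the per-stratum stock matrix in attribute `by_stratum`.
#' @export
statistical_projection <- function(initial, ensemble, years = 2020:2100,
                                   survival_rate = 0.47, planting = NULL) {
  missing <- setdiff(initial$stratum, names(ensemble$strata))
  if (length(missing))
    stop_input("no predictor for strat", if (length(missing) > 1) "a: " else "um: ",
               paste(missing, collapse = ", "))
  ny <- length(years)
  stock <- matrix(0, nrow = ny, ncol = nrow(initial),
                  dimnames = list(years, initial$stratum))
  for (i in seq_len(nrow(initial))) {
    ages <- initial$age0[i] + (years - years[1])
    stock[, i] <- initial$area_ha[i] *
      predict(ensemble, data.frame(age = pmax(ages, 1e-6),
                                   stratum = initial$stratum[i]))
  }
  if (!is.null(planting)) {
    for (j in seq_len(nrow(planting))) {
      ages <- years - planting$year[j]        # age 0 in the planting year
      live <- ages >= 1
      if (!any(live)) next
      contrib <- numeric(ny)
      contrib[live] <- survival_rate * planting$area_ha[j] *
        predict(ensemble, data.frame(age = ages[live],
                                     stratum = planting$stratum[j]))
      stock[, planting$stratum[j]] <- stock[, planting$stratum[j]] + contrib
    }
  }
  total <- rowSums(stock)
  out <- data.frame(year = years, stock_Mg = total,
                    sink_Mg = c(NA, diff(total)))
  attr(out, "by_stratum") <- stock
  class(out) <- c("fc_stat_proj", "data.frame")
  out
}
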