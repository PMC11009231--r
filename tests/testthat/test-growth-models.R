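test_that("curve evaluation matches closed forms and asymptotes", {
  expect_equal(eval_curve("richards", c(A = 100, k = 0.1, m = 2), 10),
               100 * (1 - exp(-1))^2)
  expect_equal(eval_curve("richards", c(A = 100, k = 0.2, m = 1.5), 1e6),
               100, tolerance = 1e-9)
  expect_equal(eval_curve("logarithmic", c(p = 0, q = 1), 1), 0)
  expect_equal(eval_curve("korf", c(A = 80, k = 3, m = 1), 3),
               80 * exp(-1))
  expect_equal(eval_curve("hossfeld", c(A = 100, b = 4, c = 2), 2),
               4 / (4 + 4 / 100))
  expect_error(eval_curve("richards", c(A = -1, k = 0.1, m = 2), 10),
               class = "fc_input_error")
  expect_error(eval_curve("richards", c(A = 100, k = 0.1, m = 2), 0),
               class = "fc_input_error")
})

test_that("sigmoidal families are monotone nondecreasing in age (property)", {
  set.seed(77)
  ages <- seq(0.5, 300, by = 0.5)
  for (i in 1:30) {
    fam <- sample(c("richards", "korf", "hossfeld", "logistic"), 1)
    params <- switch(fam,
      richards = c(A = runif(1, 50, 200), k = runif(1, 0.02, 0.3),
                   m = runif(1, 0.5, 3)),
      korf     = c(A = runif(1, 50, 200), k = runif(1, 1, 6),
                   m = runif(1, 0.5, 2)),
      hossfeld = c(A = runif(1, 50, 200), b = runif(1, 0.5, 20),
                   c = runif(1, 1, 3)),
      logistic = c(A = runif(1, 50, 200), b = runif(1, 1, 20),
                   k = runif(1, 0.02, 0.3)))
    y <- eval_curve(fam, params, ages)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y <= params[["A"]] + 1e-9))
  }
})

test_that("noise-free curve data are recovered essentially exactly", {
  cases <- list(
    list(fam = "richards", p = c(A = 120, k = 0.08, m = 1.8)),
    list(fam = "korf",     p = c(A = 90,  k = 4,    m = 1.1)),
    list(fam = "hossfeld", p = c(A = 150, b = 60,   c = 1.9)))
  for (cs in cases) {
    d <- curve_data(cs$fam, cs$p, seq(2, 100, by = 2))
    f <- fit_curve(d, cs$fam)
    expect_true(f$ok)
    expect_equal(unname(coef(f)), unname(cs$p), tolerance = 1e-6)
    # duplicating every point leaves the least-squares fit unchanged
    f2 <- fit_curve(rbind(d, d), cs$fam)
    expect_equal(coef(f2), coef(f), tolerance = 1e-8)
  }
})

test_that("recovery bias shrinks as noise shrinks (property)", {
  truth <- c(A = 110, k = 0.07, m = 1.6)
  err_at <- function(noise) {
    errs <- vapply(1:5, function(s) {
      d <- curve_data("richards", truth, seq(2, 120, by = 2),
                      noise_sd = noise, seed = 100 + s)
      f <- fit_curve(d, "richards")
      max(abs(coef(f) - truth) / truth)
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(0.2, 0.02, 0.002), err_at, numeric(1))
  expect_true(all(diff(e) < 0))
  expect_lt(e[3], 0.05)
})

test_that("degenerate constant data are flagged and excluded", {
  d <- data.frame(age = 1:20, stock = rep(50, 20))
  f <- fit_curve(d, "richards")
  expect_false(f$ok)
  expect_lte(f$r2, 0)
})

test_that("ensemble weights normalize as R2 ratios and degrade gracefully", {
  # weight arithmetic: r2 (0.9, 0.8, 0.7) -> (0.375, 1/3, 0.291666...)
  r2 <- c(0.9, 0.8, 0.7)
  w <- pmax(r2, 0) / sum(pmax(r2, 0))
  expect_equal(w, c(0.375, 1 / 3, 0.7 / 2.4))

  d <- curve_data("richards", c(A = 100, k = 0.09, m = 1.7),
                  rep(seq(4, 100, by = 4), 2), noise_sd = 0.05, seed = 9)
  ens <- fit_growth_ensemble(d)
  e <- ens$strata[[1]]
  expect_equal(sum(e$weights), 1)
  expect_true(all(e$weights > 0))
  expect_true(all(c("richards", "korf", "hossfeld") %in% names(e$fits) |
                    length(e$fits) >= 1))
  # three identical fits -> ensemble equals any single member
  pred <- predict(ens, data.frame(age = c(10, 50)))
  single <- sapply(e$fits, function(f) eval_curve(f$family, f$params, c(10, 50)))
  expect_equal(pred, as.numeric(single %*% e$weights))
})

test_that("ten-part validation selects per-family winners on held-out R2", {
  set.seed(13)
  d <- curve_data("hossfeld", c(A = 130, b = 40, c = 2.1),
                  rep(seq(3, 90, by = 3), 2), noise_sd = 0.08, seed = 15)
  ens <- fit_growth_ensemble(d, fold_mode = "tenfold")
  for (f in ens$strata[[1]]$fits) {
    expect_true(f$validation_part %in% 1:10)
    expect_true(f$r2 > 0)
  }
  ens9 <- fit_growth_ensemble(d, fold_mode = "ninefold")
  for (f in ens9$strata[[1]]$fits)
    expect_true(f$validation_part %in% 1:9)
  expect_error(fit_growth_ensemble(data.frame(age = 1:5, stock = 1:5)),
               class = "fc_input_error")
})

test_that("stock-age fit adopts the higher-R2 of logistic and logarithmic", {
  d_log <- curve_data("logistic", c(A = 100, b = 8, k = 0.15), seq(2, 80))
  f <- fit_stock_age(d_log)
  expect_equal(f$family, "logistic")
  d_ln <- curve_data("logarithmic", c(p = 5, q = 12), seq(2, 80))
  f2 <- fit_stock_age(d_ln)
  expect_equal(f2$family, "logarithmic")
  expect_equal(unname(coef(f2)), c(5, 12), tolerance = 1e-8)
})

test_that("statistical projection ages strata, scales plantings by survival, and saturates", {
  d <- curve_data("richards", c(A = 100, k = 0.09, m = 1.7),
                  rep(seq(4, 100, by = 4), 2), noise_sd = 0.02, seed = 23)
  ens <- fit_growth_ensemble(d)
  s <- names(ens$strata)[1]
  init <- data.frame(stratum = s, area_ha = 1000, age0 = 10)
  years <- 2020:2060
  base <- statistical_projection(init, ens, years)
  dbl <- statistical_projection(transform(init, area_ha = 2000), ens, years)
  expect_equal(dbl$stock_Mg, 2 * base$stock_Mg, tolerance = 1e-12)

  # stratum at the asymptote: sink ~ 0
  old <- statistical_projection(data.frame(stratum = s, area_ha = 1000,
                                           age0 = 2000), ens, years)
  expect_true(all(abs(old$sink_Mg[-1]) < 1e-4 * max(old$stock_Mg)))

  # new plantations scale by survival rate: 85% vs 47% at equal age
  plant <- data.frame(year = 2025, stratum = s, area_ha = 500)
  zero <- data.frame(stratum = s, area_ha = 0, age0 = 1)
  p47 <- statistical_projection(zero, ens, years, 0.47, plant)
  p85 <- statistical_projection(zero, ens, years, 0.85, plant)
  i <- which(p47$stock_Mg > 0)
  expect_equal(p85$stock_Mg[i] / p47$stock_Mg[i],
               rep(85 / 47, length(i)), tolerance = 1e-9)

  expect_error(statistical_projection(
    data.frame(stratum = "nope", area_ha = 1, age0 = 1), ens, years),
    class = "fc_input_error")
})

test_that("the closed-forest statistical sink eventually declines", {
  d <- curve_data("richards", c(A = 100, k = 0.09, m = 1.7),
                  rep(seq(4, 100, by = 4), 2), noise_sd = 0.02, seed = 29)
  ens <- fit_growth_ensemble(d)
  proj <- statistical_projection(
    data.frame(stratum = names(ens$strata)[1], area_ha = 1000, age0 = 15),
    ens, 2020:2100)
  sink <- proj$sink_Mg[-1]
  expect_lt(sink[length(sink)], max(sink) / 2)
  late <- sink[(length(sink) - 20):length(sink)]
  expect_true(all(diff(late) <= 1e-9))
})
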