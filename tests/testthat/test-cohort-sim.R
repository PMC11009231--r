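test_that("growth step applies the normalized age factor to the curve increment", {
  sp <- manual_species(a = 0, age1 = 20, age2 = 40)
  co <- make_cohorts(3, age = c(10, 20, 60), density = 1)
  cv <- species_curve(sp)
  raw <- eval_curve(cv$family, cv$params, c(10, 20, 60) + 1) -
    eval_curve(cv$family, cv$params, c(10, 20, 60))
  expect_equal(step_growth(co, sp), raw)                 # a = 0: neutral factor
  expect_equal(step_growth(co, sp, growth_modifier = 0), rep(0, 3))

  sp2 <- manual_species(a = 0.4, age1 = 20, age2 = 40)
  got <- step_growth(co, sp2)
  f <- age_factor(0.4, 20, c(10, 20, 60)) / age_factor(0.4, 20, 40)
  expect_equal(got, raw * f)
  # instantaneous growth peaks near age1: increment at age1 beats 3x age1
  inc <- step_growth(make_cohorts(2, age = c(20, 60), density = 0), sp2)
  expect_gt(inc[1], inc[2])
})

test_that("mortality resets cohorts, emits their carbon, and respects rate limits", {
  sp <- manual_species()
  land <- manual_landscape(make_cohorts(50, age = 30, density = 40))
  none <- apply_mortality(land, 0, seed = 1)
  expect_identical(none$landscape$cohorts, land$cohorts)
  expect_equal(none$emitted_Mg, 0)
  all_die <- apply_mortality(land, 1, seed = 1)
  expect_equal(all_die$emitted_Mg, 50 * 40 * 100)
  expect_true(all(all_die$landscape$cohorts$carbon_density == 0))
  expect_true(all(all_die$landscape$cohorts$age_yr == 0))
  expect_equal(all_die$landscape$cohorts$species_id, land$cohorts$species_id)
  expect_error(apply_mortality(land, 0.6, multiplier = 2),
               class = "fc_input_error")
})

test_that("age accrual is +1 for timber and truncated-normal for mixed non-timber stands", {
  sp <- manual_species(inc_mean = 1, inc_sd = 0)
  co <- make_cohorts(10, age = 5)
  co$mgmt <- "nontimber"; co$mixed_flag <- TRUE
  land <- manual_landscape(co)
  aged <- increment_ages(land, sp, seed = 3)
  expect_equal(aged$cohorts$age_yr, rep(6, 10))  # sd 0 degenerates to +1

  sp2 <- manual_species(inc_mean = 0.2, inc_sd = 1)
  big <- manual_landscape(make_cohorts(1e5, age = 10))
  big$cohorts$mgmt <- "nontimber"; big$cohorts$mixed_flag <- TRUE
  aged2 <- increment_ages(big, sp2, seed = 4)
  steps <- aged2$cohorts$age_yr - 10
  expect_true(all(steps >= 0))                   # truncation at 0
  # law of large numbers: mean step ~ E[max(0, N(0.2, 1))]
  mu_trunc <- integrate(function(x) x * dnorm(x, 0.2, 1), 0, Inf)$value
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - mu_trunc), 3 * se + 1e-3)

  # timber cohorts always age exactly +1 regardless of inc params
  tim <- manual_landscape(make_cohorts(20, age = 7))
  aged3 <- increment_ages(tim, sp2, seed = 5)
  expect_equal(aged3$cohorts$age_yr, rep(8, 20))
})

test_that("harvest cuts only mature timber, oldest first, under the allowable-cut cap", {
  sp <- manual_species(age2 = 36)
  # 72 mature planted units, rotation 36 -> at most 2 cut this year
  land <- manual_landscape(make_cohorts(72, age = 50, density = 30))
  h <- harvest(land, sp)
  expect_equal(h$units_cut, 2L)
  expect_equal(h$removed_Mg, 2 * 30 * 100)

  # non-timber cohorts are never harvested
  nt <- manual_landscape(make_cohorts(72, age = 50, density = 30,
                                      mgmt = "nontimber"))
  expect_equal(harvest(nt, sp)$units_cut, 0L)

  # immature stands: zero removal
  young <- manual_landscape(make_cohorts(72, age = 10, density = 5))
  expect_equal(harvest(young, sp)$units_cut, 0L)

  # oldest-first: ages 50 and 40, cap 1 of 36 units -> the 50-yr cohort goes
  two <- manual_landscape(make_cohorts(36, age = c(50, rep(40, 35)),
                                       density = 10))
  h2 <- harvest(two, sp)
  expect_equal(h2$units_cut, 1L)
  expect_equal(h2$landscape$cohorts$age_yr[1], 0)

  # fractional carryover: 18 units, rotation 36 -> one cut every 2 years
  small <- manual_landscape(make_cohorts(18, age = 100, density = 10))
  carry <- NULL; cuts <- integer(6)
  for (y in 1:6) {
    hh <- harvest(small, sp, carryover = carry)
    small <- hh$landscape; carry <- hh$carryover
    cuts[y] <- hh$units_cut
    small$cohorts$age_yr <- small$cohorts$age_yr + 1
  }
  expect_equal(cuts, c(0L, 1L, 0L, 1L, 0L, 1L))

  # rotation extension raises both the maturity bar and the cap divisor
  ext <- manual_landscape(make_cohorts(72, age = 38, density = 10))
  expect_equal(harvest(ext, sp, extension_yr = 5)$units_cut, 0L)
})

test_that("allowable-cut invariant holds per cell-species-year on random landscapes (property)", {
  sp <- gen_species_table(4, seed = 71)
  land <- gen_landscape(sp, 6, 12, seed = 72)
  carry <- NULL
  for (y in 1:30) {
    h <- harvest(land, sp, carryover = carry)
    co_before <- land$cohorts
    key <- paste(co_before$cell_id, co_before$species_id, sep = "|")
    cut_per <- table(key[co_before$mgmt == "timber" &
                           h$landscape$cohorts$age_yr == 0 &
                           co_before$age_yr > 0])
    for (g in names(cut_per)) {
      i <- key == g & co_before$mgmt == "timber"
      s <- co_before$species_id[i][1]
      rot <- sp$age2_years[sp$species_id == s]
      expect_lte(as.integer(cut_per[[g]]), sum(i) / rot + 1)
    }
    land <- h$landscape; carry <- h$carryover
    land$cohorts$age_yr <- land$cohorts$age_yr + 1
  }
})

test_that("key-year detection requires a sustained non-positive window", {
  years <- 2020:2060
  pos <- rep(5, length(years))
  expect_true(is.na(detect_key_year(pos, years)))
  step <- ifelse(years < 2040, 5, -1)
  expect_equal(detect_key_year(step, years), 2040)
  blip <- pos; blip[years %in% 2030:2031] <- -2    # shorter than the window
  expect_true(is.na(detect_key_year(blip, years, window = 3)))
  expect_equal(detect_key_year(blip, years, window = 2), 2030)
})

test_that("species replacement converts flagged non-timber cohorts, conserves units, and routes carbon", {
  sp <- rbind(manual_species(species_id = "bad", replacement_target = "good"),
              manual_species(species_id = "good"))
  co <- make_cohorts(10, species_id = c(rep("bad", 6), rep("good", 4)),
                     age = 30, density = 20, mgmt = "nontimber")
  land <- manual_landscape(co)
  r0 <- replace_species(land, sp, target_area_km2 = 0)
  expect_identical(r0$landscape$cohorts, co)
  r <- replace_species(land, sp, target_area_km2 = 4, seed = 8)
  expect_equal(r$units_replaced, 4L)
  expect_equal(nrow(r$landscape$cohorts), 10)      # unit count conserved
  expect_equal(r$removed_Mg, 4 * 20 * 100)
  full <- replace_species(land, sp, target_area_km2 = 100)
  expect_equal(full$units_replaced, 6L)
  expect_false(any(full$landscape$cohorts$species_id == "bad"))
  expect_true(all(full$landscape$cohorts$age_yr[co$species_id == "bad"] == 0))

  # the practice targets non-timber forests: timber stands are untouched
  co_t <- co; co_t$mgmt[1:3] <- "timber"
  rt <- replace_species(manual_landscape(co_t), sp, target_area_km2 = 100)
  expect_equal(rt$units_replaced, 3L)
  expect_equal(rt$landscape$cohorts$species_id[1:3], rep("bad", 3))

  bad_sp <- sp; bad_sp$replacement_target[1] <- "missing"
  expect_error(replace_species(land, bad_sp, 2), class = "fc_input_error")
})

test_that("forestation deployment respects survival, suitability priority and land budget", {
  sp <- manual_species(timber_fraction = 0)
  co <- make_cohorts(1, age = 5, density = 1)
  land <- manual_landscape(co, grass_km2 = c(1000, 1000), n_cells = 2)
  suit <- matrix(c(0.9, 0.2), nrow = 2,
                 dimnames = list(1:2, "spX"))
  plan <- data.frame(province = "prov1", area_km2 = 100)

  sure <- deploy_forestation(land, sp, plan, suit, survival_rate = 1, seed = 2)
  expect_equal(sure$established_units, 100L)
  expect_equal(sure$shortfall_units, 0L)
  # all units land in the higher-suitability cell while its budget lasts
  newc <- sure$landscape$cohorts[-1, ]
  expect_true(all(newc$cell_id == 1))
  expect_true(all(newc$age_yr == 0 & newc$carbon_density == 0))
  expect_equal(sure$landscape$cells$grassland_shrubland_km2, c(900, 1000))

  # zero land: nothing planted, shortfall logged
  dry <- manual_landscape(co, grass_km2 = 0)
  d <- deploy_forestation(dry, sp, plan, matrix(0.5, 1, 1,
                                                dimnames = list(1, "spX")),
                          survival_rate = 1, seed = 2)
  expect_equal(d$established_units, 0L)
  expect_equal(d$shortfall_units, 100L)

  # fractional plan areas accumulate via carryover
  frac <- data.frame(province = "prov1", area_km2 = 0.5)
  carry <- NULL; tot <- 0L
  landf <- manual_landscape(co, grass_km2 = 1000)
  suit1 <- matrix(0.5, 1, 1, dimnames = list(1, "spX"))
  for (y in 1:4) {
    dd <- deploy_forestation(landf, sp, frac, suit1, 1, seed = y, carry = carry)
    landf <- dd$landscape; carry <- dd$carry
    tot <- tot + dd$established_units
  }
  expect_equal(tot, 2L)
})

test_that("simulation groups switch processes off as designed", {
  sp <- gen_species_table(3, seed = 81)
  land <- gen_landscape(sp, 8, 6, seed = 82)
  plan <- gen_forestation_plan(unique(land$cells$province), 80, 2021, 2035,
                               seed = 83)
  suit <- gen_suitability_maps(sp, land, seed = 84)
  years <- 2020:2050

  g3 <- run_simulation(land, sp, scenario_config(group = 3, seed = 5),
                       plan, suit, years = years)
  expect_true(all(g3$series$harvest_Mg == 0))      # harvest off

  g4 <- run_simulation(land, sp, scenario_config(group = 4, seed = 5),
                       plan, suit, years = years)
  expect_true(all(g4$series$planted_units == 0))
  expect_true(all(rowSums(g4$cell_units) == nrow(land$cohorts)))

  g1 <- run_simulation(land, sp, scenario_config(group = 1, seed = 5),
                       plan, suit, years = years)
  expect_gt(sum(g1$series$planted_units), 0)
  # group 1 vs group 4 difference isolates the new-forest contribution:
  # identical sub-streams make the existing-forest dynamics match until
  # planting starts, and group 1 accumulates extra stock afterwards
  expect_equal(g1$series$stock_Mg[1], g4$series$stock_Mg[1])
  ny <- length(years)
  expect_gt(g1$series$stock_Mg[ny], g4$series$stock_Mg[ny])
  new_forest_sink <- g1$series$stock_Mg[ny] - g4$series$stock_Mg[ny]
  expect_gt(new_forest_sink, 0)
})

test_that("annual mass balance closes and class series sum to the national total", {
  sp <- gen_species_table(3, seed = 91)
  land <- gen_landscape(sp, 6, 8, seed = 92)
  plan <- gen_forestation_plan(unique(land$cells$province), 50, 2021, 2040,
                               seed = 93)
  suit <- gen_suitability_maps(sp, land, seed = 94)
  res <- run_simulation(land, sp, scenario_config(group = 1, seed = 7),
                        plan, suit, years = 2020:2060)
  expect_true(all(res$mass_balance$residual_rel <= 1e-9))
  cls <- as.matrix(res$series[, paste0("stock_", c(
    "natural_nontimber", "natural_timber",
    "planted_nontimber", "planted_timber"))])
  expect_equal(unname(rowSums(cls)), res$series$stock_Mg, tolerance = 1e-9)
  expect_equal(unname(rowSums(res$by_species)), res$series$stock_Mg,
               tolerance = 1e-9)
  expect_equal(unname(rowSums(res$cell_sink_Mg[-1, ])),
               res$series$sink_Mg[-1], tolerance = 1e-6)
})

test_that("scenario configs validate management and delay combinations", {
  expect_error(scenario_config(delay_yr = 5), class = "fc_input_error")
  expect_error(scenario_config(group = 1, rotation_extension_yr = 5),
               class = "fc_input_error")
  cfg <- scenario_config(group = 2, rotation_extension_yr = 5, delay_yr = 10)
  expect_s3_class(cfg, "fc_scenario_config")
  expect_error(scenario_config(group = 7))
})
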