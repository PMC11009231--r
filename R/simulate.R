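## Annual simulation driver --------------------------------------------------

cohort_stock_Mg <- function(cohorts) sum(cohorts$carbon_density) * HA_PER_KM2

class_key <- function(cohorts) paste(cohorts$origin, cohorts$mgmt, sep = "_")
CLASS_LEVELS <- c("natural_nontimber", "natural_timber",
                  "planted_nontimber", "planted_timber")

stock_by <- function(cohorts, key, levels) {
  v <- tapply(cohorts$carbon_density * HA_PER_KM2, factor(key, levels), sum)
  v[is.na(v)] <- 0
  as.numeric(v)
}

#' Run one cohort simulation
#'
#' Executes the annual loop over the simulation horizon:
#' growth -> mortality -> harvest (off in group 3) -> management
#' interventions (group 2, honoring the implementation delay) ->
#' wood-product inflow -> age accrual -> forestation (off in group 4).
#' Carbon is tracked per species, per (origin x management) class and per
#' grid cell; a strict annual mass balance
#' (delta stock = growth - harvest - mortality - replacement) is enforced
#' to 1e-9 relative and any violation aborts the run.
#'
#' Harvested and replaced carbon feeds the IPCC Tier-2 wood-product pool,
#' projected after the loop from the removal series (the pool does not feed
#' back on the forest).
#'
#' @param landscape an `fc_landscape` (initial 2020 state).
#' @param species species table.
#' @param config an `fc_scenario_config`.
#' @param plan forestation plan from [gen_forestation_plan()] (optional).
#' @param suitability suitability matrix (required when `plan` is given).
#' @param ratio_series wood-product ratio series; defaults to fixed 2020
#'   shares over the horizon.
#' @param years simulation years (default 2020:2100).
#' @param a_override optional named per-species calibrated age-factor `a`.
#' @return an object of class `fc_sim`; see Details.  Main components:
#'   `series` (annual national stocks, sinks and fluxes in Mg C, plus the
#'   four class stocks), `by_species` and `species_sink` matrices,
#'   `cell_sink_Mg` and `cell_sink_gm2` (years x cells), `key_years`,
#'   `pool` (wood-product series, Tg C), `mass_balance`, `config`.
#' @export
run_simulation <- function(landscape, species, config = scenario_config(),
                           plan = NULL, suitability = NULL,
                           ratio_series = NULL, years = 2020:2100,
                           a_override = NULL) {
  stopifnot(inherits(landscape, "fc_landscape"),
            inherits(config, "fc_scenario_config"))
  validate_species_table(species)
  do_harvest <- config$group != 3
  do_expand  <- config$group != 4 && !is.null(plan)
  if (do_expand && is.null(suitability))
    stop_input("suitability maps required when a forestation plan is given")
  seed <- config$seed
  ny <- length(years)
  n_sp <- nrow(species)
  cells <- landscape$cells$cell_id
  sp_ids <- species$species_id

  by_species <- matrix(0, ny, n_sp, dimnames = list(years, sp_ids))
  by_class   <- matrix(0, ny, 4, dimnames = list(years, CLASS_LEVELS))
  cell_stock <- matrix(0, ny, length(cells), dimnames = list(years, cells))
  cell_units <- matrix(0, ny, length(cells), dimnames = list(years, cells))
  flows <- data.frame(year = years, stock_Mg = 0, sink_Mg = 0,
                      growth_Mg = 0, mortality_Mg = 0, harvest_Mg = 0,
                      replacement_Mg = 0, units_cut = 0L, mortality_events = 0L,
                      planted_units = 0L, attempted_units = 0L,
                      shortfall_units = 0L)
  balance <- data.frame(year = years, residual_rel = 0)

  sp_of <- function(co) match(co$species_id, sp_ids)
  prev_total <- cohort_stock_Mg(landscape$cohorts)
  prev_sp <- stock_by(landscape$cohorts,
                      factor(landscape$cohorts$species_id, sp_ids), sp_ids)
  key_year <- stats::setNames(rep(NA_real_, n_sp), sp_ids)
  ext_active_from <- stats::setNames(rep(Inf, n_sp), sp_ids)
  species_sink <- matrix(NA_real_, ny, n_sp, dimnames = list(years, sp_ids))
  # the landscape enters 2020 mid-rotation, not phase-aligned: initialize
  # each (cell, species) allowable-cut carryover uniformly in [0, 1)
  harvest_carry <- local({
    co0 <- landscape$cohorts
    keys <- unique(paste(co0$cell_id, co0$species_id,
                         sep = "|")[co0$mgmt == "timber"])
    if (length(keys) == 0) NULL else
      with_substream("harvest_phase", seed, NULL,
        stats::setNames(as.list(stats::runif(length(keys))), keys))
  })
  plant_carry <- NULL
  w <- config$key_year_window

  for (ti in seq_len(ny)) {
    t <- years[ti]
    co <- landscape$cohorts

    ## 1. growth
    inc <- step_growth(co, species, config$growth_modifier, a_override)
    landscape$cohorts$carbon_density <- co$carbon_density + inc
    flows$growth_Mg[ti] <- sum(inc) * HA_PER_KM2

    ## 2. mortality (per-species baseline rates)
    rates <- species$mortality_rate[sp_of(landscape$cohorts)]
    m <- with_substream("mortality", seed, t,
      apply_mortality(landscape, rates, config$mortality_multiplier))
    landscape <- m$landscape
    flows$mortality_Mg[ti] <- m$emitted_Mg
    flows$mortality_events[ti] <- m$n_events

    ## 3. harvest with allowable-cut cap (skipped in group 3)
    if (do_harvest) {
      ext <- stats::setNames(ifelse(t >= ext_active_from,
                                    config$rotation_extension_yr, 0), sp_ids)
      h <- harvest(landscape, species, ext, harvest_carry)
      landscape <- h$landscape
      harvest_carry <- h$carryover
      flows$harvest_Mg[ti] <- h$removed_Mg
      flows$units_cut[ti] <- h$units_cut
    }

    ## 4. species replacement (group 2, at replacement_year + delay)
    if (config$group == 2 && config$replacement_enabled &&
        t == config$replacement_year + config$delay_yr) {
      r <- with_substream("replacement", seed, t,
        replace_species(landscape, species, config$replacement_area_km2))
      landscape <- r$landscape
      flows$replacement_Mg[ti] <- r$removed_Mg
    }

    ## 5. age accrual
    landscape <- with_substream("aging", seed, t,
      increment_ages(landscape, species, fixed = config$fixed_age_increment))

    ## 6. forestation deployment (skipped in group 4)
    if (do_expand) {
      rows <- plan[plan$year == t, , drop = FALSE]
      if (nrow(rows)) {
        d <- with_substream("planting", seed, t,
          deploy_forestation(landscape, species, rows, suitability,
                             config$survival_rate, carry = plant_carry))
        landscape <- d$landscape
        plant_carry <- d$carry
        flows$planted_units[ti] <- d$established_units
        flows$attempted_units[ti] <- d$attempted_units
        flows$shortfall_units[ti] <- d$shortfall_units
      }
    }

    ## 7. accounting
    co <- landscape$cohorts
    total <- cohort_stock_Mg(co)
    flows$stock_Mg[ti] <- total
    flows$sink_Mg[ti] <- total - prev_total
    by_species[ti, ] <- stock_by(co, factor(co$species_id, sp_ids), sp_ids)
    by_class[ti, ] <- stock_by(co, factor(class_key(co), CLASS_LEVELS),
                               CLASS_LEVELS)
    cs <- stock_by(co, factor(co$cell_id, cells), cells)
    cell_stock[ti, ] <- cs
    cell_units[ti, ] <- as.numeric(table(factor(co$cell_id, cells)))
    species_sink[ti, ] <- by_species[ti, ] - prev_sp

    ## mass balance: delta stock = growth - mortality - harvest - replacement
    expected <- flows$growth_Mg[ti] - flows$mortality_Mg[ti] -
      flows$harvest_Mg[ti] - flows$replacement_Mg[ti]
    res <- abs((total - prev_total) - expected) / max(total, 1)
    balance$residual_rel[ti] <- res
    if (res > 1e-9)
      stop("mass-balance violation in year ", t, ": relative residual ",
           signif(res, 3))

    ## key-year detection (drives the rotation-extension practice)
    if (ti >= w) {
      for (si in seq_len(n_sp)) {
        s <- sp_ids[si]
        if (!is.na(key_year[s])) next
        win <- species_sink[(ti - w + 1):ti, si]
        if (all(win <= 0)) {
          key_year[s] <- years[ti - w + 1]
          # practice implemented at key year + delay, never before detection
          ext_active_from[s] <- max(key_year[s] + config$delay_yr, t + 1)
        }
      }
    }
    prev_total <- total
    prev_sp <- by_species[ti, ]
  }

  cell_sink <- rbind(cell_stock[1, , drop = FALSE] * NA,
                     diff(cell_stock))
  cell_sink[1, ] <- NA
  # Mg per cell-year over the cell's forested area (units x 1 km2):
  # 1 Mg / 1 km2 = 1e6 g / 1e6 m2 = 1 g m-2, so g C m-2 yr-1 = Mg / units
  cell_sink_gm2 <- cell_sink / pmax(cell_units, 1)

  inflow_Tg <- (flows$harvest_Mg + flows$replacement_Mg) * 1e-6
  if (is.null(ratio_series))
    ratio_series <- gen_product_ratio_series(years[1], years[ny], "fixed")
  pool <- project_pool(data.frame(year = years, inflow = inflow_Tg),
                       ratio_series,
                       C0 = "steady_first_decade")

  structure(list(
    series = cbind(flows,
                   stats::setNames(as.data.frame(by_class),
                                   paste0("stock_", CLASS_LEVELS))),
    by_species = by_species, species_sink = species_sink,
    cell_sink_Mg = cell_sink, cell_sink_gm2 = cell_sink_gm2,
    cell_units = cell_units, key_years = key_year,
    pool = pool, mass_balance = balance, config = config,
    years = years, landscape = landscape), class = "fc_sim")
}

#' @export
print.fc_sim <- function(x, ...) {
  s <- x$series
  ny <- nrow(s)
  cat(sprintf("Cohort simulation, group %d (%s), %d-%d, seed %d\n",
              x$config$group, x$config$ssp_label, x$years[1], x$years[ny],
              x$config$seed))
  cat(sprintf("  cohorts: %d -> %d (1 km2 units)\n",
              sum(x$cell_units[1, ]), sum(x$cell_units[ny, ])))
  cat(sprintf("  biomass stock: %.2f -> %.2f Tg C (net %+.2f Tg C)\n",
              s$stock_Mg[1] * 1e-6, s$stock_Mg[ny] * 1e-6,
              (s$stock_Mg[ny] - s$stock_Mg[1]) * 1e-6))
  cat(sprintf("  mean sink: %.3f Tg C/yr; peak sink year (5-yr mean): %d\n",
              mean(s$sink_Mg) * 1e-6, peak_year(s$sink_Mg, x$years)))
  cat(sprintf("  harvested: %.2f Tg C; product pool %d: %.3f Tg C\n",
              sum(s$harvest_Mg) * 1e-6, x$years[ny],
              x$pool$total[nrow(x$pool)]))
  kk <- x$key_years[!is.na(x$key_years)]
  if (length(kk))
    cat("  key years: ",
        paste(sprintf("%s=%d", names(kk), kk), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fc_sim <- function(object, ...) {
  s <- object$series
  ny <- nrow(s)
  cls <- grep("^stock_", names(s), value = TRUE)
  cls <- setdiff(cls, "stock_Mg")
  out <- data.frame(
    class = sub("^stock_", "", cls),
    stock_2020_Tg = as.numeric(s[1, cls]) * 1e-6,
    stock_end_Tg = as.numeric(s[ny, cls]) * 1e-6)
  out$change_Tg <- out$stock_end_Tg - out$stock_2020_Tg
  out$share_of_change <- out$change_Tg / sum(out$change_Tg)
  out
}

#' @export
plot.fc_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$years, x$series$stock_Mg * 1e-6, type = "l",
                 xlab = "year", ylab = "stock (Tg C)",
                 main = "Forest biomass carbon stock", ...)
  graphics::plot(x$years, x$series$sink_Mg * 1e-6, type = "l",
                 xlab = "year", ylab = "sink (Tg C/yr)",
                 main = "Annual biomass carbon sink", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Peak year of a sink series
#'
#' Smooths an annual sink series with a centered moving average and returns
#' the argmax year (ties broken by the earliest year).
#'
#' @param sink numeric vector of annual sinks (leading `NA` allowed).
#' @param years matching calendar years.
#' @param window moving-average window in years (default 5).
#' @return the peak year (integer).
#' @export
peak_year <- function(sink, years, window = 5) {
  ok <- !is.na(sink)
  sm <- stats::filter(sink, rep(1 / window, window), sides = 2)
  sm[!ok] <- NA
  cand <- which(sm == max(sm, na.rm = TRUE))
  as.integer(years[cand[1]])
}
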