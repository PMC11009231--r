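## Annual age-cohort landscape simulator ------------------------------------
##
## The process-emulation core.  Each 1-km2 cohort carries (species, age,
## carbon density, management class); the annual loop applies growth along
## the species stock--age curve modulated by the normalized age factor,
## stochastic stand mortality, policy-constrained harvest with an
## allowable-cut cap, wood-product inflow, age accrual (survey-derived for
## mixed non-timber stands), provincial forestation deployment, and the two
## management interventions.  Every stochastic operation draws from its own
## (operation, year)-keyed sub-stream so that toggling one process never
## perturbs another's draws.
##
## Units: carbon density is Mg C/ha; one cohort is 1 km2 = 100 ha, so a
## cohort holds density * 100 Mg C.

HA_PER_KM2 <- 100

#' Scenario configuration
#'
#' Bundles the experiment-group switches.  Group 1 is the realistic
#' baseline (harvest + forestation, no interventions); group 2 adds the
#' improved management practices (rotation extension after the key year
#' and/or species replacement, possibly delayed); group 3 switches wood
#' harvest off (optionally also forcing +1/yr age accrual, the
#' statistical-model-style assumption); group 4 freezes land use (no
#' forestation).
#'
#' @param group experiment group 1--4.
#' @param ssp_label scenario label (`"SSP1"`, `"SSP2"`, `"SSP3"`, `"SSP5"`),
#'   carried into `growth_modifier`/`mortality_multiplier` defaults.
#' @param survival_rate planting survival fraction (baseline 0.47,
#'   improved 0.85).
#' @param mortality_multiplier multiplier on the baseline stand mortality
#'   rate (1--5; climate-stress emulation).
#' @param rotation_extension_yr harvest-age extension after the key year
#'   (0 or 5), group 2 only.
#' @param replacement_enabled replace flagged species in the replacement
#'   year, group 2 only.
#' @param delay_yr delay of both management practices (0/5/10/15), only
#'   meaningful when a management flag is on.
#' @param growth_modifier multiplicative scenario modifier on annual growth
#'   (SSP emulation; 1 = none).
#' @param fixed_age_increment force every cohort to age exactly +1/yr
#'   (ignoring survey-derived accrual in mixed non-timber stands).
#' @param replacement_year calendar year of the species-replacement
#'   intervention before any delay (default 2025).
#' @param replacement_area_km2 area cap on replacement (default 41300 km2,
#'   i.e. 4.13 Mha, scaled down by callers on desk-scale landscapes).
#' @param key_year_window consecutive non-positive-sink years required to
#'   declare a key year (default 3).
#' @param seed integer seed for all stochastic sub-streams.
#' @return an object of class `fc_scenario_config` (a validated list).
#' @export
scenario_config <- function(group = 1, ssp_label = "SSP2",
                            survival_rate = 0.47, mortality_multiplier = 1,
                            rotation_extension_yr = 0,
                            replacement_enabled = FALSE, delay_yr = 0,
                            growth_modifier = 1,
                            fixed_age_increment = FALSE,
                            replacement_year = 2025,
                            replacement_area_km2 = 41300,
                            key_year_window = 3, seed = 1L) {
  stopifnot(group %in% 1:4, ssp_label %in% c("SSP1", "SSP2", "SSP3", "SSP5"))
  check_scalar_num(survival_rate, "survival_rate", lower = 0, upper = 1)
  check_scalar_num(mortality_multiplier, "mortality_multiplier", lower = 0)
  check_scalar_num(growth_modifier, "growth_modifier", lower = 0)
  stopifnot(delay_yr %in% c(0, 5, 10, 15))
  mgmt_on <- rotation_extension_yr > 0 || replacement_enabled
  if (delay_yr > 0 && !mgmt_on)
    stop_input("delay_yr applies only when a management practice is enabled")
  if (mgmt_on && group != 2)
    stop_input("management practices require group = 2")
  structure(list(group = group, ssp_label = ssp_label,
                 survival_rate = survival_rate,
                 mortality_multiplier = mortality_multiplier,
                 rotation_extension_yr = rotation_extension_yr,
                 replacement_enabled = replacement_enabled,
                 delay_yr = delay_yr, growth_modifier = growth_modifier,
                 fixed_age_increment = fixed_age_increment,
                 replacement_year = replacement_year,
                 replacement_area_km2 = replacement_area_km2,
                 key_year_window = key_year_window,
                 seed = as.integer(seed)),
            class = "fc_scenario_config")
}

## per-cohort annual growth increment ---------------------------------------

#' Annual cohort growth step
#'
#' Computes each cohort's carbon-density increment as the species stock--age
#' curve increment at the cohort's age, modulated by the age factor
#' normalized at the harvest age (so curve shape and age factor are not
#' double-counted), times the scenario growth modifier:
#' `dC = [curve(age+1) - curve(age)] * F(age) / F(Age2) * modifier`.
#'
#' @param cohorts cohort table (columns `species_id`, `age_yr`,
#'   `carbon_density`).
#' @param species species table.
#' @param growth_modifier scenario multiplier (>= 0).
#' @param a_override optional named per-species replacement for the
#'   species-table `age_factor_a` (from calibration).
#' @return numeric vector of density increments (Mg C/ha), >= 0.
#' @export
step_growth <- function(cohorts, species, growth_modifier = 1,
                        a_override = NULL) {
  check_scalar_num(growth_modifier, "growth_modifier", lower = 0)
  inc <- numeric(nrow(cohorts))
  for (s in unique(cohorts$species_id)) {
    sp <- species[species$species_id == s, ]
    if (nrow(sp) != 1) stop_input("species not in table: ", s)
    i <- which(cohorts$species_id == s)
    cv <- species_curve(sp)
    a <- if (!is.null(a_override) && s %in% names(a_override))
      a_override[[s]] else sp$age_factor_a
    raw <- curve_increment(cv$family, cv$params, cohorts$age_yr[i])
    f <- age_factor(a, sp$age1_years, cohorts$age_yr[i]) /
      age_factor(a, sp$age1_years, sp$age2_years)
    inc[i] <- raw * f * growth_modifier
  }
  inc
}

#' Stochastic stand mortality
#'
#' Each cohort independently dies with probability
#' `base_rate * multiplier`; a dying cohort's carbon is emitted to the
#' atmosphere and the stand regenerates in place (age 0, density 0, same
#' species and class).
#'
#' @param landscape an `fc_landscape`.
#' @param base_rate annual per-stand mortality probability (national
#'   baseline 0.00084, i.e. 0.084%); a scalar or a per-cohort vector (e.g.
#'   species-specific rates).
#' @param multiplier scenario multiplier (1--5); the product must be a
#'   probability.
#' @param seed optional seed; when given, draws come from the `"mortality"`
#'   sub-stream of that seed, otherwise from the current RNG state.
#' @return list: `landscape`, `emitted_Mg` (carbon to atmosphere),
#'   `n_events`.
#' @export
apply_mortality <- function(landscape, base_rate = 0.00084, multiplier = 1,
                            seed = NULL) {
  p <- base_rate * multiplier
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_input("mortality probability must be in [0, 1]")
  if (length(p) != 1L && length(p) != nrow(landscape$cohorts))
    stop_input("base_rate must be scalar or one per cohort")
  draw <- function() stats::runif(nrow(landscape$cohorts)) < p
  die <- if (is.null(seed)) draw() else
    with_substream("mortality", seed, NULL, draw())
  emitted <- sum(landscape$cohorts$carbon_density[die]) * HA_PER_KM2
  landscape$cohorts$age_yr[die] <- 0
  landscape$cohorts$carbon_density[die] <- 0
  list(landscape = landscape, emitted_Mg = emitted, n_events = sum(die))
}

#' Annual age accrual
#'
#' Timber cohorts and pure (unmixed) non-timber cohorts age exactly +1 year
#' (fixed rotation bookkeeping); mixed non-timber cohorts age by a draw from
#' `N(inc_mean, inc_sd^2)` truncated at 0, the survey-derived accrual that
#' reflects mortality, regeneration and natural growth within the stand.
#'
#' @param landscape an `fc_landscape`.
#' @param species species table (per-species `inc_mean`, `inc_sd`).
#' @param seed optional seed for the `"aging"` sub-stream.
#' @param fixed force +1/yr for every cohort (scenario switch).
#' @return the aged landscape.
#' @export
increment_ages <- function(landscape, species, seed = NULL, fixed = FALSE) {
  co <- landscape$cohorts
  if (fixed) {
    co$age_yr <- co$age_yr + 1
    landscape$cohorts <- co
    return(landscape)
  }
  step <- rep(1, nrow(co))
  mixed <- co$mgmt == "nontimber" & co$mixed_flag
  if (any(mixed)) {
    im <- species$inc_mean[match(co$species_id[mixed], species$species_id)]
    is <- species$inc_sd[match(co$species_id[mixed], species$species_id)]
    draw <- function() pmax(0, stats::rnorm(sum(mixed), im, is))
    step[mixed] <- if (is.null(seed)) draw() else
      with_substream("aging", seed, NULL, draw())
  }
  co$age_yr <- co$age_yr + step
  landscape$cohorts <- co
  landscape
}

#' Policy-constrained timber harvest
#'
#' Harvests only mature timber cohorts (age >= harvest age `Age2` plus any
#' rotation extension), oldest first, and caps the number of units cut per
#' (cell, species, year) at the allowable cut: total timber units of the
#' species in the cell divided by the rotation length, with fractional
#' allowance carried over (capped below one unit) so the long-run cut rate
#' equals area/rotation.  Harvested cohorts are replanted in place (age 0,
#' density 0, same species and classes); removed carbon is routed to the
#' wood-product pool by the caller.
#'
#' @param landscape an `fc_landscape`.
#' @param species species table (`age2_years` defines the rotation).
#' @param extension_yr rotation extension in years: scalar or named vector
#'   by species id (0 when the key year has not passed).
#' @param carryover named numeric vector of fractional allowances from the
#'   previous year (keys `cell|species`), or NULL on the first year.
#' @return list: `landscape`, `removed_Mg`, `units_cut`, updated
#'   `carryover`.
#' @export
harvest <- function(landscape, species, extension_yr = 0, carryover = NULL) {
  co <- landscape$cohorts
  ext_of <- function(s) {
    if (length(extension_yr) == 1L && is.null(names(extension_yr)))
      return(extension_yr)
    if (s %in% names(extension_yr)) extension_yr[[s]] else 0
  }
  timber <- co$mgmt == "timber"
  removed <- 0; cut_total <- 0L
  if (is.null(carryover)) carryover <- numeric(0)
  if (any(timber)) {
    key <- paste(co$cell_id, co$species_id, sep = "|")
    for (g in unique(key[timber])) {
      i <- which(key == g & timber)
      s <- co$species_id[i[1]]
      sp <- species[species$species_id == s, ]
      rot <- sp$age2_years + ext_of(s)
      carry <- if (g %in% names(carryover)) carryover[[g]] else 0
      allow <- length(i) / rot + carry
      mature <- i[co$age_yr[i] >= rot]
      n_cut <- min(floor(allow), length(mature))
      if (n_cut > 0) {
        # oldest first; ties by creation index (cohort_id)
        ord <- mature[order(-co$age_yr[mature], co$cohort_id[mature])]
        cut <- ord[seq_len(n_cut)]
        removed <- removed + sum(co$carbon_density[cut]) * HA_PER_KM2
        co$age_yr[cut] <- 0
        co$carbon_density[cut] <- 0
        cut_total <- cut_total + n_cut
      }
      carryover[[g]] <- min(allow - n_cut, 1 - 1e-12)
    }
  }
  landscape$cohorts <- co
  list(landscape = landscape, removed_Mg = removed,
       units_cut = cut_total, carryover = carryover)
}

#' Detect the key year of a sink series
#'
#' The key year is the first year whose annual sink is non-positive and
#' stays non-positive for `window` consecutive years -- the year the carbon
#' sink plummets, triggering the rotation-extension practice.
#'
#' @param sink numeric vector of annual sinks.
#' @param years matching calendar years.
#' @param window consecutive non-positive years required (default 3).
#' @return the key year, or `NA` if the sink never collapses.
#' @export
detect_key_year <- function(sink, years, window = 3) {
  ok <- !is.na(sink)
  nonpos <- sink <= 0 & ok
  n <- length(sink)
  if (n < window) return(NA_real_)
  for (t in seq_len(n - window + 1))
    if (all(nonpos[t:(t + window - 1)])) return(years[t])
  NA_real_
}

#' Replace inappropriate species by their indigenous targets
#'
#' Converts up to `target_area_km2` one-km2 non-timber units of species
#' flagged with a `replacement_target` into that target species at age 0
#' and density 0; the standing carbon of replaced cohorts is removed and
#' routed to the wood-product pool by the caller.  Unit count is conserved.
#' The practice targets non-timber forests only (timber stands are managed
#' through the rotation instead).
#'
#' @param landscape an `fc_landscape`.
#' @param species species table (`replacement_target` column).
#' @param target_area_km2 area cap (units are 1 km2 each).
#' @param seed optional seed for the `"replacement"` sub-stream (selection
#'   among flagged cohorts when the cap binds).
#' @return list: `landscape`, `removed_Mg`, `units_replaced`.
#' @export
replace_species <- function(landscape, species, target_area_km2,
                            seed = NULL) {
  co <- landscape$cohorts
  flagged_sp <- species$species_id[!is.na(species$replacement_target)]
  idx <- which(co$species_id %in% flagged_sp & co$mgmt == "nontimber")
  n <- min(length(idx), floor(target_area_km2))
  if (n == 0)
    return(list(landscape = landscape, removed_Mg = 0, units_replaced = 0L))
  pick <- if (n < length(idx)) {
    draw <- function() sample(idx, n)
    if (is.null(seed)) draw() else with_substream("replacement", seed, NULL, draw())
  } else idx
  tgt <- species$replacement_target[match(co$species_id[pick],
                                          species$species_id)]
  if (anyNA(tgt) || !all(tgt %in% species$species_id))
    stop_input("missing replacement_target for species: ",
               paste(unique(co$species_id[pick][is.na(tgt)]), collapse = ", "))
  removed <- sum(co$carbon_density[pick]) * HA_PER_KM2
  co$species_id[pick] <- tgt
  co$age_yr[pick] <- 0
  co$carbon_density[pick] <- 0
  landscape$cohorts <- co
  list(landscape = landscape, removed_Mg = removed,
       units_replaced = as.integer(n))
}

#' Deploy one year of the forestation plan
#'
#' For each province, converts the planned area (plus fractional carryover
#' from earlier years) into whole 1-km2 planting attempts, fills cells in
#' descending suitability order (each cell planted with its most suitable
#' species), and establishes each attempted unit with probability
#' `survival_rate`.  Established units become age-0 cohorts and decrement
#' the cell's grassland/shrubland budget; failed plantings revert.
#' Planting stops when the provincial land budget is exhausted; the
#' shortfall is recorded.
#'
#' @param landscape an `fc_landscape`.
#' @param species species table.
#' @param plan_rows the plan rows of the current year (province, area_km2).
#' @param suitability cell x species suitability matrix
#'   (from [gen_suitability_maps()]).
#' @param survival_rate establishment probability (0.47 baseline / 0.85
#'   improved).
#' @param seed optional seed for the `"planting"` sub-stream.
#' @param carry named per-province fractional area carried from previous
#'   years.
#' @return list: `landscape`, `established_units`, `attempted_units`,
#'   `shortfall_units`, updated `carry`.
#' @export
deploy_forestation <- function(landscape, species, plan_rows, suitability,
                               survival_rate, seed = NULL, carry = NULL) {
  check_scalar_num(survival_rate, "survival_rate", lower = 0, upper = 1)
  if (is.null(carry)) carry <- numeric(0)
  run <- function() {
    cells <- landscape$cells
    co <- landscape$cohorts
    next_id <- if (nrow(co)) max(co$cohort_id) + 1L else 1L
    established <- attempted <- shortfall <- 0L
    new_rows <- list()
    for (j in seq_len(nrow(plan_rows))) {
      prov <- plan_rows$province[j]
      tot <- plan_rows$area_km2[j] +
        (if (prov %in% names(carry)) carry[[prov]] else 0)
      units <- floor(tot)
      carry[[prov]] <<- tot - units
      if (units == 0) next
      ci <- which(cells$province == prov)
      if (length(ci) == 0) { shortfall <- shortfall + units; next }
      # priority: cells by their best suitability, descending
      best_sp <- colnames(suitability)[
        apply(suitability[ci, , drop = FALSE], 1, which.max)]
      ord <- order(-apply(suitability[ci, , drop = FALSE], 1, max))
      planted <- 0L
      for (k in ord) {
        if (planted >= units) break
        cell <- ci[k]
        budget <- cells$grassland_shrubland_km2[cell]
        while (planted < units && budget >= 1) {
          planted <- planted + 1L
          attempted <- attempted + 1L
          if (stats::runif(1) < survival_rate) {
            s <- best_sp[k]
            sp <- species[species$species_id == s, ]
            budget <- budget - 1
            established <- established + 1L
            new_rows[[length(new_rows) + 1L]] <- data.frame(
              cohort_id = next_id, cell_id = cells$cell_id[cell],
              species_id = s, age_yr = 0, area_km2 = 1, carbon_density = 0,
              mgmt = if (stats::runif(1) < sp$timber_fraction) "timber"
                     else "nontimber",
              origin = "planted", mixed_flag = FALSE,
              stringsAsFactors = FALSE)
            next_id <- next_id + 1L
          }
        }
        cells$grassland_shrubland_km2[cell] <- budget
      }
      if (planted < units) shortfall <- shortfall + (units - planted)
    }
    if (length(new_rows))
      co <- rbind(co, do.call(rbind, new_rows))
    landscape$cells <- cells
    landscape$cohorts <- co
    list(landscape = landscape, established_units = established,
         attempted_units = attempted, shortfall_units = shortfall,
         carry = carry)
  }
  if (is.null(seed)) run() else with_substream("planting", seed, NULL, run())
}
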