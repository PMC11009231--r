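## Packaged example study landscape ------------------------------------------
##
## A deterministic desk-scale landscape whose structure mirrors the study
## system: a staggered-rotation pine timber estate, a mature fir timber
## block entering its harvest wave, a dominant young mixed-conifer
## non-timber block whose survey-derived age accrual is well below 1 yr/yr,
## a flagged short-rotation plantation species with an indigenous
## slow-growing replacement target, and an official provincial forestation
## plan with suitability-priority planting.  Used by the vignette and the
## package's end-to-end property tests.

#' Example species table for the packaged study landscape
#'
#' Five species groups with self-consistent demography: for the Richards
#' curves the shape is m = 3 and the rate k = ln(3)/Age1, which places the
#' instantaneous growth peak exactly at `age1_years`; the harvest age
#' `age2_years` (the peak of the mean accumulated growth rate) then falls
#' at about 1.74 x Age1.  The eucalypt group is flagged as inappropriate
#' with the slow-growing spruce group as its indigenous replacement.
#'
#' @return a species table, see [gen_species_table()] for the schema.
#' @export
example_species <- function() {
  tab <- data.frame(
    species_id = c("pine_fast", "fir", "mixed_conifer", "spruce_slow",
                   "euc_flag"),
    vb_slope = c(0.7, 0.65, 0.68, 0.6, 0.8),
    vb_intercept = c(0.2, 0.3, 0.25, 0.25, 0.1),
    carbon_fraction = c(0.51, 0.50, 0.50, 0.50, 0.47),
    age1_years = c(18, 26, 30, 45, 8),
    age2_years = c(31, 45, 52, 78, 14),
    age_factor_a = 0.05,
    mortality_rate = 0.00084,
    timber_fraction = c(0.75, 0.67, 0, 0, 0),
    inc_mean = c(1, 0.9, 0.6, 0.85, 0.9),
    inc_sd = c(0.2, 0.3, 0.4, 0.3, 0.3),
    curve_family = "richards",
    curve_p1 = c(90, 110, 120, 140, 60),
    curve_p2 = log(3) / c(18, 26, 30, 45, 8),
    curve_p3 = 3,
    replacement_target = c(NA, NA, NA, NA, "spruce_slow"),
    stringsAsFactors = FALSE)
  validate_species_table(tab)
  tab
}

#' Packaged example landscape, plan and suitability maps
#'
#' Builds the deterministic study landscape: each cell holds 3 staggered
#' pine timber units (rotation 31), 3 just-mature fir timber units
#' (rotation 45), 12 young mixed-conifer non-timber units (ages 5--15,
#' aging by survey-derived increments), 2 flagged eucalypt units and one
#' old spruce unit, plus a grassland/shrubland budget of 40 km2.  The
#' forestation plan deploys 300 km2 across the five provinces over
#' 2021--2050.
#'
#' @param n_cells number of 0.5-degree grid cells (default 50).
#' @param seed seed for the plan weights and suitability maps.
#' @return list with `species`, `landscape`, `plan`, `suitability`.
#' @export
example_inputs <- function(n_cells = 50, seed = 2024) {
  sp <- example_species()
  rows <- vector("list", n_cells)
  mk <- function(species_id, age, mgmt, origin, mixed)
    data.frame(species_id = species_id, age_yr = age, mgmt = mgmt,
               origin = origin, mixed_flag = mixed, stringsAsFactors = FALSE)
  for (c0 in seq_len(n_cells)) {
    rows[[c0]] <- cbind(cell_id = c0, rbind(
      mk("pine_fast", 3 + ((c0 * 7 + c(0, 12, 24)) %% 36),
         "timber", "planted", FALSE),
      mk("fir", 44 + (c0 %% 3) + c(0, 1, 2), "timber", "natural", FALSE),
      mk("mixed_conifer", 5 + ((c0 * 3 + 0:11) %% 11),
         "nontimber", "natural", TRUE),
      mk("euc_flag", 2 + ((c0 * 5 + c(0, 5)) %% 10),
         "nontimber", "planted", TRUE),
      mk("spruce_slow", 55 + (c0 %% 10), "nontimber", "natural", FALSE)))
  }
  co <- do.call(rbind, rows)
  co$cohort_id <- seq_len(nrow(co))
  co$area_km2 <- 1
  cv <- lapply(split(sp, sp$species_id), species_curve)
  co$carbon_density <- vapply(seq_len(nrow(co)), function(i) {
    cc <- cv[[co$species_id[i]]]
    eval_curve(cc$family, cc$params, max(co$age_yr[i], 1))
  }, numeric(1))
  ncol_g <- ceiling(sqrt(n_cells))
  idx <- seq_len(n_cells) - 1L
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    row = idx %/% ncol_g, col = idx %% ncol_g,
    lat = 20 + 0.5 * (idx %/% ncol_g), lon = 100 + 0.5 * (idx %% ncol_g),
    province = sprintf("prov%d", (idx %% 5) + 1),
    grassland_shrubland_km2 = 40, stringsAsFactors = FALSE)
  land <- structure(list(
    cells = cells,
    cohorts = co[, c("cohort_id", "cell_id", "species_id", "age_yr",
                     "area_km2", "carbon_density", "mgmt", "origin",
                     "mixed_flag")],
    grid = c(nrow = max(cells$row) + 1L, ncol = ncol_g)),
    class = "fc_landscape")
  list(species = sp, landscape = land,
       plan = gen_forestation_plan(unique(cells$province), 300, 2021, 2050,
                                   seed = seed),
       suitability = gen_suitability_maps(sp, land, seed = seed))
}
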