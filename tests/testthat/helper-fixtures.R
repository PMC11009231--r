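# Shared fixtures, all generated in code at test time.

# a deterministic single-species table with hand-picked parameters, so
# expected values in tests can be computed by hand
manual_species <- function(curve_family = "richards",
                           A = 100, k = 0.1, m = 2,
                           age1 = 20, age2 = 40,
                           vb_slope = 0.6, vb_intercept = 0,
                           carbon_fraction = 0.5,
                           mortality = 0.00084, timber_fraction = 1,
                           inc_mean = 1, inc_sd = 0, a = 0.05,
                           species_id = "spX",
                           replacement_target = NA_character_) {
  data.frame(species_id = species_id, vb_slope = vb_slope,
             vb_intercept = vb_intercept, carbon_fraction = carbon_fraction,
             age1_years = age1, age2_years = age2, age_factor_a = a,
             mortality_rate = mortality, timber_fraction = timber_fraction,
             inc_mean = inc_mean, inc_sd = inc_sd,
             curve_family = curve_family,
             curve_p1 = A, curve_p2 = k, curve_p3 = m,
             replacement_target = replacement_target,
             stringsAsFactors = FALSE)
}

# a minimal hand-built landscape: one province, explicit cohorts
manual_landscape <- function(cohorts, grass_km2 = 1000, n_cells = 1,
                             province = "prov1") {
  cells <- data.frame(cell_id = seq_len(n_cells),
                      row = 0, col = seq_len(n_cells) - 1L,
                      lat = 30, lon = 100 + 0.5 * (seq_len(n_cells) - 1L),
                      province = province,
                      grassland_shrubland_km2 = grass_km2,
                      stringsAsFactors = FALSE)
  if (is.null(cohorts$cohort_id)) cohorts$cohort_id <- seq_len(nrow(cohorts))
  if (is.null(cohorts$area_km2)) cohorts$area_km2 <- 1
  if (is.null(cohorts$mixed_flag)) cohorts$mixed_flag <- FALSE
  if (is.null(cohorts$origin)) cohorts$origin <- "planted"
  structure(list(cells = cells, cohorts = cohorts,
                 grid = c(nrow = 1L, ncol = n_cells)),
            class = "fc_landscape")
}

make_cohorts <- function(n, species_id = "spX", age = 10, density = 0,
                         mgmt = "timber", cell_id = 1L) {
  data.frame(cohort_id = seq_len(n), cell_id = cell_id,
             species_id = species_id, age_yr = age, area_km2 = 1,
             carbon_density = density, mgmt = mgmt, origin = "planted",
             mixed_flag = FALSE, stringsAsFactors = FALSE)
}

# exact (age, stock) samples from a known curve, optional lognormal noise
curve_data <- function(family, params, ages, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- eval_curve(family, params, ages)
  if (noise_sd > 0) y <- y * exp(rnorm(length(ages), 0, noise_sd))
  data.frame(age = ages, stock = y)
}
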