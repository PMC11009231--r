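## Synthetic NFI-like inputs ------------------------------------------------
##
## Everything the projection pipeline consumes can be generated here with
## known ground truth: species parameter tables, plot/tree records, gridded
## age-cohort landscapes, provincial forestation plans, suitability maps and
## wood-product ratio series.  Every generator is a pure function of its
## arguments and a single integer seed (sub-streams are hashed per generator,
## see substream_seed()).

#' Generate a species parameter table
#'
#' Draws per-species biological and policy constants: linear volume-biomass
#' conversion coefficients (continuous biomass-expansion-factor form),
#' carbon fraction, age of peak instantaneous growth (`age1_years`), harvest
#' age (`age2_years`, the rotation length, spanning 11--101 years), annual
#' stand mortality probability (national baseline 0.084%), timber share,
#' age-accrual distribution and a ground-truth stand growth curve per
#' species.  Roughly every fifth species is flagged as inappropriate and
#' carries a `replacement_target` (an indigenous substitute) used by the
#' species-replacement intervention.
#'
#' @param n_species number of species to generate (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a data.frame with one row per species; curve parameters are held
#'   in `curve_p1..curve_p3` and interpreted per `curve_family` (see
#'   [species_curve()]).
#' @export
gen_species_table <- function(n_species, seed = 1L) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 1)
    stop_input("n_species must be a positive integer")
  n_species <- as.integer(n_species)
  with_substream("species_table", seed, NULL, {
    age2 <- sample(11:101, n_species, replace = TRUE)
    age1 <- pmax(3L, as.integer(round(age2 * stats::runif(n_species, 0.35, 0.6))))
    fam  <- sample(c("richards", "korf", "hossfeld"), n_species, replace = TRUE)
    A    <- stats::runif(n_species, 60, 160)    # asymptotic stock, Mg C/ha
    p1 <- p2 <- p3 <- numeric(n_species)
    for (i in seq_len(n_species)) {
      p1[i] <- A[i]
      if (fam[i] == "richards") {
        p2[i] <- stats::runif(1, 3, 5) / age2[i]          # rate k
        p3[i] <- stats::runif(1, 1.2, 2.5)                # shape m
      } else if (fam[i] == "korf") {
        p2[i] <- stats::runif(1, 2, 6)                    # rate k
        p3[i] <- stats::runif(1, 0.8, 1.5)                # shape m
      } else {                                            # hossfeld
        p3[i] <- stats::runif(1, 1.5, 2.5)                # shape c
        p2[i] <- age1[i]^p3[i] / A[i]                     # b: half-stock near age1
      }
    }
    tab <- data.frame(
      species_id      = sprintf("sp%02d", seq_len(n_species)),
      vb_slope        = stats::runif(n_species, 0.5, 1.1),
      vb_intercept    = stats::runif(n_species, 0, 0.5),
      carbon_fraction = stats::runif(n_species, 0.45, 0.55),
      age1_years      = age1,
      age2_years      = age2,
      age_factor_a    = 0.05,
      mortality_rate  = 0.00084,
      timber_fraction = stats::runif(n_species, 0.2, 0.6),
      inc_mean        = stats::runif(n_species, 0.6, 1.1),
      inc_sd          = stats::runif(n_species, 0.1, 0.5),
      curve_family    = fam,
      curve_p1        = p1,
      curve_p2        = p2,
      curve_p3        = p3,
      replacement_target = NA_character_,
      stringsAsFactors = FALSE
    )
    if (n_species >= 2) {
      flagged <- which(seq_len(n_species) %% 5L == 0L)
      for (i in flagged)
        tab$replacement_target[i] <- tab$species_id[if (i == 1L) 2L else 1L]
    }
    validate_species_table(tab)
    tab
  })
}

#' Ground-truth growth curve of one species
#'
#' @param sp one row of a species table.
#' @return list with `family` and named `params` usable by [eval_curve()].
#' @export
species_curve <- function(sp) {
  fam <- sp$curve_family
  params <- switch(fam,
    richards    = c(A = sp$curve_p1, k = sp$curve_p2, m = sp$curve_p3),
    korf        = c(A = sp$curve_p1, k = sp$curve_p2, m = sp$curve_p3),
    hossfeld    = c(A = sp$curve_p1, b = sp$curve_p2, c = sp$curve_p3),
    logistic    = c(A = sp$curve_p1, b = sp$curve_p2, k = sp$curve_p3),
    logarithmic = c(p = sp$curve_p1, q = sp$curve_p2),
    stop_input("unknown curve family: ", fam))
  list(family = fam, params = params)
}

#' @rdname gen_species_table
#' @param tab a species table to validate.
#' @export
validate_species_table <- function(tab) {
  with(tab, {
    stopifnot(
      all(carbon_fraction > 0 & carbon_fraction < 1),
      all(age1_years < age2_years),
      all(mortality_rate >= 0 & mortality_rate <= 1),
      all(inc_sd >= 0),
      all(age_factor_a >= 0 & age_factor_a < 1),
      all(timber_fraction >= 0 & timber_fraction <= 1),
      !anyDuplicated(species_id)
    )
  })
  invisible(tab)
}

#' Generate NFI-like plot and tree records
#'
#' Each plot (300--600 m2, one province, planted or natural origin, site
#' class 1--9) carries an aggregate carbon density equal to its species'
#' ground-truth growth curve at the plot's stand age, times multiplicative
#' lognormal noise of scale `noise_sd`.  Individual tree volumes (all trees
#' with DBH >= 5 cm) are then decomposed so that the inventory conversion
#' chain reproduces that density exactly.  The generating curves are
#' returned for parameter-recovery tests.
#'
#' @param species species table from [gen_species_table()].
#' @param n_plots number of plots.
#' @param noise_sd standard deviation of log-scale multiplicative noise
#'   (0 puts every plot exactly on its generating curve).
#' @param seed integer seed.
#' @param provinces character vector of province labels to sample from.
#' @return list with data.frames `plots`, `trees` and `ground_truth`
#'   (species id, curve family and parameters).
#' @export
gen_nfi_plots <- function(species, n_plots, noise_sd = 0.1, seed = 1L,
                          provinces = sprintf("prov%d", 1:6)) {
  if (nrow(species) < 1) stop_input("species table must be nonempty")
  check_scalar_num(n_plots, "n_plots", lower = 1)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_input("noise_sd must be nonnegative")
  n_plots <- as.integer(n_plots)
  with_substream("nfi_plots", seed, NULL, {
    idx <- sample(nrow(species), n_plots, replace = TRUE)
    sp  <- species[idx, ]
    age <- integer(n_plots)
    for (i in seq_len(n_plots))
      age[i] <- sample(seq(ceiling(0.1 * sp$age2_years[i]),
                           ceiling(1.2 * sp$age2_years[i])), 1L)
    dens_true <- vapply(seq_len(n_plots), function(i) {
      cv <- species_curve(sp[i, ])
      eval_curve(cv$family, cv$params, age[i])
    }, numeric(1))
    dens <- dens_true * exp(stats::rnorm(n_plots, 0, noise_sd))
    plots <- data.frame(
      plot_id      = sprintf("plot%05d", seq_len(n_plots)),
      province     = sample(provinces, n_plots, replace = TRUE),
      origin       = sample(c("planted", "natural"), n_plots, replace = TRUE),
      stand_age_yr = age,
      site_class   = sample(1:9, n_plots, replace = TRUE),
      area_m2      = round(stats::runif(n_plots, 300, 600)),
      mixed_flag   = sample(c(TRUE, FALSE), n_plots, replace = TRUE),
      species_id   = sp$species_id,
      carbon_true_Mg_ha  = dens_true,
      carbon_noisy_Mg_ha = dens,
      stringsAsFactors = FALSE
    )
    tree_list <- vector("list", n_plots)
    for (i in seq_len(n_plots)) {
      area_ha <- plots$area_m2[i] / 1e4
      # invert the plot-level conversion chain: density -> stand volume per ha
      vol_ha <- (dens[i] / sp$carbon_fraction[i] - sp$vb_intercept[i]) /
        sp$vb_slope[i]
      if (vol_ha <= 0)
        stop("internal: generated stand density below conversion intercept")
      vol_tot <- vol_ha * area_ha
      n_tree  <- sample(5:30, 1L)
      w <- stats::rgamma(n_tree, shape = 2)
      v <- vol_tot * w / sum(w)
      tree_list[[i]] <- data.frame(
        plot_id    = plots$plot_id[i],
        species_id = sp$species_id[i],
        dbh_cm     = 5 + 60 * (v / (max(v) + 1e-12))^(1 / 2.4) *
          stats::runif(n_tree, 0.8, 1),
        volume_m3  = v,
        stringsAsFactors = FALSE
      )
    }
    list(plots = plots,
         trees = do.call(rbind, tree_list),
         ground_truth = species[, c("species_id", "curve_family",
                                    "curve_p1", "curve_p2", "curve_p3")])
  })
}

#' Generate a gridded age-cohort landscape
#'
#' Builds an abstract row-major 0.5-degree grid of `n_cells` cells, each
#' holding `units_per_cell` age cohorts of fixed 1 km2 area plus an
#' available grassland/shrubland budget for future planting.  Cohort ages
#' are sampled per species (uniform up to 1.1x the harvest age), densities
#' sit on the species ground-truth curve, and cohorts are classed timber
#' with the species' timber fraction; non-timber cohorts may be mixed
#' stands (which age by survey-derived increments rather than +1/yr).
#'
#' @param species species table.
#' @param n_cells number of grid cells.
#' @param units_per_cell cohorts per cell (1 km2 each).
#' @param seed integer seed.
#' @param provinces province labels, recycled over cells in blocks.
#' @param max_age_frac upper end of the cohort age distribution as a
#'   fraction of the species harvest age (default 1.1; smaller values give
#'   the younger age structure typical of a recently expanded forest
#'   estate).
#' @return an object of class `fc_landscape`: list with `cells`, `cohorts`
#'   and `grid` (nrow, ncol).
#' @export
gen_landscape <- function(species, n_cells, units_per_cell, seed = 1L,
                          provinces = sprintf("prov%d", 1:6),
                          max_age_frac = 1.1) {
  validate_species_table(species)
  check_scalar_num(n_cells, "n_cells", lower = 1)
  check_scalar_num(units_per_cell, "units_per_cell", lower = 1)
  n_cells <- as.integer(n_cells); units_per_cell <- as.integer(units_per_cell)
  with_substream("landscape", seed, NULL, {
    ncol_g <- ceiling(sqrt(n_cells))
    row <- (seq_len(n_cells) - 1L) %/% ncol_g
    col <- (seq_len(n_cells) - 1L) %% ncol_g
    cells <- data.frame(
      cell_id  = seq_len(n_cells),
      row = row, col = col,
      lat = 20 + 0.5 * row, lon = 100 + 0.5 * col,  # label only, no geodesy
      province = provinces[((seq_len(n_cells) - 1L) %% length(provinces)) + 1L],
      grassland_shrubland_km2 = round(stats::runif(n_cells, 20, 100)),
      stringsAsFactors = FALSE
    )
    n_coh <- n_cells * units_per_cell
    idx <- sample(nrow(species), n_coh, replace = TRUE)
    sp  <- species[idx, ]
    age <- numeric(n_coh)
    for (i in seq_len(n_coh))
      age[i] <- sample(seq_len(ceiling(max_age_frac * sp$age2_years[i])), 1L)
    dens <- vapply(seq_len(n_coh), function(i) {
      cv <- species_curve(sp[i, ])
      eval_curve(cv$family, cv$params, age[i])
    }, numeric(1))
    timber <- stats::runif(n_coh) < sp$timber_fraction
    cohorts <- data.frame(
      cohort_id  = seq_len(n_coh),
      cell_id    = rep(seq_len(n_cells), each = units_per_cell),
      species_id = sp$species_id,
      age_yr     = age,
      area_km2   = 1,
      carbon_density = dens,      # Mg C / ha
      mgmt       = ifelse(timber, "timber", "nontimber"),
      origin     = sample(c("planted", "natural"), n_coh, replace = TRUE),
      mixed_flag = !timber & stats::runif(n_coh) < 0.5,
      stringsAsFactors = FALSE
    )
    structure(list(cells = cells, cohorts = cohorts,
                   grid = c(nrow = max(row) + 1L, ncol = ncol_g)),
              class = "fc_landscape")
  })
}

#' Generate a provincial forestation plan
#'
#' Splits a total planting area across provinces with fixed weights (the
#' provincial afforestation rates, constant over the plan horizon) and
#' evenly across years, so the plan sums exactly to `total_area_km2`.
#'
#' @param provinces character vector of provinces.
#' @param total_area_km2 total area to plant over the horizon (> 0).
#' @param start_year,end_year plan horizon (inclusive).
#' @param seed integer seed (used only when `weights` is NULL).
#' @param weights optional nonnegative provincial weights; defaults to
#'   random rates, standing in for the inventory-period provincial rates.
#' @return data.frame (province, year, area_km2).
#' @export
gen_forestation_plan <- function(provinces, total_area_km2,
                                 start_year, end_year, seed = 1L,
                                 weights = NULL) {
  check_scalar_num(total_area_km2, "total_area_km2", lower = 0,
                   strict_lower = TRUE)
  if (start_year > end_year) stop_input("start_year must be <= end_year")
  np <- length(provinces)
  if (is.null(weights))
    weights <- with_substream("forestation_plan", seed, NULL,
                              stats::runif(np, 0.5, 1.5))
  if (length(weights) != np || any(weights < 0) || sum(weights) == 0)
    stop_input("weights must be nonnegative, one per province")
  w <- weights / sum(weights)
  years <- seq(start_year, end_year)
  annual <- total_area_km2 * w / length(years)   # constant per-province rate
  data.frame(
    province = rep(provinces, each = length(years)),
    year     = rep(years, times = np),
    area_km2 = rep(annual, each = length(years)),
    stringsAsFactors = FALSE
  )
}

#' Generate per-species land-suitability maps
#'
#' One suitability index in \[0, 1\] per (cell, species), emulating the
#' habitat-suitability surfaces that rank cells for planting priority.
#'
#' @param species species table.
#' @param landscape an `fc_landscape`.
#' @param seed integer seed.
#' @return numeric matrix, `n_cells` x `n_species`, rownames = cell ids,
#'   colnames = species ids.
#' @export
gen_suitability_maps <- function(species, landscape, seed = 1L) {
  stopifnot(inherits(landscape, "fc_landscape"))
  n_cells <- nrow(landscape$cells)
  with_substream("suitability", seed, NULL, {
    m <- matrix(stats::runif(n_cells * nrow(species)),
                nrow = n_cells, ncol = nrow(species),
                dimnames = list(landscape$cells$cell_id, species$species_id))
    m
  })
}

#' Generate an annual wood-product ratio series
#'
#' Shares of harvested carbon routed to sawn wood, wood-based panels and
#' paper/paperboard.  `fixed` mode holds the 2020 shares throughout (paper/
#' paperboard at 61.5%); `trending` mode linearly shifts carbon from paper
#' to sawn wood (continuing the pre-2020 drift toward longer-lived
#' products) until 2060, constant afterwards.  Each year's shares sum to 1.
#'
#' @param start_year,end_year series horizon (inclusive).
#' @param mode `"fixed"` or `"trending"`.
#' @param drift annual shift of share from paper to sawn wood in trending
#'   mode (default 0.004/yr).
#' @return data.frame (year, sawn, panel, paper).
#' @export
gen_product_ratio_series <- function(start_year, end_year,
                                     mode = c("fixed", "trending"),
                                     drift = 0.004) {
  if (start_year > end_year) stop_input("start_year must be <= end_year")
  mode <- match.arg(mode)
  base <- c(sawn = 0.250, panel = 0.135, paper = 0.615)  # 2020 shares
  years <- seq(start_year, end_year)
  sawn <- rep(base["sawn"], length(years))
  paper <- rep(base["paper"], length(years))
  if (mode == "trending") {
    shift <- pmin(pmax(pmin(years, 2060) - 2020, 0) * drift,
                  base["paper"] - 0.05)   # keep paper share positive
    sawn  <- base["sawn"] + shift
    paper <- base["paper"] - shift
  }
  data.frame(year = years, sawn = as.numeric(sawn),
             panel = base["panel"], paper = as.numeric(paper),
             row.names = NULL)
}
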