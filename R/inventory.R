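## Inventory conversion chain -----------------------------------------------
##
## Volume -> biomass -> carbon at the plot level, then species-level
## reference stocks and the (species, origin, province, DBH-bin, site-class)
## stratification that the growth-curve ensemble is fitted on.
##
## The volume-biomass conversion is the continuous biomass-expansion-factor
## form, linear in stand volume per hectare: B = slope * V + intercept, with
## B in Mg/ha and V in m3/ha.  The exact per-species coefficient tables are
## a documented assumption of the linear form.

#' Convert stand volume to biomass
#'
#' @param volume_m3 stand volume (m3, or m3/ha when used at stand level);
#'   must be > 0.
#' @param params one species-table row (uses `vb_slope`, `vb_intercept`).
#' @return biomass in Mg (same areal basis as the input volume).
#' @export
volume_to_biomass <- function(volume_m3, params) {
  if (!is.numeric(volume_m3) || any(volume_m3 <= 0))
    stop_input("volume_m3 must be positive")
  params$vb_slope * volume_m3 + params$vb_intercept
}

#' Convert biomass to carbon
#'
#' @param biomass_Mg biomass (Mg), >= 0.
#' @param params one species-table row (uses `carbon_fraction`).
#' @return carbon in Mg C.
#' @export
biomass_to_carbon <- function(biomass_Mg, params) {
  if (!is.numeric(biomass_Mg) || any(biomass_Mg < 0))
    stop_input("biomass_Mg must be nonnegative")
  biomass_Mg * params$carbon_fraction
}

#' Plot-level carbon stock
#'
#' Sums tree volumes to a stand volume per hectare, applies the species
#' conversion chain and returns per-hectare carbon.  The plot's species
#' label is the dominant species by carbon.
#'
#' @param trees tree records of one plot (plot_id, species_id, volume_m3).
#' @param plot the matching plot record (uses `area_m2`, `stand_age_yr`).
#' @param species species table.
#' @return data.frame row: plot_id, species_id, stand_age_yr,
#'   carbon_Mg_per_ha.
#' @export
plot_carbon_stock <- function(trees, plot, species) {
  area_ha <- plot$area_m2 / 1e4
  if (nrow(trees) == 0) {
    warning("plot ", plot$plot_id, " has no trees; zero stock")
    return(data.frame(plot_id = plot$plot_id, species_id = NA_character_,
                      stand_age_yr = plot$stand_age_yr,
                      carbon_Mg_per_ha = 0, stringsAsFactors = FALSE))
  }
  stopifnot(all(trees$plot_id == plot$plot_id))
  per_sp <- vapply(split(trees$volume_m3, trees$species_id), function(v) {
    NA_real_
  }, numeric(1))
  sp_ids <- names(per_sp)
  for (s in sp_ids) {
    p <- species[species$species_id == s, ]
    if (nrow(p) != 1) stop_input("unknown species in tree records: ", s)
    vol_ha <- sum(trees$volume_m3[trees$species_id == s]) / area_ha
    per_sp[s] <- biomass_to_carbon(volume_to_biomass(vol_ha, p), p)
  }
  dominant <- sp_ids[which.max(per_sp)]
  data.frame(plot_id = plot$plot_id, species_id = dominant,
             stand_age_yr = plot$stand_age_yr,
             carbon_Mg_per_ha = sum(per_sp), stringsAsFactors = FALSE)
}

#' Carbon stocks for a whole plot table
#'
#' Vectorised convenience wrapper around [plot_carbon_stock()].
#'
#' @param plots plot records.
#' @param trees tree records.
#' @param species species table.
#' @return data.frame of plot carbon rows, one per plot.
#' @export
plots_carbon <- function(plots, trees, species) {
  tr <- split(trees, trees$plot_id)
  out <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    ti <- tr[[plots$plot_id[i]]]
    if (is.null(ti)) ti <- trees[0, ]
    out[[i]] <- plot_carbon_stock(ti, plots[i, ], species)
  }
  do.call(rbind, out)
}

#' Stratify plots for growth-curve fitting
#'
#' Assigns every plot to a (species, origin, province, 2-cm DBH bin,
#' site class) stratum.  DBH bins are half-open `[lo, lo + 2)` starting at
#' 5 cm (the census threshold).  Within each (species, origin, province,
#' bin) group the number of site classes is clamped to 3--9 according to
#' the sample count, and plots are assigned to site classes by quantiles of
#' their recorded site-class index.
#'
#' @param plots plot records.
#' @param trees tree records (mean DBH per plot defines the bin).
#' @param plot_carbons output of [plots_carbon()] (species labels).
#' @return `plots` with added columns `species_id`, `dbh_bin`,
#'   `site_bin`, `stratum`.
#' @export
stratify_plots <- function(plots, trees, plot_carbons) {
  if (nrow(plots) == 0 || nrow(trees) == 0) stop_input("empty input tables")
  mean_dbh <- tapply(trees$dbh_cm, trees$plot_id, mean)
  plots$mean_dbh <- as.numeric(mean_dbh[plots$plot_id])
  plots$dbh_bin <- 5 + 2 * floor((plots$mean_dbh - 5) / 2)
  plots$species_id <-
    plot_carbons$species_id[match(plots$plot_id, plot_carbons$plot_id)]
  key <- interaction(plots$species_id, plots$origin, plots$province,
                     plots$dbh_bin, drop = TRUE)
  plots$site_bin <- NA_integer_
  for (g in levels(key)) {
    i <- which(key == g)
    n_cl <- max(3L, min(9L, length(i) %/% 4L))
    # quantile cut of the recorded site-class index into n_cl classes
    r <- rank(plots$site_class[i], ties.method = "first")
    plots$site_bin[i] <- as.integer(ceiling(r / length(i) * n_cl))
  }
  plots$stratum <- paste(plots$species_id, plots$origin, plots$province,
                         plots$dbh_bin, plots$site_bin, sep = "|")
  plots
}

#' Species-level reference stocks
#'
#' Area-weighted totals of plot carbon per species; the 2018-style species
#' reference stocks used to check simulated initial states.
#'
#' @param plot_carbons output of [plots_carbon()].
#' @param plots plot records (for areas).
#' @return data.frame (species_id, total_Mg_C, area_ha); attribute
#'   `grand_total` holds the sum over species.
#' @export
species_reference_stock <- function(plot_carbons, plots) {
  if (nrow(plot_carbons) == 0) stop_input("empty plot carbon table")
  area_ha <- plots$area_m2[match(plot_carbons$plot_id, plots$plot_id)] / 1e4
  tot <- tapply(plot_carbons$carbon_Mg_per_ha * area_ha,
                plot_carbons$species_id, sum)
  ar  <- tapply(area_ha, plot_carbons$species_id, sum)
  out <- data.frame(species_id = names(tot), total_Mg_C = as.numeric(tot),
                    area_ha = as.numeric(ar), stringsAsFactors = FALSE)
  attr(out, "grand_total") <- sum(out$total_Mg_C)
  out
}
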