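## Scenario orchestration and reporting --------------------------------------

#' Run a set of scenario configurations
#'
#' Runs [run_simulation()] once per configuration on shared inputs and
#' pools the results: per-year mean and standard deviation across scenarios
#' of the national stock and sink series, and of the per-cell sink maps.
#' Deterministic given the configs' seeds and permutation-invariant in the
#' config list.
#'
#' @param configs list of `fc_scenario_config`.
#' @param landscape,species,plan,suitability,ratio_series shared inputs,
#'   see [run_simulation()].
#' @param years shared horizon.
#' @return object of class `fc_sweep`: `runs` (list of `fc_sim`), `mean`
#'   and `sd` data.frames (year, stock_Mg, sink_Mg), and per-cell mean/sd
#'   sink matrices.
#' @export
sweep_scenarios <- function(configs, landscape, species, plan = NULL,
                            suitability = NULL, ratio_series = NULL,
                            years = 2020:2100) {
  stopifnot(length(configs) >= 1)
  runs <- lapply(configs, function(cf)
    run_simulation(landscape, species, cf, plan, suitability,
                   ratio_series, years))
  horizons <- vapply(runs, function(r) paste(range(r$years), collapse = "-"),
                     "")
  if (length(unique(horizons)) != 1)
    stop_input("scenario runs have mismatched horizons: ",
               paste(unique(horizons), collapse = ", "))
  stock <- sapply(runs, function(r) r$series$stock_Mg)
  sink  <- sapply(runs, function(r) r$series$sink_Mg)
  sd0 <- function(m) apply(m, 1, function(v) if (length(v) > 1) stats::sd(v) else 0)
  cell_arr <- lapply(runs, function(r) r$cell_sink_Mg)
  cell_mean <- Reduce(`+`, cell_arr) / length(cell_arr)
  cell_sd <- if (length(runs) == 1) cell_mean * 0 else {
    sqrt(Reduce(`+`, lapply(cell_arr, function(m) (m - cell_mean)^2)) /
           (length(runs) - 1))
  }
  structure(list(
    runs = runs,
    mean = data.frame(year = years, stock_Mg = rowMeans(stock),
                      sink_Mg = rowMeans(sink)),
    sd = data.frame(year = years,
                    stock_Mg = if (length(runs) > 1) apply(stock, 1, stats::sd)
                               else stock[, 1] * 0,
                    sink_Mg = if (length(runs) > 1) apply(sink, 1, stats::sd)
                              else sink[, 1] * 0),
    cell_sink_mean = cell_mean, cell_sink_sd = cell_sd),
    class = "fc_sweep")
}

#' @export
print.fc_sweep <- function(x, ...) {
  ny <- nrow(x$mean)
  cat(sprintf("Scenario sweep: %d runs, %d-%d\n", length(x$runs),
              x$mean$year[1], x$mean$year[ny]))
  cat(sprintf("  mean sink %.3f Tg C/yr (across-scenario sd of 2100 stock: %.3f Tg C)\n",
              mean(x$mean$sink_Mg, na.rm = TRUE) * 1e-6,
              x$sd$stock_Mg[ny] * 1e-6))
  invisible(x)
}

#' Per-cell sink-peak maps
#'
#' For every grid cell and scenario, smooths the annual sink series with a
#' centered moving average (default 5 years), takes the argmax year (ties
#' broken by the earliest year) and the smoothed maximum in
#' g C m-2 yr-1, then reports across-scenario means and standard
#' deviations.  Cells with an all-zero sink series are flagged `NA`.
#'
#' @param sweep an `fc_sweep` (or a list of `fc_sim` runs).
#' @param window smoothing window in years (default 5).
#' @return data.frame per cell: peak_year_mean, peak_year_sd,
#'   peak_mag_mean, peak_mag_sd (g C m-2 yr-1).
#' @export
peak_maps <- function(sweep, window = 5) {
  runs <- if (inherits(sweep, "fc_sweep")) sweep$runs else sweep
  cells <- colnames(runs[[1]]$cell_sink_Mg)
  per_run <- lapply(runs, function(r) {
    yrs <- r$years
    t(vapply(seq_along(cells), function(ci) {
      sink <- r$cell_sink_gm2[, ci]
      if (all(is.na(sink) | sink == 0)) return(c(NA_real_, NA_real_))
      sm <- stats::filter(sink, rep(1 / window, window), sides = 2)
      mx <- max(sm, na.rm = TRUE)
      c(as.numeric(yrs[which(sm == mx)[1]]), mx)
    }, numeric(2)))
  })
  py <- sapply(per_run, function(m) m[, 1])
  pm <- sapply(per_run, function(m) m[, 2])
  if (is.null(dim(py))) { py <- matrix(py, ncol = length(runs)); pm <- matrix(pm, ncol = length(runs)) }
  sdr <- function(m) apply(m, 1, function(v)
    if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  data.frame(cell_id = cells,
             peak_year_mean = rowMeans(py),
             peak_year_sd = sdr(py),
             peak_mag_mean = rowMeans(pm),
             peak_mag_sd = sdr(pm),
             stringsAsFactors = FALSE)
}

mgmt_fields <- c("group", "rotation_extension_yr", "replacement_enabled",
                 "delay_yr")

#' Additional sink from management practices
#'
#' Differences a managed run against its baseline: the additional sink per
#' year and the accumulated total (the 2100 stock difference, optionally
#' including the wood-product pool).  The paired configs must differ only
#' in management fields.
#'
#' @param baseline,managed `fc_sim` results from paired configs.
#' @param include_products also difference the product-pool stocks.
#' @return list: `additional_sink_Mg` (data.frame year, delta),
#'   `total_Mg` (2100 stock difference), `total_with_products_Mg`.
#' @export
management_delta <- function(baseline, managed, include_products = FALSE) {
  cb <- baseline$config; cm <- managed$config
  other <- setdiff(names(cb), mgmt_fields)
  diffs <- other[!vapply(other, function(f) identical(cb[[f]], cm[[f]]), TRUE)]
  if (length(diffs))
    stop_input("paired configs differ outside management fields: ",
               paste(diffs, collapse = ", "))
  ny <- nrow(baseline$series)
  delta <- managed$series$sink_Mg - baseline$series$sink_Mg
  total <- managed$series$stock_Mg[ny] - baseline$series$stock_Mg[ny]
  totp <- total + if (include_products)
    (managed$pool$total[ny] - baseline$pool$total[ny]) * 1e6 else 0
  list(additional_sink_Mg = data.frame(year = baseline$years, delta_Mg = delta),
       total_Mg = total, total_with_products_Mg = totp)
}

#' Carbon loss from delayed management implementation
#'
#' @param results named list of `fc_sim` runs keyed by delay (`"0"`, `"5"`,
#'   `"10"`, `"15"`), all sharing the same config apart from `delay_yr`.
#' @return data.frame (delay_yr, stock_2100_Mg, loss_Mg) where
#'   `loss = stock2100(delay 0) - stock2100(delay d)`.
#' @export
delay_loss <- function(results) {
  need <- c("0", "5", "10", "15")
  if (!all(need %in% names(results)))
    stop_input("missing delay level(s): ",
               paste(setdiff(need, names(results)), collapse = ", "))
  s2100 <- vapply(results[need], function(r)
    r$series$stock_Mg[nrow(r$series)], 0)
  data.frame(delay_yr = as.numeric(need),
             stock_2100_Mg = as.numeric(s2100),
             loss_Mg = s2100[["0"]] - as.numeric(s2100))
}

#' Write simulation outputs
#'
#' Writes the annual series, per-cell sink rasters (long CSV with row/col
#' grid indices and lat/lon labels), the product-pool series and a run
#' manifest (config echo, seed, package version, mass-balance summary).
#'
#' @param result an `fc_sim`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(result, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_input("cannot create output dir: ", out_dir)
  f_series <- file.path(out_dir, "series.csv")
  utils::write.csv(result$series, f_series, row.names = FALSE)
  f_pool <- file.path(out_dir, "product_pool.csv")
  utils::write.csv(result$pool, f_pool, row.names = FALSE)
  cells <- result$landscape$cells
  sink <- result$cell_sink_gm2
  long <- data.frame(
    year = rep(as.integer(rownames(sink)), times = ncol(sink)),
    cell_id = rep(cells$cell_id, each = nrow(sink)),
    row = rep(cells$row, each = nrow(sink)),
    col = rep(cells$col, each = nrow(sink)),
    lat = rep(cells$lat, each = nrow(sink)),
    lon = rep(cells$lon, each = nrow(sink)),
    sink_gC_m2_yr = as.vector(sink))
  f_raster <- file.path(out_dir, "cell_sink_raster.csv")
  utils::write.csv(long, f_raster, row.names = FALSE)
  f_manifest <- file.path(out_dir, "manifest.txt")
  cfg <- result$config
  writeLines(c(
    paste0("package_version: ", as.character(utils::packageVersion("forestcarbon"))),
    paste0("seed: ", cfg$seed),
    vapply(setdiff(names(cfg), "seed"),
           function(f) paste0(f, ": ", cfg[[f]]), ""),
    paste0("grid: ", paste(result$landscape$grid, collapse = " x ")),
    paste0("max_mass_balance_residual_rel: ",
           format(max(result$mass_balance$residual_rel), digits = 3))),
    f_manifest)
  invisible(c(f_series, f_pool, f_raster, f_manifest))
}
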