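#' Configuration for an end-to-end run
#'
#' Collects every knob of the analysis: the data sources (synthetic
#' generator parameters, or paths to an ESRI ASCII DEM plus MAT/MAP rasters
#' and a checklist CSV), the band constructions, the range-size group
#' thresholds, the number of mid-domain simulations, and named seeds for
#' each stochastic stage, all derived from one base seed.
#'
#' @param mountain A [mountain_params()] object (ignored if `dem_path` set).
#' @param checklist A [checklist_params()] object (ignored if
#'   `checklist_path` set).
#' @param dem_path,mat_path,map_path Optional ESRI ASCII raster paths.
#' @param checklist_path Optional checklist CSV path.
#' @param n_bands Number of equal-area bands (default 37).
#' @param band_width Equal-elevation band width in metres (default 100).
#' @param group_thresholds Range-size group limits (default `c(150, 500)`).
#' @param n_sim Mid-domain simulations (default 1000).
#' @param correlogram_max_lag Distance classes per correlogram (default 10).
#' @param correlogram_n_perm Permutations per Moran's I test (default 199).
#' @param seed Base seed from which the stage seeds are derived.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mountain = mountain_params(seed = seed),
                       checklist = checklist_params(seed = seed + 1L),
                       dem_path = NULL, mat_path = NULL, map_path = NULL,
                       checklist_path = NULL,
                       n_bands = 37L, band_width = 100,
                       group_thresholds = c(150, 500),
                       n_sim = 1000L,
                       correlogram_max_lag = 10L,
                       correlogram_n_perm = 199L,
                       seed = 1L) {
  if (length(group_thresholds) != 2L || group_thresholds[1] >= group_thresholds[2]) {
    stop_invalid("group_thresholds must be increasing")
  }
  if (n_sim < 1) stop_invalid("n_sim must be >= 1")
  structure(
    list(mountain = mountain, checklist = checklist,
         dem_path = dem_path, mat_path = mat_path, map_path = map_path,
         checklist_path = checklist_path,
         n_bands = as.integer(n_bands), band_width = band_width,
         group_thresholds = group_thresholds, n_sim = as.integer(n_sim),
         correlogram_max_lag = as.integer(correlogram_max_lag),
         correlogram_n_perm = as.integer(correlogram_n_perm),
         seeds = list(jitter = seed + 11L, mde_ee = seed + 23L,
                      mde_ea = seed + 24L, perm = seed + 37L),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full elevational-diversity analysis
#'
#' Executes every stage in order: build (or load) the DEM and climate
#' layers; construct the equal-elevation and equal-area band schemes with
#' areas and climate summaries; interpolate the checklist into observed
#' richness (method 2 corrected richness is the identical count on the
#' equal-area scheme); fit the three species--area versions per richness
#' variable, select by AICc and apply the method-1 power-law correction;
#' simulate the mid-domain null on both schemes; fit first- and
#' second-order OLS and SAR error models of every richness variable against
#' elevation, MAT, MAP and the MDE prediction, select orders by AICc, and
#' compute residual correlograms for overall species richness; and compare
#' the two correction methods by SAR pseudo-R^2.
#'
#' @param config A [run_config()] object.
#' @param out_dir Optional directory; when given, all tables plus a JSON
#'   manifest of seeds and convention flags are written there as CSV/JSON.
#' @return An object of class `altiband_run`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  grid <- stage("grid", {
    if (is.null(config$dem_path)) {
      generate_climate(generate_elevation_grid(config$mountain), config$mountain)
    } else {
      g <- read_esri_ascii(config$dem_path)
      if (!is.null(config$mat_path)) g$mat <- read_esri_ascii(config$mat_path)$elev
      if (!is.null(config$map_path)) g$map <- read_esri_ascii(config$map_path)$elev
      g
    }
  })
  domain <- grid$domain

  ee <- stage("equal_elevation_bands", {
    s <- make_equal_elevation_bands(domain[1], domain[2], config$band_width)
    summarize_band_climate(assign_band_areas(s, grid), grid)
  })
  ea <- stage("equal_area_bands", {
    summarize_band_climate(make_equal_area_bands(grid, config$n_bands,
                                                 config$seeds$jitter), grid)
  })

  checklist <- stage("checklist", {
    if (is.null(config$checklist_path)) {
      generate_checklist(config$checklist, domain)
    } else {
      read_checklist_csv(config$checklist_path, domain = domain)
    }
  })

  rich_obs <- stage("richness_obs",
                    richness_table(checklist, ee, config$group_thresholds))
  rich_cor2 <- stage("richness_cor2",
                     richness_table(checklist, ea, config$group_thresholds))
  single_band <- stage("single_band", single_band_subset(checklist, ee))
  rich_single <- stage("richness_single",
                       richness_table(single_band, ee, config$group_thresholds))

  sar_fits <- stage("species_area", {
    lapply(stats::setNames(nm = richness_variables), function(v) {
      fits <- lapply(c("untransformed", "semilog", "loglog"),
                     function(ver) fit_species_area(rich_obs[[v]], ee$area_km2, ver))
      best <- select_best_version(fits)
      z <- best$all_fits[[3]]$slope   # power-law exponent from the loglog fit
      list(best = best, z = z,
           cor1 = correct_method1(rich_obs[[v]], ee$area_km2, z))
    })
  })
  rich_cor1 <- rich_obs
  for (v in richness_variables) rich_cor1[[v]] <- sar_fits[[v]]$cor1$trcor1

  mde_ee <- stage("mde_equal_elevation",
                  simulate_mde(checklist$elev_max - checklist$elev_min, domain,
                               ee, config$n_sim, config$seeds$mde_ee))
  mde_ea <- stage("mde_equal_area",
                  simulate_mde(checklist$elev_max - checklist$elev_min, domain,
                               ea, config$n_sim, config$seeds$mde_ea))

  battery <- stage("band_stats", run_battery(config, ee, ea, rich_obs, rich_cor1,
                                             rich_cor2, mde_ee, mde_ea))

  comparison <- stage("comparison", {
    sel <- battery$fits[battery$fits$engine == "SAR" & battery$fits$selected, ]
    compare_methods(sel[, c("group", "predictor", "richness_kind", "r2")])
  })

  peaks <- data.frame(
    group = richness_variables,
    peak_obs_m = vapply(richness_variables,
                        function(v) ee$mid[which.max(rich_obs[[v]])], 0),
    peak_cor1_m = vapply(richness_variables,
                         function(v) ee$mid[which.max(rich_cor1[[v]])], 0),
    peak_cor2_m = vapply(richness_variables,
                         function(v) ea$mid[which.max(rich_cor2[[v]])], 0)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("altiband")),
    seeds = config$seeds, base_seed = config$seed,
    n_bands = config$n_bands, band_width = config$band_width,
    n_sim = config$n_sim,
    conventions = list(
      band_intervals = "half-open [lower, upper), top band closed",
      group_boundaries = "150 m and 500 m inclusive in Group II",
      species_at_lower_bound = "counted into the touched band",
      mde_variant = "uniform midpoint within the feasible interval",
      weights_equal_elevation = "binary, distance class 100 m on band mids",
      weights_equal_area = "binary rank adjacency (band i with i +/- 1)",
      weights_on_subsets = "recomputed on the analyzed (non-zero) band subset",
      aicc_K = "OLS: order + 2 (incl. error variance); SAR: order + 3 (incl. lambda)",
      area_unit = "km2",
      sar_prediction = "trend + spatial signal (trend-only R2 reported alongside)"
    )
  )

  run <- structure(
    list(grid = grid, scheme_ee = ee, scheme_ea = ea, checklist = checklist,
         richness = list(obs = rich_obs, cor1 = rich_cor1, cor2 = rich_cor2,
                         single_band = rich_single),
         species_area = sar_fits, mde = list(ee = mde_ee, ea = mde_ea),
         fits = battery$fits, models = battery$models,
         correlograms = battery$correlograms,
         comparison = comparison, peaks = peaks,
         manifest = manifest, config = config),
    class = "altiband_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# The regression battery: for each richness kind on its scheme, each of the
# nine variables and each of the four predictors, fit order-1/2 OLS and SAR
# models, select the order by AICc, and keep residual correlograms for
# overall species richness.
run_battery <- function(config, ee, ea, rich_obs, rich_cor1, rich_cor2,
                        mde_ee, mde_ea) {
  kinds <- list(
    obs = list(rich = rich_obs, scheme = ee, mde = mde_ee),
    cor1 = list(rich = rich_cor1, scheme = ee, mde = mde_ee),
    cor2 = list(rich = rich_cor2, scheme = ea, mde = mde_ea)
  )
  rows <- list()
  models <- list()
  cgs <- list()
  for (kind in names(kinds)) {
    kk <- kinds[[kind]]
    sch <- kk$scheme
    preds <- list(elevation = sch$mid, MAT = sch$mat_mean, MAP = sch$map_mean,
                  MDE = kk$mde$mean_richness)
    equal_spacing <- attr(sch, "kind") == "equal_elevation"
    for (v in richness_variables) {
      y <- kk$rich[[v]]
      # zero-richness bands carry no information about the group and are
      # dropped; the weights are rebuilt on the analyzed subset
      # (method-1 corrected richness is zero exactly where observed is zero)
      y[y == 0] <- NA
      usable <- which(is.finite(y))
      if (length(usable) < 5) next
      w <- if (equal_spacing) {
        distance_weights(sch$mid[usable], config$band_width)
      } else {
        rank_weights(length(usable))
      }
      for (pn in names(preds)) {
        x <- preds[[pn]]
        for (engine in c("OLS", "SAR")) {
          f1 <- fit_polynomial(y[usable], x[usable], 1L, engine,
                               weights = w, response_name = v,
                               predictor_name = pn)
          f2 <- fit_polynomial(y[usable], x[usable], 2L, engine,
                               weights = w, response_name = v,
                               predictor_name = pn)
          if (engine == "SAR") {
            f1$response_name <- f2$response_name <- v
            f1$predictor_name <- f2$predictor_name <- pn
          }
          sel <- select_order(f1, f2)
          for (f in list(f1, f2)) {
            f$selected <- f$order == sel$order
            key <- paste(kind, v, pn, engine, f$order, sep = ".")
            models[[key]] <- f
            rows[[key]] <- data.frame(
              richness_kind = kind, group = v, predictor = pn,
              engine = engine, order = f$order,
              Q = if (f$order == 2) unname(f$coef["Q"]) else NA_real_,
              S = unname(f$coef["S"]), C = unname(f$coef["C"]),
              r2 = f$r2, p = f$p_value, aicc = f$aicc,
              lambda = f$lambda, n = f$n_used,
              selected = f$selected
            )
          }
          if (v == "S") {
            key <- paste(kind, pn, engine, sep = ".")
            pos <- if (equal_spacing) sch$mid[usable] else seq_along(usable)
            step <- if (equal_spacing) config$band_width else 1
            cgs[[key]] <- correlogram(
              residuals(sel), pos, step = step,
              max_lag = config$correlogram_max_lag,
              n_perm = config$correlogram_n_perm,
              seed = config$seeds$perm
            )
          }
        }
      }
    }
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  list(fits = fits, models = models, correlograms = cgs)
}

# Serialize every table of a run to CSV plus a JSON manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_band_scheme_csv(run$scheme_ee, fp("bands_equal_elevation.csv"))
  write_band_scheme_csv(run$scheme_ea, fp("bands_equal_area.csv"))
  write_checklist_csv(run$checklist, fp("checklist.csv"))
  for (k in names(run$richness)) {
    utils::write.csv(as.data.frame(run$richness[[k]]),
                     fp(sprintf("richness_%s.csv", k)), row.names = FALSE)
  }
  for (k in names(run$mde)) {
    utils::write.csv(
      as.data.frame(run$mde[[k]])[, c("band", "mid", "mean_richness", "q025", "q975")],
      fp(sprintf("mde_%s.csv", k)), row.names = FALSE)
  }
  utils::write.csv(run$fits, fp("model_fits.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$comparison), fp("method_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(run$peaks, fp("richness_peaks.csv"), row.names = FALSE)
  sa <- do.call(rbind, lapply(names(run$species_area), function(v) {
    b <- run$species_area[[v]]$best
    data.frame(group = v, version = b$version, z = run$species_area[[v]]$z,
               slope = b$slope, intercept = b$intercept, adj_r2 = b$adj_r2,
               p = b$p_value, aicc = b$aicc, n = b$n_used,
               co_best = paste(b$co_best, collapse = ";"))
  }))
  utils::write.csv(sa, fp("species_area_fits.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.altiband_run <- function(x, ...) {
  cat("<altiband_run>\n")
  cat(sprintf("  DEM: %d cells, domain [%g, %g] m; checklist: %d species\n",
              length(x$grid$elev), x$grid$domain[1], x$grid$domain[2],
              nrow(x$checklist)))
  cat(sprintf("  bands: %d equal-elevation (%g m), %d equal-area\n",
              nrow(x$scheme_ee), x$config$band_width, nrow(x$scheme_ea)))
  cat(sprintf("  species richness peaks (m): obs %g, cor1 %g, cor2 %g\n",
              x$peaks$peak_obs_m[1], x$peaks$peak_cor1_m[1], x$peaks$peak_cor2_m[1]))
  w <- attr(x$comparison, "wins")
  cat(sprintf("  SAR pseudo-R2 comparison: method1 wins %d, method2 wins %d, ties %d\n",
              w[["method1"]], w[["method2"]], w[["tie"]]))
  invisible(x)
}

#' @export
summary.altiband_run <- function(object, ...) {
  print(object)
  cat("\nSelected SAR models (species richness):\n")
  sel <- object$fits[object$fits$group == "S" & object$fits$engine == "SAR" &
                       object$fits$selected, ]
  print(sel[, c("richness_kind", "predictor", "order", "Q", "S", "C", "r2", "lambda")],
        row.names = FALSE, digits = 3)
  invisible(object)
}
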