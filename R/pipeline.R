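#' Materialize a complete synthetic demo dataset
#'
#' Writes a ready-to-run experiment to `outdir`: a baseline environmental
#' stack plus two future stacks (a moderate and a stronger warming scenario,
#' standing in for two climate-model forcings), occurrence records for two
#' "threatened" and two "commercial" virtual species, six protected-area
#' polygons, a whole-domain study region, and a pipeline config YAML.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving every random choice.
#' @return Path of the written config YAML, invisibly.
#' @export
make_demo <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  env_dir <- file.path(outdir, "env")

  base_params <- scenario_params(seed = seed)
  sc_moderate <- make_env_scenario(
    scenario_params(warming_delta = 0.77, seed = seed),
    period_labels = c("1985", "2050_moderate")
  )
  sc_strong <- make_env_scenario(
    scenario_params(warming_delta = 1.27, seed = seed),
    period_labels = c("1985", "2050_strong")
  )
  write_env_stack(sc_moderate$baseline, env_dir)
  write_env_stack(sc_moderate$future, env_dir)
  write_env_stack(sc_strong$future, env_dir)

  species <- list(
    virtual_species("skate_a", list(sst = c(6, 8, 11, 13),
                                    sbt = c(5.5, 7.5, 10.5, 12.5)),
                    depth_limit = 150),
    virtual_species("shark_b", list(sst = c(7, 9, 12, 14),
                                    sbt = c(6.5, 8.5, 11.5, 13.5)),
                    depth_limit = 200),
    virtual_species("cod_c", list(sst = c(5, 7, 10, 12),
                                  sbt = c(4.5, 6.5, 9.5, 11.5)),
                    depth_limit = 250),
    virtual_species("sole_d", list(sst = c(8, 10, 13, 15),
                                   sbt = c(7.5, 9.5, 12.5, 14.5)),
                    depth_limit = 120)
  )
  groups <- c(skate_a = "threatened", shark_b = "threatened",
              cod_c = "commercial", sole_d = "commercial")

  occ <- do.call(rbind, lapply(seq_along(species), function(i) {
    sample_occurrences(species[[i]], sc_moderate$baseline, n = 400,
                       seed = seed + i)
  }))
  occ_path <- file.path(outdir, "occurrences.csv")
  write_occurrences(occ, occ_path)

  areas <- make_protected_areas(base_params$spec, n_areas = 6,
                                seed = seed + 100)
  areas_path <- file.path(outdir, "protected_areas.geojson")
  write_polygons(areas, areas_path)

  spec <- base_params$spec
  region <- list(name = "study_area", ring = cbind(
    lon = c(spec$lon_min, spec$lon_max, spec$lon_max, spec$lon_min,
            spec$lon_min),
    lat = c(spec$lat_min, spec$lat_min, spec$lat_max, spec$lat_max,
            spec$lat_min)
  ))
  regions_path <- file.path(outdir, "regions.geojson")
  write_polygons(list(region), regions_path)

  config <- list(
    env_dir = env_dir,
    baseline_period = "1985",
    future_periods = c("2050_moderate", "2050_strong"),
    occurrences = occ_path,
    regions = regions_path,
    protected_areas = areas_path,
    species = lapply(names(groups), function(nm) {
      sp <- species[[which(vapply(species, `[[`, character(1), "name") == nm)]]
      list(name = nm, group = unname(groups[nm]),
           max_depth = sp$depth_limit, allowed_regions = list("study_area"))
    }),
    models = c("envelope", "maxent", "dbem"),
    variables = c("sst", "sbt", "salinity"),
    thresholds = c(0.05, 0.5, 0.7),
    use_max_ss = TRUE,
    dispersal_scenarios = c("full_dispersal", "no_dispersal"),
    depth_inflation = 1.5,
    train_fraction = 0.75,
    dbem = list(r = 0.5, d = 0.1, n_bins = 20,
                start_year = 1985, end_year = 2050),
    maxent = list(beta = 0.1, max_iter = 2000, tol = 1e-8),
    envelope = list(percentiles = c(0.1, 0.9), buffer = 0),
    seed = seed,
    output_dir = file.path(outdir, "results")
  )
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  need <- c("env_dir", "baseline_period", "future_periods", "occurrences",
            "species", "models", "seed", "output_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config lacks fields: ", paste(missing, collapse = ", "))
  }
  if (length(config$models) < 1 || length(config$species) < 1) {
    stop("config needs at least one model and one species")
  }
  bad <- setdiff(unlist(config$models), c("envelope", "maxent", "dbem"))
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  config
}

stage_fail <- function(stage, species, model, e) {
  stop(sprintf("pipeline stage '%s' failed for species=%s model=%s: %s",
               stage, species, model, conditionMessage(e)), call. = FALSE)
}

#' Run the full projection and impact-analysis pipeline
#'
#' Executes, for every species x model x future-scenario combination:
#' occurrence QC and gridding, a 75/25 cell split, model fitting on the
#' training cells, baseline and future prediction, depth/region clipping,
#' threshold selection (fixed set plus optional max sensitivity+specificity),
#' dispersal scenarios, and the impact metrics (centroid shifts, range
#' change, pairwise Schoener's D overlap between threatened and commercial
#' species, and protected-area suitability change). All tables are written as
#' CSV under the configured output directory, maps as ASCII grids, and a JSON
#' manifest records the config hash, seed, per-stage counts and warnings.
#' Identical config and seed give identical outputs.
#'
#' @param config A config list or path to a YAML file (see [make_demo()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map_dir <- file.path(out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }

  variables <- unlist(cfg$variables %||% c("sst", "sbt", "salinity"))
  all_vars <- unique(c(variables, "depth"))
  baseline <- read_env_stack(cfg$env_dir, cfg$baseline_period)
  futures <- lapply(unlist(cfg$future_periods), function(p) {
    read_env_stack(cfg$env_dir, p)
  })
  names(futures) <- unlist(cfg$future_periods)
  spec <- baseline$spec
  if (!all(all_vars %in% names(baseline$layers))) {
    stop("baseline stack lacks variables: ",
         paste(setdiff(all_vars, names(baseline$layers)), collapse = ", "))
  }

  region_polys <- if (!is.null(cfg$regions)) read_polygons(cfg$regions) else list()
  region_masks <- lapply(region_polys, function(p) {
    ra <- rasterize_area(p, spec)
    m <- matrix(FALSE, spec$n_lat, spec$n_lon)
    m[ra$cells] <- TRUE
    region_mask(spec, m, p$name)
  })
  names(region_masks) <- vapply(region_polys, `[[`, character(1), "name")

  pa_list <- if (!is.null(cfg$protected_areas)) {
    lapply(read_polygons(cfg$protected_areas), rasterize_area, spec = spec)
  } else list()

  occ_all <- read_occurrences(cfg$occurrences)
  qc <- qc_filter(occ_all, baseline)
  occ <- qc$records

  background <- region_mask(spec, sea_mask(baseline), "background")
  models <- unlist(cfg$models)
  thresholds <- as.numeric(unlist(cfg$thresholds %||% c(0.05, 0.5, 0.7)))
  use_max_ss <- isTRUE(cfg$use_max_ss)
  scenarios <- unlist(cfg$dispersal_scenarios %||% "full_dispersal")
  depth_layer <- baseline$layers$depth
  depth_inflation <- cfg$depth_inflation %||% 1.5

  sp_names <- vapply(cfg$species, `[[`, character(1), "name")
  sp_groups <- vapply(cfg$species, function(s) s$group %||% "unknown",
                      character(1))

  maps <- list()        # maps[[species]][[model]][[period]]
  threshold_rows <- list()
  map_files <- character(0)

  for (si in seq_along(cfg$species)) {
    sp_cfg <- cfg$species[[si]]
    sp <- sp_cfg$name
    pres <- tryCatch(
      aggregate_to_grid(occ[occ$species == sp, , drop = FALSE], spec,
                        species = sp),
      error = function(e) stage_fail("aggregate", sp, "-", e)
    )
    split <- tryCatch(
      split_train_test(pres, cfg$train_fraction %||% 0.75,
                       seed = cfg$seed + 17 * si),
      error = function(e) stage_fail("split", sp, "-", e)
    )
    allowed <- region_masks[unlist(sp_cfg$allowed_regions)]
    clip <- function(map) {
      apply_clip(map, depth_layer, sp_cfg$max_depth %||% Inf,
                 regions = allowed, depth_inflation = depth_inflation)
    }

    maps[[sp]] <- list()
    for (model in models) {
      fitted_maps <- tryCatch({
        if (model == "envelope") {
          m <- fit_envelope(split$train, baseline, variables = variables,
                            percentiles = unlist(cfg$envelope$percentiles
                                                 %||% c(0.1, 0.9)),
                            buffer = cfg$envelope$buffer %||% 0)
          c(list(baseline = predict_envelope(m, baseline)),
            lapply(futures, function(f) predict_envelope(m, f)))
        } else if (model == "maxent") {
          m <- fit_maxent(split$train, baseline, background = background,
                          variables = variables,
                          beta = cfg$maxent$beta %||% 0.1,
                          max_iter = cfg$maxent$max_iter %||% 300,
                          tol = cfg$maxent$tol %||% 1e-8)
          if (!m$converged) note("maxent not converged for %s", sp)
          c(list(baseline = predict_maxent(m, baseline)),
            lapply(futures, function(f) predict_maxent(m, f)))
        } else {
          env_m <- fit_envelope(split$train, baseline, variables = variables)
          seed_map <- clip(predict_envelope(env_m, baseline))
          params <- dbem_params(
            r = cfg$dbem$r %||% 0.5, d = cfg$dbem$d %||% 0.1,
            K_scale = cfg$dbem$K_scale %||% 1,
            start_year = cfg$dbem$start_year %||% 1985,
            end_year = cfg$dbem$end_year %||% 2050,
            n_bins = cfg$dbem$n_bins %||% 20
          )
          base_run <- run_dbem(seed_map, baseline, baseline,
                               dbem_params(params$r, params$d, params$K_scale,
                                           params$start_year,
                                           params$start_year, params$n_bins),
                               variables = variables)
          out <- list(baseline = base_run$map)
          for (p in names(futures)) {
            run <- run_dbem(seed_map, baseline, futures[[p]], params,
                            variables = variables)
            out[[p]] <- run$map
          }
          out
        }
      }, error = function(e) stage_fail("fit_predict", sp, model, e))

      fitted_maps <- lapply(fitted_maps, clip)
      for (p in names(fitted_maps)) {
        f <- file.path(map_dir, sprintf("%s_%s_%s.asc", sp, model, p))
        write_suitability(fitted_maps[[p]], f)
        map_files <- c(map_files, f)
      }
      maps[[sp]][[model]] <- fitted_maps

      t_set <- thresholds
      if (use_max_ss) {
        t_sel <- tryCatch(
          select_max_ss_threshold(fitted_maps$baseline, split$test,
                                  background),
          error = function(e) stage_fail("max_ss", sp, model, e)
        )
        if (isTRUE(attr(t_sel, "no_discrimination"))) {
          note("no discrimination for %s/%s; max-S+S threshold degenerate",
               sp, model)
        }
        t_set <- c(t_set, max_ss = as.numeric(t_sel))
      }
      threshold_rows[[paste(sp, model)]] <- data.frame(
        species = sp, model = model,
        kind = c(rep("fixed", length(thresholds)),
                 if (use_max_ss) "max_ss"),
        threshold = unname(t_set), stringsAsFactors = FALSE
      )
    }
  }

  t_table <- do.call(rbind, threshold_rows)
  rownames(t_table) <- NULL

  centroid_rows <- list(); range_rows <- list(); overlap_rows <- list()
  rhs_rows <- list(); rhs_overall_rows <- list()

  for (sp in sp_names) {
    for (model in models) {
      mp <- maps[[sp]][[model]]
      tt <- t_table[t_table$species == sp & t_table$model == model, ]
      for (p in names(futures)) {
        for (k in seq_len(nrow(tt))) {
          t_val <- tt$threshold[k]
          t_lab <- if (tt$kind[k] == "max_ss") "max_ss" else
            format(t_val, trim = TRUE)
          cur_t <- apply_threshold(mp$baseline, t_val)
          for (scen in scenarios) {
            fut_scen <- apply_dispersal_scenario(mp$baseline, mp[[p]],
                                                 scenario = scen, t = t_val)
            fut_t <- apply_threshold(fut_scen, t_val)
            if (scen == "full_dispersal") {
              # centroid shift is defined on the full-dispersal projection
              ok <- sum(cur_t$values, na.rm = TRUE) > 0 &&
                sum(fut_t$values, na.rm = TRUE) > 0
              if (ok) {
                l1 <- latitudinal_centroid(cur_t)
                l2 <- latitudinal_centroid(fut_t)
                centroid_rows[[length(centroid_rows) + 1]] <- data.frame(
                  species = sp, model = model, scenario = p,
                  threshold = t_lab,
                  centroid_baseline = l1, centroid_future = l2,
                  shift_km = centroid_shift_km(l1, l2),
                  stringsAsFactors = FALSE
                )
                rc <- range_change(mp$baseline, mp[[p]], t = t_val)
                range_rows[[length(range_rows) + 1]] <- data.frame(
                  species = sp, model = model, scenario = p,
                  threshold = t_lab,
                  area_baseline_km2 = rc$area_baseline_km2,
                  loss_pct = rc$loss_pct, gain_pct = rc$gain_pct,
                  net_pct = rc$net_pct, stringsAsFactors = FALSE
                )
              } else {
                note("empty thresholded range for %s/%s/%s t=%s", sp, model,
                     p, t_lab)
              }
            }
          }
        }
      }
    }
  }

  threatened <- sp_names[sp_groups == "threatened"]
  commercial <- sp_names[sp_groups == "commercial"]
  for (model in models) {
    for (p in names(futures)) {
      for (tk in seq_len(nrow(t_table[t_table$species == sp_names[1] &
                                        t_table$model == model, ]))) {
        for (thr in threatened) {
          for (com in commercial) {
            tt_t <- t_table[t_table$species == thr & t_table$model == model, ]
            tt_c <- t_table[t_table$species == com & t_table$model == model, ]
            t_thr <- tt_t$threshold[tk]; t_com <- tt_c$threshold[tk]
            t_lab <- if (tt_t$kind[tk] == "max_ss") "max_ss" else
              format(t_thr, trim = TRUE)
            mx <- apply_threshold(maps[[thr]][[model]]$baseline, t_thr)
            my <- apply_threshold(maps[[com]][[model]]$baseline, t_com)
            fx <- apply_threshold(maps[[thr]][[model]][[p]], t_thr)
            fy <- apply_threshold(maps[[com]][[model]][[p]], t_com)
            sums <- c(sum(mx$values, na.rm = TRUE), sum(my$values, na.rm = TRUE),
                      sum(fx$values, na.rm = TRUE), sum(fy$values, na.rm = TRUE))
            if (any(sums <= 0)) {
              note("zero-sum map in overlap %s x %s (%s, %s, t=%s)",
                   thr, com, model, p, t_lab)
              next
            }
            d1 <- schoener_d(mx, my)
            d2 <- schoener_d(fx, fy)
            overlap_rows[[length(overlap_rows) + 1]] <- data.frame(
              threatened = thr, commercial = com, model = model,
              scenario = p, threshold = t_lab,
              D_baseline = d1, D_future = d2,
              pct_change = overlap_change_pct(d1, d2),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }

  if (length(pa_list) > 0) {
    for (sp in threatened) {
      for (model in models) {
        for (p in names(futures)) {
          std <- tryCatch(
            standardize_rhs(maps[[sp]][[model]]$baseline,
                            maps[[sp]][[model]][[p]], pa_list),
            error = function(e) {
              note("rhs standardization failed for %s/%s/%s: %s", sp, model,
                   p, conditionMessage(e))
              NULL
            }
          )
          if (is.null(std)) next
          rep <- rhs_change(std, species = sp, model = model)
          rep$by_area$scenario <- p
          rep$overall$scenario <- p
          rhs_rows[[length(rhs_rows) + 1]] <- rep$by_area
          rhs_overall_rows[[length(rhs_overall_rows) + 1]] <- rep$overall
        }
      }
    }
  }

  bind_or_empty <- function(rows) {
    if (length(rows)) do.call(rbind, rows) else data.frame()
  }
  tables <- list(
    thresholds = t_table,
    centroids = bind_or_empty(centroid_rows),
    range_changes = bind_or_empty(range_rows),
    overlaps = bind_or_empty(overlap_rows),
    protected_areas = bind_or_empty(rhs_rows),
    protected_areas_overall = bind_or_empty(rhs_overall_rows)
  )
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }

  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_tmp)),
    seed = cfg$seed,
    species = sp_names, groups = sp_groups, models = models,
    future_periods = names(futures),
    qc_log = qc$log,
    n_maps = length(map_files),
    map_files = basename(map_files),
    tables = stats::setNames(
      lapply(tables, nrow),
      names(tables)
    ),
    warnings = warnings_log
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
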