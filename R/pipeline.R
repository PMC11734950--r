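#' End-to-end pipeline orchestration
#'
#' Runs the full analysis chain on synthetic data from a single validated
#' config: environment simulation, sightings and vessel activity, presence
#' gridding, ensemble SDM fitting and projection, regridding, risk surfaces,
#' incident regressions, overlap statistics and acoustic validation. Every
#' stochastic stage draws its seed from the config, so identical configs give
#' identical outputs; outputs and their checksums are recorded in a JSON run
#' manifest, and a rerun with an unchanged config and intact outputs is
#' skipped.
#'
#' @name pipeline
NULL

#' A small, fast demonstration config
#'
#' One species on a 45 x 36-cell fine grid (coarse analysis grid 15 x 12),
#' 1,500 sightings, 900 pseudo-absences, 100 permutations. Completes in well
#' under five minutes on one CPU.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a config list for [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("whalerisk_run_"), seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    grid = list(lon_min = -75, lon_max = -30, lat_min = 35, lat_max = 71,
                resolution = 1, coarse_resolution = 3),
    species = "humpback",
    periods = c("present", "near_future", "mid_future"),
    n_sightings = 1500,
    pseudo_absences = 900,
    cv_repeats = 3,
    num_trees = 200,
    tss_cutoff = 0.7,
    permutations = 100,
    risk_mode = "sum1",
    receivers = 10,
    detections_per_receiver = 40)
}

required_config_fields <- c("seed", "out_dir", "grid", "species", "periods",
                            "n_sightings", "pseudo_absences", "cv_repeats",
                            "tss_cutoff", "permutations", "risk_mode")

#' Validate a pipeline config
#'
#' @param config a config list or path to a YAML file.
#' @return the validated config list (invisibly errors otherwise, naming the
#'   offending field).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  for (f in required_config_fields)
    if (is.null(config[[f]]))
      stop("config validation error: missing required field `", f, "`")
  for (f in c("lon_min", "lon_max", "lat_min", "lat_max", "resolution",
              "coarse_resolution"))
    if (is.null(config$grid[[f]]))
      stop("config validation error: missing required field `grid.", f, "`")
  if (!is.numeric(config$seed))
    stop("config validation error: `seed` must be numeric")
  if (!config$risk_mode %in% c("range01", "sum1"))
    stop("config validation error: `risk_mode` must be 'range01' or 'sum1'")
  bad <- setdiff(config$species, WHALE_SPECIES)
  if (length(bad))
    stop("config validation error: unknown species in `species`: ",
         paste(bad, collapse = ", "))
  config
}

# deterministic per-stage seeds derived from the master seed (kept < 2^31)
stage_seed <- function(config, stage) {
  offsets <- c(environment = 11, sightings = 23, vessels = 37, incidents = 41,
               pseudo_absences = 53, sdm = 67, importance = 71,
               acoustic = 83, overlap = 97)
  as.integer((as.numeric(config$seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the full pipeline
#'
#' @param config config list or YAML path (see [demo_config()],
#'   [validate_config()]).
#' @param force rerun even if an up-to-date manifest exists.
#' @return the run manifest (list), invisibly also written to
#'   `out_dir/manifest.json`. Tables are written as CSV under `out_dir`:
#'   member/ensemble TSS (`tss.csv`), variable importance
#'   (`importance_<sp>.csv`), HSV/risk surfaces per species x period,
#'   incident-model coefficients (`zinb_<sp>.csv`, `poisson_risk_<sp>.csv`)
#'   and the overlap table (`overlap_<sp>.csv`).
#' @export
run_pipeline <- function(config, force = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_hash <- config_hash(config)
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(old$config_hash, cfg_hash) && all(file.exists(
      file.path(out_dir, names(old$outputs)))) &&
      identical(unname(unlist(old$outputs)),
                unname(tools::md5sum(file.path(out_dir, names(old$outputs))))))
      return(invisible(old))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gcfg <- config$grid
  fine <- build_grid(gcfg$lon_min, gcfg$lon_max, gcfg$lat_min, gcfg$lat_max,
                     gcfg$resolution)
  coarse <- build_grid(gcfg$lon_min, gcfg$lon_max, gcfg$lat_min, gcfg$lat_max,
                       gcfg$coarse_resolution)
  truth <- truth_params()
  env <- gen_environment(fine, seed = stage_seed(config, "environment"))
  effort <- effort_surface(env)
  vessels <- gen_vessel_activity(env$grid, truth,
                                 seed = stage_seed(config, "vessels"))
  vessels_1deg <- regrid_mean(vessels, coarse)
  covars <- env_covariates(env, "present")
  keep_vars <- filter_collinear(covars[env$grid$mask, ], threshold = 0.7)

  tss_rows <- list(); outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (inherits(obj, "surface")) write_surface_csv(obj, path)
    else utils::write.csv(obj, path, row.names = FALSE)
    outputs[[name]] <<- unname(tools::md5sum(path))
  }

  for (sp in config$species) {
    suit <- true_suitability(env, truth, sp, "present")
    sightings <- sample_sightings(suit, effort, config$n_sightings,
                                  seed = stage_seed(config, "sightings"),
                                  species = sp)
    counts <- aggregate_points(sightings, env$grid, species = sp)
    pres <- presence_binarize(counts)
    pres_cells <- which(pres$values == 1)
    pa_cells <- generate_pseudo_absences(env$grid, pres_cells,
                                         n = config$pseudo_absences,
                                         seed = stage_seed(config, "pseudo_absences"))
    occ <- make_occurrence(pres_cells, pa_cells,
                           covars[, keep_vars, drop = FALSE], species = sp)
    ens <- build_ensemble(occ, repeats = config$cv_repeats,
                          cutoff = config$tss_cutoff,
                          seed = stage_seed(config, "sdm"),
                          num_trees = config$num_trees %||% 300)
    tss_rows[[sp]] <- data.frame(species = sp,
                                 t(ens$member_tss), ensemble = ens$ensemble_tss)
    emit(variable_importance(ens, occ, seed = stage_seed(config, "importance")),
         paste0("importance_", sp, ".csv"))

    hsv_1deg_present <- NULL
    for (per in config$periods) {
      pr <- project_suitability(ens, env, per)
      emit(pr$hsv, sprintf("hsv_%s_%s.csv", sp, per))
      hsv_1deg <- regrid_mean(pr$hsv, coarse)
      if (per == "present") hsv_1deg_present <- hsv_1deg
      rs <- risk_surfaces(hsv_1deg, align_surface(vessels_1deg, hsv_1deg),
                          mode = config$risk_mode, species = sp, period = per)
      emit(rs$E_norm, sprintf("risk_%s_%s.csv", sp, per))
    }

    # incidents on the coarse grid, generated from the true covariate link
    v1 <- align_surface(vessels_1deg, hsv_1deg_present)
    vk <- v1; vk$values <- vk$values / 1000  # hours -> kilo-hours for the link
    incid <- gen_incidents(truth, seed = stage_seed(config, "incidents"),
                           V = vk, HSV = hsv_1deg_present)
    emit(incid, sprintf("incidents_%s.csv", sp))
    zinb <- fit_zinb(incid, v1, hsv_1deg_present)
    emit(cbind(term = rownames(zinb$coefficients), zinb$coefficients,
               theta = zinb$theta, zero_prob = zinb$zero_prob),
         paste0("zinb_", sp, ".csv"))
    rs_present <- risk_surfaces(hsv_1deg_present, v1, mode = "sum1",
                                species = sp, period = "present")
    pois <- tryCatch(fit_poisson_risk(incid, rs_present$E_norm),
                     error = function(e) NULL)
    if (!is.null(pois))
      emit(cbind(term = rownames(pois$coefficients), pois$coefficients,
                 r_squared = pois$r_squared),
           paste0("poisson_risk_", sp, ".csv"))
    emit(overlap_table(incid, hsv_1deg_present, v1, n = config$permutations,
                       seed = stage_seed(config, "overlap")),
         paste0("overlap_", sp, ".csv"))

    # acoustic validation on the fine grid
    nrec <- config$receivers %||% 10
    ocean <- which(env$grid$mask)
    set.seed(stage_seed(config, "acoustic"))
    rec_cells <- sample(ocean, nrec)
    cen <- cell_centroids(env$grid, rec_cells)
    det <- gen_acoustic_detections(suit, data.frame(lon = cen$lon, lat = cen$lat),
                                   n_per_receiver = config$detections_per_receiver %||% 40,
                                   seed = stage_seed(config, "acoustic"))
    evald <- evaluate_against_detections(
      project_suitability(ens, env, "present")$hsv, det)
    emit(data.frame(mean_hsv_detection = evald$mean_hsv_detection,
                    mean_hsv_non_detection = evald$mean_hsv_non_detection),
         paste0("acoustic_validation_", sp, ".csv"))
  }
  emit(do.call(rbind, tss_rows), "tss.csv")
  emit(vessels_1deg, "vessel_hours_1deg.csv")

  manifest <- list(config_hash = cfg_hash, config = config,
                   outputs = as.list(outputs),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# put one surface onto another's (sub)mask so regressions see aligned cells
align_surface <- function(x, template) {
  g <- template$grid
  out <- x
  out$grid <- g
  out$values[!g$mask] <- NA_real_
  out
}

# stable hash of a config list
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
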