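PIPELINE_STAGES <- c("simulate", "localize", "track", "label", "assign",
                     "fit", "fpsd")
SCHEMA_VERSION <- 1L

#' Pipeline configuration
#'
#' Collects everything a reproducible run needs: the synthetic-campaign
#' configuration, the scene geometry, the trajectory-linking gates, the
#' imprecision filter threshold, and the model/switch-distance settings.
#'
#' @param sim a [sim_config()].
#' @param geometry a [scene_geometry()].
#' @param max_speed,max_gap trajectory-linking gates (m/s, s).
#' @param max_imprecision quality-filter threshold on `I` (m).
#' @param imprecision_floor systematic per-axis error floor (m) the
#'   localization stage adds in quadrature to the propagated SDs; see
#'   [localize_calls()].
#' @param fit_zones spatial subsets to model (subset of
#'   `c("all","above","under","back","front")`).
#' @param fit_references reference spectra to report.
#' @param fit_min_n minimum positions for a species group to be modelled.
#' @param onset_threshold PFIF threshold of the onset distance.
#' @param d_max prediction-curve extent (m).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            geometry = scene_geometry(),
                            max_speed = 20, max_gap = 1.0,
                            max_imprecision = 1.0,
                            imprecision_floor = 0.08,
                            fit_zones = "all",
                            fit_references = c("dark", "white"),
                            fit_min_n = 100,
                            onset_threshold = 0.05,
                            d_max = 25) {
  stopifnot(inherits(sim, "sim_config"), inherits(geometry, "scene_geometry"),
            all(fit_zones %in% c("all", "above", "under", "back", "front")))
  structure(list(sim = sim, geometry = geometry,
                 max_speed = max_speed, max_gap = max_gap,
                 max_imprecision = max_imprecision,
                 imprecision_floor = imprecision_floor,
                 fit_zones = fit_zones, fit_references = fit_references,
                 fit_min_n = fit_min_n,
                 onset_threshold = onset_threshold, d_max = d_max),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as YAML (or JSON, by file extension). Matrix
#' fields (`mic_positions`, `sim_box`) are stored as lists of rows.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param config a [pipeline_config()] (write only).
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  rows_to_matrix <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  sim_args <- raw$sim
  if (!is.null(sim_args$peak_freq_bands))
    sim_args$peak_freq_bands <- lapply(sim_args$peak_freq_bands, as.numeric)
  for (nm in c("true_beta0", "true_beta_dist", "species_mix"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  if (!is.null(sim_args$sim_box))
    sim_args$sim_box <- rows_to_matrix(sim_args$sim_box)
  geo_args <- raw$geometry
  if (!is.null(geo_args$mic_positions))
    geo_args$mic_positions <- rows_to_matrix(geo_args$mic_positions)
  rest <- raw[setdiff(names(raw), c("sim", "geometry"))]
  do.call(pipeline_config,
          c(list(sim = do.call(sim_config, sim_args %||% list()),
                 geometry = do.call(scene_geometry, geo_args %||% list())),
            rest))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- list(
    sim = serialize_sim(config$sim),
    geometry = list(
      mic_positions = unname(apply(config$geometry$mic_positions, 1,
                                   as.numeric, simplify = FALSE)),
      light_position = config$geometry$light_position,
      edge_normal = config$geometry$edge_normal,
      edge_offset = config$geometry$edge_offset,
      air_temp_c = config$geometry$air_temp_c,
      speed_of_sound = config$geometry$speed_of_sound
    ),
    max_speed = config$max_speed, max_gap = config$max_gap,
    max_imprecision = config$max_imprecision,
    imprecision_floor = config$imprecision_floor,
    fit_zones = config$fit_zones, fit_references = config$fit_references,
    fit_min_n = config$fit_min_n,
    onset_threshold = config$onset_threshold, d_max = config$d_max
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(ser, path)
  invisible(path)
}

serialize_sim <- function(sim) {
  s <- unclass(sim)
  s$sim_box <- unname(apply(s$sim_box, 1, as.numeric, simplify = FALSE))
  s$true_beta0 <- as.list(s$true_beta0)
  s$true_beta_dist <- as.list(s$true_beta_dist)
  s$species_mix <- as.list(s$species_mix)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, localize, track, label, assign (species), fit and
#' fpsd as one reproducible run. Every stage writes its table (CSV with a
#' schema-version comment line) into the run directory, together with a
#' deterministic manifest (configuration, its MD5 hash, seed, package
#' version, per-stage record accounting) and a timestamped log. Re-running
#' with the same configuration and seed reproduces byte-identical tables.
#'
#' `stages` must be a contiguous slice of the canonical order; a run that
#' does not start at `"simulate"` reads the upstream tables it needs from
#' `out_dir` and fails with the name of the missing stage otherwise.
#'
#' @param config a [pipeline_config()] or the path of a YAML/JSON
#'   configuration file.
#' @param stages character vector of stages to run, in order.
#' @param seed optional integer overriding the configuration's `rng_seed`.
#' @param out_dir run directory (created if needed).
#' @param quiet suppress console progress messages?
#' @return (invisibly) a list with the run directory, the manifest, and the
#'   in-memory stage results (`truth`, `calls`, `positions`, `labeled`,
#'   `fits`, `fpsd`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = PIPELINE_STAGES,
                         seed = NULL, out_dir = tempfile("pfif_run_"),
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  idx <- match(stages, PIPELINE_STAGES)
  if (anyNA(idx)) stop("unknown stage(s): ",
                       paste(stages[is.na(idx)], collapse = ", "))
  if (is.unsorted(idx) || !all(diff(idx) == 1))
    stop("`stages` must be a contiguous slice of: ",
         paste(PIPELINE_STAGES, collapse = " > "))
  if (!is.null(seed)) config$sim$rng_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                   sprintf(...))
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) message(line)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  state <- new.env(parent = emptyenv())
  accounting <- list()

  need_input <- function(stage, key, file) {
    if (!is.null(state[[key]])) return(invisible())
    p <- file.path(out_dir, file)
    if (!file.exists(p))
      stop("stage '", stage, "' needs the output of an earlier stage ",
           "(missing ", file, "); run the upstream stages first")
    state[[key]] <- read_stage_csv(p)
  }

  for (stage in stages) {
    logit("stage %s: start", stage)
    switch(stage,
      simulate = {
        state$truth <- simulate_trajectories(config$sim, config$geometry)
        state$calls <- emit_calls(state$truth, config$sim, config$geometry)
        write_stage_csv(state$truth, file.path(out_dir, "truth.csv"), "truth")
        write_stage_csv(state$calls, file.path(out_dir, "calls.csv"), "calls")
        accounting$simulate <- c(n_input = nrow(state$truth),
                                 n_kept = nrow(state$calls), n_discarded = 0L)
      },
      localize = {
        need_input(stage, "calls", "calls.csv")
        state$positions <- localize_calls(
          state$calls, config$geometry,
          toa_noise_sd = config$sim$toa_noise_sd,
          imprecision_floor = config$imprecision_floor)
        write_stage_csv(state$positions, file.path(out_dir, "positions.csv"),
                        "positions")
        n_ok <- sum(state$positions$status == "ok")
        accounting$localize <- c(n_input = nrow(state$calls), n_kept = n_ok,
                                 n_discarded = nrow(state$positions) - n_ok)
      },
      track = {
        need_input(stage, "positions", "positions.csv")
        pos <- state$positions
        pos <- pos[order(pos$night, pos$time), , drop = FALSE]
        linked <- lapply(split(pos, pos$night), function(p) {
          link_trajectories(p, config$max_speed, config$max_gap,
                            id_prefix = sprintf("n%02d_t",
                                                as.integer(p$night[1])),
                            fold_geometry = config$geometry)
        })
        state$positions <- tibble::as_tibble(do.call(rbind, unname(linked)))
        write_stage_csv(state$positions,
                        file.path(out_dir, "positions_tracked.csv"),
                        "positions_tracked")
        n_as <- sum(!is.na(state$positions$trajectory_id))
        accounting$track <- c(n_input = nrow(pos), n_kept = n_as,
                              n_discarded = nrow(pos) - n_as)
      },
      label = {
        need_input(stage, "positions", "positions_tracked.csv")
        flt <- filter_positions(state$positions, config$max_imprecision)
        logit("filter: %d of %d positions kept (%d discarded)",
              flt$counts[["n_kept"]], flt$counts[["n_input"]],
              flt$counts[["n_discarded"]])
        state$labeled <- label_positions(flt$kept, config$geometry)
        write_stage_csv(state$labeled,
                        file.path(out_dir, "positions_labeled.csv"),
                        "positions_labeled")
        write_stage_csv(flt$discarded,
                        file.path(out_dir, "positions_discarded.csv"),
                        "positions_discarded")
        accounting$label <- flt$counts
      },
      assign = {
        need_input(stage, "labeled", "positions_labeled.csv")
        lab <- state$labeled
        lab <- lab[order(lab$night, lab$time), , drop = FALSE]
        assigned <- lapply(split(lab, lab$night), function(p) {
          p <- segment_five_seconds(p)
          assign_species_groups(p, config$sim$peak_freq_bands,
                                config$max_speed, config$max_gap)
        })
        state$labeled <- tibble::as_tibble(do.call(rbind, unname(assigned)))
        write_stage_csv(state$labeled,
                        file.path(out_dir, "positions_species.csv"),
                        "positions_species")
        n_cl <- sum(!is.na(state$labeled$species_group))
        accounting$assign <- c(n_input = nrow(lab), n_kept = n_cl,
                               n_discarded = nrow(lab) - n_cl)
      },
      fit = {
        need_input(stage, "labeled", "positions_species.csv")
        lab <- state$labeled[!is.na(state$labeled$species_group), , drop = FALSE]
        groups <- names(which(table(lab$species_group) >= config$fit_min_n))
        fits <- list()
        for (g in groups) {
          for (zn in config$fit_zones) {
            f <- tryCatch(
              fit_pfif_glmm(lab, reference = config$fit_references[1],
                            zone = zn, species_group = g),
              error = function(e) {
                logit("fit skipped (%s, %s): %s", g, zn, conditionMessage(e))
                NULL
              })
            if (is.null(f)) next
            fits[[paste(g, zn, sep = "/")]] <- f
            for (ref in setdiff(config$fit_references, f$reference))
              fits[[paste(g, zn, ref, sep = "/")]] <- relevel_contrasts(f, ref)
          }
        }
        if (!length(fits)) stop("stage 'fit': no species group/zone subset ",
                                "had enough data to model")
        state$fits <- fits
        write_stage_csv(coef_table(fits),
                        file.path(out_dir, "coefficients.csv"), "coefficients")
        jsonlite::write_json(lapply(fits, fit_summary_list),
                             file.path(out_dir, "fit_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        accounting$fit <- c(n_input = nrow(lab), n_kept = length(fits),
                            n_discarded = 0L)
      },
      fpsd = {
        if (is.null(state$fits)) {
          p <- file.path(out_dir, "fit_summary.json")
          if (!file.exists(p))
            stop("stage 'fpsd' needs the output of stage 'fit' ",
                 "(missing fit_summary.json); run the upstream stages first")
          state$fits <- lapply(jsonlite::read_json(p, simplifyVector = TRUE),
                               rehydrate_fit)
        }
        primary <- state$fits[!grepl("/(dark|red|white)$",
                                     names(state$fits))]
        res <- lapply(primary, fpsd_analysis,
                      threshold = config$onset_threshold,
                      d_grid = seq(0, config$d_max, by = 0.1))
        tab <- do.call(rbind, lapply(names(res), function(k) {
          cbind(model = k, res[[k]]$table)
        }))
        crv <- do.call(rbind, lapply(names(res), function(k) {
          cbind(model = k, res[[k]]$curves)
        }))
        state$fpsd <- res
        write_stage_csv(tab, file.path(out_dir, "fpsd.csv"), "fpsd")
        write_stage_csv(crv, file.path(out_dir, "fpsd_curves.csv"),
                        "fpsd_curves")
        accounting$fpsd <- c(n_input = length(primary),
                             n_kept = sum(tab$estimable),
                             n_discarded = sum(!tab$estimable))
      }
    )
    logit("stage %s: done", stage)
  }

  manifest <- list(
    package_version = as.character(packageVersion("pfif")),
    schema_version = SCHEMA_VERSION,
    seed = config$sim$rng_seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(cfg_path)),
    accounting = lapply(accounting, as.list)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest,
                 truth = state$truth, calls = state$calls,
                 positions = state$positions, labeled = state$labeled,
                 fits = state$fits, fpsd = state$fpsd))
}

fit_summary_list <- function(fit) {
  list(beta = as.list(fit$beta),
       vcov = unname(apply(fit$vcov, 1, as.numeric, simplify = FALSE)),
       re_sd = as.list(fit$re_sd),
       logLik = fit$logLik, AIC = fit$AIC, AIC_null = fit$AIC_null,
       r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
       n_obs = fit$n_obs, converged = fit$converged,
       reference = fit$reference, levels = fit$levels,
       zone = fit$zone,
       species_group = fit$species_group %||% NA)
}

# rebuild the minimal fit object the switch-distance stage needs
rehydrate_fit <- function(s) {
  beta <- unlist(s$beta)
  V <- do.call(rbind, lapply(s$vcov, as.numeric))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov = V, re_sd = unlist(s$re_sd),
                 logLik = s$logLik, AIC = s$AIC, AIC_null = s$AIC_null,
                 r2_marginal = s$r2_marginal, r2_conditional = s$r2_conditional,
                 n_obs = s$n_obs, converged = s$converged,
                 reference = s$reference, levels = unlist(s$levels),
                 zone = s$zone, species_group = s$species_group),
            class = "pfif_glmm")
}

#' Read and write schema-versioned pipeline tables
#'
#' Pipeline tables are UTF-8 CSV files (header row, `.` decimal separator)
#' whose first line is a comment recording the table name and schema
#' version.
#'
#' @param x data frame to write.
#' @param path file path.
#' @param name table name recorded in the schema comment.
#' @return `read_stage_csv()` returns a tibble.
#' @export
write_stage_csv <- function(x, path, name = "table") {
  writeLines(sprintf("# pfif %s schema v%d", name, SCHEMA_VERSION), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_stage_csv
#' @export
read_stage_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
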