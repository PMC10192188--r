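#' Pipeline configuration
#'
#' Builds (and validates) the configuration list consumed by
#' [run_pipeline()].  A configuration can equally be written as a YAML
#' file and loaded with [read_pipeline_config()].
#'
#' @param vectors,freqs,lists,trials,samples input file paths (the
#'   dialects written by [gen_experiment()]).
#' @param out_dir directory for all stage outputs.
#' @param rt_lower,rt_upper overall-RT exclusion bounds (ms).
#' @param outlier_k SD multiple of the per-participant DV filter.
#' @param measure a [measure_params()] list.
#' @param dvs named character vector mapping model labels to
#'   modelling-table DV columns for the four LMMs.
#' @param criticism_threshold standardized-residual cutoff for model
#'   criticism.
#' @param power_n_sims simulations for observed power; `0` disables the
#'   power stage.
#' @param alpha test level for the power stage.
#' @param seed RNG seed for the stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vectors, freqs, lists, trials, samples,
                            out_dir,
                            rt_lower = 300, rt_upper = 5000,
                            outlier_k = 3,
                            measure = measure_params(),
                            dvs = c(init_rt = "log_init_rt", md = "md",
                                    entropy = "log_entropy",
                                    mdtime = "log_mdtime"),
                            criticism_threshold = 2.5,
                            power_n_sims = 0, alpha = 0.05,
                            seed = 1L) {
  cfg <- list(paths = list(vectors = vectors, freqs = freqs,
                           lists = lists, trials = trials,
                           samples = samples),
              out_dir = out_dir, rt_lower = rt_lower,
              rt_upper = rt_upper, outlier_k = outlier_k,
              measure = measure, dvs = dvs,
              criticism_threshold = criticism_threshold,
              power_n_sims = power_n_sims, alpha = alpha,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  need <- c("paths", "out_dir", "rt_lower", "rt_upper", "outlier_k",
            "measure", "dvs", "criticism_threshold", "power_n_sims",
            "alpha", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("invalid pipeline config, missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pneed <- c("vectors", "freqs", "lists", "trials", "samples")
  pmiss <- setdiff(pneed, names(cfg$paths))
  if (length(pmiss))
    stop("invalid pipeline config, missing path(s): ",
         paste(pmiss, collapse = ", "), call. = FALSE)
  if (cfg$rt_lower >= cfg$rt_upper)
    stop("rt_lower must be below rt_upper", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(rt_lower = 300, rt_upper = 5000, outlier_k = 3,
                   measure = measure_params(),
                   dvs = c(init_rt = "log_init_rt", md = "md",
                           entropy = "log_entropy",
                           mdtime = "log_mdtime"),
                   criticism_threshold = 2.5, power_n_sims = 0,
                   alpha = 0.05, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$dvs <- unlist(cfg$dvs)
  cfg$measure <- do.call(measure_params, as.list(cfg$measure))
  validate_pipeline_config(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, SSim scoring, trajectory measurement, trial
#' exclusion, and the five confirmatory models (the response GLMM and
#' four LMMs, each with singularity fallback and model criticism, and
#' -- when `power_n_sims > 0` -- observed power for the triple
#' interaction).  Every stage writes a plain CSV/JSON artifact into
#' `out_dir`, and a run manifest records config hash, input checksums,
#' per-stage row counts, exclusion fractions, model provenance and
#' output checksums, so any stage can be re-run and audited in
#' isolation.
#'
#' @param config a [pipeline_config()] or the path to its YAML file.
#' @return Invisibly, a list with all fitted objects and the manifest
#'   (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  t0 <- Sys.time()
  log_stage <- function(...) message("[drmtrack] ", ...)

  lists <- read_study_lists(cfg$paths$lists)
  space <- read_word_vectors(cfg$paths$vectors,
                             restrict = as.data.frame(lists)$word)
  freqs <- read_frequency_norms(cfg$paths$freqs)
  trial_log <- utils::read.csv(cfg$paths$trials,
                               stringsAsFactors = FALSE)
  samples <- utils::read.csv(cfg$paths$samples,
                             stringsAsFactors = FALSE)
  log_stage("ingest: ", nrow(trial_log), " trials, ",
            nrow(samples), " samples")

  scores <- score_items(lists, space, freqs)
  write_ssim_scores(scores, file.path(cfg$out_dir, "ssim_scores.csv"))

  measures <- measure_trials(trial_log, samples, cfg$measure)
  utils::write.csv(measures, file.path(cfg$out_dir, "measures.csv"),
                   row.names = FALSE)
  log_stage("measures: ", sum(measures$aberrant), " aberrant of ",
            nrow(measures), " trials (",
            round(100 * mean(measures$aberrant), 1), "%)")

  filtered <- apply_trial_filters(measures, lower = cfg$rt_lower,
                                  upper = cfg$rt_upper,
                                  k = cfg$outlier_k)
  excl <- exclusion_report(filtered)
  jsonlite::write_json(excl, file.path(cfg$out_dir,
                                       "exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("filters: retained ", excl$n_retained, "/", excl$n_input,
            " (rt_bounds ", excl$counts$rt_bounds, ", aberrant ",
            excl$counts$aberrant, ", dv_outlier ",
            excl$counts$dv_outlier, ")")

  table <- build_model_table(filtered, scores)
  utils::write.csv(as.data.frame(table),
                   file.path(cfg$out_dir, "model_table.csv"),
                   row.names = FALSE)

  # descriptives both before and after the DV-outlier stage
  pre_outlier <- filter_aberrant(filter_overall_rt(
    measures, cfg$rt_lower, cfg$rt_upper))
  pre_outlier <- pre_outlier[!pre_outlier$excluded, , drop = FALSE]
  desc_raw <- dv_descriptives(pre_outlier)
  desc_filtered <- dv_descriptives(table)
  utils::write.csv(desc_raw$descriptives,
                   file.path(cfg$out_dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(stage = c(rep("pre_dv_filter", 4),
                                   rep("post_dv_filter", 4)),
                         rbind(as.data.frame(desc_raw$correlations),
                               as.data.frame(desc_filtered$correlations))),
                   file.path(cfg$out_dir, "correlations.csv"),
                   row.names = TRUE)

  fits <- list()
  glmm <- fit_glmm_response(table)
  glmm <- fallback_on_singularity(glmm, table)
  crit <- model_criticism(glmm, table,
                          threshold = cfg$criticism_threshold)
  fits$response <- list(fit = crit$fit,
                        slopes = simple_slopes(crit$fit),
                        removed = crit$removed)
  log_stage("glmm response: n = ", stats::nobs(crit$fit$fit),
            ", criticism removed ", length(crit$removed))

  power <- list()
  for (label in names(cfg$dvs)) {
    dv <- cfg$dvs[[label]]
    f <- fit_lmm_dv(table, dv)
    f <- fallback_on_singularity(f, table)
    cr <- model_criticism(f, table, threshold = cfg$criticism_threshold)
    tab_crit <- if (length(cr$removed)) table[-cr$removed, , drop = FALSE]
                else table
    fits[[label]] <- list(fit = cr$fit, slopes = simple_slopes(cr$fit),
                          removed = cr$removed)
    log_stage("lmm ", label, " (", dv, "): n = ",
              stats::nobs(cr$fit$fit), ", criticism removed ",
              length(cr$removed),
              if (cr$fit$provenance$fallback) ", item intercept dropped"
              else "")
    if (cfg$power_n_sims > 0) {
      power[[label]] <- observed_power(cr$fit, tab_crit,
                                       n_sims = cfg$power_n_sims,
                                       alpha = cfg$alpha,
                                       seed = cfg$seed + match(label,
                                         names(cfg$dvs)))
      log_stage("power ", label, ": ",
                round(100 * power[[label]]$power, 1), "%")
    }
  }

  for (label in names(fits)) {
    f <- fits[[label]]
    jsonlite::write_json(list(
      label = label, dv = f$fit$spec$dv,
      estimates = f$fit$estimates,
      varcomp = as.list(f$fit$varcomp),
      pseudo_r2_total = f$fit$pseudo_r2_total,
      singular = f$fit$singular, converged = f$fit$converged,
      provenance = f$fit$provenance[c("random", "fallback",
                                      "df_method",
                                      "pseudo_r2_method")],
      criticism_removed = f$removed,
      simple_slopes = f$slopes),
      file.path(cfg$out_dir, paste0("model_", label, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (length(power))
    jsonlite::write_json(lapply(power, unclass),
                         file.path(cfg$out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("drmtrack")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    inputs = as.list(tools::md5sum(unlist(cfg$paths))),
    rows = list(ingested = nrow(trial_log),
                measured = nrow(measures),
                retained = excl$n_retained,
                modelled = nrow(table)),
    exclusions = excl,
    models = lapply(fits, function(f) list(
      n = stats::nobs(f$fit$fit), singular = f$fit$singular,
      fallback = f$fit$provenance$fallback,
      criticism_removed = length(f$removed))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  outputs <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                     manifest_path)
  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  log_stage("done in ", round(manifest$elapsed_s, 1), " s")
  invisible(list(config = cfg, scores = scores, measures = measures,
                 filtered = filtered, table = table, fits = fits,
                 power = power, descriptives = list(
                   raw = desc_raw, filtered = desc_filtered),
                 manifest = manifest))
}

# Stable hash of the configuration (paths excluded, so the same
# analysis settings hash identically wherever the inputs live).
config_hash <- function(cfg) {
  core <- cfg[setdiff(names(cfg), c("paths", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
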