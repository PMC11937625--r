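#' Assemble and validate a pipeline run configuration
#'
#' @param mode One of `"simulate"`, `"run_daa"`, `"evaluate_split"`,
#'   `"evaluate_cross"`, `"calibrate"`, `"rank"`.
#' @param methods Registered method names.
#' @param alpha_grid Nominal FDR levels in (0, 1\].
#' @param n_repeats,min_group_size,prevalence_threshold,ci_level,
#'   validation_cutoff,validation_adjust Protocol parameters (see
#'   [evaluate_split()]).
#' @param covariate_names Covariates to adjust for.
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   small offsets, so a run is fully reproducible from the manifest.
#' @param sim Optional [sim_config()] for `mode = "simulate"` and for
#'   evaluation modes without input files.
#' @param input Optional named list of input paths: `counts`, `metadata`,
#'   `group_column`, `case_label`; or for `evaluate_cross`, `manifest` (a
#'   tab-separated dataset manifest with columns `id`, `condition`,
#'   `counts_path`, `metadata_path`, `group_column`, `case_label`).
#' @param target_nhits Target for `mode = "calibrate"`.
#' @param out_dir Output directory for reports.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "run_daa", "evaluate_split",
                                "evaluate_cross", "calibrate", "rank"),
                       methods = c("orm", "linear_logtss", "logr"),
                       alpha_grid = c(0.01, 0.05, 0.10, 0.20),
                       n_repeats = 5L, min_group_size = 10L,
                       prevalence_threshold = 0.10, ci_level = 0.834,
                       validation_cutoff = 0.05, validation_adjust = "none",
                       covariate_names = character(), seed = 1L,
                       sim = NULL, input = NULL, target_nhits = NULL,
                       out_dir = ".") {
  mode <- match.arg(mode)
  if (any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop_config("alpha_grid", "all values must be in (0, 1]")
  }
  unknown <- setdiff(methods, names(daa_method_registry()))
  if (length(unknown)) {
    stop_config("methods", paste("unknown method(s):",
                                 paste(unknown, collapse = ", ")))
  }
  structure(list(mode = mode, methods = methods, alpha_grid = alpha_grid,
                 n_repeats = n_repeats, min_group_size = min_group_size,
                 prevalence_threshold = prevalence_threshold,
                 ci_level = ci_level, validation_cutoff = validation_cutoff,
                 validation_adjust = validation_adjust,
                 covariate_names = covariate_names, seed = as.integer(seed),
                 sim = sim, input = input, target_nhits = target_nhits,
                 out_dir = out_dir),
            class = "run_config")
}

# fixed per-stage seed derivation from the master seed
stage_seed <- function(config, stage) {
  offsets <- c(simulate = 1L, split = 2L, permute = 3L)
  config$seed + offsets[[stage]]
}

pipeline_input_dataset <- function(config) {
  if (!is.null(config$input) && !is.null(config$input$counts)) {
    read_count_dataset(config$input$counts, config$input$metadata,
                       group_column = config$input$group_column %||% "group",
                       case_label = config$input$case_label)
  } else if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- sim$seed %||% stage_seed(config, "simulate")
    simulate_dataset(sim)$dataset
  } else {
    stop_data("mode '%s' needs either input files or a sim config",
              config$mode)
  }
}

#' Run the configured pipeline end to end
#'
#' Executes one pipeline mode and writes its reports (tab-separated tables)
#' and a plain-text manifest capturing the configuration, derived seeds and
#' package version into `config$out_dir`. Per-taxon model failures never
#' abort a run; they are downgraded to degenerate/failed status and counted
#' in the log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the mode's main result (and the paths
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  result <- NULL

  if (config$mode == "simulate") {
    sim_cfg <- config$sim %||% sim_config()
    sim_cfg$seed <- sim_cfg$seed %||% stage_seed(config, "simulate")
    sim <- simulate_dataset(sim_cfg)
    paths <- write_count_dataset(
      sim$dataset,
      counts_path = file.path(config$out_dir, "counts.tsv"),
      metadata_path = file.path(config$out_dir, "metadata.tsv"),
      truth = sim$truth,
      truth_path = file.path(config$out_dir, "truth.tsv"))
    result <- sim
  } else if (config$mode == "run_daa") {
    dataset <- pipeline_input_dataset(config)
    flt <- filter_prevalence(dataset, config$prevalence_threshold)
    paths <- file.path(config$out_dir, "filter_report.tsv")
    write_filter_report(flt$report, paths)
    result <- lapply(config$methods, function(m) {
      res <- run_method(m, flt$dataset,
                        covariate_names = config$covariate_names,
                        ci_level = config$ci_level)
      p <- file.path(config$out_dir, sprintf("daa_%s.tsv", m))
      write_daa_result(res, p)
      paths <<- c(paths, p)
      res
    })
    names(result) <- config$methods
  } else if (config$mode %in% c("evaluate_split", "calibrate", "rank")) {
    dataset <- pipeline_input_dataset(config)
    ev <- evaluate_split(dataset, methods = config$methods,
                         alpha_grid = config$alpha_grid,
                         n_repeats = config$n_repeats,
                         min_group_size = config$min_group_size,
                         prevalence_threshold = config$prevalence_threshold,
                         validation_cutoff = config$validation_cutoff,
                         validation_adjust = config$validation_adjust,
                         ci_level = config$ci_level,
                         covariate_names = config$covariate_names,
                         seed = stage_seed(config, "split"))
    p <- file.path(config$out_dir, "metrics_summary.tsv")
    utils::write.table(ev$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- p
    result <- ev
    if (config$mode == "calibrate") {
      if (is.null(config$target_nhits)) {
        stop_config("target_nhits", "required for mode 'calibrate'")
      }
      cal <- lapply(config$methods, function(m) {
        expl <- lapply(ev$results[[m]], `[[`, "exploratory")
        calibrate_alpha_for_nhits(expl, config$target_nhits)
      })
      names(cal) <- config$methods
      cal_df <- data.frame(method = config$methods,
                           alpha = vapply(cal, `[[`, numeric(1), "alpha"),
                           n_hits = vapply(cal, `[[`, integer(1), "n_hits"))
      p <- file.path(config$out_dir, "calibrated_alpha.tsv")
      utils::write.table(cal_df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
      result$calibration <- cal
    }
    if (config$mode == "rank") {
      rk <- rank_methods(ev$summary)
      p <- file.path(config$out_dir, "ranking.tsv")
      utils::write.table(rk, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
      result$ranking <- rk
    }
  } else if (config$mode == "evaluate_cross") {
    if (is.null(config$input$manifest)) {
      stop_config("input$manifest", "required for mode 'evaluate_cross'")
    }
    man <- utils::read.delim(config$input$manifest,
                             stringsAsFactors = FALSE)
    needed <- c("id", "condition", "counts_path", "metadata_path",
                "group_column", "case_label")
    miss <- setdiff(needed, names(man))
    if (length(miss)) {
      stop_data("dataset manifest missing column(s): %s",
                paste(miss, collapse = ", "))
    }
    if (anyDuplicated(man$id)) stop_data("duplicated dataset id in manifest")
    datasets <- lapply(seq_len(nrow(man)), function(i) {
      read_count_dataset(man$counts_path[i], man$metadata_path[i],
                         group_column = man$group_column[i],
                         case_label = man$case_label[i])
    })
    names(datasets) <- man$id
    cond <- stats::setNames(man$condition, man$id)
    ev <- evaluate_cross(datasets, cond, methods = config$methods,
                         alpha_grid = config$alpha_grid,
                         min_group_size = config$min_group_size,
                         prevalence_threshold = config$prevalence_threshold,
                         validation_cutoff = config$validation_cutoff,
                         validation_adjust = config$validation_adjust,
                         ci_level = config$ci_level,
                         covariate_names = config$covariate_names)
    if (!is.null(ev$summary)) {
      p <- file.path(config$out_dir, "metrics_summary.tsv")
      utils::write.table(ev$summary, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- p
    }
    result <- ev
  }

  manifest <- c(
    sprintf("daareplic version: %s",
            as.character(utils::packageVersion("daareplic"))),
    sprintf("mode: %s", config$mode),
    sprintf("methods: %s", paste(config$methods, collapse = ", ")),
    sprintf("alpha_grid: %s", paste(config$alpha_grid, collapse = ", ")),
    sprintf("n_repeats: %d", config$n_repeats),
    sprintf("min_group_size: %d", config$min_group_size),
    sprintf("prevalence_threshold: %g", config$prevalence_threshold),
    sprintf("ci_level: %g", config$ci_level),
    sprintf("validation_cutoff: %g", config$validation_cutoff),
    sprintf("validation_adjust: %s", config$validation_adjust),
    sprintf("seed: %d", config$seed),
    sprintf("written: %s", paste(paths, collapse = ", "))
  )
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(list(result = result, paths = paths,
                 manifest = file.path(config$out_dir, "manifest.txt")))
}
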