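#' Split-data replication evaluation of DAA methods
#'
#' The within-study protocol: a dataset is randomly split `n_repeats` times
#' into exploratory/validation halves (stratified by group); each half is
#' prevalence-filtered independently; every requested method is run on both
#' halves; candidate taxa are classified as replicated, conflicting or not
#' validated; and the consistency/sensitivity metrics are pooled over all
#' splits for every nominal FDR level in `alpha_grid`.
#'
#' @param dataset A [count_dataset()].
#' @param methods Character vector of registered method names
#'   (see [daa_method_registry()]).
#' @param alpha_grid Nominal FDR levels (default `c(0.01, 0.05, 0.10,
#'   0.20)`).
#' @param n_repeats,min_group_size,seed Passed to [split_dataset()].
#' @param prevalence_threshold Prevalence filter applied independently to
#'   each half (default 0.10).
#' @param validation_cutoff,validation_adjust Passed to
#'   [classify_outcomes()].
#' @param ci_level Level of the confidence intervals used for the CI%
#'   metric (default 0.834).
#' @param covariate_names Covariates passed to every method.
#' @return A list with
#'   \describe{
#'     \item{summary}{data.frame with one row per method per alpha: method,
#'       alpha, n_candidates, conflict_pct, replication_pct, n_hits,
#'       pooled_spearman, ci_overlap_pct, ideal_conflict_bound;}
#'     \item{outcomes}{nested list `[[method]][[alpha]][[pair]]` of
#'       `outcome_record` tables;}
#'     \item{results}{nested list `[[method]][[pair]]` with the exploratory
#'       and validation `daa_result` tables;}
#'     \item{pairs}{the `split_pair` list (unfiltered halves).}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_case = 40, n_control = 40, seed = 7))
#' ev <- evaluate_split(sim$dataset, methods = "linear_logtss",
#'                      n_repeats = 2, seed = 11)
#' ev$summary
#' }
#' @export
evaluate_split <- function(dataset, methods = c("orm", "linear_logtss", "logr"),
                           alpha_grid = c(0.01, 0.05, 0.10, 0.20),
                           n_repeats = 5L, min_group_size = 10L,
                           prevalence_threshold = 0.10,
                           validation_cutoff = 0.05,
                           validation_adjust = "none",
                           ci_level = 0.834,
                           covariate_names = character(), seed = NULL) {
  pairs <- split_dataset(dataset, n_repeats = n_repeats,
                         min_group_size = min_group_size, seed = seed)
  evaluate_pairs(pairs, methods = methods, alpha_grid = alpha_grid,
                 prevalence_threshold = prevalence_threshold,
                 validation_cutoff = validation_cutoff,
                 validation_adjust = validation_adjust,
                 ci_level = ci_level, covariate_names = covariate_names,
                 aggregation = "any")
}

#' Separate-study replication evaluation of DAA methods
#'
#' The between-study protocol: same-condition datasets are paired so each
#' eligible dataset serves as the exploratory study with all other eligible
#' same-condition datasets as its validation studies; methods are run on
#' every (independently filtered) dataset and candidate outcomes are
#' aggregated over the validation studies of each exploratory dataset.
#'
#' With `aggregation = "any"` (default) a candidate counts as replicated if
#' it replicates in at least one validation dataset and as conflicting if
#' it conflicts in at least one; a candidate that does both increments both
#' numerators over a single-candidate denominator and is reported in
#' `n_double`. With `aggregation = "first"` the first validation dataset in
#' which the candidate is present decides its outcome.
#'
#' @inheritParams evaluate_split
#' @param datasets Named list of [count_dataset()] objects.
#' @param condition_map Named character vector of condition labels (see
#'   [pair_separate_studies()]).
#' @param aggregation `"any"` or `"first"`.
#' @return As [evaluate_split()]; the summary additionally carries
#'   `n_double`.
#' @export
evaluate_cross <- function(datasets, condition_map,
                           methods = c("orm", "linear_logtss", "logr"),
                           alpha_grid = c(0.01, 0.05, 0.10, 0.20),
                           min_group_size = 10L,
                           prevalence_threshold = 0.10,
                           validation_cutoff = 0.05,
                           validation_adjust = "none",
                           ci_level = 0.834,
                           covariate_names = character(),
                           aggregation = c("any", "first")) {
  aggregation <- match.arg(aggregation)
  pairs <- pair_separate_studies(datasets, condition_map,
                                 min_group_size = min_group_size)
  if (length(pairs) == 0) {
    return(list(summary = NULL, outcomes = list(), results = list(),
                pairs = pairs))
  }
  evaluate_pairs(pairs, methods = methods, alpha_grid = alpha_grid,
                 prevalence_threshold = prevalence_threshold,
                 validation_cutoff = validation_cutoff,
                 validation_adjust = validation_adjust,
                 ci_level = ci_level, covariate_names = covariate_names,
                 aggregation = aggregation)
}

# shared engine for both protocols: run methods on the filtered datasets of
# every pair, classify candidates, pool metrics
evaluate_pairs <- function(pairs, methods, alpha_grid, prevalence_threshold,
                           validation_cutoff, validation_adjust, ci_level,
                           covariate_names, aggregation) {
  filtered <- lapply(pairs, function(pr) {
    list(
      exploratory = filter_prevalence(pr$exploratory,
                                      prevalence_threshold)$dataset,
      validation = lapply(pr$validation, function(v) {
        filter_prevalence(v, prevalence_threshold)$dataset
      })
    )
  })

  results <- lapply(methods, function(m) {
    lapply(filtered, function(fp) {
      list(
        exploratory = run_method(m, fp$exploratory,
                                 covariate_names = covariate_names,
                                 ci_level = ci_level),
        validation = lapply(fp$validation, function(v) {
          run_method(m, v, covariate_names = covariate_names,
                     ci_level = ci_level)
        })
      )
    })
  })
  names(results) <- methods

  summary_rows <- list()
  outcomes_all <- list()
  for (m in methods) {
    res_m <- results[[m]]
    # estimate correlation over all (exploratory, validation) combinations
    corr_pairs <- unlist(lapply(res_m, function(rp) {
      lapply(rp$validation, function(vres) {
        list(exploratory = stats::setNames(rp$exploratory$estimate,
                                           rp$exploratory$taxon_id),
             validation = stats::setNames(vres$estimate, vres$taxon_id))
      })
    }), recursive = FALSE)
    pooled_rho <- suppressMessages(pool_estimate_correlation(corr_pairs))

    outcomes_all[[m]] <- list()
    for (a in alpha_grid) {
      per_pair <- vector("list", length(pairs))
      n_conf <- n_repl <- n_cand <- n_double <- 0L
      ov_num <- ov_den <- 0L
      for (i in seq_along(pairs)) {
        fp <- filtered[[i]]
        rp <- res_m[[i]]
        per_val <- lapply(seq_along(fp$validation), function(j) {
          cand <- identify_candidates(rp$exploratory, fp$validation[[j]], a)
          classify_outcomes(cand, rp$exploratory, rp$validation[[j]],
                            validation_cutoff = validation_cutoff,
                            validation_adjust = validation_adjust)
        })
        agg <- aggregate_pair_outcomes(per_val, aggregation)
        per_pair[[i]] <- agg$outcomes
        n_cand <- n_cand + agg$n_candidates
        n_conf <- n_conf + agg$n_conflicting
        n_repl <- n_repl + agg$n_replicated
        n_double <- n_double + agg$n_double
        # CI overlap pooled over validation datasets of the pair
        for (j in seq_along(fp$validation)) {
          ov <- ci_overlap_pct(per_val[[j]], rp$exploratory,
                               rp$validation[[j]],
                               exploratory_dataset = fp$exploratory,
                               validation_dataset = fp$validation[[j]],
                               min_group_prevalence = prevalence_threshold)
          if (ov$n_eligible > 0) {
            ov_num <- ov_num + round(ov$ci_overlap_pct * ov$n_eligible)
            ov_den <- ov_den + ov$n_eligible
          }
        }
      }
      outcomes_all[[m]][[format(a)]] <- per_pair
      nhits <- count_hits(lapply(res_m, `[[`, "exploratory"), a)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        method = m, alpha = a,
        n_candidates = n_cand,
        conflict_pct = if (n_cand > 0) n_conf / n_cand else NA_real_,
        replication_pct = if (n_cand > 0) n_repl / n_cand else NA_real_,
        n_hits = nhits,
        pooled_spearman = pooled_rho,
        ci_overlap_pct = if (ov_den > 0) ov_num / ov_den else NA_real_,
        n_ci_eligible = ov_den,
        n_double = n_double,
        ideal_conflict_bound = ideal_conflict_bound(a),
        stringsAsFactors = FALSE
      )
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(summary = summary, outcomes = outcomes_all, results = results,
       pairs = pairs)
}

# combine per-validation outcome records of one exploratory dataset
aggregate_pair_outcomes <- function(per_val, aggregation) {
  all_cand <- unique(unlist(lapply(per_val, `[[`, "taxon_id")))
  if (length(all_cand) == 0) {
    return(list(outcomes = per_val[[1]], n_candidates = 0L,
                n_conflicting = 0L, n_replicated = 0L, n_double = 0L))
  }
  status <- t(vapply(all_cand, function(tx) {
    oc <- unlist(lapply(per_val, function(o) o$outcome[o$taxon_id == tx]))
    if (aggregation == "first") oc <- oc[1]
    c(repl = any(oc == "replicated"), conf = any(oc == "conflicting"))
  }, logical(2)))
  n_repl <- sum(status[, "repl"])
  n_conf <- sum(status[, "conf"])
  n_double <- sum(status[, "repl"] & status[, "conf"])
  merged <- do.call(rbind, per_val)
  merged <- merged[!duplicated(merged$taxon_id), , drop = FALSE]
  merged$outcome <- ifelse(
    status[match(merged$taxon_id, all_cand), "repl"] &
      status[match(merged$taxon_id, all_cand), "conf"], "both",
    ifelse(status[match(merged$taxon_id, all_cand), "repl"], "replicated",
           ifelse(status[match(merged$taxon_id, all_cand), "conf"],
                  "conflicting", merged$outcome)))
  list(outcomes = merged, n_candidates = length(all_cand),
       n_conflicting = n_conf, n_replicated = n_repl, n_double = n_double)
}
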