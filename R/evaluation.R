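#' @title Replication protocols and consistency metrics
#' @description
#' Implements the two replication protocols — random split-halves of one
#' dataset, and exploratory/validation pairing of separate same-condition
#' studies — together with the consistency and sensitivity metrics computed
#' on them: percentage of conflicting results (Conflict%), percentage of
#' replicated results (Replication%), number of hits (NHits), pooled
#' Spearman correlation of effect estimates, and the overlap percentage of
#' confidence intervals (CI%).
#' @name evaluation
NULL

#' Randomly split a dataset into exploratory/validation halves
#'
#' Each of `n_repeats` splits partitions the samples into two equal-sized
#' halves (sizes differing by at most one), stratified by group so that both
#' halves preserve the case/control proportions. When a group has an odd
#' count the extra sample goes to the exploratory half. Both groups must
#' have at least `2 * min_group_size` samples so each half keeps the
#' required minimum per group.
#'
#' @param dataset A [count_dataset()].
#' @param n_repeats Number of independent random splits (default 5).
#' @param min_group_size Minimum case and control count required in each
#'   half (default 10).
#' @param seed Integer seed; `NULL` uses the ambient RNG.
#' @return A list of `split_pair` objects, each a list with `exploratory`
#'   (a `count_dataset`), `validation` (a list of `count_dataset`, length 1
#'   here), `replicate_index` and `origin`. Prevalence filtering is *not*
#'   applied here; each half is filtered independently downstream.
#' @export
split_dataset <- function(dataset, n_repeats = 5L, min_group_size = 10L,
                          seed = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (!is_count_scalar(n_repeats) || n_repeats < 1) {
    stop_data("'n_repeats' must be a positive integer")
  }
  sizes <- table(dataset$group)
  too_small <- sizes < 2L * min_group_size
  if (any(too_small)) {
    g <- names(sizes)[too_small][1]
    stop_data(paste0("group '%s' has %d samples; %d are required so both ",
                     "halves keep at least %d per group"),
              g, sizes[[g]], 2L * min_group_size, min_group_size)
  }
  ids <- colnames(dataset$counts)
  with_seed_or_ambient(seed, {
    lapply(seq_len(n_repeats), function(r) {
      expl_ids <- unlist(lapply(c("control", "case"), function(g) {
        in_g <- ids[dataset$group == g]
        n_expl <- ceiling(length(in_g) / 2)
        sample(in_g, n_expl)
      }), use.names = FALSE)
      val_ids <- setdiff(ids, expl_ids)
      structure(
        list(exploratory = subset_dataset(dataset, samples = expl_ids),
             validation = list(subset_dataset(dataset, samples = val_ids)),
             replicate_index = r, origin = dataset$provenance),
        class = "split_pair"
      )
    })
  })
}

#' Pair separate same-condition studies as exploratory/validation sets
#'
#' For each condition with at least two eligible datasets, every eligible
#' dataset serves once as the exploratory dataset with all other
#' same-condition eligible datasets as its validation list. A dataset is
#' eligible when both its groups have at least `min_group_size` samples.
#'
#' @param datasets Named list of [count_dataset()] objects.
#' @param condition_map Named character vector mapping dataset names to
#'   condition labels.
#' @param min_group_size Minimum per-group sample count (default 10).
#' @return A list of `split_pair` objects (possibly empty, with a message
#'   when no condition has two eligible datasets).
#' @export
pair_separate_studies <- function(datasets, condition_map,
                                  min_group_size = 10L) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  missing_cond <- setdiff(names(datasets), names(condition_map))
  if (length(missing_cond)) {
    stop_data("no condition label for dataset(s): %s",
              paste(missing_cond, collapse = ", "))
  }
  eligible <- vapply(datasets, function(ds) {
    all(table(ds$group) >= min_group_size) && nlevels(droplevels(ds$group)) == 2
  }, logical(1))
  pairs <- list()
  for (cond in unique(condition_map[names(datasets)])) {
    members <- names(datasets)[condition_map[names(datasets)] == cond & eligible]
    if (length(members) < 2) next
    for (ex in members) {
      others <- setdiff(members, ex)
      pairs[[length(pairs) + 1L]] <- structure(
        list(exploratory = datasets[[ex]],
             validation = datasets[others],
             replicate_index = length(pairs) + 1L,
             origin = sprintf("%s[%s]", cond, ex)),
        class = "split_pair"
      )
    }
  }
  if (length(pairs) == 0) {
    message("pair_separate_studies: no condition has two eligible datasets")
  }
  pairs
}

#' Identify candidate taxa
#'
#' A taxon is a candidate when it is significant in the exploratory dataset
#' (FDR-adjusted q-value below `alpha`) and still present — i.e. retained by
#' the prevalence filter — in the validation dataset.
#'
#' @param exploratory_results A `daa_result` from the exploratory dataset.
#' @param validation_dataset The *already prevalence-filtered* validation
#'   [count_dataset()].
#' @param alpha Nominal FDR level.
#' @return Character vector of candidate taxon ids.
#' @export
identify_candidates <- function(exploratory_results, validation_dataset,
                                alpha) {
  stopifnot(inherits(exploratory_results, "daa_result"),
            inherits(validation_dataset, "count_dataset"))
  sig <- exploratory_results$taxon_id[
    !is.na(exploratory_results$q) & exploratory_results$q < alpha &
      exploratory_results$status == "ok"]
  intersect(sig, rownames(validation_dataset$counts))
}

#' Classify candidate outcomes against a validation dataset
#'
#' A candidate replicates when it is significant in the validation dataset
#' (unadjusted P below `validation_cutoff` by default) with the same nonzero
#' effect direction as in the exploratory dataset; it conflicts when it is
#' significant with the opposite nonzero direction; otherwise it is not
#' validated. With `validation_adjust = "bh"` the validation P-values of the
#' candidate taxa are BH-adjusted before applying the cutoff.
#'
#' @param candidates Character vector of candidate taxon ids (from
#'   [identify_candidates()]).
#' @param exploratory_results,validation_results `daa_result` tables.
#' @param validation_cutoff Significance cutoff in validation (default .05).
#' @param validation_adjust `"none"` (default) or `"bh"`.
#' @return A data.frame of class `outcome_record` with columns `taxon_id`,
#'   `exploratory_direction`, `exploratory_q`, `validation_p`,
#'   `validation_direction` and `outcome` in
#'   `{replicated, conflicting, not_validated, absent_in_validation}`.
#' @export
classify_outcomes <- function(candidates, exploratory_results,
                              validation_results, validation_cutoff = 0.05,
                              validation_adjust = c("none", "bh")) {
  validation_adjust <- match.arg(validation_adjust)
  ex <- exploratory_results[match(candidates, exploratory_results$taxon_id), ]
  vl <- validation_results[match(candidates, validation_results$taxon_id), ]
  vp <- vl$p
  if (validation_adjust == "bh" && length(candidates)) {
    ok <- !is.na(vp)
    vp[ok] <- adjust_fdr_bh(vp[ok])
  }
  outcome <- character(length(candidates))
  for (i in seq_along(candidates)) {
    if (is.na(vl$taxon_id[i]) || is.na(vp[i]) || vl$status[i] == "failed") {
      outcome[i] <- "absent_in_validation"
    } else if (vp[i] < validation_cutoff &&
               ex$direction[i] != 0 && vl$direction[i] != 0) {
      outcome[i] <- if (ex$direction[i] == vl$direction[i]) "replicated"
                    else "conflicting"
    } else {
      outcome[i] <- "not_validated"
    }
  }
  out <- data.frame(taxon_id = candidates,
                    exploratory_direction = ex$direction,
                    exploratory_q = ex$q,
                    validation_p = vp,
                    validation_direction = vl$direction,
                    outcome = outcome,
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome_record", "data.frame")
  out
}

#' Pool Conflict% and Replication% across exploratory/validation pairs
#'
#' Overall percentages are computed by summing numerators (conflicting or
#' replicated candidates) and denominators (all candidates) over all pairs
#' before dividing — pooling, not averaging of per-pair percentages. With 5
#' of 8 candidates replicating in one pair and 2 of 2 in another, the pooled
#' Replication% is (5+2)/(8+2) = 0.70, not the mean of 5/8 and 2/2.
#'
#' @param outcomes_by_pair List of `outcome_record` data.frames, one per
#'   exploratory/validation pair.
#' @return List with `conflict_pct` and `replication_pct` (proportions of
#'   all candidates; `NA` when there are no candidates) and `n_candidates`.
#' @export
pool_metrics <- function(outcomes_by_pair) {
  n_cand <- sum(vapply(outcomes_by_pair, nrow, integer(1)))
  n_conf <- sum(vapply(outcomes_by_pair,
                       function(o) sum(o$outcome == "conflicting"), numeric(1)))
  n_repl <- sum(vapply(outcomes_by_pair,
                       function(o) sum(o$outcome == "replicated"), numeric(1)))
  if (n_cand == 0) {
    return(list(conflict_pct = NA_real_, replication_pct = NA_real_,
                n_candidates = 0L))
  }
  list(conflict_pct = n_conf / n_cand, replication_pct = n_repl / n_cand,
       n_candidates = as.integer(n_cand))
}

#' Total number of significant taxa across exploratory datasets (NHits)
#'
#' @param results_by_exploratory List of `daa_result` tables, one per
#'   exploratory dataset.
#' @param alpha Nominal FDR level; a taxon counts when `q < alpha`.
#' @return Integer total; non-decreasing in `alpha`.
#' @export
count_hits <- function(results_by_exploratory, alpha) {
  sum(vapply(results_by_exploratory, function(res) {
    sum(!is.na(res$q) & res$q < alpha & res$status == "ok")
  }, numeric(1)))
}

#' Pool Spearman correlations of effect estimates across pairs
#'
#' For each pair, the Spearman correlation between exploratory and
#' validation effect estimates over their shared taxa; the pooled value is
#' the hyperbolic tangent of the mean of the inverse-hyperbolic-tangent
#' (Fisher z) transformed per-pair correlations. Correlations of magnitude
#' one are clipped to `1 - 1e-12` before the z-transform; pairs with fewer
#' than three shared taxa are skipped with a message.
#'
#' @param pairs List where each element is a list with named numeric vectors
#'   `exploratory` and `validation` of effect estimates (names = taxon ids).
#' @return Pooled correlation in \[-1, 1\], or `NA` if no pair is usable.
#' @export
pool_estimate_correlation <- function(pairs) {
  rhos <- vapply(pairs, function(pr) {
    shared <- intersect(names(pr$exploratory), names(pr$validation))
    e <- pr$exploratory[shared]; v <- pr$validation[shared]
    keep <- is.finite(e) & is.finite(v)
    if (sum(keep) < 3) return(NA_real_)
    suppressWarnings(stats::cor(e[keep], v[keep], method = "spearman"))
  }, numeric(1))
  skipped <- sum(is.na(rhos))
  if (skipped > 0) {
    message(sprintf(
      "pool_estimate_correlation: skipped %d pair(s) with < 3 shared taxa or undefined correlation",
      skipped))
  }
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0) return(NA_real_)
  rhos <- pmin(pmax(rhos, -(1 - 1e-12)), 1 - 1e-12)
  tanh(mean(atanh(rhos)))
}

#' Overlap percentage of confidence intervals (CI%)
#'
#' Fraction of eligible candidate taxa whose exploratory and validation
#' confidence intervals intersect. Intervals are treated as closed: a shared
#' endpoint counts as overlap. Eligibility follows the protocol: candidate
#' taxa with at least `min_group_prevalence` prevalence in *both*
#' experimental groups (checked in both datasets when they are supplied).
#' With normally distributed estimates of equal standard error, two
#' independent 83.4% intervals for the same quantity overlap about 95% of
#' the time, which motivates the default level.
#'
#' @param outcomes An `outcome_record` data.frame (the candidates).
#' @param exploratory_results,validation_results `daa_result` tables
#'   carrying `ci_low`/`ci_high` at the same level.
#' @param exploratory_dataset,validation_dataset Optional
#'   [count_dataset()]s used to compute per-group prevalences for the
#'   eligibility rule; when omitted, the prevalence condition is not
#'   applied.
#' @param min_group_prevalence Minimum per-group prevalence (default 0.10).
#' @return List with `ci_overlap_pct` (proportion, `NA` when no taxon is
#'   eligible or the method provides no intervals) and `n_eligible`.
#' @export
ci_overlap_pct <- function(outcomes, exploratory_results, validation_results,
                           exploratory_dataset = NULL,
                           validation_dataset = NULL,
                           min_group_prevalence = 0.10) {
  taxa <- outcomes$taxon_id
  if (length(taxa) == 0) {
    return(list(ci_overlap_pct = NA_real_, n_eligible = 0L))
  }
  eligible <- rep(TRUE, length(taxa))
  for (ds in list(exploratory_dataset, validation_dataset)) {
    if (is.null(ds)) next
    pc <- taxon_prevalence(ds, "case")
    pt <- taxon_prevalence(ds, "control")
    present <- taxa %in% rownames(ds$counts)
    ok <- present & pc[taxa] >= min_group_prevalence &
      pt[taxa] >= min_group_prevalence
    ok[is.na(ok)] <- FALSE
    eligible <- eligible & ok
  }
  ex <- exploratory_results[match(taxa, exploratory_results$taxon_id), ]
  vl <- validation_results[match(taxa, validation_results$taxon_id), ]
  has_ci <- is.finite(ex$ci_low) & is.finite(ex$ci_high) &
    is.finite(vl$ci_low) & is.finite(vl$ci_high)
  eligible <- eligible & has_ci
  if (!any(eligible)) {
    return(list(ci_overlap_pct = NA_real_, n_eligible = 0L))
  }
  overlap <- ex$ci_low[eligible] <= vl$ci_high[eligible] &
    vl$ci_low[eligible] <= ex$ci_high[eligible]
  list(ci_overlap_pct = mean(overlap), n_eligible = sum(eligible))
}

#' Ideal upper bound for Conflict%
#'
#' Approximate upper limit for the percentage of conflicting results a
#' well-calibrated method should produce in split-data evaluation at
#' nominal FDR level `alpha`: at most a fraction `alpha` of candidates are
#' false discoveries, and a false discovery conflicts only when it is
#' significant in validation (probability 0.05 at the unadjusted .05
#' cutoff) with the opposite of its exploratory direction (probability
#' 0.50). The bound is therefore `alpha * 0.50 * 0.05` — e.g. 0.125% at
#' alpha = 0.05 and 0.50% at alpha = 0.20.
#'
#' @param alpha Nominal FDR level in \[0, 1\].
#' @return The bound, as a proportion.
#' @export
ideal_conflict_bound <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha < 0 | alpha > 1)) {
    stop_data("'alpha' must be in [0, 1]")
  }
  alpha * 0.50 * 0.05
}

#' Monte Carlo overlap rate of confidence intervals under normal sampling
#'
#' Simulates pairs of independent, equal-standard-error normal estimates of
#' a common mean, forms Wald intervals at `ci_level` for each, and returns
#' the fraction of pairs whose intervals intersect. At the 83.4% level this
#' fraction is approximately 95%, the calibration motivating the CI%
#' metric's interval level.
#'
#' @param n_pairs Number of simulated pairs (default 100000).
#' @param ci_level Interval level (default 0.834).
#' @param seed Integer seed; `NULL` uses the ambient RNG.
#' @return Proportion of overlapping pairs.
#' @export
ci_overlap_normal_mc <- function(n_pairs = 1e5, ci_level = 0.834,
                                 seed = NULL) {
  if (!is_count_scalar(n_pairs) || n_pairs < 1) {
    stop_data("'n_pairs' must be a positive integer")
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  with_seed_or_ambient(seed, {
    e1 <- stats::rnorm(n_pairs)
    e2 <- stats::rnorm(n_pairs)
    mean(abs(e1 - e2) <= 2 * z)
  })
}

#' Calibrate the nominal FDR level to reach a target number of hits
#'
#' Finds the smallest significance level `alpha` (searching the grid of
#' observed q-values, where NHits steps) such that
#' `count_hits(results, alpha) >= target_nhits`. Exact equality is attained
#' whenever the q-value grid allows it, so methods can be compared at an
#' identical number of detections.
#'
#' @param results_by_exploratory List of `daa_result` tables, one per
#'   exploratory dataset.
#' @param target_nhits Target total number of significant taxa.
#' @return List with `alpha`, the achieved `n_hits`, and `exact`
#'   (`TRUE` when `n_hits == target_nhits`).
#' @export
calibrate_alpha_for_nhits <- function(results_by_exploratory, target_nhits) {
  if (!is_count_scalar(target_nhits)) {
    stop_data("'target_nhits' must be a non-negative integer")
  }
  qs <- sort(unique(unlist(lapply(results_by_exploratory, function(res) {
    res$q[!is.na(res$q) & res$status == "ok"]
  }))))
  if (target_nhits == 0) {
    a <- if (length(qs)) qs[1] / 2 else 0
    return(list(alpha = a, n_hits = 0L, exact = TRUE))
  }
  # candidate alphas: just above each distinct q (counting uses strict <)
  grid <- c(if (length(qs) > 1) (qs[-length(qs)] + qs[-1]) / 2,
            min(1, qs[length(qs)] + .Machine$double.eps * 4), 1)
  grid <- sort(unique(grid))
  max_hits <- count_hits(results_by_exploratory, 1 + 1e-9)
  if (max_hits < target_nhits) {
    stop_data("target of %d hits unattainable; maximum attainable is %d",
              target_nhits, max_hits)
  }
  lo <- 1L; hi <- length(grid)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (count_hits(results_by_exploratory, grid[mid]) >= target_nhits) {
      hi <- mid
    } else {
      lo <- mid + 1L
    }
  }
  achieved <- count_hits(results_by_exploratory, grid[lo])
  list(alpha = grid[lo], n_hits = as.integer(achieved),
       exact = achieved == target_nhits)
}

#' Type-I-error calibration by group-label permutation
#'
#' Runs a DAA method on `n_perms` label-permuted versions of a dataset (a
#' scenario with no truly differentially abundant taxa) and returns the
#' pooled fraction of unadjusted P-values below .05. For a well-calibrated
#' method this fraction is close to 5%. Degenerate and failed taxa are
#' excluded from the denominator.
#'
#' @param method Name of a registered method (see [daa_method_registry()]).
#' @param dataset A [count_dataset()]; the prevalence filter is applied once
#'   before permuting (permutation does not change prevalences).
#' @param n_perms Number of permutations (>= 1).
#' @param seed Integer seed; `NULL` uses the ambient RNG.
#' @param prevalence_threshold Prevalence filter threshold (default 0.10).
#' @param covariate_names Covariates passed to the method.
#' @return List with `rate` (pooled fraction of P < .05), `n_pvalues` and
#'   `n_excluded` (degenerate or failed fits).
#' @export
permutation_calibration <- function(method, dataset, n_perms, seed = NULL,
                                    prevalence_threshold = 0.10,
                                    covariate_names = character()) {
  if (!is_count_scalar(n_perms) || n_perms < 1) {
    stop_data("'n_perms' must be a positive integer")
  }
  flt <- filter_prevalence(dataset, prevalence_threshold)$dataset
  with_seed_or_ambient(seed, {
    n_sig <- 0L; n_tot <- 0L; n_excl <- 0L
    for (i in seq_len(n_perms)) {
      perm <- permute_labels(flt)
      res <- run_method(method, perm, covariate_names = covariate_names)
      ok <- res$status == "ok" & !is.na(res$p)
      n_sig <- n_sig + sum(res$p[ok] < 0.05)
      n_tot <- n_tot + sum(ok)
      n_excl <- n_excl + sum(!ok)
    }
    list(rate = if (n_tot > 0) n_sig / n_tot else NA_real_,
         n_pvalues = n_tot, n_excluded = n_excl)
  })
}

#' Rank methods by standardized consistency and sensitivity metrics
#'
#' For every nominal FDR level in the summary table, three metric columns
#' are formed: the square root of Conflict% with flipped sign (lower
#' conflict is better), Replication%, and NHits. Each column is standardized
#' to zero mean and unit variance across methods, and a method's score is
#' the mean of its standardized values over all levels; methods are returned
#' in descending score order (stable for ties). A metric missing for any
#' method at a level is skipped for all methods at that level, with a
#' message.
#'
#' @param summaries A data.frame of metric summaries (as produced by
#'   [evaluate_split()]) with columns `method`, `alpha`, `conflict_pct`,
#'   `replication_pct`, `n_hits`.
#' @return The per-method score table, ordered by decreasing `score`.
#' @export
rank_methods <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  methods <- unique(summaries$method)
  if (length(methods) < 2) stop_data("ranking needs at least two methods")
  alphas <- unique(summaries$alpha)
  cols <- list()
  for (a in alphas) {
    sub <- summaries[summaries$alpha == a, ]
    sub <- sub[match(methods, sub$method), ]
    for (metric in c("conflict_pct", "replication_pct", "n_hits")) {
      vals <- sub[[metric]]
      if (any(is.na(vals))) {
        message(sprintf(
          "rank_methods: metric '%s' missing for some method at alpha = %s; skipped",
          metric, format(a)))
        next
      }
      v <- switch(metric,
                  conflict_pct = -sqrt(vals),
                  replication_pct = vals,
                  n_hits = vals)
      s <- stats::sd(v)
      cols[[paste(metric, a, sep = "@")]] <-
        if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    }
  }
  if (length(cols) == 0) stop_data("no complete metric column to rank on")
  score_mat <- do.call(cbind, cols)
  scores <- rowMeans(score_mat)
  out <- data.frame(method = methods, score = scores,
                    stringsAsFactors = FALSE)
  out <- cbind(out, score_mat)
  rownames(out) <- NULL
  out[order(-out$score), , drop = FALSE]
}
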