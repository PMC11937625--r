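#' Configuration for the synthetic count-data generator
#'
#' Describes one simulated case/control microbiome study. Baseline taxon mean
#' relative abundances are drawn from a Dirichlet distribution (independent
#' gamma draws normalized to sum one), which with a small shape parameter
#' gives the heavy-tailed, few-dominant-taxa profile typical of gut
#' microbiome data. A configurable fraction of taxa carries a true group
#' effect: their case-group means are multiplied by `exp(+/- effect_log_fc)`
#' (sign drawn per taxon) and the composition is renormalized, so the planted
#' truth is a relative-abundance effect. Counts are gamma-Poisson (negative
#' binomial) draws around `library_size * relative_abundance`, giving the
#' overdispersed, zero-heavy counts seen in real taxonomic profiles.
#'
#' @param n_case,n_control Number of case and control samples (each >= 1).
#' @param n_taxa Number of taxa to simulate.
#' @param frac_differential Fraction of taxa in \[0, 1\] with a true group
#'   effect.
#' @param effect_log_fc Positive magnitude of the planted log fold-change;
#'   the sign is drawn uniformly per differential taxon.
#' @param base_abundance_dispersion Dirichlet shape for baseline mean
#'   relative abundances; smaller values give heavier tails (more very rare
#'   taxa). Default 0.2.
#' @param taxon_dispersion Gamma-Poisson overdispersion: counts have variance
#'   `mu + taxon_dispersion * mu^2`. Default 4.
#' @param library_size_range Length-2 integer vector, `c(min, max)`;
#'   per-sample library sizes are drawn uniformly from this range.
#' @param dropout_prob Optional extra probability in \[0, 1\] of zeroing any
#'   single count, for prevalence-structure stress tests. Default 0 (zeros
#'   arise only from low means plus overdispersion).
#' @param covariate_spec Optional list of covariate descriptions; each
#'   element is a list with fields `name`, `effect` (log-scale multiplicative
#'   effect on affected taxon means per covariate unit), and optionally
#'   `type` (`"continuous"` or `"binary"`, default continuous),
#'   `frac_affected` (fraction of taxa affected, default 0.1) and
#'   `cor_with_group` (in \[-1, 1\], shifts the covariate mean by group to
#'   induce confounding, default 0).
#' @param seed Integer seed; identical configuration (including the seed)
#'   gives bit-identical output. `NULL` uses the ambient RNG stream.
#'
#' @return An object of class `sim_config` (validated list of the above).
#' @seealso [simulate_dataset()], [simulate_null_dataset()]
#' @export
sim_config <- function(n_case = 50L, n_control = 50L, n_taxa = 100L,
                       frac_differential = 0.1, effect_log_fc = 1.5,
                       base_abundance_dispersion = 0.2, taxon_dispersion = 4,
                       library_size_range = c(2000L, 20000L),
                       dropout_prob = 0, covariate_spec = NULL, seed = NULL) {
  if (!is_count_scalar(n_case) || n_case < 1) stop_config("n_case", "must be an integer >= 1")
  if (!is_count_scalar(n_control) || n_control < 1) stop_config("n_control", "must be an integer >= 1")
  if (!is_count_scalar(n_taxa) || n_taxa < 1) stop_config("n_taxa", "must be an integer >= 1")
  if (!is_proportion(frac_differential)) stop_config("frac_differential", "must be a proportion in [0, 1]")
  if (!is.numeric(effect_log_fc) || length(effect_log_fc) != 1 || effect_log_fc < 0) {
    stop_config("effect_log_fc", "must be a non-negative number")
  }
  if (!is.numeric(base_abundance_dispersion) || base_abundance_dispersion <= 0) {
    stop_config("base_abundance_dispersion", "must be a positive number")
  }
  if (!is.numeric(taxon_dispersion) || taxon_dispersion < 0) {
    stop_config("taxon_dispersion", "must be a non-negative number")
  }
  if (length(library_size_range) != 2 || any(library_size_range < 1) ||
      library_size_range[1] > library_size_range[2]) {
    stop_config("library_size_range", "must be c(min, max) with 1 <= min <= max")
  }
  if (!is_proportion(dropout_prob)) stop_config("dropout_prob", "must be a proportion in [0, 1]")
  if (!is.null(covariate_spec)) {
    if (!is.list(covariate_spec)) stop_config("covariate_spec", "must be a list of covariate descriptions")
    covariate_spec <- lapply(covariate_spec, function(cv) {
      if (is.null(cv$name) || is.null(cv$effect)) {
        stop_config("covariate_spec", "each covariate needs 'name' and 'effect'")
      }
      cv$type <- cv$type %||% "continuous"
      if (!cv$type %in% c("continuous", "binary")) {
        stop_config("covariate_spec", "type must be 'continuous' or 'binary'")
      }
      cv$frac_affected <- cv$frac_affected %||% 0.1
      cv$cor_with_group <- cv$cor_with_group %||% 0
      cv
    })
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
      stop_config("seed", "must be a single integer or NULL")
    }
    seed <- as.integer(seed)
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_taxa = as.integer(n_taxa), frac_differential = frac_differential,
         effect_log_fc = effect_log_fc,
         base_abundance_dispersion = base_abundance_dispersion,
         taxon_dispersion = taxon_dispersion,
         library_size_range = as.integer(library_size_range),
         dropout_prob = dropout_prob,
         covariate_spec = covariate_spec, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a case/control microbiome count dataset with known ground truth
#'
#' Draws one dataset according to a [sim_config()]:
#' 1. baseline taxon mean relative abundances from a Dirichlet distribution;
#' 2. a random subset of taxa (fraction `frac_differential`) receives a
#'    multiplicative case-group effect `exp(+/- effect_log_fc)`, after which
#'    group mean compositions are renormalized to sum one;
#' 3. per-sample library sizes uniform on `library_size_range`;
#' 4. counts from a gamma-Poisson with the configured overdispersion (and
#'    optional extra dropout).
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{a [count_dataset()] (taxa x samples);}
#'     \item{truth}{a data.frame with one row per taxon: `taxon_id`,
#'       `is_differential`, `true_direction` (-1/0/+1), `true_log_fc` (the
#'       planted signed log fold-change, 0 for null taxa) and
#'       `true_rel_log_fc` (the realized log fold-change of relative
#'       abundance after compositional renormalization — the estimand of
#'       relative-abundance methods; it is nonzero even for null taxa
#'       because perturbing some taxa rescales all others).}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_case = 10, n_control = 10,
#'                                    n_taxa = 30, seed = 1))
#' sim$dataset
#' table(sim$truth$true_direction)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_or_ambient(config$seed, simulate_dataset_impl(config))
}

#' Simulate a global-null dataset
#'
#' Identical generative pipeline to [simulate_dataset()] with
#' `frac_differential` forced to 0: no taxon carries a group effect, so any
#' significant finding downstream is a false positive. This is the synthetic
#' analogue of permuting group labels on a real dataset.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()]; `truth$is_differential` is all `FALSE`.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$frac_differential <- 0
  simulate_dataset(config)
}

simulate_dataset_impl <- function(config) {
  n_taxa <- config$n_taxa
  n <- config$n_case + config$n_control
  grp <- rep(c("control", "case"), c(config$n_control, config$n_case))

  # baseline composition: normalized gamma draws = Dirichlet
  base <- stats::rgamma(n_taxa, shape = config$base_abundance_dispersion, rate = 1)
  base[base < .Machine$double.xmin] <- .Machine$double.xmin
  base <- base / sum(base)

  n_diff <- round(config$frac_differential * n_taxa)
  is_diff <- rep(FALSE, n_taxa)
  sign_diff <- rep(0, n_taxa)
  if (n_diff > 0) {
    idx <- sample.int(n_taxa, n_diff)
    is_diff[idx] <- TRUE
    sign_diff[idx] <- sample(c(-1, 1), n_diff, replace = TRUE)
  }
  case_mean <- base * exp(sign_diff * config$effect_log_fc)
  case_norm <- sum(case_mean)
  case_mean <- case_mean / case_norm

  # realized relative-abundance log fold-change (includes the renormalization
  # offset -log(case_norm) shared by all taxa)
  true_rel_log_fc <- sign_diff * config$effect_log_fc - log(case_norm)

  # per-sample expected composition, optionally modulated by covariates
  mean_mat <- matrix(base, nrow = n_taxa, ncol = n)
  mean_mat[, grp == "case"] <- case_mean

  covariates <- data.frame(row.names = sprintf("sample_%03d", seq_len(n)))
  if (!is.null(config$covariate_spec)) {
    for (cv in config$covariate_spec) {
      shift <- cv$cor_with_group * (grp == "case")
      z <- if (cv$type == "binary") {
        stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.5) + 2 * shift))
      } else {
        stats::rnorm(n, mean = shift, sd = 1)
      }
      n_aff <- round(cv$frac_affected * n_taxa)
      if (n_aff > 0) {
        aff <- sample.int(n_taxa, n_aff)
        mean_mat[aff, ] <- mean_mat[aff, , drop = FALSE] *
          exp(cv$effect * matrix(z, nrow = n_aff, ncol = n, byrow = TRUE))
      }
      covariates[[cv$name]] <- z
    }
    # covariate effects break the sum-to-one constraint; re-close per sample
    mean_mat <- sweep(mean_mat, 2, colSums(mean_mat), "/")
  }

  lib <- sample(seq.int(config$library_size_range[1], config$library_size_range[2]),
                n, replace = TRUE)
  mu <- sweep(mean_mat, 2, lib, "*")
  counts <- if (config$taxon_dispersion > 0) {
    matrix(stats::rnbinom(n_taxa * n, mu = mu, size = 1 / config$taxon_dispersion),
           nrow = n_taxa)
  } else {
    matrix(stats::rpois(n_taxa * n, lambda = mu), nrow = n_taxa)
  }
  if (config$dropout_prob > 0) {
    counts[matrix(stats::runif(n_taxa * n) < config$dropout_prob, nrow = n_taxa)] <- 0L
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("taxon_%03d", seq_len(n_taxa))
  colnames(counts) <- rownames(covariates)

  # a sample with no reads at all carries no information; resample its
  # largest-mean taxon to one read to keep library sizes positive
  empty <- colSums(counts) == 0
  if (any(empty)) {
    top <- apply(mu[, empty, drop = FALSE], 2, which.max)
    counts[cbind(top, which(empty))] <- 1L
  }

  dataset <- count_dataset(
    counts, group = grp, case_label = "case",
    covariates = if (ncol(covariates) > 0) covariates else NULL,
    provenance = sprintf("simulated(seed=%s)",
                         if (is.null(config$seed)) "ambient" else config$seed)
  )
  truth <- data.frame(
    taxon_id = rownames(counts),
    is_differential = is_diff,
    true_direction = sign_diff,
    true_log_fc = sign_diff * config$effect_log_fc,
    true_rel_log_fc = true_rel_log_fc,
    stringsAsFactors = FALSE
  )
  list(dataset = dataset, truth = truth)
}

#' Randomly permute the group labels of a dataset
#'
#' Counts and covariates stay attached to their samples; only the case/control
#' assignment is shuffled (uniformly over permutations). Used to build
#' empirical null datasets for type-I-error calibration of DAA methods.
#'
#' @param dataset A [count_dataset()].
#' @param seed Integer seed for the permutation; `NULL` uses the ambient RNG.
#' @return A `count_dataset` with permuted `group`.
#' @export
permute_labels <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  out <- dataset
  perm <- with_seed_or_ambient(seed, sample.int(ncol(dataset$counts)))
  out$group <- dataset$group[perm]
  out$provenance <- paste0(dataset$provenance, "+permuted")
  out
}
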