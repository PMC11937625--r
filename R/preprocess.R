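#' Filter taxa by prevalence
#'
#' Removes taxa whose prevalence (fraction of samples with a nonzero count)
#' is strictly below `threshold`; a taxon at exactly the threshold is
#' retained. Filtering is applied to one dataset at a time — in the
#' replication protocols each exploratory and validation dataset is filtered
#' independently, never jointly.
#'
#' @param dataset A [count_dataset()].
#' @param threshold Prevalence threshold in (0, 1\]; default 0.10.
#' @return A list with `dataset` (the filtered [count_dataset()]) and
#'   `report`, a list of class `prevalence_filter_report` with the threshold,
#'   per-taxon prevalence, retained and removed taxon ids and an
#'   `empty_result` flag (no taxon passing is allowed, not an error).
#' @examples
#' sim <- simulate_dataset(sim_config(n_case = 15, n_control = 15, seed = 1))
#' flt <- filter_prevalence(sim$dataset)
#' flt$report
#' @export
filter_prevalence <- function(dataset, threshold = 0.10) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop_data("'threshold' must be a proportion in (0, 1]")
  }
  prev <- taxon_prevalence(dataset)
  keep <- prev >= threshold
  report <- structure(
    list(threshold = threshold, prevalence = prev,
         retained_taxa = names(prev)[keep], removed_taxa = names(prev)[!keep],
         empty_result = !any(keep)),
    class = "prevalence_filter_report"
  )
  filtered <- subset_dataset(dataset, taxa = which(keep))
  list(dataset = filtered, report = report)
}

#' @export
print.prevalence_filter_report <- function(x, ...) {
  cat(sprintf("prevalence filter (< %.0f%% removed): %d retained, %d removed\n",
              100 * x$threshold, length(x$retained_taxa), length(x$removed_taxa)))
  if (x$empty_result) cat("NOTE: no taxon passed the filter\n")
  invisible(x)
}

#' Write a prevalence filter report as tab-separated text
#'
#' @param report A `prevalence_filter_report` from [filter_prevalence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "prevalence_filter_report"))
  df <- data.frame(taxon_id = names(report$prevalence),
                   prevalence = as.numeric(report$prevalence),
                   retained = names(report$prevalence) %in% report$retained_taxa)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total-sum-scaling (TSS) normalization
#'
#' Divides each sample's counts by its library size, giving per-sample
#' relative abundances (proportions over the taxa currently in the dataset).
#'
#' @param dataset A [count_dataset()].
#' @return A taxa-by-sample numeric matrix of proportions; every column sums
#'   to 1.
#' @export
tss_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  lib <- colSums(dataset$counts)
  zero <- lib == 0
  if (any(zero)) {
    stop_data("zero library size for sample(s): %s",
              paste(colnames(dataset$counts)[zero], collapse = ", "))
  }
  sweep(dataset$counts, 2, lib, "/")
}

#' Log-transform a relative abundance matrix
#'
#' Natural log of proportion plus a pseudocount. The pseudocount policy
#' handles the zeros that are ubiquitous in taxonomic profiles:
#' \describe{
#'   \item{`half_min_nonzero`}{half the smallest nonzero proportion in the
#'     whole matrix (default, the convention of MaAsLin2-style log-TSS
#'     analyses);}
#'   \item{`half_min_nonzero_sample`}{half the smallest nonzero proportion
#'     per sample;}
#'   \item{`constant`}{a fixed value supplied via `pseudocount`.}
#' }
#'
#' @param relab Taxa-by-sample matrix of proportions (from
#'   [tss_normalize()]).
#' @param pseudo_policy One of `"half_min_nonzero"`,
#'   `"half_min_nonzero_sample"`, `"constant"`.
#' @param pseudocount Fixed pseudocount for `pseudo_policy = "constant"`.
#' @return Matrix of the same shape with `log(p + pseudocount)` entries. The
#'   transform is monotone, so within-taxon sample rankings of positive
#'   values are preserved.
#' @export
log_transform <- function(relab,
                          pseudo_policy = c("half_min_nonzero",
                                            "half_min_nonzero_sample",
                                            "constant"),
                          pseudocount = NULL) {
  pseudo_policy <- match.arg(pseudo_policy)
  if (!is.matrix(relab) || !is.numeric(relab)) {
    stop_data("'relab' must be a numeric matrix of proportions")
  }
  pos <- relab[relab > 0]
  switch(pseudo_policy,
    half_min_nonzero = {
      pc <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
      log(relab + pc)
    },
    half_min_nonzero_sample = {
      pc <- apply(relab, 2, function(col) {
        p <- col[col > 0]
        if (length(p)) min(p) / 2 else .Machine$double.eps
      })
      log(sweep(relab, 2, pc, "+"))
    },
    constant = {
      if (is.null(pseudocount) || pseudocount <= 0) {
        stop_data("'pseudocount' must be a positive number for policy 'constant'")
      }
      log(relab + pseudocount)
    }
  )
}

#' Binarize counts to presence/absence
#'
#' @param dataset A [count_dataset()] or a numeric matrix.
#' @return Taxa-by-sample 0/1 integer matrix; 1 wherever the count is
#'   nonzero. Row means equal taxon prevalences.
#' @export
binarize <- function(dataset) {
  m <- if (inherits(dataset, "count_dataset")) dataset$counts else dataset
  if (!is.matrix(m) || !is.numeric(m)) stop_data("input must be a count matrix or count_dataset")
  out <- (m > 0) + 0L
  storage.mode(out) <- "integer"
  out
}
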