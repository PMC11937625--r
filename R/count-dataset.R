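#' Construct a taxa-by-sample count dataset
#'
#' The central container of the package: an integer count matrix with taxa in
#' rows and samples in columns, a binary case/control group factor, and an
#' optional per-sample covariate table. All differential abundance methods and
#' replication protocols operate on this object.
#'
#' @param counts Numeric matrix of non-negative integer counts, taxa in rows,
#'   samples in columns. Row names are taken as taxon ids and column names as
#'   sample ids when present; otherwise ids are generated.
#' @param group Character or factor vector of length `ncol(counts)` with
#'   exactly two levels; the level named by `case_label` is coded as the case
#'   group.
#' @param case_label Label in `group` identifying the case group. Effect
#'   directions throughout the package are positive when a taxon is estimated
#'   to be more abundant in the case group.
#' @param covariates Optional data.frame of per-sample covariates
#'   (rows = samples, in column order of `counts`).
#' @param provenance Free-text source tag stored with the object.
#'
#' @return An object of class `count_dataset`: a list with elements `counts`
#'   (integer matrix with dimnames), `group` (factor with levels
#'   `c("control", "case")`), `covariates` (data.frame, possibly 0-column) and
#'   `provenance`.
#'
#' @examples
#' m <- matrix(rpois(30, 5), nrow = 5,
#'             dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
#' ds <- count_dataset(m, group = rep(c("A", "B"), each = 3), case_label = "B")
#' ds
#' @export
count_dataset <- function(counts, group, case_label = NULL, covariates = NULL,
                          provenance = "unspecified") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_data("'counts' must be a numeric matrix (taxa x samples)")
  }
  if (anyNA(counts)) stop_data("'counts' contains missing values")
  if (any(counts < 0)) stop_data("'counts' contains negative values")
  if (any(counts != round(counts))) stop_data("'counts' contains non-integer values")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon_%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop_data("duplicated taxon id: %s",
              rownames(counts)[anyDuplicated(rownames(counts))])
  }
  if (anyDuplicated(colnames(counts))) {
    stop_data("duplicated sample id: %s",
              colnames(counts)[anyDuplicated(colnames(counts))])
  }
  if (length(group) != ncol(counts)) {
    stop_data("'group' has length %d but there are %d samples",
              length(group), ncol(counts))
  }
  lv <- unique(as.character(group))
  if (length(lv) != 2L) {
    stop_data("'group' must have exactly two levels, found: %s",
              paste(lv, collapse = ", "))
  }
  if (is.null(case_label)) {
    if (!is.factor(group)) {
      stop_data("'case_label' must be given unless 'group' is a factor whose second level is the case group")
    }
    case_label <- levels(group)[2L]
  }
  if (!case_label %in% lv) {
    stop_data("case_label '%s' not among group levels: %s",
              case_label, paste(lv, collapse = ", "))
  }
  control_label <- setdiff(lv, case_label)
  grp <- factor(ifelse(as.character(group) == case_label, "case", "control"),
                levels = c("control", "case"))
  zero_lib <- colSums(counts) == 0
  if (any(zero_lib)) {
    stop_data("zero library size for sample(s): %s",
              paste(colnames(counts)[zero_lib], collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = colnames(counts))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(counts)) {
      stop_data("'covariates' has %d rows but there are %d samples",
                nrow(covariates), ncol(counts))
    }
    rownames(covariates) <- colnames(counts)
  }
  structure(
    list(counts = counts, group = grp, covariates = covariates,
         provenance = provenance,
         labels = c(control = control_label, case = case_label)),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d taxa x %d samples (%d case / %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == "case"), sum(x$group == "control")))
  if (ncol(x$covariates) > 0) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Subset a count dataset by taxa and/or samples
#'
#' @param dataset A [count_dataset()].
#' @param taxa Taxon ids or indices to keep (default: all).
#' @param samples Sample ids or indices to keep (default: all).
#' @return A `count_dataset` restricted to the requested taxa and samples.
#' @export
subset_dataset <- function(dataset, taxa = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts
  grp <- dataset$group
  cov <- dataset$covariates
  if (!is.null(taxa)) counts <- counts[taxa, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    idx <- match(colnames(counts), colnames(dataset$counts))
    grp <- grp[idx]
    cov <- cov[idx, , drop = FALSE]
  }
  out <- dataset
  out$counts <- counts
  out$group <- grp
  out$covariates <- cov
  out
}

#' Library sizes of a count dataset
#'
#' @param dataset A [count_dataset()].
#' @return Named numeric vector of per-sample column sums.
#' @export
library_sizes <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  colSums(dataset$counts)
}

#' Per-taxon prevalence
#'
#' Prevalence of a taxon is the fraction of samples in which it has a nonzero
#' count.
#'
#' @param dataset A [count_dataset()].
#' @param group Optional: `"case"` or `"control"` to restrict to one group.
#' @return Named numeric vector in \[0, 1\].
#' @export
taxon_prevalence <- function(dataset, group = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  m <- dataset$counts
  if (!is.null(group)) {
    group <- match.arg(group, c("case", "control"))
    m <- m[, dataset$group == group, drop = FALSE]
  }
  rowMeans(m > 0)
}
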