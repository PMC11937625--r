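#' Read a delimited count table
#'
#' Reads a tab-separated (or comma-separated) text file with a header row
#' and an id column into an integer taxa-by-sample matrix. Non-integer,
#' negative or missing entries and duplicated ids are rejected with a
#' message naming the offender.
#'
#' @param path File path.
#' @param orientation `"taxa_by_samples"` (rows = taxa, the canonical
#'   layout) or `"samples_by_taxa"` (transposed on read).
#' @param sep Field separator (default tab).
#' @return Integer matrix, taxa in rows, with dimnames.
#' @export
read_count_table <- function(path,
                             orientation = c("taxa_by_samples",
                                             "samples_by_taxa"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_data("duplicated id '%s' in %s", dup[1], path)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2,
                        function(x) is.numeric(x) || all(grepl("^\\s*-?\\d+\\s*$", x))))
    stop_data("non-numeric entries in column '%s' of %s",
              colnames(tab)[-1][bad[1]], path)
  }
  if (anyNA(m)) stop_data("missing values in count table %s", path)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_data("negative count at row '%s', column '%s' in %s",
              ids[idx[1]], colnames(m)[idx[2]], path)
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop_data("non-integer count at row '%s', column '%s' in %s",
              ids[idx[1]], colnames(m)[idx[2]], path)
  }
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  if (orientation == "samples_by_taxa") m <- t(m)
  m
}

#' Read a sample metadata table
#'
#' @param path Tab-separated file with header; first column is the sample
#'   id.
#' @param group_column Name of the column holding the two group labels.
#' @param case_label Label identifying the case group.
#' @param covariate_columns Optional character vector of covariate column
#'   names to keep.
#' @param sep Field separator (default tab).
#' @return A list with `sample_ids`, `group` (original labels), `case_label`
#'   and `covariates` (data.frame).
#' @export
read_metadata <- function(path, group_column = "group", case_label,
                          covariate_columns = character(), sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!group_column %in% names(tab)) {
    stop_data("group column '%s' not found in %s", group_column, path)
  }
  missing_cov <- setdiff(covariate_columns, names(tab))
  if (length(missing_cov)) {
    stop_data("covariate column(s) not found in %s: %s", path,
              paste(missing_cov, collapse = ", "))
  }
  lv <- unique(as.character(tab[[group_column]]))
  if (length(lv) != 2) {
    stop_data("group column '%s' must have exactly two levels, found: %s",
              group_column, paste(lv, collapse = ", "))
  }
  if (!case_label %in% lv) {
    stop_data("case_label '%s' not among group levels: %s", case_label,
              paste(lv, collapse = ", "))
  }
  list(sample_ids = as.character(tab[[1]]),
       group = as.character(tab[[group_column]]),
       case_label = case_label,
       covariates = tab[, covariate_columns, drop = FALSE])
}

#' Assemble a count dataset from count and metadata files
#'
#' @inheritParams read_count_table
#' @param counts_path,metadata_path File paths.
#' @param group_column,case_label,covariate_columns Passed to
#'   [read_metadata()].
#' @return A [count_dataset()]. Samples present in only one of the two files
#'   are an error.
#' @export
read_count_dataset <- function(counts_path, metadata_path,
                               group_column = "group", case_label,
                               covariate_columns = character(),
                               orientation = "taxa_by_samples", sep = "\t") {
  m <- read_count_table(counts_path, orientation = orientation, sep = sep)
  meta <- read_metadata(metadata_path, group_column = group_column,
                        case_label = case_label,
                        covariate_columns = covariate_columns, sep = sep)
  extra_meta <- setdiff(meta$sample_ids, colnames(m))
  if (length(extra_meta)) {
    stop_data("sample '%s' in metadata but not in count table", extra_meta[1])
  }
  extra_counts <- setdiff(colnames(m), meta$sample_ids)
  if (length(extra_counts)) {
    stop_data("sample '%s' in count table but not in metadata",
              extra_counts[1])
  }
  ord <- match(colnames(m), meta$sample_ids)
  count_dataset(m, group = meta$group[ord], case_label = meta$case_label,
                covariates = if (ncol(meta$covariates))
                  meta$covariates[ord, , drop = FALSE] else NULL,
                provenance = counts_path)
}

#' Write a count dataset (and optionally its ground truth) to text files
#'
#' Writes the canonical three-file representation: a tab-separated count
#' table (taxa rows, sample columns, first column `taxon_id`), a metadata
#' table (`sample_id`, `group`, covariates), and — when `truth` is given —
#' a ground-truth table.
#'
#' @param dataset A [count_dataset()].
#' @param counts_path,metadata_path,truth_path Output paths (`truth_path`
#'   only used when `truth` is supplied).
#' @param truth Optional ground-truth data.frame from [simulate_dataset()].
#' @return Invisibly, the vector of written paths.
#' @export
write_count_dataset <- function(dataset, counts_path, metadata_path,
                                truth = NULL, truth_path = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  ct <- data.frame(taxon_id = rownames(dataset$counts), dataset$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ct, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  orig_labels <- dataset$labels[as.character(dataset$group)]
  meta <- data.frame(sample_id = colnames(dataset$counts),
                     group = orig_labels, dataset$covariates,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(counts_path, metadata_path)
  if (!is.null(truth)) {
    if (is.null(truth_path)) stop_data("'truth_path' required to write truth")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, truth_path)
  }
  invisible(written)
}
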