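# small builders used across test files

# dataset with fully controlled counts; group = first n_control control,
# rest case
toy_dataset <- function(counts, n_case, n_control,
                        covariates = NULL) {
  stopifnot(ncol(counts) == n_case + n_control)
  count_dataset(counts,
                group = rep(c("ctrl", "case"), c(n_control, n_case)),
                case_label = "case", covariates = covariates,
                provenance = "toy")
}

# dataset where one taxon has prescribed per-sample counts and a second
# "filler" taxon keeps every library size positive
two_taxon_dataset <- function(taxon_counts, n_case, n_control) {
  counts <- rbind(target = taxon_counts,
                  filler = rep(50L, length(taxon_counts)))
  toy_dataset(counts, n_case, n_control)
}

# hand-built daa_result table for metric tests
fake_daa_result <- function(taxon_id, estimate, p, q = NULL,
                            ci_low = NULL, ci_high = NULL,
                            status = "ok", method = "fake",
                            ci_level = 0.834) {
  n <- length(taxon_id)
  status_vec <- rep(status, length.out = n)
  res <- data.frame(
    taxon_id = taxon_id,
    estimate = estimate,
    se = rep(1, n),
    ci_low = if (is.null(ci_low)) estimate - 1 else ci_low,
    ci_high = if (is.null(ci_high)) estimate + 1 else ci_high,
    direction = ifelse(status_vec == "ok", sign(estimate), 0),
    p = p,
    q = if (is.null(q)) stats::p.adjust(p, "BH") else q,
    status = status_vec,
    stringsAsFactors = FALSE
  )
  attr(res, "method") <- method
  attr(res, "ci_level") <- ci_level
  class(res) <- c("daa_result", "data.frame")
  res
}

# outcome_record table with prescribed outcome labels
fake_outcomes <- function(outcomes, taxon_id = NULL) {
  n <- length(outcomes)
  out <- data.frame(
    taxon_id = taxon_id %||% sprintf("t%02d", seq_len(n)),
    exploratory_direction = rep(1, n),
    exploratory_q = rep(0.01, n),
    validation_p = rep(0.01, n),
    validation_direction = rep(1, n),
    outcome = outcomes,
    stringsAsFactors = FALSE
  )
  class(out) <- c("outcome_record", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
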