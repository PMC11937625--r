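make_abundance_dataset <- function(case_vals, control_vals, filler = 1000L) {
  # embed prescribed per-sample counts for one taxon into a two-taxon
  # dataset; the filler taxon keeps libraries comparable
  counts <- rbind(target = as.integer(c(control_vals, case_vals)),
                  filler = rep(filler, length(case_vals) + length(control_vals)))
  toy_dataset(counts, n_case = length(case_vals),
              n_control = length(control_vals))
}

test_that("ordinal regression agrees with an independent proportional-odds fit", {
  set.seed(42)
  n <- 40
  g <- rep(0:1, each = n / 2)
  vals <- as.integer(round(exp(rnorm(n, 4 + 0.8 * g, 0.5))))
  ds <- make_abundance_dataset(vals[g == 1], vals[g == 0])
  res <- run_orm(ds)
  tgt <- res[res$taxon_id == "target", ]

  relab <- tss_normalize(ds)
  pf <- MASS::polr(factor(relab["target", ]) ~ g, Hess = TRUE)
  expect_equal(tgt$estimate, unname(coef(pf)["g"]), tolerance = 1e-4)
  expect_equal(tgt$se, sqrt(vcov(pf)["g", "g"]), tolerance = 1e-3)
})

test_that("ordinal regression P-values track the Wilcoxon rank-sum test", {
  set.seed(7)
  for (shift in c(0, 0.5)) {
    n <- 60
    g <- rep(0:1, each = n / 2)
    vals <- as.integer(round(exp(rnorm(n, 5 + shift * g, 0.6))))
    ds <- make_abundance_dataset(vals[g == 1], vals[g == 0])
    res <- run_orm(ds)
    relab <- tss_normalize(ds)
    w <- wilcox.test(relab["target", g == 1], relab["target", g == 0],
                     exact = FALSE, correct = FALSE)
    tgt <- res[res$taxon_id == "target", ]
    expect_equal(tgt$p, w$p.value, tolerance = 0.1)
  }
})

test_that("ordinal regression handles separation and constant taxa", {
  # every case value strictly above every control value
  ds <- make_abundance_dataset(case_vals = 101:115, control_vals = 1:15)
  res <- run_orm(ds)
  expect_equal(res$direction[res$taxon_id == "target"], 1)

  const <- make_abundance_dataset(rep(5L, 10), rep(5L, 10), filler = 95L)
  res2 <- run_orm(const)
  tgt <- res2[res2$taxon_id == "target", ]
  expect_equal(tgt$status, "degenerate")
  expect_equal(tgt$p, 1)
  expect_equal(tgt$estimate, 0)
})

test_that("log-TSS linear model equals the pooled-variance t-test", {
  sim <- simulate_dataset(sim_config(n_case = 20, n_control = 20,
                                     n_taxa = 30, seed = 14))
  flt <- filter_prevalence(sim$dataset)$dataset
  res <- run_linear_logtss(flt, ci_level = 0.95)
  logm <- log_transform(tss_normalize(flt))
  grp <- flt$group
  for (tx in sample(res$taxon_id[res$status == "ok"], 5)) {
    tt <- t.test(logm[tx, grp == "case"], logm[tx, grp == "control"],
                 var.equal = TRUE)
    row <- res[res$taxon_id == tx, ]
    # oracle: group coefficient is the difference of group means of logs
    expect_equal(row$estimate,
                 mean(logm[tx, grp == "case"]) -
                   mean(logm[tx, grp == "control"]), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(c(row$ci_low, row$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("identical case and control values give a zero estimate", {
  vals <- c(10L, 20L, 30L, 40L, 50L)
  ds <- make_abundance_dataset(vals, vals)
  res <- run_linear_logtss(ds)
  tgt <- res[res$taxon_id == "target", ]
  expect_equal(tgt$estimate, 0, tolerance = 1e-12)
  expect_equal(tgt$direction, 0)
})

test_that("logistic regression matches the closed-form 2x2 log odds ratio", {
  pres_case <- c(rep(1L, 15), rep(0L, 5))
  pres_ctrl <- c(rep(1L, 5), rep(0L, 15))
  ds <- make_abundance_dataset(pres_case * 7L, pres_ctrl * 7L)
  res <- run_logr(ds)
  tgt <- res[res$taxon_id == "target", ]
  # oracle: Wald log-OR from the contingency table (15*15)/(5*5)
  expect_equal(tgt$estimate, log((15 * 15) / (5 * 5)), tolerance = 1e-6)
  expect_equal(tgt$se, sqrt(1 / 15 + 1 / 5 + 1 / 5 + 1 / 15),
               tolerance = 1e-6)
  expect_equal(tgt$direction, 1)
})

test_that("logistic regression flags uninformative and separated taxa", {
  always <- make_abundance_dataset(rep(3L, 12), rep(4L, 12))
  res <- run_logr(always)
  expect_equal(res$status[res$taxon_id == "target"], "degenerate")

  # case group 100% present, control mixed -> separation -> degenerate
  sep <- make_abundance_dataset(rep(2L, 12), c(rep(2L, 6), rep(0L, 6)))
  res2 <- run_logr(sep)
  expect_equal(res2$status[res2$taxon_id == "target"], "degenerate")

  equal_prev <- make_abundance_dataset(c(rep(1L, 6), rep(0L, 6)),
                                       c(rep(1L, 6), rep(0L, 6)))
  res3 <- run_logr(equal_prev)
  expect_equal(res3$estimate[res3$taxon_id == "target"], 0, tolerance = 1e-9)
})

test_that("negative binomial model recovers a planted count effect", {
  # 4 of 40 taxa carry the effect; because the offset is the realized
  # library size (column sum), every estimate is shifted by the log of the
  # case/control total-rate ratio s -- the compositional estimand
  set.seed(31)
  n <- 80; beta <- 1.0; n_taxa <- 40; n_eff <- 4
  g <- rep(0:1, each = n / 2)
  lib <- sample(20000:50000, n, replace = TRUE)
  eff <- c(rep(beta, n_eff), rep(0, n_taxa - n_eff))
  counts <- t(vapply(seq_len(n_taxa), function(i) {
    rnbinom(n, mu = lib * 0.002 * exp(eff[i] * g), size = 3)
  }, numeric(n)))
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("t%02d", seq_len(n_taxa))
  ds <- toy_dataset(counts, n_case = n / 2, n_control = n / 2)
  s <- (n_eff * exp(beta) + (n_taxa - n_eff)) / n_taxa
  target <- beta - log(s)
  res <- run_nb_glm(ds, ci_level = 0.95)
  ok_eff <- res$status == "ok" & res$taxon_id %in% sprintf("t%02d", 1:n_eff)
  expect_gte(sum(ok_eff), 3)
  expect_equal(mean(res$estimate[ok_eff]), target, tolerance = 0.15)
  ok_null <- res$status == "ok" & !res$taxon_id %in% sprintf("t%02d", 1:n_eff)
  expect_equal(mean(res$estimate[ok_null]), -log(s), tolerance = 0.2)
  coverage <- mean(res$ci_low[ok_null] <= -log(s) &
                     -log(s) <= res$ci_high[ok_null])
  expect_gt(coverage, 0.8)

  zero <- make_abundance_dataset(rep(0L, 10), rep(0L, 10))
  expect_equal(run_nb_glm(zero)$status[1], "degenerate")
})

test_that("flipping the group labels negates estimates and keeps P-values", {
  sim <- simulate_dataset(sim_config(n_case = 20, n_control = 20,
                                     n_taxa = 40, seed = 19))
  flt <- filter_prevalence(sim$dataset)$dataset
  flipped <- count_dataset(flt$counts,
                           group = as.character(flt$group),
                           case_label = "control")
  for (m in c("orm", "linear_logtss", "logr")) {
    a <- run_method(m, flt)
    b <- run_method(m, flipped)
    ok <- a$status == "ok" & b$status == "ok" & abs(a$estimate) > 1e-6
    expect_gt(sum(ok), 10)
    expect_equal(a$estimate[ok], -b$estimate[ok], tolerance = 1e-4)
    expect_equal(a$direction[ok], -b$direction[ok])
    expect_equal(a$p[ok], b$p[ok], tolerance = 1e-4)
  }
})

test_that("Wald confidence intervals cohere with P-values", {
  sim <- simulate_dataset(sim_config(n_case = 25, n_control = 25,
                                     n_taxa = 50, seed = 23))
  flt <- filter_prevalence(sim$dataset)$dataset
  for (m in c("orm", "logr", "linear_logtss")) {
    res <- run_method(m, flt, ci_level = 0.95)
    ok <- res$status == "ok" & abs(res$p - 0.05) > 1e-3
    excl <- res$ci_low[ok] > 0 | res$ci_high[ok] < 0
    expect_equal(excl, res$p[ok] < 0.05)
  }
})

test_that("an unrelated covariate barely moves the estimates", {
  sim <- simulate_dataset(sim_config(n_case = 50, n_control = 50,
                                     n_taxa = 30, seed = 29))
  ds <- sim$dataset
  ds$covariates$noise <- withr::with_seed(1, rnorm(ncol(ds$counts)))
  flt <- filter_prevalence(ds)$dataset
  plain <- run_linear_logtss(flt)
  adj <- run_linear_logtss(flt, covariate_names = "noise")
  ok <- plain$status == "ok" & adj$status == "ok"
  expect_gt(cor(plain$estimate[ok], adj$estimate[ok]), 0.98)
})

test_that("BH adjustment matches its closed form and caps at one", {
  expect_equal(adjust_fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr_bh(0.37), 0.37)
  withr::with_seed(6, {
    p <- runif(50)
    q <- adjust_fdr_bh(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  })
  expect_error(adjust_fdr_bh(c(0.5, 1.2)), "outside")
})

test_that("method dispatch is the identity on registered methods", {
  sim <- simulate_dataset(sim_config(n_case = 12, n_control = 12,
                                     n_taxa = 20, seed = 37))
  flt <- filter_prevalence(sim$dataset)$dataset
  expect_equal(run_method("orm", flt), run_orm(flt))
  expect_error(run_method("edgeR", flt), "unknown method")
})

test_that("external result tables are validated and q handled per flag", {
  tab <- data.frame(taxon_id = c("a", "b", "c"),
                    estimate = c(1.2, -0.5, 0.1),
                    p = c(0.01, 0.20, 0.90),
                    q = c(0.5, 0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  kept <- run_method(external_path = path, external_q_adjusted = TRUE)
  expect_equal(kept$q, c(0.5, 0.5, 0.5))
  recomputed <- run_method(external_path = path)
  expect_equal(recomputed$q, p.adjust(tab$p, "BH"))
  expect_equal(recomputed$direction, c(1, -1, 1))

  bad <- tab[, c("taxon_id", "estimate")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(run_method(external_path = path2), "p")
})
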