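test_that("split halves are stratified, seeded, and sized within one", {
  sim <- simulate_dataset(sim_config(n_case = 20, n_control = 20,
                                     n_taxa = 25, seed = 1))
  pairs <- split_dataset(sim$dataset, n_repeats = 3, seed = 55)
  expect_length(pairs, 3)
  for (pr in pairs) {
    expect_equal(sum(pr$exploratory$group == "case"), 10)
    expect_equal(sum(pr$exploratory$group == "control"), 10)
    expect_equal(sum(pr$validation[[1]]$group == "case"), 10)
    expect_setequal(c(colnames(pr$exploratory$counts),
                      colnames(pr$validation[[1]]$counts)),
                    colnames(sim$dataset$counts))
  }
  again <- split_dataset(sim$dataset, n_repeats = 3, seed = 55)
  expect_identical(lapply(pairs, function(p) colnames(p$exploratory$counts)),
                   lapply(again, function(p) colnames(p$exploratory$counts)))

  # odd group sizes: the extra sample goes to the exploratory half
  sim2 <- simulate_dataset(sim_config(n_case = 21, n_control = 20,
                                      n_taxa = 25, seed = 2))
  pr <- split_dataset(sim2$dataset, n_repeats = 1, seed = 9)[[1]]
  expect_equal(sum(pr$exploratory$group == "case"), 11)
  expect_equal(sum(pr$validation[[1]]$group == "case"), 10)
})

test_that("too-small groups refuse to split, naming the group", {
  sim <- simulate_dataset(sim_config(n_case = 19, n_control = 40,
                                     n_taxa = 25, seed = 3))
  expect_error(split_dataset(sim$dataset, min_group_size = 10), "case")
})

test_that("separate-study pairing enumerates same-condition datasets", {
  mk <- function(nc, s) simulate_dataset(sim_config(n_case = nc,
                                                    n_control = nc,
                                                    n_taxa = 20,
                                                    seed = s))$dataset
  datasets <- list(crc1 = mk(12, 1), crc2 = mk(15, 2), crc3 = mk(20, 3),
                   ibd1 = mk(12, 4), tiny = mk(9, 5))
  cond <- c(crc1 = "CRC", crc2 = "CRC", crc3 = "CRC",
            ibd1 = "IBD", tiny = "CRC")
  pairs <- pair_separate_studies(datasets, cond, min_group_size = 10)
  # three eligible CRC datasets -> 3 exploratory roles x 2 validations;
  # the 9-per-group dataset is excluded; IBD has no partner
  expect_length(pairs, 3)
  expect_true(all(vapply(pairs, function(p) length(p$validation), 1L) == 2))
  origins <- vapply(pairs, `[[`, "", "origin")
  expect_false(any(grepl("tiny|ibd", origins)))
})

test_that("candidate taxa need exploratory significance and validation presence", {
  expl <- fake_daa_result(c("a", "b", "c", "d"),
                          estimate = c(1, 1, 1, 1),
                          p = c(0.001, 0.001, 0.5, 0.9),
                          q = c(0.03, 0.03, 0.06, 0.9))
  val_counts <- rbind(a = rep(1L, 10), c = rep(1L, 10), d = rep(1L, 10))
  val_ds <- toy_dataset(val_counts + 1L, n_case = 5, n_control = 5)
  cand <- identify_candidates(expl, val_ds, alpha = 0.05)
  expect_equal(cand, "a")  # b filtered out of validation, c/d above alpha
})

test_that("outcomes classify by validation significance and direction", {
  expl <- fake_daa_result(c("t1", "t4", "t5", "t6"),
                          estimate = c(2, 2, 2, 2),
                          p = rep(0.001, 4), q = rep(0.01, 4))
  val <- fake_daa_result(c("t1", "t4", "t5"),
                         estimate = c(-1.5, 1.5, 0.5),
                         p = c(0.01, 0.01, 0.20))
  out <- classify_outcomes(c("t1", "t4", "t5", "t6"), expl, val)
  expect_equal(out$outcome,
               c("conflicting", "replicated", "not_validated",
                 "absent_in_validation"))

  # FDR-adjusted validation variant: p = .03 on 2 candidates -> q = .06
  val2 <- fake_daa_result(c("t1", "t4"), estimate = c(1, 1),
                          p = c(0.03, 0.06))
  out2 <- classify_outcomes(c("t1", "t4"), expl, val2,
                            validation_adjust = "bh")
  expect_true(all(out2$outcome == "not_validated"))
})

test_that("zero-direction estimates never replicate or conflict", {
  expl <- fake_daa_result("t1", estimate = 0, p = 0.001, q = 0.01)
  val <- fake_daa_result("t1", estimate = 1.5, p = 0.001)
  out <- classify_outcomes("t1", expl, val)
  expect_equal(out$outcome, "not_validated")
})

test_that("metrics pool numerators and denominators, never average ratios", {
  pair1 <- fake_outcomes(c(rep("replicated", 5), rep("not_validated", 3)))
  pair2 <- fake_outcomes(rep("replicated", 2))
  pm <- pool_metrics(list(pair1, pair2))
  expect_equal(pm$replication_pct, 0.70)           # (5+2)/(8+2)
  expect_false(isTRUE(all.equal(pm$replication_pct, mean(c(5 / 8, 1)))))
  expect_equal(pm$n_candidates, 10L)

  allconf <- fake_outcomes(rep("conflicting", 4))
  pm2 <- pool_metrics(list(allconf))
  expect_equal(pm2$conflict_pct, 1)
  expect_equal(pm2$replication_pct, 0)

  empty <- pool_metrics(list(fake_outcomes(character(0))))
  expect_true(is.na(empty$conflict_pct))
  expect_equal(empty$n_candidates, 0L)
})

test_that("hit counting sums significant taxa and is monotone in alpha", {
  r1 <- fake_daa_result(paste0("a", 1:5), estimate = 1,
                        p = c(0.001, 0.002, 0.3, 0.4, 0.5),
                        q = c(0.01, 0.02, 0.5, 0.6, 0.7))
  r2 <- fake_daa_result(paste0("b", 1:6), estimate = 1,
                        p = c(0.001, 0.002, 0.003, 0.004, 0.5, 0.6),
                        q = c(0.01, 0.02, 0.03, 0.04, 0.7, 0.8))
  expect_equal(count_hits(list(r1, r2), 0.05), 6)
  expect_equal(count_hits(list(r1, r2), 0), 0)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  hits <- vapply(alphas, function(a) count_hits(list(r1, r2), a), numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("estimate correlations pool on the Fisher z scale", {
  mk_pair <- function(e, v) list(exploratory = e, validation = v)
  x <- setNames(as.numeric(1:10), paste0("t", 1:10))

  same <- withr::with_seed(4, {
    v <- setNames(rank(x) + rnorm(10, sd = 4), names(x))
    mk_pair(x, v)
  })
  rho <- cor(same$exploratory, same$validation, method = "spearman")
  expect_equal(pool_estimate_correlation(list(same, same)), rho,
               tolerance = 1e-12)

  flipped <- mk_pair(x, setNames(rev(unname(same$validation)), names(x)))
  rho_f <- cor(flipped$exploratory, flipped$validation, method = "spearman")
  expect_equal(rho_f, -rho, tolerance = 1e-12)
  expect_equal(pool_estimate_correlation(list(same, flipped)), 0,
               tolerance = 1e-10)

  # z-scale pooling exceeds the arithmetic mean for unequal correlations
  e1 <- x; v1 <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 10, 9), names(x))
  r1 <- cor(e1, v1, method = "spearman")
  v2 <- setNames(sample(10), names(x))
  r2 <- cor(e1, v2, method = "spearman")
  pooled <- pool_estimate_correlation(list(mk_pair(e1, v1), mk_pair(e1, v2)))
  expect_equal(pooled, tanh(mean(atanh(c(r1, r2)))), tolerance = 1e-12)

  # perfect correlation must survive the clipping
  expect_equal(pool_estimate_correlation(list(mk_pair(x, x))), 1,
               tolerance = 1e-6)

  short <- mk_pair(x[1:2], x[1:2])
  expect_message(out <- pool_estimate_correlation(list(short)), "skipped")
  expect_true(is.na(out))
})

test_that("CI overlap uses closed intervals and prevalence eligibility", {
  expl <- fake_daa_result(c("t1", "t2", "t3"), estimate = c(1, 0.5, 2),
                          p = rep(0.001, 3), q = rep(0.01, 3),
                          ci_low = c(0, 0, 0), ci_high = c(2, 1, 1))
  val <- fake_daa_result(c("t1", "t2", "t3"), estimate = c(2, 1.5, 3),
                         p = rep(0.01, 3),
                         ci_low = c(1, 1, 1.1), ci_high = c(3, 2, 3))
  out <- fake_outcomes(rep("replicated", 3), taxon_id = c("t1", "t2", "t3"))
  ov <- ci_overlap_pct(out, expl, val)
  # [0,2]x[1,3] overlap; [0,1]x[1,2] touch -> overlap; [0,1]x[1.1,3] no
  expect_equal(ov$ci_overlap_pct, 2 / 3)
  expect_equal(ov$n_eligible, 3L)

  no_ci <- fake_daa_result("t1", estimate = 1, p = 0.01,
                           ci_low = NA_real_, ci_high = NA_real_)
  ov2 <- ci_overlap_pct(fake_outcomes("replicated", "t1"), no_ci, val)
  expect_true(is.na(ov2$ci_overlap_pct))

  # prevalence rule: t_rare is below 10% prevalence in the case group
  counts <- rbind(t1 = rep(10L, 40),
                  t_rare = c(rep(0L, 19), 1L, rep(10L, 20)))
  ds <- toy_dataset(counts, n_case = 20, n_control = 20)
  expl2 <- fake_daa_result(c("t1", "t_rare"), estimate = c(1, 1),
                           p = c(0.001, 0.001), q = c(0.01, 0.01))
  val2 <- fake_daa_result(c("t1", "t_rare"), estimate = c(1, 1),
                          p = c(0.01, 0.01))
  ov3 <- ci_overlap_pct(fake_outcomes(rep("replicated", 2),
                                      c("t1", "t_rare")),
                        expl2, val2, exploratory_dataset = ds,
                        validation_dataset = ds)
  expect_equal(ov3$n_eligible, 1L)
})

test_that("alpha calibration hits the target on the q-value grid", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      res <- fake_daa_result(sprintf("t%03d", 1:60), estimate = 1,
                             p = runif(60), q = sort(runif(60)))
      target <- sample(1:55, 1)
      cal <- calibrate_alpha_for_nhits(list(res), target)
      expect_gte(cal$n_hits, target)
      # oracle: exhaustive scan over a fine alpha grid
      grid <- sort(unique(c(res$q / 2, res$q * 1.0000001, 1)))
      feasible <- grid[vapply(grid, function(a) count_hits(list(res), a),
                              numeric(1)) >= target]
      expect_equal(cal$n_hits, count_hits(list(res), min(feasible)))
      expect_true(cal$exact)
    }
  })
  res <- fake_daa_result(c("a", "b"), estimate = 1, p = c(0.1, 0.2),
                         q = c(0.2, 0.4))
  cal0 <- calibrate_alpha_for_nhits(list(res), 0)
  expect_equal(cal0$n_hits, 0L)
  expect_lt(cal0$alpha, 0.2)
  expect_error(calibrate_alpha_for_nhits(list(res), 10), "unattainable")
})

test_that("permutation calibration is seeded and rejects bad inputs", {
  sim <- simulate_dataset(sim_config(n_case = 15, n_control = 15,
                                     n_taxa = 30, seed = 41))
  expect_error(permutation_calibration("linear_logtss", sim$dataset, 0),
               "n_perms")
  a <- permutation_calibration("linear_logtss", sim$dataset, 3, seed = 5)
  b <- permutation_calibration("linear_logtss", sim$dataset, 3, seed = 5)
  expect_identical(a, b)
  expect_true(a$rate >= 0 && a$rate <= 1)
  expect_gt(a$n_pvalues, 0)
})

test_that("the ideal conflict bound follows its formula", {
  expect_equal(ideal_conflict_bound(0), 0)
  expect_equal(ideal_conflict_bound(c(0.01, 0.10)), c(0.00025, 0.0025))
  expect_error(ideal_conflict_bound(1.5), "alpha")
})

test_that("method ranking standardizes metrics and respects dominance", {
  sm <- data.frame(
    method = rep(c("good", "mid", "poor"), each = 2),
    alpha = rep(c(0.05, 0.20), 3),
    conflict_pct = c(0.001, 0.002, 0.01, 0.02, 0.05, 0.08),
    replication_pct = c(0.8, 0.85, 0.6, 0.65, 0.3, 0.4),
    n_hits = c(300, 400, 200, 250, 100, 150)
  )
  rk <- rank_methods(sm)
  expect_equal(rk$method, c("good", "mid", "poor"))
  std_cols <- setdiff(names(rk), c("method", "score"))
  for (cl in std_cols) {
    expect_equal(mean(rk[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(rk[[cl]]), 1, tolerance = 1e-12)
  }

  tied <- sm
  tied$conflict_pct <- 0.01; tied$replication_pct <- 0.5; tied$n_hits <- 100
  rk2 <- rank_methods(tied)
  expect_true(all(rk2$score == rk2$score[1]))
  expect_equal(rk2$method, c("good", "mid", "poor"))  # stable order
})

test_that("split evaluation returns one summary row per method per alpha", {
  sim <- simulate_dataset(sim_config(n_case = 30, n_control = 30,
                                     n_taxa = 60, seed = 47))
  ev <- evaluate_split(sim$dataset, methods = c("linear_logtss", "logr"),
                       alpha_grid = c(0.05, 0.20), n_repeats = 2, seed = 3)
  expect_equal(nrow(ev$summary), 4)
  expect_setequal(unique(ev$summary$method), c("linear_logtss", "logr"))
  expect_true(all(ev$summary$ideal_conflict_bound ==
                    ideal_conflict_bound(ev$summary$alpha)))
  with(ev$summary[!is.na(ev$summary$conflict_pct), ],
       expect_true(all(conflict_pct + replication_pct <= 1)))
})

test_that("cross-study evaluation aggregates over multiple validations", {
  mk <- function(s) simulate_dataset(sim_config(n_case = 15, n_control = 15,
                                                n_taxa = 40,
                                                effect_log_fc = 2,
                                                seed = s))$dataset
  datasets <- list(d1 = mk(61), d2 = mk(62), d3 = mk(63))
  cond <- c(d1 = "X", d2 = "X", d3 = "X")
  ev <- evaluate_cross(datasets, cond, methods = "linear_logtss",
                       alpha_grid = 0.2)
  expect_equal(nrow(ev$summary), 1)
  expect_equal(length(ev$pairs), 3)
  expect_true(all(vapply(ev$pairs, function(p) length(p$validation), 1L) == 2))
  expect_gte(ev$summary$n_double, 0)
})
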