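test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  km <- km_estimate(c(5, 10, 15, 20), c(1, 1, 0, 1))
  expect_equal(survival_at(km, c(5, 10, 20)), c(0.75, 0.5, 0))
  expect_equal(survival_at(km, 4.9), 1)
  expect_equal(survival_at(km, 12), 0.5)  # flat between events

  # against the independent hand estimator on random censored data
  set.seed(11)
  for (i in 1:10) {
    t <- round(rexp(40, 0.05), 1) + 0.1
    e <- rbinom(40, 1, 0.6)
    if (sum(e) == 0) next
    km2 <- km_estimate(t, e)
    hand <- km_hand(t, e)
    expect_equal(survival_at(km2, hand$time), hand$surv, tolerance = 1e-12)
    # one step per distinct event time; S non-increasing
    expect_equal(sum(km2$table$n_event > 0), nrow(hand))
    expect_true(all(diff(km2$table$surv) <= 1e-12))
  }

  # all censored: S identically 1
  flat <- km_estimate(c(3, 8, 12), c(0, 0, 0))
  expect_equal(survival_at(flat, c(1, 5, 100)), c(1, 1, 1))

  # distinct event times for everyone: steps of 1/n down to 0
  full <- km_estimate(1:5, rep(1, 5))
  expect_equal(full$table$surv, seq(0.8, 0, by = -0.2))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(1, 0)), "positive")
})

test_that("log-rank matches the hand O-E-V computation and the Cox score test", {
  # identical groups: statistic exactly 0
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr0 <- log_rank(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # strong separation, tie-free: hand formula to 1e-8
  set.seed(21)
  tt <- c(sort(runif(15, 1, 30)), sort(runif(15, 20, 80)))
  ee <- rbinom(30, 1, 0.8)
  gg <- rep(c("early", "late"), each = 15)
  lr <- log_rank(tt, ee, gg)
  expect_equal(lr$chisq, logrank_hand(tt, ee, gg), tolerance = 1e-8)

  # equivalence with the Cox score test at beta = 0 (tie-free data)
  for (i in 1:10) {
    n <- 30
    tt <- rexp(n, 0.1) + cumsum(rep(1e-6, n))  # guarantee no ties
    ee <- rbinom(n, 1, 0.7)
    gg <- rbinom(n, 1, 0.5)
    if (sum(ee) == 0 || length(unique(gg)) < 2) next
    lr <- log_rank(tt, ee, ifelse(gg == 1, "g1", "g0"))
    sc <- summary(survival::coxph(survival::Surv(tt, ee) ~ gg))$sctest
    expect_equal(lr$chisq, unname(sc["test"]), tolerance = 1e-6)
  }

  expect_error(log_rank(t, e, rep("a", 4)), "two groups")
})

test_that("Cox fit agrees with the grid-search partial-likelihood oracle", {
  # tiny tie-free data sets; Efron == Breslow == exact without ties
  set.seed(31)
  for (i in 1:5) {
    n <- 7
    x <- rbinom(n, 1, 0.5)
    tt <- sort(rexp(n, 0.2)) + seq(0, 1e-3, length.out = n)
    ee <- rbinom(n, 1, 0.8)
    if (sum(ee) < 2 || length(unique(x)) < 2) next
    fit <- cox_fit(data.frame(x = x), tt, ee)
    if (fit$table$flag[1] != "") next  # separation: oracle MLE at the boundary
    beta_hat <- fit$table$coef[1]
    beta_grid <- cox_grid_mle(x, tt, ee)
    expect_lt(abs(beta_hat - beta_grid), 2e-4)
    # the grid maximum is no better than the reported maximum
    expect_lte(cox_pl(beta_grid, x, tt, ee) - cox_pl(beta_hat, x, tt, ee),
               1e-8)
  }
})

test_that("Cox diagnostics: constant covariates, separation, zero events", {
  tt <- c(2, 4, 6, 9, 12, 15); ee <- c(1, 1, 0, 1, 1, 0)
  fit <- cox_fit(data.frame(flat = rep(1, 6), x = c(0, 1, 0, 1, 1, 0)),
                 tt, ee)
  expect_match(fit$table$flag[fit$table$term == "flat"], "constant")
  expect_true(is.na(fit$table$HR[fit$table$term == "flat"]))
  # HR within its own CI
  xrow <- fit$table[fit$table$term == "x", ]
  expect_true(xrow$lower <= xrow$HR && xrow$HR <= xrow$upper)

  # perfect separation: events only in the x = 1 arm, flagged not silent
  sep <- cox_fit(data.frame(x = c(1, 1, 1, 0, 0, 0)),
                 c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_match(sep$table$flag[1], "monotone likelihood|separation")

  expect_error(cox_fit(data.frame(x = c(0, 1)), c(1, 2), c(0, 0)),
               "no events.*degenerate")
})

test_that("ROC cutoff: derived example, identities and invariances", {
  # positives (3,5) vs negatives (1,2,4): AUC 5/6, best cutoff in (2,3)
  r <- roc_cutoff(c(1, 2, 4, 3, 5), c(0, 0, 0, 1, 1))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  expect_true(r$cutoff > 2 && r$cutoff < 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 2 / 3)

  # perfectly separated marker
  rp <- roc_cutoff(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(rp$auc, 1)
  expect_equal(c(rp$sensitivity, rp$specificity), c(1, 1))
  expect_equal(rp$cutoff, 6.5)

  # AUC == U / (n1 n2) by exhaustive pair counting, with ties
  set.seed(41)
  for (i in 1:20) {
    v <- sample(1:8, 30, replace = TRUE)  # heavy ties
    o <- rbinom(30, 1, 0.5)
    if (length(unique(o)) < 2) next
    r2 <- roc_cutoff(v, o)
    expect_equal(r2$auc, auc_pairs(v[o == 1], v[o == 0]), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    r3 <- roc_cutoff(exp(v / 2), o)
    expect_equal(r3$auc, r2$auc, tolerance = 1e-12)
  }
  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  v <- c(rnorm(25, 1), rnorm(25))
  o <- rep(c(1, 0), each = 25)
  r <- roc_cutoff(v, o)
  a <- as.numeric(pROC::auc(pROC::roc(o, v, quiet = TRUE,
                                      direction = "<")))
  expect_equal(r$auc, a, tolerance = 1e-10)
})

test_that("contingency and rank tests reproduce exact references", {
  # Fisher 2x2 on (10,0; 0,10): p = 2 / C(20,10)
  ft <- contingency_test(matrix(c(10, 0, 0, 10), 2), method = "fisher_2x2")
  expect_equal(ft$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_error(contingency_test(matrix(1:9, 3), method = "fisher_2x2"),
               "2x2")

  # three-group marker positivity 7/8, 10/12, 19/50: the exact test gives
  # 0.001, chi-square gives 0.002 (printed precision)
  tab <- matrix(c(7, 1, 10, 2, 19, 31), nrow = 2)
  expect_equal(round(contingency_test(tab, method = "exact")$p, 3), 0.001)
  expect_equal(round(contingency_test(tab, method = "chi2")$p, 3), 0.002)
  # auto falls back to the exact test here (small expected cells)
  expect_equal(contingency_test(tab)$method, "fisher_exact")

  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")

  set.seed(61)
  v <- rnorm(60); g2 <- rep(c("a", "b"), 30); g3 <- rep(c("a", "b", "c"), 20)
  expect_equal(rank_test(v, g2)$method, "mann_whitney")
  expect_equal(rank_test(v, g3)$method, "kruskal_wallis")
  expect_equal(rank_test(v, g2)$p,
               suppressWarnings(wilcox.test(v[g2 == "a"], v[g2 == "b"])$p.value))
})

test_that("Kruskal-Wallis rejects at the nominal rate under the null", {
  set.seed(71)
  reps <- 400
  rej <- mean(replicate(reps, {
    v <- rnorm(500)
    g <- sample(rep(c("a", "b", "c"), length.out = 500))
    rank_test(v, g, method = "kruskal_wallis")$p < 0.05
  }))
  expect_gt(rej, 0.05 - 2.5 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rej, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("liver-RFS analysis excludes synchronous patients and gates the multivariate model", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 400, seed = 81))
  res <- liver_rfs_analysis(sim$cohort, "M1")
  expect_equal(res$n + res$n_excluded, nrow(sim$cohort))
  expect_equal(res$n_excluded, sum(sim$cohort$group == "synchronous"))

  # the planted positive-marker stratum sits at or below the negative one
  ev_times <- sort(unique(c(res$km$negative$table$time,
                            res$km$positive$table$time)))
  expect_true(all(survival_at(res$km$positive, ev_times) <=
                  survival_at(res$km$negative, ev_times) + 1e-9))

  # univariate gate: multivariate terms are exactly the univariate p < alpha
  uni <- res$univariate
  should_enter <- uni$term[!is.na(uni$p) & uni$p < res$gate_alpha &
                           uni$flag == ""]
  if (length(should_enter) > 0) {
    expect_setequal(res$multivariate$table$term, should_enter)
  } else {
    expect_null(res$multivariate)
  }
  # a univariately non-significant covariate stays out
  excluded <- uni$term[!is.na(uni$p) & uni$p >= res$gate_alpha]
  if (!is.null(res$multivariate))
    expect_length(intersect(excluded, res$multivariate$table$term), 0)

  expect_error(liver_rfs_analysis(sim$cohort, "NOPE"), "marker_NOPE")
})

test_that("liver-RFS analysis handles a cohort with no recurrences", {
  co <- toy_cohort(2, 0, 20, seed = 5)
  res <- liver_rfs_analysis(co, "M1")
  expect_equal(res$n_events, 0)
  expect_equal(survival_at(res$km$negative, c(10, 100)), c(1, 1))
  expect_equal(survival_at(res$km$positive, c(10, 100)), c(1, 1))
  expect_equal(res$logrank$p, 1)
  expect_null(res$multivariate)
})
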