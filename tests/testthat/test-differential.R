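test_that("pooling sums within groups and conserves totals", {
  m <- toy_matrix()
  pooled <- pool_counts(m)
  expect_equal(pooled$counts$n_PT, as.integer(rowSums(m[, 1:2])))
  expect_equal(pooled$counts$n_LT, as.integer(rowSums(m[, 3:4])))
  expect_equal(pooled$t_PT, sum(m[, 1:2]))
  expect_equal(pooled$t_LT, sum(m[, 3:4]))

  # single-case matrix: pooling is the identity on the two columns
  one <- count_matrix(matrix(c(3L, 0L, 7L, 2L), 2,
                             dimnames = list(c("P1", "P2"), c("PT_1", "LT_1"))),
                      group = c("PT", "LT"), case = c("c1", "c1"))
  p1 <- pool_counts(one)
  expect_equal(p1$counts$n_PT, c(3L, 0L))
  expect_equal(p1$counts$n_LT, c(7L, 2L))

  only_pt <- count_matrix(matrix(1:2, 2, 1,
                                 dimnames = list(c("P1", "P2"), "PT_1")),
                          group = "PT")
  expect_error(pool_counts(only_pt), "both groups")
})

test_that("Rsc matches hand arithmetic, symmetry and antisymmetry", {
  # direct evaluation of the two log terms
  expect_equal(compute_rsc(5, 20, 1000, 1000, f = 0.5),
               log2(20.5 / 5.5) + log2(995.5 / 980.5), tolerance = 1e-12)
  expect_equal(round(compute_rsc(5, 20, 1000, 1000, f = 0.5), 3), 1.920)
  # equal counts and totals: exactly zero
  expect_identical(compute_rsc(7, 7, 500, 500), 0)
  # fold-change convention: Rsc = log2(2.2) back-transforms to 2.2
  expect_equal(2^abs(log2(2.2)), 2.2)

  set.seed(42)
  for (i in 1:50) {
    t1 <- sample(50:5000, 1); t2 <- sample(50:5000, 1)
    n1 <- sample(0:min(40, t1), 1); n2 <- sample(0:min(40, t2), 1)
    f <- runif(1, 0.1, 2)
    expect_equal(compute_rsc(n1, n2, t1, t2, f),
                 -compute_rsc(n2, n1, t2, t1, f), tolerance = 1e-12)
  }
  # monotone: increasing in n_LT, decreasing in n_PT, totals fixed
  r <- compute_rsc(10, 0:30, 1000, 1000)
  expect_true(all(diff(r) > 0))
  r <- compute_rsc(0:30, 10, 1000, 1000)
  expect_true(all(diff(r) < 0))
  expect_error(compute_rsc(10, 5, 8, 100), "exceeds")
})

test_that("NSAF matches hand arithmetic and its invariances", {
  lens <- c(P1 = 100, P2 = 400)
  nsaf <- compute_nsaf(c(P1 = 10, P2 = 20), lens)
  expect_equal(unname(nsaf), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # single detected protein
  expect_equal(unname(compute_nsaf(c(P1 = 5, P2 = 0), lens)), c(1, 0))
  # doubling every length changes nothing
  expect_equal(compute_nsaf(c(P1 = 10, P2 = 20), lens * 2), nsaf)
  # sums to one whenever anything is detected
  set.seed(1)
  n <- rpois(50, 3); names(n) <- paste0("P", 1:50)
  L <- sample(50:2000, 50); names(L) <- names(n)
  expect_equal(sum(compute_nsaf(n, L)), 1, tolerance = 1e-12)
  expect_error(compute_nsaf(c(P1 = 4, PX = 2), lens), "missing length.*PX")
})

test_that("SpI matches hand arithmetic, bounds and sign convention", {
  m <- count_matrix(
    matrix(c(3L, 1L, 0L, 0L, 0L, 2L), 1,
           dimnames = list("P1", paste0("s", 1:6))),
    group = rep(c("PT", "LT"), each = 3))
  expect_equal(unname(compute_spi(m)), (2 / 6) * (1 / 3) - (4 / 6) * (2 / 3),
               tolerance = 1e-12)  # -1/3

  # boundary: all LT samples, no PT sample -> +1 (and mirror -> -1)
  m2 <- count_matrix(
    matrix(c(0L, 0L, 0L, 4L, 1L, 9L, 5L, 2L, 1L, 0L, 0L, 0L), 2, byrow = TRUE,
           dimnames = list(c("up", "down"), paste0("s", 1:6))),
    group = rep(c("PT", "LT"), each = 3))
  expect_equal(unname(compute_spi(m2)), c(1, -1))

  # identical PT and LT blocks -> 0; all-zero protein -> NA, never 0
  blk <- matrix(c(2L, 0L, 5L, 2L, 0L, 5L, 0L, 0L, 0L, 0L, 0L, 0L), 2,
                byrow = TRUE, dimnames = list(c("sym", "zero"), paste0("s", 1:6)))
  m3 <- count_matrix(blk, group = rep(c("PT", "LT"), each = 3))
  spi <- compute_spi(m3)
  expect_equal(unname(spi["sym"]), 0)
  expect_true(is.na(spi["zero"]))

  # bounds on random matrices, and antisymmetry under group relabeling
  set.seed(7)
  for (i in 1:20) {
    cm <- matrix(rpois(40, 1.5), 5,
                 dimnames = list(paste0("P", 1:5), paste0("s", 1:8)))
    storage.mode(cm) <- "integer"
    g <- rep(c("PT", "LT"), each = 4)
    a <- compute_spi(count_matrix(cm, g))
    b <- compute_spi(count_matrix(cm, rev(g)))
    ok <- !is.na(a)
    expect_true(all(abs(a[ok]) <= 1 + 1e-12))
    expect_equal(a[ok], -b[ok], tolerance = 1e-12)
  }
})

test_that("G-test matches the derived example and behaves at the null", {
  gt <- g_test(5, 20, 1000, 1000)
  expect_equal(gt$G, g_oracle(5, 20, 995, 980), tolerance = 1e-10)
  expect_equal(round(gt$G, 2), 9.75)
  expect_equal(gt$p, 0.0018, tolerance = 0.01)
  # Pearson X2 is close at these counts
  x2 <- suppressWarnings(chisq.test(matrix(c(5, 995, 20, 980), 2),
                                    correct = FALSE)$statistic)
  expect_equal(gt$G, unname(x2), tolerance = 0.1)

  # observed = expected: G exactly 0, p = 1
  g0 <- g_test(10, 30, 100, 300)
  expect_identical(g0$G, 0)
  expect_identical(g0$p, 1)

  expect_error(g_test(10, 5, 8, 100), "exceeds")
  # Williams correction shrinks G
  expect_lt(g_test(5, 20, 100, 100, correction = "williams")$G,
            g_test(5, 20, 100, 100)$G)
})

test_that("G agrees with the enumeration oracle on all 2x2 tables with margins <= 12", {
  # exhaustive sweep at small margins; the acceptance suite extends to 30
  for (t1 in 1:12) for (t2 in 1:12) {
    n1 <- rep(0:t1, each = t2 + 1)
    n2 <- rep(0:t2, times = t1 + 1)
    gt <- g_test(n1, n2, t1, t2)
    expect_equal(gt$G, g_oracle(n1, n2, t1 - n1, t2 - n2), tolerance = 1e-10)
  }
})

test_that("the selection gate is strict, directional and order-independent", {
  rec <- data.frame(
    accession = c("A", "B", "C", "D", "E"),
    Rsc = c(1.0, 2.5, -3.0, 1.5, 0.2),
    p = c(0.001, 0.049, 0.002, 0.050, 0.001),
    stringsAsFactors = FALSE)
  sel <- select_candidates(rec)
  # Rsc exactly 1 is NOT selected; p exactly 0.05 is NOT selected
  expect_false("A" %in% sel$accession)
  expect_false("D" %in% sel$accession)
  expect_setequal(sel$accession, c("B", "C"))
  expect_equal(sel$direction[sel$accession == "B"], "LT")
  expect_equal(sel$direction[sel$accession == "C"], "PT")
  # sorted by |Rsc| descending
  expect_equal(sel$accession, c("C", "B"))

  # gate composition: selection equals the intersection of the two gates
  set.seed(3)
  rnd <- data.frame(accession = sprintf("P%03d", 1:200),
                    Rsc = rnorm(200, 0, 1.5), p = runif(200),
                    stringsAsFactors = FALSE)
  sel2 <- select_candidates(rnd)
  expect_setequal(sel2$accession,
                  intersect(rnd$accession[abs(rnd$Rsc) > 1],
                            rnd$accession[rnd$p < 0.05]))
  # empty selection is a valid outcome
  none <- select_candidates(data.frame(accession = "X", Rsc = 0.1, p = 0.9))
  expect_identical(nrow(none), 0L)
})

test_that("Venn partition is exact on matrices and printed set sizes", {
  v <- venn_from_sizes(2622, 2993, 1893)
  expect_identical(c(v$PT_only, v$LT_only, v$shared, v$total),
                   c(729L, 1100L, 1893L, 3722L))
  expect_equal(v$pct_PT_only + v$pct_LT_only + v$pct_shared, 100)

  m <- toy_matrix()  # P1: both; P2: both; P3: both — adjust below
  vm <- venn_summary(m)
  expect_identical(vm$PT_only + vm$LT_only + vm$shared, vm$total)

  disj <- count_matrix(matrix(c(2L, 0L, 0L, 3L), 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       group = c("PT", "LT"))
  vd <- venn_summary(disj)
  expect_identical(vd$shared, 0L)
  expect_identical(vd$total, 2L)

  same <- count_matrix(matrix(c(2L, 1L, 1L, 3L), 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       group = c("PT", "LT"))
  vs <- venn_summary(same)
  expect_identical(vs$PT_only, 0L)
  expect_identical(vs$LT_only, 0L)
  expect_identical(vs$shared, vs$total)

  expect_error(venn_from_sizes(10, 10, 11), "overlap")
})

test_that("spectral_dea assembles a coherent record table with methods", {
  sim <- simulate_counts(count_sim_config(n_proteins = 300, n_cases = 7,
                                          de_fraction = 0.1, de_fold = 4,
                                          seed = 9))
  fit <- spectral_dea(sim$matrix, sim$annotation)
  tab <- fit$table
  expect_named(tab, c("accession", "symbol", "n_PT", "n_LT", "Rsc",
                      "fold_change", "direction", "G", "p", "q",
                      "NSAF_PT", "NSAF_LT", "SpI", "selected"))
  expect_true(all(tab$fold_change >= 1))
  expect_true(all(tab$NSAF_PT >= 0 & tab$NSAF_PT <= 1))
  expect_equal(sum(tab$NSAF_PT), 1, tolerance = 1e-12)
  expect_equal(sum(tab$NSAF_LT), 1, tolerance = 1e-12)
  ok <- !is.na(tab$SpI)
  expect_true(all(abs(tab$SpI[ok]) <= 1 + 1e-12))
  expect_identical(tab$selected,
                   abs(tab$Rsc) > 1 & tab$p < 0.05)
  # q is the BH adjustment of p
  expect_equal(tab$q, p.adjust(tab$p, "BH"))

  expect_output(print(fit), "selected")
  expect_equal(unname(coef(fit)), tab$Rsc)
  expect_s3_class(summary(fit), "data.frame")

  # per-case mode on a single case equals pooled mode
  one <- count_matrix(matrix(c(3L, 0L, 9L, 7L, 2L, 1L), 3,
                             dimnames = list(paste0("P", 1:3),
                                             c("PT_1", "LT_1"))),
                      group = c("PT", "LT"), case = c("c1", "c1"))
  f_pool <- spectral_dea(one)
  f_case <- spectral_dea(one, mode = "per_case")
  expect_equal(f_case$table$Rsc, f_pool$table$Rsc, tolerance = 1e-12)
})
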