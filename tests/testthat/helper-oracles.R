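# independent oracles: brute-force / alternative-derivation implementations
# used to cross-check the package's statistics on tiny inputs

# likelihood-ratio G via the entropy decomposition
#   G = 2 * (sum O ln O - sum_rows R ln R - sum_cols C ln C + N ln N)
# (algebraically equivalent to 2 * sum O ln(O/E) but derived and coded
# differently from the package's cell-wise formula)
g_oracle <- function(a, b, c, d) {
  xlx <- function(v) ifelse(v == 0, 0, v * log(v))
  2 * (xlx(a) + xlx(b) + xlx(c) + xlx(d) -
       xlx(a + b) - xlx(c + d) - xlx(a + c) - xlx(b + d) +
       xlx(a + b + c + d))
}

# Cox log partial likelihood for tie-free data, single covariate
cox_pl <- function(beta, x, time, event) {
  sum(vapply(which(event == 1), function(i) {
    risk <- time >= time[i]
    beta * x[i] - log(sum(exp(beta * x[risk])))
  }, numeric(1)))
}

# grid-search MLE of the Cox coefficient
cox_grid_mle <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, cox_pl, numeric(1), x = x, time = time, event = event)
  grid[which.max(ll)]
}

# AUC by exhaustive pair counting, ties counted 1/2
auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# hand product-limit estimator (right-continuous step at event times)
km_hand <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  data.frame(time = ts, surv = out)
}

# two-group log-rank chi-square from the O/E/V tables
logrank_hand <- function(times, events, grp) {
  g1 <- unique(grp)[1L]
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(times >= t); n1 <- sum(times >= t & grp == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small well-formed count matrix used across io / differential tests
toy_matrix <- function() {
  counts <- matrix(c(2L, 0L, 3L,  1L, 4L, 0L,
                     0L, 5L, 1L,  2L, 0L, 6L), nrow = 3,
                   dimnames = list(c("P1", "P2", "P3"),
                                   c("PT_01", "PT_02", "LT_01", "LT_02")))
  count_matrix(counts, group = c("PT", "PT", "LT", "LT"),
               case = c("c1", "c2", "c1", "c2"))
}

# minimal schema-complete cohort with chosen group sizes
toy_cohort <- function(n_sync = 2, n_meta = 3, n_none = 5, seed = 1) {
  n <- n_sync + n_meta + n_none
  set.seed(seed)
  grp <- rep(c("synchronous", "metachronous", "none"),
             c(n_sync, n_meta, n_none))
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    group = grp,
    gender = rep_len(c("male", "female"), n),
    age = 40 + seq_len(n),
    function_type = rep_len(c("NF", "insulinoma"), n),
    who_grade = rep_len(c("G1", "G2", "G3"), n),
    ki67 = round(runif(n, 1, 40), 1),
    mitotic_count = rpois(n, 2),
    tumor_size = round(runif(n, 10, 80)),
    lymph_node_metastasis = rbinom(n, 1, 0.3),
    vascular_invasion = rbinom(n, 1, 0.4),
    lymphatic_invasion = rbinom(n, 1, 0.3),
    enets_stage = rep_len(c("I", "II", "III", "IV"), n),
    liver_rfs_months = ifelse(grp == "synchronous", NA,
                              round(runif(n, 5, 120), 1)),
    liver_recurrence = ifelse(grp == "synchronous", NA,
                              as.integer(grp == "metachronous")),
    os_months = round(runif(n, 10, 150), 1),
    death = rbinom(n, 1, 0.3),
    marker_M1 = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
  as_cohort_table(df)
}
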