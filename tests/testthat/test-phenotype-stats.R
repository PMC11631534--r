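# The phenotype statistics battery: Fisher exact, Holm, Wilcoxon,
# Welch t, Kaplan-Meier, log-rank, top-quantile subsetting, Wilson
# intervals, composition percentages.

test_that("Fisher exact matches hand-enumerable cases", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(c(1, 9, 9, 1))$p_value, 202 / 184756,
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(c(0, 10, 0, 10))$p_value,
                 "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "0, 1")
  # hand-coded step-down oracle on random vectors
  holm_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
    out <- numeric(m); out[o] <- adj
    out
  }
  set.seed(14)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(holm_bonferroni(p), holm_oracle(p))
    expect_true(all(holm_bonferroni(p) >= p))
  }
})

test_that("Wilcoxon rank-sum is exact for small untied samples", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$mode, "exact")
  expect_equal(r$p_value, 2 / 6)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  set.seed(2)
  big <- wilcoxon_rank_sum(rnorm(200), rnorm(200, 1))
  expect_equal(big$mode, "normal")
  expect_lt(big$p_value, 0.001)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("Wilcoxon exact and normal modes agree closely at n=6+6", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Welch t-test handles shifted and degenerate inputs", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- welch_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.01)
  expect_warning(flat <- welch_t_test(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(flat$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  ev <- event_table(paste0("s", 1:3), "a", c(1, 2, 3), 1)
  km <- km_estimate(ev)
  expect_equal(km$surv[km$n_event == 1], c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  ev2 <- event_table(paste0("s", 1:4), "a", c(1, 2, 3, 4), 0)
  km2 <- km_estimate(ev2)
  expect_true(all(km2$surv == 1))
  # censoring between deaths shrinks later risk sets:
  # death@1 (n=5), censor@2, deaths@3,4,5 -> S = 4/5, 8/15, 4/15, 0
  ev3 <- event_table(paste0("s", 1:5), "a", c(1, 2, 3, 4, 5),
                     c(1, 0, 1, 1, 1))
  km3 <- km_estimate(ev3)
  expect_equal(km3$surv[km3$n_event == 1],
               c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 / 2, 0))
  expect_equal(km3$n_risk[km3$n_event == 1], c(5, 3, 2, 1))
})

test_that("without censoring the KM curve equals one minus the empirical CDF", {
  set.seed(31)
  times <- sample(1:20, 30, replace = TRUE)
  ev <- event_table(paste0("s", 1:30), "a", times, 1)
  km <- km_estimate(ev)
  ecdf_t <- ecdf(times)
  expect_equal(km$surv, 1 - ecdf_t(km$time))
})

test_that("log-rank matches a hand-computed O-E table and is label-symmetric", {
  # A deaths at 1,2,3; B deaths at 4,5,6
  ev <- event_table(paste0("s", 1:6), rep(c("A", "B"), each = 3),
                    c(1, 2, 3, 4, 5, 6), 1)
  # independent O-E computation
  oe <- local({
    time <- c(1, 2, 3, 4, 5, 6)
    grp <- rep(c("A", "B"), each = 3)
    o_a <- 0; e_a <- 0; v <- 0
    for (t in sort(time)) {
      at_risk <- time >= t
      d <- sum(time == t)
      n <- sum(at_risk); n_a <- sum(at_risk & grp == "A")
      o_a <- o_a + sum(time == t & grp == "A")
      e_a <- e_a + d * n_a / n
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / max(1, n - 1)
    }
    (o_a - e_a)^2 / v
  })
  lr <- logrank_test(ev)
  expect_equal(lr$statistic, oe, tolerance = 1e-8)
  expect_equal(lr$p_value, pchisq(oe, 1, lower.tail = FALSE))
  # swapping labels leaves the statistic unchanged
  ev_sw <- ev; ev_sw$group <- ifelse(ev$group == "A", "B", "A")
  expect_equal(logrank_test(ev_sw)$statistic, lr$statistic)
  # identical group data: statistic 0
  ev_same <- event_table(paste0("s", 1:6), rep(c("A", "B"), 3),
                         rep(c(2, 4, 6), each = 2), 1)
  expect_equal(logrank_test(ev_same)$statistic, 0)
  expect_equal(logrank_test(ev_same)$p_value, 1)
  # no deaths is an error
  ev_c <- event_table(paste0("s", 1:4), rep(c("A", "B"), 2), 1:4, 0)
  expect_error(logrank_test(ev_c), "no deaths")
})

test_that("top-quantile subsetting keeps the ceiling(q n) longest-lived deaths", {
  ev <- event_table(sprintf("s%02d", 1:8), "a", c(5, 8, 2, 9, 7, 1, 3, 6), 1)
  top <- top_quantile_subset(ev, 0.25)
  expect_equal(nrow(top), 2L)
  expect_setequal(top$time, c(9, 8))
  expect_equal(nrow(top_quantile_subset(ev, 1)), 8L)
  # ties at the cutoff break by subject_id
  ev_t <- event_table(c("s2", "s1", "s3"), "a", c(5, 5, 5), 1)
  expect_equal(top_quantile_subset(ev_t, 1 / 3)$subject_id, "s1")
  expect_error(top_quantile_subset(ev, 0), "0, 1")
})

test_that("Wilson intervals hit the boundaries and the closed form", {
  expect_equal(unname(proportion_ci(0, 20)["lower"]), 0)
  expect_equal(unname(proportion_ci(20, 20)["upper"]), 1)
  # closed-form Wilson oracle
  wilson <- function(k, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- k / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(centre - half, centre + half)
  }
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci), wilson(50, 100), tolerance = 1e-9)
  ci2 <- proportion_ci(10, 40)
  expect_equal(unname(ci2), wilson(10, 40), tolerance = 1e-9)
  expect_error(proportion_ci(5, 0), "n >= 1")
})

test_that("composition percentages reproduce within-family proportions", {
  counts <- data.frame(
    group = c("x", "x", "y", "y"),
    family = "sex",
    category = c("m", "f", "m", "f"),
    count = c(3, 1, 1, 3)
  )
  out <- composition_percentages(counts)
  expect_equal(out$percent, c(75, 25, 25, 75))
  expect_equal(out$total, c(4L, 4L, 4L, 4L))
})
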