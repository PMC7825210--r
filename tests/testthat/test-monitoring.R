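test_that("welch_ttest agrees with the reference implementation to 1e-6", {
  withr::with_seed(19, {
    for (i in 1:30) {
      a <- rnorm(sample(3:25, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(3:25, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      got <- welch_ttest(a, b)
      ref <- stats::t.test(a, b, var.equal = FALSE)
      expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(got$degrees_of_freedom, unname(ref$parameter), tolerance = 1e-6)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
      # Welch-Satterthwaite df within its standard bounds
      expect_gte(got$degrees_of_freedom, min(length(a), length(b)) - 1)
      expect_lte(got$degrees_of_freedom, length(a) + length(b) - 2)
    }
  })
})

test_that("identical groups give t = 0 and p = 1; swapping groups negates t", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- welch_ttest(x, x)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  y <- c(2.5, 6.1, 4.4)
  ab <- welch_ttest(x, y)
  ba <- welch_ttest(y, x)
  expect_equal(ba$t_statistic, -ab$t_statistic)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("degenerate samples are rejected with informative errors", {
  expect_error(welch_ttest(1, c(1, 2, 3)), ">= 2",
               class = "octavca_validation_error")
  expect_error(welch_ttest(c(2, 2, 2), c(3, 3, 3)), "variances are zero")
  expect_error(welch_ttest(c(2, 2), c(2, 2)), "means are equal")
})

test_that("tidy methods return one-row summaries", {
  tt <- welch_ttest(c(1, 2, 3, 4), c(2, 3, 4, 8))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_identical(td$statistic, tt$t_statistic)
})

test_that("significance labels follow the figure legend convention", {
  expect_identical(significance_label(c(0.005, 0.03, 0.2)), c("**", "*", "ns"))
})

make_study <- function(n = 14, decline = 0.6, noise_sd = 0.05, seed = 1,
                       width_shift = 1.0) {
  withr::with_seed(seed, {
    l1 <- rnorm(n, 100, 10)
    l7 <- decline * l1 * (1 + rnorm(n, 0, noise_sd))
    w1 <- rnorm(n, 5, 0.4)
    w7 <- width_shift * w1 * (1 + rnorm(n, 0, noise_sd))
    tibble::tibble(
      subject_id = rep(sprintf("S%02d", seq_len(n)), each = 2),
      day = rep(c(1L, 7L), n),
      length_px = as.vector(rbind(l1, l7)),
      width_px = as.vector(rbind(w1, w7)))
  })
}

test_that("a planted length decline is recovered with the right significance", {
  tab <- make_study(n = 14, decline = 0.6, seed = 42)
  mon <- monitor_study(tab)
  ch <- mon$changes
  expect_lte(abs(ch$percent_change[ch$parameter == "length"] - (-40)), 5)
  ts <- mon$tests
  expect_lt(ts$p_value[ts$parameter == "length"], 0.01)
  expect_identical(ts$label[ts$parameter == "length"], "**")
  g <- glance(mon)
  expect_identical(g$label_length, "**")
  # cross-check the length test against the reference implementation
  ref <- stats::t.test(tab$length_px[tab$day == 1], tab$length_px[tab$day == 7])
  expect_equal(ts$t_statistic[ts$parameter == "length"],
               unname(ref$statistic), tolerance = 1e-8)
})

test_that("no change means zero percent change and p = 1", {
  tab <- make_study(n = 6, decline = 1, noise_sd = 0, seed = 3)
  mon <- monitor_study(tab)
  expect_equal(mon$changes$percent_change, c(0, 0), tolerance = 1e-12)
  expect_equal(mon$tests$p_value, c(1, 1), tolerance = 1e-12)
  expect_equal(mon$changes$percent_of_reference, c(100, 100))
})

test_that("the summary is invariant to row order of the input table", {
  tab <- make_study(n = 10, seed = 8)
  mon1 <- monitor_study(tab)
  mon2 <- monitor_study(tab[sample(nrow(tab)), ])
  expect_equal(mon1$per_day, mon2$per_day)
  expect_equal(mon1$changes, mon2$changes)
  expect_equal(mon1$tests, mon2$tests)
})

test_that("input validation: duplicates and absent days are rejected by name", {
  tab <- make_study(n = 4, seed = 5)
  expect_error(monitor_study(rbind(tab, tab[1, ])), "duplicate")
  expect_error(monitor_study(tab, day_from = 1, day_to = 5),
               "day 5 is absent")
  expect_error(monitor_study(tab[0, ]), "empty")
})

test_that("per-day summaries are cross-subject arithmetic means and sds", {
  tab <- make_study(n = 7, seed = 11)
  mon <- monitor_study(tab)
  d1 <- tab$length_px[tab$day == 1]
  row <- mon$per_day[mon$per_day$day == 1 & mon$per_day$parameter == "length", ]
  expect_equal(row$mean, mean(d1))
  expect_equal(row$sd, sd(d1))
  expect_identical(row$n, 7L)
})

test_that("the paired variant uses within-subject differences with n - 1 df", {
  tab <- make_study(n = 9, seed = 13)
  mon <- monitor_study(tab, paired = TRUE)
  diffs <- tab$length_px[tab$day == 7] - tab$length_px[tab$day == 1]
  ref <- stats::t.test(diffs)
  got <- mon$tests[mon$tests$parameter == "length", ]
  expect_equal(abs(got$t_statistic), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_identical(got$df, 8)
})

test_that("autoplot returns a faceted ggplot of per-day means", {
  p <- autoplot(monitor_study(make_study(n = 5, seed = 2)))
  expect_s3_class(p, "ggplot")
})
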