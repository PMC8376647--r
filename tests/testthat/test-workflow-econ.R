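test_that("half-up rounding uses the commercial convention", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.4, 1054.5)), c(1, 2, 2, 1055))
  expect_equal(round_half_up(-0.5), -1)
})

test_that("Welch interval collapses to the pooled df for equal groups", {
  g1 <- group_summary(50, 10, sd = 2, unit = "hours")
  g2 <- group_summary(50, 10, sd = 2, unit = "hours")
  w <- welch_interval(g1, g2)
  expect_equal(w$diff, 0)
  expect_equal(w$df, 98)
  expect_equal(w$lower, -w$upper)
  # unequal variances shrink the effective df below pooled
  g3 <- group_summary(50, 12, sd = 6, unit = "hours")
  expect_lt(welch_interval(g3, g2)$df, 98)
  expect_error(welch_interval(group_summary(50, 10, ci95 = c(9, 11), unit = "hours"), g2),
               "sd")
  expect_error(welch_interval(g1, group_summary(50, 10, sd = 2, unit = "minutes")),
               "unit mismatch")
})

test_that("Welch interval covers the true difference at the nominal rate", {
  set.seed(2024)
  n1 <- 30; n2 <- 45; true_diff <- 1.5
  hits <- 0L; reps <- 1000L
  for (r in seq_len(reps)) {
    x <- rnorm(n1, 5 + true_diff, 2)
    y <- rnorm(n2, 5, 3)
    w <- welch_interval(group_summary(n1, mean(x), sd = sd(x)),
                        group_summary(n2, mean(y), sd = sd(y)))
    if (w$lower <= true_diff && true_diff <= w$upper) hits <- hits + 1L
  }
  cov <- hits / reps
  expect_gte(cov, 0.93); expect_lte(cov, 0.97)
})

test_that("audit differences reproduce the printed audit arithmetic", {
  d <- audit_differences()
  expect_equal(d$turnaround_diff_hours, 77)     # 7 d 10 h vs 4 d 5 h
  expect_equal(d$reporting_diff_minutes, 15.5)  # 33.4 vs 17.9 min
  eq <- list(ihc = group_summary(10, 5, unit = "hours"),
             no_ihc = group_summary(10, 5, unit = "hours"))
  expect_equal(audit_differences(turnaround = eq)$turnaround_diff_hours, 0)
  bad <- list(ihc = group_summary(10, 5, unit = "hours"),
              no_ihc = group_summary(10, 5, unit = "minutes"))
  expect_error(audit_differences(turnaround = bad), "unit mismatch")
})

test_that("session duplication sums its duplicated components linearly", {
  expect_equal(session_duplication(session_model()), 10.0)  # 7.5 + 1.5 + 1.0
  expect_equal(session_duplication(session_model(0, 0, 0, 0)), 0)
  m <- session_model(3, 2, 1, 0.5)
  m2 <- session_model(6, 4, 2, 1)
  expect_equal(session_duplication(m2), 2 * session_duplication(m))
})

test_that("economics table reproduces its defining arithmetic", {
  tab <- econ_table()
  get <- function(lbl, col) tab[tab$label == lbl, col]
  expect_equal(get("point_1_spec_0.60", "turnaround_savings_days"), 703)
  expect_equal(get("point_1_spec_0.60", "reporting_savings_hours"), 42)
  expect_equal(get("point_1_spec_0.60", "extra_cost_currency"), 627)
  expect_equal(get("point_2_spec_0.75", "turnaround_savings_days"), 879)
  expect_equal(get("point_2_spec_0.75", "reporting_savings_hours"), 52)
  expect_equal(get("point_2_spec_0.75", "extra_cost_currency"), 1379)
  expect_equal(get("point_3_spec_0.90", "reporting_savings_hours"), 63)
  expect_equal(get("point_3_spec_0.90", "extra_cost_currency"), 2006)
  expect_equal(get("reflex_testing", "reporting_savings_hours"), 70)
  expect_equal(get("reflex_testing", "extra_cost_currency"), 4180)
  # exact columns expose the unrounded arithmetic
  expect_equal(get("reflex_testing", "turnaround_savings_days_exact"),
               380 * 74 / 24)
  expect_equal(get("point_3_spec_0.90", "turnaround_savings_days_exact"), 1054.5)
  # degenerate assumption
  zero <- econ_table(assumptions = operating_assumption("none", 0, 0))
  expect_true(all(zero[, c("turnaround_savings_days", "reporting_savings_hours",
                           "extra_cost_currency")] == 0))
  expect_error(operating_assumption("bad", 1.2, 0), "\\[0, 1\\]")
})

test_that("savings grow with detection and costs with over-ordering", {
  d_grid <- seq(0, 1, by = 0.1)
  tab_d <- econ_table(assumptions = do.call(rbind, lapply(d_grid, function(d)
    operating_assumption(paste0("d", d), d, 0.5))))
  expect_true(all(diff(tab_d$turnaround_savings_days) >= 0))
  expect_true(all(diff(tab_d$reporting_savings_hours) >= 0))
  tab_f <- econ_table(assumptions = do.call(rbind, lapply(d_grid, function(f)
    operating_assumption(paste0("f", f), 0.5, f))))
  expect_true(all(diff(tab_f$extra_cost_currency) >= 0))
  # reflex testing dominates every operating point in savings and cost
  tab <- econ_table()
  reflex <- tab[tab$label == "reflex_testing", ]
  others <- tab[tab$label != "reflex_testing", ]
  expect_true(all(reflex$turnaround_savings_days >= others$turnaround_savings_days))
  expect_true(all(reflex$extra_cost_currency >= others$extra_cost_currency))
})

test_that("scaled reporting saving is the stated linear form", {
  expect_equal(scaled_reporting_saving(1000, 0.9, 11), 165)
  expect_equal(scaled_reporting_saving(1000, 0, 11), 0)
  expect_equal(scaled_reporting_saving(2000, 0.9, 11),
               2 * scaled_reporting_saving(1000, 0.9, 11))
})
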