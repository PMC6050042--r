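test_that("survival tables are one row per track with correct bookkeeping", {
  tracks <- c(
    lapply(1:4, function(i) make_track(i, "a", "dead", i)),
    lapply(5:10, function(i) make_track(i, "a", "alive-at-end", 10))
  )
  tab <- build_survival_table(tracks)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$event), 4)
  expect_equal(tab$time_days[tab$event == 0], rep(10, 6))
  expect_error(build_survival_table(list(make_track(1, "a", "unclassified", 5))),
               "exit time")
})

test_that("covariates attach at the nearest frame and missing frames give NA", {
  tr <- make_track(1, "a", "dead", 4)
  tab <- build_survival_table(list(tr), covariates = list(
    gfp_24h = list(channel = "reporter", at_hour = 24),
    late = list(channel = "reporter", at_hour = 240),
    ratio = list(channel = "reporter", ratio_hours = c(48, 24))
  ))
  expect_equal(tab$gfp_24h, 200)
  expect_true(is.na(tab$late))      # cell dead long before 240 h
  expect_equal(tab$ratio, 1)
})

test_that("Cox fits match the exhaustive partial-likelihood grid oracle", {
  # hand-built 6-record dataset, two groups, no ties
  rec6 <- data.frame(id = 1:6, group = rep(c("a", "b"), 3),
                     time_days = c(2, 1, 4, 3, 6, 5),
                     event = c(1, 1, 1, 0, 1, 1))
  f <- fit_cox(rec6, reference = "a")
  expect_equal(f$table$beta, cox_grid_beta(rec6, "a"), tolerance = 1e-3)
  # heavily tied interval-censored data, several shapes
  for (s in 1:3) {
    set.seed(40 + s)
    n <- 10
    rec <- data.frame(id = 1:n, group = sample(c("a", "b"), n, TRUE),
                      time_days = sample(1:4, n, TRUE),
                      event = rbinom(n, 1, 0.7))
    if (length(unique(rec$group)) < 2 || sum(rec$event) == 0) next
    f <- fit_cox(rec, reference = "a")
    expect_equal(f$table$beta, cox_grid_beta(rec, "a"), tolerance = 1e-3)
  }
})

test_that("Cox fit symmetry, invariances, and error contracts hold", {
  # identical event-time multisets in both groups -> HR = 1
  rec <- data.frame(id = 1:10, group = rep(c("a", "b"), each = 5),
                    time_days = rep(c(1, 2, 3, 4, 10), 2),
                    event = rep(c(1, 1, 1, 1, 0), 2))
  expect_equal(fit_cox(rec)$table$hr, 1, tolerance = 1e-6)
  # relabeling groups inverts the HR exactly
  set.seed(44)
  rec2 <- simulate_survival_cohort(80, c(a = 0, b = 0.4), 0.1, seed = 44)$records
  hr_ab <- fit_cox(rec2, reference = "a")$table$hr
  hr_ba <- fit_cox(rec2, reference = "b")$table$hr
  expect_equal(hr_ab, 1 / hr_ba, tolerance = 1e-8)
  # shifting all times by a constant leaves the HR unchanged
  rec3 <- rec2; rec3$time_days <- rec3$time_days + 5
  expect_equal(fit_cox(rec3, reference = "a")$table$hr, hr_ab,
               tolerance = 1e-10)
  expect_error(fit_cox(rec[rec$group == "a", ]), "2 groups")
  rec_noev <- rec; rec_noev$event <- 0
  expect_error(fit_cox(rec_noev), "no information")
})

test_that("cumulative risk curves are KM complements", {
  # all censored -> flat zero
  rec <- data.frame(id = 1:5, group = "a", time_days = 1:5, event = 0)
  cr <- cumulative_risk_curve(rec)
  expect_true(all(cr$cum_risk == 0))
  # all die at day 3 -> single step to 1
  rec2 <- data.frame(id = 1:5, group = "a", time_days = 3, event = 1)
  cr2 <- cumulative_risk_curve(rec2)
  expect_equal(cr2$cum_risk, c(0, 1))
  expect_equal(cr2$time_days, c(0, 3))
  # hand-computed KM on a 5-record mix of deaths and censorings:
  # S = 4/5, then 4/5 * 3/4, then 0.6 * 1/2
  rec3 <- data.frame(id = 1:5, group = "a",
                     time_days = c(1, 2, 2, 3, 4), event = c(1, 0, 1, 1, 0))
  cr3 <- cumulative_risk_curve(rec3)
  expect_equal(cr3$cum_risk[cr3$time_days %in% c(1, 2, 3)],
               c(0.2, 0.4, 0.7), tolerance = 1e-12)
  # right-continuous nondecreasing in [0, 1]
  expect_true(all(diff(cr3$cum_risk) >= 0))
  expect_true(all(cr3$cum_risk >= 0 & cr3$cum_risk <= 1))
})
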