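test_that("nuclear CV matches its definition and invariances", {
  m <- matrix(c(1, 3, 0, 0), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  # two-pixel region {1, 3}: mean 2, population sd 1 -> CV 0.5
  expect_equal(nuclear_cv(m, mask), 0.5)
  expect_equal(nuclear_cv(matrix(7, 5, 5), matrix(TRUE, 5, 5)), 0)
  # multiplicative scale invariance
  expect_equal(nuclear_cv(m * 10, mask), nuclear_cv(m, mask),
               tolerance = 1e-12)
  expect_error(nuclear_cv(matrix(0, 2, 2), matrix(TRUE, 2, 2)),
               "undefined CV")
  # CV strictly increases with the contrast of a fixed punctum
  base <- matrix(100, 21, 21)
  msk <- matrix(TRUE, 21, 21)
  cvs <- vapply(c(1, 2, 4), function(k) {
    img <- base; img[10, 10] <- 100 * (1 + k); nuclear_cv(img, msk)
  }, 1)
  expect_true(all(diff(cvs) > 0))
})

test_that("ROC curves are monotone and perfect separation gives J = 1", {
  roc <- build_roc(c(0.2, 0.3, 0.4, 1.2, 1.3, 1.5),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_equal(roc$auc, 1)
  # monotonicity across the full sweep on overlapping data
  set.seed(50)
  cvs <- c(rnorm(200, 1, 0.3), rnorm(200, 0.6, 0.3))
  truth <- rep(c(TRUE, FALSE), each = 200)
  r <- build_roc(cvs, truth)
  expect_true(all(diff(r$curve$sensitivity) <= 0))
  expect_true(all(diff(r$curve$specificity) >= 0))
  # random labels give chance-level AUC
  set.seed(51)
  r2 <- build_roc(runif(500), sample(c(TRUE, FALSE), 500, TRUE))
  expect_equal(r2$auc, 0.5, tolerance = 0.1)
  expect_error(build_roc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("classification reproduces published-style granule fractions", {
  # construct CV vectors realizing the printed counts
  cv_a <- c(rep(1.2, 2081), rep(0.5, 2734 - 2081))
  cv_b <- c(rep(1.2, 1590), rep(0.5, 1743 - 1590))
  cls <- classify_cells(c(cv_a, cv_b), threshold = 0.92,
                        groups = rep(c("dRRM2", "dRRM1/2"),
                                     c(2734, 1743)))
  s <- cls$summary
  expect_equal(s$percent[s$group == "dRRM2"], 76.1)
  expect_equal(s$percent[s$group == "dRRM1/2"], 91.2)
  expect_equal(s$n_positive, c(1590, 2081)[order(c("dRRM1/2", "dRRM2"))])
})

test_that("classification is deterministic with boundary counted positive", {
  cls <- classify_cells(c(0.92, 0.9199999), threshold = 0.92)
  expect_equal(cls$calls$call, c("granule-positive", "diffuse"))
  # idempotent: reclassifying the same CVs gives identical calls
  expect_identical(cls, classify_cells(c(0.92, 0.9199999), threshold = 0.92))
})

test_that("Fisher exact p matches full enumeration and its contracts", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p, 1)
  set.seed(52)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_p_enum(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "empty margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("granule-stratified survival compares each stratum to the pool", {
  # identical survival in both strata -> both HRs ~ 1
  set.seed(53)
  n <- 400
  rec <- data.frame(id = 1:n, group = "g",
                    time_days = sample(1:10, n, TRUE),
                    event = rbinom(n, 1, 0.6))
  calls <- data.frame(id = 1:n,
                      call = rep(c("granule-positive", "diffuse"), n / 2))
  out <- stratified_survival_by_granule(rec, calls)
  expect_equal(out$granular$table$hr, 1, tolerance = 0.25)
  expect_equal(out$diffuse$table$hr, 1, tolerance = 0.25)
  expect_equal(out$n[["granular"]] + out$n[["diffuse"]], out$n[["pooled"]])
  # protective granules: HR(granular vs pooled) < 1 < HR(diffuse vs pooled)
  s <- simulate_survival_cohort(c(1500, 500),
                                c(gran = log(0.8), diff = log(1.8)),
                                0.1, seed = 54)
  rec2 <- s$records
  calls2 <- data.frame(id = rec2$id,
                       call = ifelse(rec2$group == "gran",
                                     "granule-positive", "diffuse"))
  out2 <- stratified_survival_by_granule(rec2, calls2)
  expect_lt(out2$granular$table$hr, 1)
  expect_gt(out2$diffuse$table$hr, 1)
  expect_error(stratified_survival_by_granule(
    rec2, data.frame(id = rec2$id, call = "diffuse")), "empty stratum")
})
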