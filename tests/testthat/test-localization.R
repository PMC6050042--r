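test_that("nuclear masks recover a bright central disc inside the soma", {
  soma <- lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 15)
  nuc_true <- lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 7)
  img <- matrix(5, 64, 64); img[soma] <- 30; img[nuc_true] <- 300
  nm <- nuclear_mask(soma, img)
  # within a 1-px boundary tolerance of the construction
  boundary <- lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 8) &
    !lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 6)
  expect_true(all(xor(nm, nuc_true)[!boundary] == FALSE))
  expect_true(all(nm[!soma] == FALSE))          # containment
  expect_lte(sum(nm), sum(soma))
  expect_error(nuclear_mask(soma, matrix(5, 64, 64)), "nucleus not found")
})

test_that("nucleocytoplasmic ratios are scale-invariant and flag dim cytoplasm", {
  soma <- lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 15)
  nuc <- lfmkit:::disc_mask(c(64, 64), 31.5, 31.5, 7)
  img <- matrix(2, 64, 64); img[soma] <- 40; img[nuc] <- 400
  m <- nuc_cyto_ratio(soma, nuc, img)
  expect_equal(m$ratio, 10)
  expect_false(m$unbounded)
  # global multiplicative rescaling leaves the ratio unchanged
  m2 <- nuc_cyto_ratio(soma, nuc, img * 7)
  expect_equal(m2$ratio, m$ratio, tolerance = 1e-12)
  # uniform soma -> ratio 1
  img_u <- matrix(2, 64, 64); img_u[soma] <- 50
  expect_equal(nuc_cyto_ratio(soma, nuc, img_u)$ratio, 1)
  # 10x construction with noise recovered within 2%
  set.seed(60)
  img_n <- img + matrix(rnorm(64 * 64, 0, 2), 64)
  expect_equal(nuc_cyto_ratio(soma, nuc, img_n)$ratio, 10,
               tolerance = 0.02)
  # cytoplasm at background level -> unbounded flag, NA ratio
  img_b <- matrix(2, 64, 64); img_b[nuc] <- 400
  mb <- nuc_cyto_ratio(soma, nuc, img_b)
  expect_true(mb$unbounded)
  expect_true(is.na(mb$ratio))
  expect_error(nuc_cyto_ratio(nuc, nuc, img), "cytoplasmic")
})

test_that("immunoreactivity quantification recovers constructed fold-changes", {
  soma <- lfmkit:::disc_mask(c(48, 48), 23.5, 23.5, 10)
  mk <- function(level) { m <- matrix(10, 48, 48); m[soma] <- 10 + level; m }
  # identical conditions -> fold-change 1
  q1 <- quantify_immunoreactivity(
    c(replicate(6, mk(50), simplify = FALSE)),
    replicate(6, soma, simplify = FALSE),
    rep(c("ref", "cond"), each = 3))
  expect_equal(q1$fold_changes$fold_change, 1, tolerance = 1e-12)
  # 2.8x construction, and a 65% knockdown
  imgs <- c(replicate(3, mk(50), simplify = FALSE),
            replicate(3, mk(140), simplify = FALSE),
            replicate(3, mk(17.5), simplify = FALSE))
  q2 <- quantify_immunoreactivity(
    imgs, replicate(9, soma, simplify = FALSE),
    rep(c("untransfected", "overexpress", "knockdown"), each = 3),
    reference = "untransfected")
  fc <- q2$fold_changes
  expect_equal(fc$fold_change[fc$condition == "overexpress"], 2.8,
               tolerance = 1e-6)
  expect_equal(fc$knockdown_percent[fc$condition == "knockdown"], 65,
               tolerance = 1e-6)
  expect_error(quantify_immunoreactivity(
    imgs[1:2], replicate(2, soma, simplify = FALSE), c("a", "a")),
    "2 conditions")
})

test_that("antibody signal tracks reporter intensity cell by cell", {
  # linear relation (slope 0.9) with 10% noise: per-cell regression r2 >= 0.8
  set.seed(61)
  soma <- lfmkit:::disc_mask(c(32, 32), 15.5, 15.5, 8)
  gfp <- rlnorm(80, log(100), 0.5)
  ab_level <- 0.9 * gfp * exp(rnorm(80, 0, 0.1))
  imgs <- lapply(ab_level, function(v) {
    m <- matrix(5, 32, 32); m[soma] <- 5 + v
    m + matrix(rnorm(32 * 32, 0, 1), 32)
  })
  q <- quantify_immunoreactivity(imgs, replicate(80, soma, simplify = FALSE),
                                 rep(c("a", "b"), 40))
  fit <- lm(q$cells$intensity ~ gfp)
  expect_gte(summary(fit)$r.squared, 0.8)
  expect_equal(unname(coef(fit)[2]), 0.9, tolerance = 0.15)
})

test_that("group comparisons behave exactly in degenerate cases", {
  expect_equal(compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p, 1)
  expect_equal(compare_groups(list(a = c(2, 2), b = c(2, 2)))$p, 1)
  expect_equal(compare_groups(list(a = c(2, 2), b = c(3, 3)))$p, 0)
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(compare_groups(list(a = c(1, 2), b = c(1, 2), c = c(1, 2))),
               "exactly 2")
})

test_that("Tukey pairwise p-values match the studentized-range oracle", {
  vals <- list(a = c(5.1, 4.8, 5.0, 5.3, 4.9),
               b = c(6.0, 6.2, 5.8, 6.1, 6.4),
               c = c(5.4, 5.6, 5.2, 5.5, 5.8))
  out <- compare_groups(vals, method = "anova_tukey")
  # oracle: q = |diff| / sqrt(MSE/n), p = ptukey(q, 3, 12)
  v <- unlist(vals); g <- rep(names(vals), each = 5)
  mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / 12
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    q <- abs(mean(vals[[pair[1]]]) - mean(vals[[pair[2]]])) / sqrt(mse / 5)
    p_oracle <- ptukey(q, 3, 12, lower.tail = FALSE)
    comp <- paste(pair, collapse = "-")
    expect_equal(out$pairwise$p_adj[out$pairwise$comparison == comp],
                 p_oracle, tolerance = 0.005)
  }
  # calibration sanity: one-way ANOVA on null data keeps its size
  set.seed(62)
  rej <- vapply(1:200, function(i) {
    grp <- split(rnorm(30), rep(1:3, each = 10))
    names(grp) <- c("x", "y", "z")
    compare_groups(grp, method = "anova_tukey")$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})
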