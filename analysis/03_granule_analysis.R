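#!/usr/bin/env Rscript
# Granule classification analysis: nuclear CV on annotated synthetic
# nuclei, ROC threshold selection, per-group granule fractions at the
# published 0.92 operating point, Fisher's exact comparison, the
# granule-onset spline model, and granule-stratified survival.

library(lfmkit)
dir.create("results", showWarnings = FALSE)

## ROC calibration on an annotated synthetic set
nuc <- simulate_nuclear_images(300, 300, seed = 201)
cvs <- vapply(nuc, function(x) nuclear_cv(x$image, x$mask), 1)
labels <- vapply(nuc, `[[`, "", "label")
roc <- build_roc(cvs, labels)
print(roc)
write.csv(roc$curve, "results/granule_roc_curve.csv", row.names = FALSE)

## Granule fractions from the published per-group counts, at CV >= 0.92
counts <- list(dRRM2 = c(2081, 2734), dRRM1_2 = c(1590, 1743))
cv_vec <- unlist(lapply(counts, function(ct)
  c(rep(1.5, ct[1]), rep(0.3, ct[2] - ct[1]))))
cls <- classify_cells(cv_vec, threshold = 0.92,
                      groups = rep(names(counts), sapply(counts, `[`, 2)))
print(cls$summary)
write.csv(cls$summary, "results/granule_fractions.csv", row.names = FALSE)

fis <- fisher_exact_2x2(matrix(c(2081, 1590, 653, 153), 2, 2))
cat(sprintf("Fisher exact on granule-by-variant table: p = %.3g (OR %.2f)\n",
            fis$p, fis$odds_ratio))

## Onset model: probability of granule formation by day 3 as a smooth
## function of the day2/day1 expression ratio (rapid accumulation model)
set.seed(202)
ratio <- rlnorm(800, log(1.1), 0.25)
onset <- rbinom(800, 1, plogis(-4 + 5 * (ratio - 1) + 2))
onset_fit <- fit_granule_onset_model(ratio, onset)
print(onset_fit)
write.csv(onset_fit$curve, "results/granule_onset_curve.csv",
          row.names = FALSE)

## Granule-stratified survival: protective granules vs toxic diffuse pool
strat_cohort <- simulate_survival_cohort(
  c(2081, 653), c(granular = log(0.86), diffuse = log(1.75)),
  baseline_hazard = 0.08, follow_up = 10, seed = 203)
rec <- strat_cohort$records
calls <- data.frame(id = rec$id,
                    call = ifelse(rec$group == "granular",
                                  "granule-positive", "diffuse"))
strat <- stratified_survival_by_granule(rec, calls)
cat(sprintf("HR granular vs pooled: %.2f; HR diffuse vs pooled: %.2f\n",
            strat$granular$table$hr, strat$diffuse$table$hr))

jsonlite::write_json(list(
  roc = list(threshold = roc$threshold, sensitivity = roc$sensitivity,
             specificity = roc$specificity, auc = roc$auc),
  fractions = cls$summary, fisher_p = fis$p,
  onset = list(p = onset_fit$p, edf = onset_fit$edf),
  stratified = list(hr_granular = strat$granular$table$hr,
                    hr_diffuse = strat$diffuse$table$hr)
), "results/granule_analysis.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
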