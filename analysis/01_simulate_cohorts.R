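#!/usr/bin/env Rscript
# Simulate the tabular single-cell cohorts used by the downstream
# analyses: a two-arm overexpression survival experiment at the study's
# scale, a knockdown experiment, and an expression-graded cohort whose
# hazard rises smoothly with reporter level. Writes the survival tables
# under results/.

library(lfmkit)
dir.create("results", showWarnings = FALSE)

# Overexpression arm: ~1250 neurons per arm, 10 days of daily imaging,
# true hazard ratio 1.48 for the tagged construct.
over <- simulate_survival_cohort(c(1286, 1183),
                                 c(egfp = 0, matr3_egfp = log(1.48)),
                                 baseline_hazard = 0.08, follow_up = 10,
                                 seed = 101)
write.csv(over$records, "results/cohort_overexpression.csv",
          row.names = FALSE)

# Knockdown arm: true hazard ratio 1.20 against scrambled siRNA.
kd <- simulate_survival_cohort(c(2507, 2623),
                               c(scrambled = 0, anti_matr3 = log(1.20)),
                               baseline_hazard = 0.08, follow_up = 10,
                               seed = 102)
write.csv(kd$records, "results/cohort_knockdown.csv", row.names = FALSE)

# Expression-graded cohort: log hazard linear in day-1 reporter level,
# for the penalized-spline expression-risk model.
graded <- simulate_survival_cohort(
  2000, c(matr3_egfp = 0), baseline_hazard = 0.08, follow_up = 10,
  log_hazard_fun = function(x) 0.4 * (x - 500) / 300, seed = 103)
write.csv(graded$records, "results/cohort_expression_graded.csv",
          row.names = FALSE)

cat(sprintf(
  "wrote %d + %d + %d records; event fractions %.2f / %.2f / %.2f\n",
  nrow(over$records), nrow(kd$records), nrow(graded$records),
  mean(over$records$event), mean(kd$records$event),
  mean(graded$records$event)))
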