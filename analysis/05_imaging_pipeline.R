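#!/usr/bin/env Rscript
# End-to-end imaging run: render multi-field time-lapse cohorts, segment,
# track, call deaths, and compare the pipeline's hazard ratio with the
# one computed from the generator's true death times; also audits
# segmentation and death-call accuracy, and demonstrates the one-config
# pipeline runner with a nucleocytoplasmic measurement example.

library(lfmkit)
dir.create("results", showWarnings = FALSE)

coh <- simulate_tracked_cohort(c(control = 0, mutant = log(1.5)),
                               n_fields = 6, cells_per_field = 50,
                               seed = 601, baseline_hazard = 0.08)
write.csv(coh$records, "results/pipeline_survival_table.csv",
          row.names = FALSE)
hr_pipe <- fit_cox(coh$records, reference = "control")$table$hr
hr_true <- fit_cox(coh$truth_records, reference = "control")$table$hr
cat(sprintf(
  "segmentation F1 %.3f | deaths within 1 frame %.1f%% | HR %.2f (truth %.2f)\n",
  mean(coh$audit$detection_f1),
  100 * mean(abs(coh$audit$death_frame_errors) <= 1), hr_pipe, hr_true))

## one-config run: simulate -> segment -> track -> death-call -> reports
manifest <- run_pipeline(list(
  seed = 602,
  simulate = list(n_cells = 40, groups = c("control", "mutant"),
                  group_log_hrs = list(control = 0, mutant = 0.4),
                  baseline_hazard = 0.1, puncta_contrast = 2)
), outdir = "results/pipeline_demo")
cat("pipeline outputs:", paste(names(manifest$outputs), collapse = ", "),
    "\n")

## nucleocytoplasmic quantification on a rendered cell with a bright
## nucleus (nuclear-retained protein) vs an evenly distributed one
sz <- c(64, 64)
soma <- disc_mask(sz, 31.5, 31.5, 14)
reporter <- matrix(3, sz[1], sz[2])
reporter[soma] <- 35
nucleus_img <- matrix(0, sz[1], sz[2])
nucleus_img[disc_mask(sz, 31.5, 31.5, 6)] <- 300
reporter_nuc <- reporter + nucleus_img
set.seed(603)
reporter_nuc <- pmax(reporter_nuc + rnorm(prod(sz), 0, 1.5), 0)
nm <- nuclear_mask(soma, reporter_nuc)
m <- nuc_cyto_ratio(soma, nm, reporter_nuc)
cat(sprintf("nucleocytoplasmic ratio (nuclear-retained): %.1f\n", m$ratio))

jsonlite::write_json(list(
  segmentation_f1 = mean(coh$audit$detection_f1),
  death_within_1_frame = mean(abs(coh$audit$death_frame_errors) <= 1),
  hr_pipeline = hr_pipe, hr_truth = hr_true,
  nc_ratio_example = m$ratio
), "results/imaging_pipeline.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
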