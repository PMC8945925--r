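#!/usr/bin/env Rscript
# Simulate two patients' paired PET scans as SUL phantoms with ground truth:
# patient A responds (both lesions shrink), patient B progresses (a new
# lesion appears despite a modest decrease of the hottest one).
# Outputs: results/phantoms/*.nii.gz, results/phantoms/ground_truth.csv

suppressPackageStartupMessages(library(petburden))
out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(
  A = list(
    baseline = phantom_spec(
      lesions = list(
        lesion_spec(c(40, 40, 96), radii = 11, peak_sul = 10.7,
                    organ_label = 2L, id = "pleura"),
        lesion_spec(c(88, 80, 60), radii = 8, peak_sul = 6.2,
                    organ_label = 3L, id = "lung")),
      noise_sd = 0.05, rng_seed = 101L),
    followup = followup_spec(factors = c(pleura = 0.38, lung = 0.55),
                             rng_seed = 102L)),
  B = list(
    baseline = phantom_spec(
      lesions = list(
        lesion_spec(c(44, 88, 72), radii = 12, peak_sul = 9.37,
                    organ_label = 3L, id = "rul_mass")),
      noise_sd = 0.05, rng_seed = 201L),
    followup = followup_spec(
      factors = c(rul_mass = 0.951),  # -4.9% on the hottest lesion
      new_lesions = list(lesion_spec(c(96, 40, 40), radii = 7, peak_sul = 5.5,
                                     organ_label = 4L, id = "adrenal_new")),
      rng_seed = 202L))
)

gt_all <- list()
for (pid in names(specs)) {
  base <- make_phantom(specs[[pid]]$baseline)
  fu <- make_followup(specs[[pid]]$baseline, specs[[pid]]$followup)
  write_volume(base$volume, file.path(out, sprintf("%s_baseline_sul.nii.gz", pid)))
  write_volume(base$organs, file.path(out, sprintf("%s_baseline_organs.nii.gz", pid)))
  write_volume(fu$volume, file.path(out, sprintf("%s_followup_sul.nii.gz", pid)))
  write_volume(fu$organs, file.path(out, sprintf("%s_followup_organs.nii.gz", pid)))
  for (tp in c("baseline", "followup")) {
    gt <- if (tp == "baseline") base$ground_truth else fu$ground_truth
    if (nrow(gt)) gt_all[[length(gt_all) + 1L]] <-
        cbind(patient = pid, timepoint = tp,
              gt[setdiff(names(gt), "baseline_id")])
  }
  cat(sprintf("patient %s: %d baseline lesion(s), %d follow-up lesion(s)\n",
              pid, nrow(base$ground_truth), nrow(fu$ground_truth)))
}
write.csv(do.call(rbind, gt_all), file.path(out, "ground_truth.csv"),
          row.names = FALSE)
cat("phantoms written to", out, "\n")
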