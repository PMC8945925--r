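#!/usr/bin/env Rscript
# PERCIST response assessment of the simulated patients: hottest-lesion
# delta-SUL category, target-lesion selection (<=5, <=2/organ), lesion
# matching across timepoints and summed burden changes.
# Requires 01_simulate_phantoms.R; outputs results/response/<pid>_report.json

suppressPackageStartupMessages(library(petburden))
pdir <- "results/phantoms"
out <- "results/response"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
liver_center <- c(40, 40, 40)

for (pid in c("A", "B")) {
  read_pair <- function(tp) list(
    volume = read_volume(file.path(pdir, sprintf("%s_%s_sul.nii.gz", pid, tp))),
    organs = read_volume(file.path(pdir, sprintf("%s_%s_organs.nii.gz", pid, tp)),
                         "labels"))
  res <- assess_patient(read_pair("baseline"), read_pair("followup"),
                        liver_center)
  p <- res$percist
  cat(sprintf(
    "patient %s: bSUL %.2f -> %s, dSUL %.1f%%%s => %s (%s); dsumMTV %.1f%%\n",
    pid, p$baseline_hottest_sul,
    ifelse(is.na(p$followup_hottest_sul), "resolved",
           sprintf("%.2f", p$followup_hottest_sul)),
    p$delta_sul_pct, if (p$new_lesion) ", new lesion" else "",
    p$category, if (p$responder) "MR" else "nMR",
    res$burden$dsum_mtv_pct))
  write_report(list(
    percist = list(bsul = p$baseline_hottest_sul,
                   delta_sul_pct = p$delta_sul_pct,
                   new_lesion = p$new_lesion,
                   category = p$category, responder = p$responder),
    burden = unclass(res$burden),
    n_targets = res$targets$n),
    file.path(out, sprintf("%s_report.json", pid)))
}
cat("response reports written to", out, "\n")
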