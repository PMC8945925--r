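#!/usr/bin/env Rscript
# Outcome analyses on the simulated cohorts, mirroring the study's
# statistics stage: diagnostic accuracy and odds ratio of metabolic
# response for 3-month non-progression, disease control rate, univariate
# group comparisons, KM/log-rank with the median-outward optimal-cutoff
# search for dCt, Cox multivariate models, and the dCt-burden correlation.
# Requires 04_simulate_cohort.R; outputs results/outcomes/*.csv|json

suppressPackageStartupMessages(library(petburden))
co <- read.csv("results/cohort_n30.csv")
big <- read.csv("results/cohort_n200.csv")
out <- "results/outcomes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## 3-month response prediction ---------------------------------------------
npd <- co$npd_3mo == "nPD"
mr <- co$percist_responder
tab <- two_by_two(tp = sum(mr & npd), fn = sum(!mr & npd),
                  fp = sum(mr & !npd), tn = sum(!mr & !npd))
metrics <- confusion_metrics(tab)
or <- tryCatch(odds_ratio(tab), error = function(e) odds_ratio(tab, haldane = TRUE))
dcr <- disease_control_rate(co$npd_3mo)
cat(sprintf("MR vs nPD(3mo): sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%, acc %.0f%%\n",
            metrics$sensitivity, metrics$specificity, metrics$ppv,
            metrics$npv, metrics$accuracy))
cat(sprintf("odds ratio %.1f (%.2f-%.3g); disease control rate %.0f%%\n",
            or$or, or$ci_low, or$ci_high, dcr))
chs <- chi_square(tab)
cat(sprintf("association test (%s): p = %.4f\n", chs$method, chs$p))

## univariate comparisons of continuous markers by 3-month outcome ----------
cont <- c("dct", "bsum_mtv", "dsum_mtv_pct", "cea", "age")
uni <- do.call(rbind, lapply(cont, function(v) {
  mwp <- mann_whitney(co[[v]][npd], co[[v]][!npd])
  data.frame(variable = v,
             median_npd = median(co[[v]][npd]),
             median_pd = median(co[[v]][!npd]),
             U = mwp$U, p = mwp$p)
}))
write.csv(uni, file.path(out, "univariate_npd.csv"), row.names = FALSE)

## survival: KM medians, optimal dCt cutoff, Cox models ---------------------
km_all <- km_fit(co$pfs_months, co$pfs_event)
cat(sprintf("median PFS %.1f months (95%% CI %.1f-%.1f)\n",
            km_all$median, km_all$ci_low, km_all$ci_high))

cut <- optimal_cutoff(co$dct, co$pfs_months, co$pfs_event)
cat(sprintf("optimal dCt cutoff for PFS: %.2f (log-rank p = %.4f); group medians %s\n",
            cut$cutoff, cut$p,
            paste(sprintf("%.1f", cut$medians), collapse = " vs ")))
write.csv(cut$trace, file.path(out, "dct_cutoff_trace.csv"), row.names = FALSE)

cox_pfs <- cox_fit(data.frame(dct_ge_cut = as.integer(co$dct >= cut$cutoff),
                              bsummtv_ge40 = as.integer(co$bsum_mtv >= 40)),
                   co$pfs_months, co$pfs_event)
cox_os <- cox_fit(data.frame(dct_ge_cut = as.integer(co$dct >= cut$cutoff),
                             dsummtv_ge_m60 = as.integer(co$dsum_mtv_pct >= -60)),
                  co$os_months, co$os_event)
cox_pfs$outcome <- "PFS"; cox_os$outcome <- "OS"
cox_tab <- rbind(cox_pfs, cox_os)
print(cox_tab, digits = 3)
write.csv(cox_tab, file.path(out, "cox_models.csv"), row.names = FALSE)

## correlation of mutant-allele burden marker with tumor burden -------------
sp <- spearman_cor(big$dct, big$bsum_mtv)
cat(sprintf("Spearman dCt vs bsumMTV (n=%d): rho = %.3f, p = %.2g\n",
            nrow(big), sp$rho, sp$p))

write_report(list(
  diagnostic = metrics, odds_ratio = or,
  disease_control_rate_pct = dcr,
  optimal_dct_cutoff = cut$cutoff,
  optimal_cutoff_logrank_p = cut$p,
  spearman_dct_bsummtv = sp$rho),
  file.path(out, "summary.json"))
cat("outcome tables written to", out, "\n")
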