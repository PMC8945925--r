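#' Specification of a simulated outcome cohort
#'
#' Describes a cohort with known statistical structure linking the EGFR
#' mutant-allele marker (dCt, cycles), baseline metabolic tumor burden,
#' PERCIST response, the 3-month CT outcome, and proportional-hazards
#' survival. The defaults are the study conditions the package's analyses
#' are exercised under: 30 patients, median dCt near the prognostic
#' boundary of 6 cycles, median baseline sumMTV near 40 cm^3, a 70%
#' metabolic-responder rate, log hazard ratios of ln(4.85) (dCt >= 6) and
#' ln(5.60) (bsumMTV >= 40) on PFS and ln(9.84) / ln(13.1) (dCt >= 6,
#' DsumMTV >= -60%) on OS, exponential baseline hazards with medians 12 and
#' 25.3 months, uniform independent censoring on a 33-month horizon, and a
#' logistic 3-month non-progression model whose responder odds ratio is 25.
#'
#' @param n number of patients (`>= 2`).
#' @param dct_mean,dct_sd normal distribution of dCt (cycles).
#' @param burden_link coefficient coupling dCt to log baseline sumMTV
#'   (positive = higher dCt, larger burden).
#' @param burden_log_sd residual SD of log baseline sumMTV.
#' @param burden_median_cm3 median baseline sumMTV (cm^3).
#' @param responder_prob probability of metabolic response (MR).
#' @param dsum_mtv_mr,dsum_mtv_nmr mean and SD (length-2 vectors) of
#'   DsumMTV (%) for responders and non-responders.
#' @param hr_pfs,hr_os named log-hazard coefficient vectors for the PFS and
#'   OS models; recognized predictor names: `dct_ge6`, `bsummtv_ge40`,
#'   `dsummtv_ge_m60`, `responder`.
#' @param median_pfs_months,median_os_months baseline (all-predictors-zero)
#'   exponential medians; the rate is `log(2) / median`.
#' @param weibull_shape shape of the event-time distribution (1 =
#'   exponential, the default).
#' @param censoring_horizon_months independent uniform censoring on
#'   `[0, horizon]`.
#' @param response_intercept,response_coef logistic model for the 3-month
#'   non-progression label: `logit P(nPD) = intercept + coef * responder`.
#' @param rng_seed integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n = 30L,
                            dct_mean = 5, dct_sd = 2,
                            burden_link = 0.25,
                            burden_log_sd = 0.9,
                            burden_median_cm3 = 40,
                            responder_prob = 0.7,
                            dsum_mtv_mr = c(-75, 20),
                            dsum_mtv_nmr = c(-20, 35),
                            hr_pfs = c(dct_ge6 = log(4.85),
                                       bsummtv_ge40 = log(5.60)),
                            hr_os = c(dct_ge6 = log(9.84),
                                      dsummtv_ge_m60 = log(13.1)),
                            median_pfs_months = 12,
                            median_os_months = 25.3,
                            weibull_shape = 1,
                            censoring_horizon_months = 33,
                            response_intercept = stats::qlogis(4 / 9),
                            response_coef = log(25),
                            rng_seed = 1L) {
  stopifnot(n >= 2, dct_sd >= 0, censoring_horizon_months > 0,
            median_pfs_months > 0, median_os_months > 0, weibull_shape > 0)
  structure(list(n = as.integer(n), dct_mean = dct_mean, dct_sd = dct_sd,
                 burden_link = burden_link, burden_log_sd = burden_log_sd,
                 burden_median_cm3 = burden_median_cm3,
                 responder_prob = responder_prob,
                 dsum_mtv_mr = dsum_mtv_mr, dsum_mtv_nmr = dsum_mtv_nmr,
                 hr_pfs = hr_pfs, hr_os = hr_os,
                 median_pfs_months = median_pfs_months,
                 median_os_months = median_os_months,
                 weibull_shape = weibull_shape,
                 censoring_horizon_months = censoring_horizon_months,
                 response_intercept = response_intercept,
                 response_coef = response_coef,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_sim_spec")
}

# Event times from a proportional-hazards Weibull model: with shape k and
# baseline scale chosen so the baseline median is as specified,
# S(t) = exp(-(lambda0 t)^k * exp(lp)) and inversion gives
# t = (-log(U))^(1/k) * exp(-lp/k) / lambda0.
ph_event_times <- function(n, lp, median_months, shape) {
  lambda0 <- log(2)^(1 / shape) / median_months
  u <- stats::runif(n)
  (-log(u))^(1 / shape) * exp(-lp / shape) / lambda0
}

#' Simulate an outcome cohort with known generative parameters
#'
#' Per patient: dCt is drawn from its normal distribution; log baseline
#' sumMTV is centered on `log(burden_median_cm3)` plus
#' `burden_link * (dCt - dct_mean)` plus noise, so a positive `burden_link`
#' induces a positive Spearman correlation between dCt and burden; PERCIST
#' responder status is Bernoulli; DsumMTV is drawn per responder status
#' (clamped at -100%); PFS and OS times come from the proportional-hazards
#' model over the dichotomized predictors (dCt >= 6, bsumMTV >= 40 cm^3,
#' DsumMTV >= -60%); censoring is independent uniform on the horizon; the
#' 3-month RECIST label is drawn from the logistic non-progression model
#' (non-progressors are mostly PR). Deterministic given `rng_seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return List with `cohort` (data.frame, one row per patient) and
#'   `true_parameters` (the generative coefficients and rates).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n
    age <- round(stats::rnorm(n, 70, 10))
    sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4))
    smoking <- sample(c("never", "ever"), n, replace = TRUE, prob = c(0.73, 0.27))
    cea <- exp(stats::rnorm(n, log(7), 1.3))
    classical_mutation <- stats::runif(n) < 0.83
    dct <- stats::rnorm(n, spec$dct_mean, spec$dct_sd)
    bsum_mtv <- exp(log(spec$burden_median_cm3) +
                      spec$burden_link * (dct - spec$dct_mean) +
                      stats::rnorm(n, 0, spec$burden_log_sd))
    responder <- stats::runif(n) < spec$responder_prob
    dsum_mtv <- ifelse(responder,
                       stats::rnorm(n, spec$dsum_mtv_mr[1], spec$dsum_mtv_mr[2]),
                       stats::rnorm(n, spec$dsum_mtv_nmr[1], spec$dsum_mtv_nmr[2]))
    dsum_mtv <- pmax(dsum_mtv, -100)

    preds <- data.frame(dct_ge6 = as.integer(dct >= 6),
                        bsummtv_ge40 = as.integer(bsum_mtv >= 40),
                        dsummtv_ge_m60 = as.integer(dsum_mtv >= -60),
                        responder = as.integer(responder))
    lp_of <- function(coefs) {
      if (!length(coefs)) return(rep(0, n))
      unknown <- setdiff(names(coefs), names(preds))
      if (length(unknown)) stop("unknown predictor(s): ",
                                paste(unknown, collapse = ", "))
      as.vector(as.matrix(preds[names(coefs)]) %*% coefs)
    }
    t_pfs <- ph_event_times(n, lp_of(spec$hr_pfs),
                            spec$median_pfs_months, spec$weibull_shape)
    t_os <- ph_event_times(n, lp_of(spec$hr_os),
                           spec$median_os_months, spec$weibull_shape)
    c_pfs <- stats::runif(n, 0, spec$censoring_horizon_months)
    c_os <- stats::runif(n, 0, spec$censoring_horizon_months)

    p_npd <- stats::plogis(spec$response_intercept +
                             spec$response_coef * as.integer(responder))
    npd <- stats::runif(n) < p_npd
    recist_3mo <- ifelse(npd,
                         sample(c("PR", "SD"), n, replace = TRUE,
                                prob = c(23 / 24, 1 / 24)),
                         "PD")

    cohort <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age, sex = sex, smoking = smoking, cea = cea,
      classical_mutation = classical_mutation,
      dct = dct, bsum_mtv = bsum_mtv,
      percist_responder = responder, dsum_mtv_pct = dsum_mtv,
      recist_3mo = recist_3mo,
      npd_3mo = dichotomize_recist(recist_3mo),
      pfs_months = pmin(t_pfs, c_pfs), pfs_event = as.integer(t_pfs <= c_pfs),
      os_months = pmin(t_os, c_os), os_event = as.integer(t_os <= c_os))
    list(cohort = cohort,
         true_parameters = list(
           hr_pfs = spec$hr_pfs, hr_os = spec$hr_os,
           burden_link = spec$burden_link,
           baseline_median_pfs = spec$median_pfs_months,
           baseline_median_os = spec$median_os_months,
           response_intercept = spec$response_intercept,
           response_coef = spec$response_coef))
  })
}
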