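#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimator; the median is the first time at which the
#' survival curve drops to 0.5 or below, with the inverted-confidence-band
#' (Brookmeyer-Crowley style) 95% CI as computed by
#' [survival::survfit()]. With every observation censored the median is
#' undefined (`NA`).
#'
#' @param times non-negative event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group optional grouping factor for stratified curves.
#' @return A `km_fit` list: `fit` (the survfit object), `median`,
#'   `ci_low`, `ci_high` (per group when `group` is given).
#' @export
km_fit <- function(times, events, group = NULL) {
  stopifnot(all(times >= 0))
  events <- as.integer(events)
  # median = first event time with S(t) <= 0.5 (undefined if never reached)
  first_half <- function(f) {
    i <- which(f$surv <= 0.5 + 1e-12)
    if (length(i)) f$time[i[1]] else NA_real_
  }
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    tab <- summary(fit)$table
    med <- first_half(fit)
    lo <- unname(tab["0.95LCL"]); hi <- unname(tab["0.95UCL"])
  } else {
    g <- as.factor(group)
    fit <- survival::survfit(survival::Surv(times, events) ~ g)
    tab <- summary(fit)$table
    ns <- fit$strata
    idx <- rep(seq_along(ns), ns)
    med <- vapply(seq_along(ns), function(k) {
      first_half(list(surv = fit$surv[idx == k], time = fit$time[idx == k]))
    }, numeric(1))
    names(med) <- names(ns)
    lo <- tab[, "0.95LCL"]; hi <- tab[, "0.95UCL"]
  }
  structure(list(fit = fit, median = med, ci_low = lo, ci_high = hi),
            class = "km_fit")
}

#' Log-rank test between two (or more) groups
#'
#' @param times,events as in [km_fit()].
#' @param group grouping vector with at least two levels.
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(g) < 2) stop("log-rank needs at least two groups")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ g)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median-outward optimal cutoff by log-rank significance
#'
#' Dichotomizes a continuous marker at every distinct observed value,
#' starting from the median and stepping alternately to the next distinct
#' value above and below it, and keeps the cutoff with the most significant
#' log-rank p value. Groups are `< cutoff` vs `>= cutoff`; a candidate is
#' eligible only if both groups hold at least `min_group` of the cohort
#' (floor against degenerate one-patient groups). Ties in p keep the
#' candidate reached earliest, i.e. closest to the median. The full search
#' trace is returned.
#'
#' @param values continuous marker, at least 2 distinct values.
#' @param times,events survival outcome.
#' @param min_group minimum group size as a fraction of `n` (default 0.15).
#' @return A `cutoff_result`: `cutoff`, `p`, `chisq`, `medians` (per-group
#'   KM medians), `trace` (data.frame in search order: `cutoff`, `n_low`,
#'   `n_high`, `eligible`, `p`).
#' @export
optimal_cutoff <- function(values, times, events, min_group = 0.15) {
  stopifnot(length(values) == length(times))
  cand <- sort(unique(values))
  if (length(cand) < 2) stop("need at least 2 distinct marker values")
  n <- length(values)
  floor_n <- ceiling(min_group * n)
  # search order: median-closest candidate first, then alternately outward
  start <- which.min(abs(cand - stats::median(values)))
  lo <- start - 1L; hi <- start + 1L
  order_idx <- start
  up <- TRUE
  while (lo >= 1L || hi <= length(cand)) {
    if (up && hi <= length(cand)) { order_idx <- c(order_idx, hi); hi <- hi + 1L }
    else if (!up && lo >= 1L)     { order_idx <- c(order_idx, lo); lo <- lo - 1L }
    up <- !up
  }
  trace <- data.frame(cutoff = cand[order_idx], n_low = NA_integer_,
                      n_high = NA_integer_, eligible = FALSE, p = NA_real_)
  best <- NULL
  for (r in seq_len(nrow(trace))) {
    cc <- trace$cutoff[r]
    g <- values >= cc
    trace$n_low[r] <- sum(!g); trace$n_high[r] <- sum(g)
    if (min(trace$n_low[r], trace$n_high[r]) < floor_n) next
    trace$eligible[r] <- TRUE
    lr <- log_rank(times, events, g)
    trace$p[r] <- lr$p
    if (is.null(best) || lr$p < best$p) {
      best <- list(cutoff = cc, p = lr$p, chisq = lr$chisq)
    }
  }
  if (is.null(best)) stop("no cutoff satisfies the minimum group-size floor")
  g <- factor(ifelse(values >= best$cutoff, "high", "low"),
              levels = c("low", "high"))
  km <- km_fit(times, events, g)
  structure(c(best, list(medians = km$median, trace = trace)),
            class = "cutoff_result")
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' confidence intervals. Constant covariates, non-convergence and monotone
#' likelihood (infinite coefficients) raise explicit errors.
#'
#' @param covariates data.frame of covariates (numeric or factor).
#' @param times,events survival outcome.
#' @return Data.frame with one row per coefficient: `term`, `coef`, `hr`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  }
  if (sum(events) < ncol(covariates) + 1) {
    stop("too few events for the number of covariates")
  }
  dat <- cbind(covariates, .time = times, .event = as.integer(events))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged before",
                conditionMessage(w))) {
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$conf.int[, "exp(coef)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL)
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood binomial GLM; odds ratios with Wald confidence
#' intervals. Perfect separation raises an explicit error instead of
#' returning a silently divergent fit.
#'
#' @param covariates data.frame of covariates.
#' @param labels binary outcome (logical, 0/1, or two-level factor).
#' @return Data.frame with `term`, `coef`, `or`, `ci_low`, `ci_high`, `p`
#'   (intercept excluded).
#' @export
logistic_fit <- function(covariates, labels) {
  covariates <- as.data.frame(covariates)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  dat <- cbind(covariates, .y = y)
  fml <- stats::as.formula(paste(".y ~", paste(names(covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        stop("logistic fit failed (separation or non-convergence): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)[-1]) > 15)) {
    stop("logistic fit failed: coefficient diverging (quasi-separation)")
  }
  s <- summary(fit)$coefficients
  s <- s[-1, , drop = FALSE]  # drop intercept
  z <- stats::qnorm(0.975)
  data.frame(term = rownames(s),
             coef = s[, "Estimate"],
             or = exp(s[, "Estimate"]),
             ci_low = exp(s[, "Estimate"] - z * s[, "Std. Error"]),
             ci_high = exp(s[, "Estimate"] + z * s[, "Std. Error"]),
             p = s[, "Pr(>|z|)"],
             row.names = NULL)
}

#' ROC curve with Youden-optimal cutoff
#'
#' AUC and the Youden-index cutoff (maximizing sensitivity + specificity -
#' 1) for a continuous score against a binary condition; higher scores are
#' taken to indicate the positive condition. The AUC satisfies the
#' Mann-Whitney identity `AUC = U / (n1 * n0)`.
#'
#' @param scores continuous predictor.
#' @param labels binary condition (logical or 0/1; 1 = positive).
#' @return List with `auc`, `cutoff`, `sensitivity`, `specificity` (the
#'   latter two at the chosen cutoff, as percentages).
#' @export
roc_cutoff <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) != 2) stop("labels must have exactly two levels")
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]  # ties in Youden: first reported cutoff
  list(auc = as.numeric(pROC::auc(r)),
       cutoff = best$threshold,
       sensitivity = 100 * best$sensitivity,
       specificity = 100 * best$specificity)
}
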