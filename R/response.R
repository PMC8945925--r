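#' Percentage change from baseline
#'
#' `100 * (followup - baseline) / baseline`. Percentages are carried at full
#' precision; rounding (1 decimal) happens only at report serialization.
#'
#' @param baseline positive scalar.
#' @param followup non-negative scalar.
#' @return Percent change.
#' @export
#' @examples
#' delta_percent(10.7, 4.10)  # -61.7
delta_percent <- function(baseline, followup) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  if (any(followup < 0)) stop("followup must be non-negative")
  100 * (followup - baseline) / baseline
}

#' PERCIST 1.0 response category from the hottest lesions
#'
#' The hottest measurable lesion is identified independently on each scan
#' (it need not be the same lesion). With `dsul = delta_percent(baseline,
#' followup)`, the category is assigned with precedence:
#' * PMD if a new lesion has appeared, or if `dsul > +30`;
#' * CMR if no measurable lesion remains on follow-up (complete resolution
#'   of tumor uptake);
#' * PMR if `dsul <= -30`;
#' * SMD otherwise.
#' Metabolic responders (MR) are CMR or PMR; non-responders (nMR) are SMD or
#' PMD. Boundaries follow the rule text exactly: -30% is PMR, +30% is SMD.
#'
#' With `strict_percist = TRUE` the PERCIST 1.0 absolute-change condition is
#' added: PMR additionally requires a drop of at least 0.8 SUL units and PMD
#' (by uptake increase) a rise of at least 0.8; the default applies the
#' percentage-only rules.
#'
#' @param baseline_hottest_sul SUL_max of the hottest baseline lesion (bSUL).
#' @param followup_hottest_sul SUL_max of the hottest measurable follow-up
#'   lesion, or `NA` if none is measurable.
#' @param new_lesion has any new lesion developed?
#' @param strict_percist add the 0.8-SUL absolute-change requirement.
#' @return A `percist_assessment`: list with `baseline_hottest_sul`,
#'   `followup_hottest_sul`, `delta_sul_pct`, `new_lesion`, `category`
#'   (CMR/PMR/SMD/PMD), `responder`.
#' @export
classify_percist <- function(baseline_hottest_sul, followup_hottest_sul,
                             new_lesion = FALSE, strict_percist = FALSE) {
  if (is.na(baseline_hottest_sul)) stop("baseline hottest SUL is missing")
  if (baseline_hottest_sul <= 0) stop("baseline hottest SUL must be positive")
  fu_absent <- is.na(followup_hottest_sul)
  dsul <- if (fu_absent) -100 else
    delta_percent(baseline_hottest_sul, followup_hottest_sul)
  abs_change <- if (fu_absent) baseline_hottest_sul else
    abs(followup_hottest_sul - baseline_hottest_sul)
  pmd_rise <- !fu_absent && dsul > 30 &&
    (!strict_percist || abs_change >= 0.8)
  category <-
    if (new_lesion || pmd_rise) "PMD"
    else if (fu_absent) "CMR"
    else if (dsul <= -30 && (!strict_percist || abs_change >= 0.8)) "PMR"
    else "SMD"
  structure(list(baseline_hottest_sul = baseline_hottest_sul,
                 followup_hottest_sul = if (fu_absent) NA_real_ else followup_hottest_sul,
                 delta_sul_pct = dsul,
                 new_lesion = isTRUE(new_lesion),
                 category = category,
                 responder = category %in% c("CMR", "PMR")),
            class = "percist_assessment")
}

#' @export
print.percist_assessment <- function(x, ...) {
  cat(sprintf("<percist> bSUL %.2f -> %s, dSUL %.1f%%%s: %s (%s)\n",
              x$baseline_hottest_sul,
              ifelse(is.na(x$followup_hottest_sul), "resolved",
                     sprintf("%.2f", x$followup_hottest_sul)),
              x$delta_sul_pct,
              if (x$new_lesion) ", new lesion" else "",
              x$category, if (x$responder) "MR" else "nMR"))
  invisible(x)
}

#' Summed tumor-burden metrics and their percentage changes
#'
#' Baseline sums (bsumSUL, bsumMTV, bsumTLG) come from the baseline target
#' set; the Delta-sum percentages (DsumSUL, DsumMTV, DsumTLG) are
#' [delta_percent()] of each sum, with resolved lesions contributing zero to
#' the follow-up sums (the follow-up set is the matched one, see
#' [matched_target_set()]).
#'
#' @param baseline baseline [select_targets()] result (non-empty).
#' @param followup_matched follow-up `target_set` over the matched lesions.
#' @return A `burden_summary` list: `bsum_sul`, `bsum_mtv`, `bsum_tlg`,
#'   `dsum_sul_pct`, `dsum_mtv_pct`, `dsum_tlg_pct`.
#' @export
summarize_burden <- function(baseline, followup_matched) {
  stopifnot(inherits(baseline, "target_set"),
            inherits(followup_matched, "target_set"))
  if (baseline$n == 0L) stop("baseline target set is empty")
  structure(list(
    bsum_sul = baseline$sum_sul,
    bsum_mtv = baseline$sum_mtv,
    bsum_tlg = baseline$sum_tlg,
    dsum_sul_pct = delta_percent(baseline$sum_sul, followup_matched$sum_sul),
    dsum_mtv_pct = delta_percent(baseline$sum_mtv, followup_matched$sum_mtv),
    dsum_tlg_pct = delta_percent(baseline$sum_tlg, followup_matched$sum_tlg)),
    class = "burden_summary")
}

#' Dichotomize a RECIST 1.1 label into progression vs non-progression
#'
#' CR, PR and SD collapse to non-progressive disease (`"nPD"`); PD stays
#' `"PD"`. This is the 3-month CT outcome the PET metrics are asked to
#' predict.
#'
#' @param recist_label character vector with values in CR/PR/SD/PD.
#' @return Character vector with values `"nPD"` or `"PD"`.
#' @export
dichotomize_recist <- function(recist_label) {
  bad <- setdiff(unique(recist_label), c("CR", "PR", "SD", "PD"))
  if (length(bad)) stop("unknown RECIST label(s): ", paste(bad, collapse = ", "))
  ifelse(recist_label == "PD", "PD", "nPD")
}
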