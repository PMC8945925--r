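#' Lean body mass
#'
#' Default is the Janmahasatian estimate, the usual choice in PERCIST-style
#' SUL normalization; the James formula is available as an alternative.
#' Janmahasatian: male `9270 W / (6680 + 216 BMI)`, female
#' `9270 W / (8780 + 244 BMI)` with `BMI = W / height_m^2`.
#' James: male `1.1 W - 128 (W/H_cm)^2`, female `1.07 W - 148 (W/H_cm)^2`.
#'
#' @param weight_kg body weight in kg, `> 0`.
#' @param height_cm height in cm, `> 0`.
#' @param sex `"male"` or `"female"`.
#' @param formula `"janmahasatian"` (default) or `"james"`.
#' @return Lean body mass in kg.
#' @export
#' @examples
#' lean_body_mass(80, 180, "male")   # ~61.8 kg
lean_body_mass <- function(weight_kg, height_cm, sex = c("male", "female"),
                           formula = c("janmahasatian", "james")) {
  sex <- match.arg(sex)
  formula <- match.arg(formula)
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  if (formula == "janmahasatian") {
    bmi <- weight_kg / (height_cm / 100)^2
    if (sex == "male") 9270 * weight_kg / (6680 + 216 * bmi)
    else               9270 * weight_kg / (8780 + 244 * bmi)
  } else {
    r <- weight_kg / height_cm
    if (sex == "male") 1.10 * weight_kg - 128 * r^2
    else               1.07 * weight_kg - 148 * r^2
  }
}

#' Scan session metadata for SUL conversion
#'
#' @param injected_dose_mbq injected FDG dose in MBq, `> 0`.
#' @param body_weight_kg,height_cm,sex anthropometrics for lean body mass.
#' @param uptake_time_min uptake time in minutes (metadata only; decay
#'   correction is assumed already applied to the activity map).
#' @param lbm_formula passed to [lean_body_mass()].
#' @return A `scan_session` list including the derived `lbm_kg`.
#' @export
scan_session <- function(injected_dose_mbq, body_weight_kg, height_cm,
                         sex = c("male", "female"), uptake_time_min = 60,
                         lbm_formula = c("janmahasatian", "james")) {
  sex <- match.arg(sex)
  if (injected_dose_mbq <= 0) stop("injected dose must be positive")
  lbm <- lean_body_mass(body_weight_kg, height_cm, sex, lbm_formula)
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg, height_cm = height_cm,
                 sex = sex, uptake_time_min = uptake_time_min,
                 lbm_kg = lbm),
            class = "scan_session")
}

#' Convert an activity-concentration volume to SUL
#'
#' `SUL = activity [MBq/g] / (injected dose [MBq] / lean body mass [g])`,
#' i.e. every voxel is scaled by `LBM[g] / dose[MBq]`. The map is linear, so
#' doubling the dose halves every SUL value.
#'
#' @param activity a 3-D array of activity concentration in MBq/g, or a
#'   [sul_volume()]-shaped list whose `values` are activity.
#' @param session a [scan_session()].
#' @param spacing voxel spacing in mm (required when `activity` is a bare
#'   array).
#' @return A [sul_volume()].
#' @export
activity_to_sul <- function(activity, session, spacing = NULL) {
  stopifnot(inherits(session, "scan_session"))
  if (inherits(activity, "sul_volume")) {
    arr <- activity$values; spacing <- activity$spacing
  } else {
    arr <- activity
    if (is.null(spacing)) stop("spacing is required for a bare activity array")
  }
  if (any(arr < 0)) stop("activity concentrations must be non-negative")
  scale <- (session$lbm_kg * 1000) / session$injected_dose_mbq  # g / MBq
  sul_volume(arr * scale, spacing)
}

#' Liver background from a spherical ROI
#'
#' Mean and sample (n-1) standard deviation of SUL over the voxels whose
#' centers lie in a sphere (default 3 cm diameter) placed in normal liver.
#' If the liver carries metastases the caller supplies an exclusion mask and
#' must re-site the ROI so the sphere avoids it.
#'
#' @param vol a [sul_volume()].
#' @param center mm coordinates of the ROI center.
#' @param diameter_mm ROI diameter in mm (default 30).
#' @param exclusion optional logical array (same grid) of voxels the ROI must
#'   not intersect, e.g. segmented liver metastases.
#' @return A `liver_background` list with `mean_sul`, `sd_sul`, `n_voxels`,
#'   `roi_center`, `roi_diameter_mm`.
#' @export
liver_background <- function(vol, center, diameter_mm = 30, exclusion = NULL) {
  stopifnot(inherits(vol, "sul_volume"), length(center) == 3L, diameter_mm > 0)
  dims <- dim(vol$values)
  r <- diameter_mm / 2
  extent <- dims * vol$spacing
  if (any(center - r < 0) || any(center + r > extent)) {
    stop("liver ROI sphere extends outside the volume")
  }
  mask <- ellipsoid_mask(dims, vol$spacing, center, rep(r, 3L))$mask
  if (!is.null(exclusion)) {
    stopifnot(identical(dim(exclusion), dims))
    if (any(mask & exclusion)) {
      stop("liver ROI intersects the exclusion mask; re-site the ROI")
    }
  }
  v <- vol$values[mask]
  if (length(v) < 2L) stop("liver ROI contains fewer than 2 voxels")
  structure(list(mean_sul = mean(v), sd_sul = stats::sd(v),
                 n_voxels = length(v), roi_center = as.numeric(center),
                 roi_diameter_mm = diameter_mm),
            class = "liver_background")
}

#' Measurability threshold for lesions
#'
#' A lesion is measurable when its SUL_max is at least 1.5-fold the liver
#' mean SUL plus twice the liver standard deviation: `1.5*mu + 2*sigma`
#' (the PERCIST 1.0 reading). The alternative grouping `1.5*(mu + 2*sigma)`
#' is available for sensitivity analyses.
#'
#' @param bg a [liver_background()].
#' @param parse `"percist"` (default, `1.5*mu + 2*sigma`) or `"grouped"`
#'   (`1.5*(mu + 2*sigma)`).
#' @return Threshold SUL.
#' @export
measurability_threshold <- function(bg, parse = c("percist", "grouped")) {
  parse <- match.arg(parse)
  stopifnot(inherits(bg, "liver_background"))
  if (parse == "percist") 1.5 * bg$mean_sul + 2 * bg$sd_sul
  else 1.5 * (bg$mean_sul + 2 * bg$sd_sul)
}

#' Segmentation threshold for lesion VOIs
#'
#' Lower bound of the lesion volumes of interest: two standard deviations
#' above the liver mean SUL, `mu + 2*sigma`.
#'
#' @param bg a [liver_background()].
#' @return Threshold SUL.
#' @export
segmentation_threshold <- function(bg) {
  stopifnot(inherits(bg, "liver_background"))
  bg$mean_sul + 2 * bg$sd_sul
}
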