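#' Pipeline configuration
#'
#' Bundles every tunable threshold of the image-to-response pipeline with
#' the phantom/cohort seeds, so a whole run is reproducible from one
#' object. Serializes round-trip stable to JSON.
#'
#' @param measurability_parse `"percist"` or `"grouped"`
#'   (see [measurability_threshold()]).
#' @param strict_percist add PERCIST's 0.8-SUL absolute-change requirement.
#' @param match_radius_mm lesion matching radius (mm).
#' @param min_group_fraction group-size floor of [optimal_cutoff()].
#' @param lbm_formula lean-body-mass formula.
#' @param liver_roi_diameter_mm liver background ROI diameter.
#' @param exclude_labels physiologic-uptake organ labels to exclude.
#' @param seed integer seed for the synthetic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(measurability_parse = "percist",
                            strict_percist = FALSE,
                            match_radius_mm = 20,
                            min_group_fraction = 0.15,
                            lbm_formula = "janmahasatian",
                            liver_roi_diameter_mm = 30,
                            exclude_labels = integer(0),
                            seed = 1L) {
  structure(list(measurability_parse = measurability_parse,
                 strict_percist = strict_percist,
                 match_radius_mm = match_radius_mm,
                 min_group_fraction = min_group_fraction,
                 lbm_formula = lbm_formula,
                 liver_roi_diameter_mm = liver_roi_diameter_mm,
                 exclude_labels = as.integer(exclude_labels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

round_for_report <- function(x, digits_pct = 1, digits_sul = 2) {
  walk <- function(v, name) {
    if (is.list(v)) {
      for (k in seq_along(v)) v[[k]] <- walk(v[[k]], names(v)[k] %||% "")
      v
    } else if (is.numeric(v)) {
      if (grepl("pct|percent|rate", name)) round(v, digits_pct)
      else round(v, digits_sul)
    } else v
  }
  walk(x, "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results report as JSON
#'
#' Keys keep their insertion order; a package version stamp is added.
#' Percentages are rounded to 1 decimal and other numeric values to 2
#' decimals at serialization only -- the in-memory objects keep full
#' precision. Re-serializing a written report is idempotent.
#'
#' @param results named list of results.
#' @param path output path (`.json`).
#' @param digits_pct,digits_sul rounding applied at serialization.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, digits_pct = 1, digits_sul = 2) {
  out <- c(list(generator = "petburden",
                version = as.character(utils::packageVersion("petburden"))),
           round_for_report(results, digits_pct, digits_sul))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Assess one patient's paired scans
#'
#' The per-patient core of the pipeline: liver background on the baseline
#' scan, lesion segmentation on both scans with the baseline thresholds,
#' hottest-lesion PERCIST classification (with new-lesion detection via
#' matching), target selection, and summed burden metrics.
#'
#' @param baseline,followup lists with `volume` and `organs` (as returned
#'   by [make_phantom()] / [make_followup()], or read from NIfTI).
#' @param liver_center mm coordinates of the liver background ROI.
#' @param config a [pipeline_config()].
#' @return List with `liver`, `baseline_lesions`, `followup_lesions`,
#'   `targets`, `correspondence`, `percist` ([classify_percist()] result)
#'   and `burden` ([summarize_burden()] result, `NULL` if no baseline
#'   target lesion).
#' @export
assess_patient <- function(baseline, followup, liver_center,
                           config = pipeline_config()) {
  bg <- liver_background(baseline$volume, liver_center,
                         config$liver_roi_diameter_mm)
  bl <- find_lesions(baseline$volume, baseline$organs, bg,
                     exclude_labels = config$exclude_labels,
                     measurability_parse = config$measurability_parse)
  fl <- find_lesions(followup$volume, followup$organs, bg,
                     exclude_labels = config$exclude_labels,
                     measurability_parse = config$measurability_parse)
  if (nrow(bl) == 0L) stop("no measurable baseline lesion")
  targets <- select_targets(bl)
  corr <- match_lesions(targets, fl, radius_mm = config$match_radius_mm)
  new_les <- detect_new_lesions(corr)
  b_hot <- hottest_lesion(bl)
  f_hot_sul <- if (nrow(fl)) hottest_lesion(fl)$sul_max else NA_real_
  percist <- classify_percist(b_hot$sul_max, f_hot_sul,
                              new_lesion = new_les$new_lesion,
                              strict_percist = config$strict_percist)
  fu_set <- matched_target_set(targets, fl, corr)
  burden <- summarize_burden(targets, fu_set)
  list(liver = bg, baseline_lesions = bl, followup_lesions = fl,
       targets = targets, correspondence = corr,
       percist = percist, burden = burden)
}

#' Run the demonstration pipeline end to end
#'
#' Generates a baseline/follow-up phantom pair, quantifies and classifies
#' it, and writes the per-patient report plus lesion tables. Intended both
#' as a smoke test and as the template the analysis scripts follow. The
#' run is fully deterministic given the config seed.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param phantom optional [phantom_spec()]; default is a two-lesion demo
#'   phantom with a partial-response follow-up.
#' @param followup optional [followup_spec()] paired with `phantom`.
#' @return Invisibly, the [assess_patient()] result; side effects: writes
#'   `report.json`, `baseline_lesions.csv`, `followup_lesions.csv` under
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         phantom = NULL, followup = NULL) {
  if (is.null(phantom)) {
    phantom <- phantom_spec(
      lesions = list(
        lesion_spec(center = c(40, 40, 96), radii = 11, peak_sul = 10.7,
                    organ_label = 2L, id = "pleura"),
        lesion_spec(center = c(88, 80, 60), radii = 8, peak_sul = 6.2,
                    organ_label = 3L, id = "lung")),
      noise_sd = 0.05, rng_seed = config$seed)
  }
  if (is.null(followup)) {
    followup <- followup_spec(factors = c(pleura = 0.38, lung = 0.55),
                              rng_seed = config$seed + 1L)
  }
  base <- make_phantom(phantom)
  fu <- make_followup(phantom, followup)
  res <- assess_patient(base, fu, liver_center = phantom$liver_center, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drop_vox <- function(df) df[, setdiff(names(df), "voxels"), drop = FALSE]
  utils::write.csv(drop_vox(res$baseline_lesions),
                   file.path(out_dir, "baseline_lesions.csv"), row.names = FALSE)
  utils::write.csv(drop_vox(res$followup_lesions),
                   file.path(out_dir, "followup_lesions.csv"), row.names = FALSE)
  report <- list(
    thresholds = list(
      liver_mean_sul = res$liver$mean_sul,
      liver_sd_sul = res$liver$sd_sul,
      segmentation_threshold = segmentation_threshold(res$liver),
      measurability_threshold = measurability_threshold(
        res$liver, config$measurability_parse)),
    percist = list(
      bsul = res$percist$baseline_hottest_sul,
      followup_sul = res$percist$followup_hottest_sul,
      delta_sul_pct = res$percist$delta_sul_pct,
      new_lesion = res$percist$new_lesion,
      category = res$percist$category,
      responder = res$percist$responder),
    burden = unclass(res$burden))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(res)
}
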