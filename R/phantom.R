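#' Specification of a synthetic SUL phantom
#'
#' Describes a 3-D SUL phantom: uniform background activity, a spherical
#' liver region with its own mean and standard deviation (the background ROI
#' of the PERCIST workflow is placed inside it), and a set of ellipsoidal
#' lesions with known peak SUL. The phantom is the ground-truth substrate on
#' which segmentation and response metrics are validated.
#'
#' @param grid_shape integer length-3, voxel counts per axis.
#' @param voxel_spacing mm per axis (scalar or length-3), `> 0`.
#' @param background_sul scalar background SUL.
#' @param noise_sd standard deviation of additive Gaussian noise (SUL units),
#'   truncated so SUL stays `>= 0`; `0` gives a noiseless phantom.
#' @param liver_center,liver_radius_mm,liver_mean,liver_sd spherical liver
#'   region: center (mm), radius (mm), and the normal distribution its voxel
#'   values are drawn from (`liver_sd = 0` gives a uniform liver).
#' @param lesions list of [lesion_spec()] objects.
#' @param liver_label integer label used for the liver in the organ map.
#' @param lesion_profile `"plateau"` (uniform SUL at `peak_sul` inside the
#'   ellipsoid; makes SUL_mean and TLG analytically checkable) or
#'   `"gaussian"` (SUL falls to half the peak at the ellipsoid boundary).
#' @param rng_seed integer seed; identical seeds give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = 2,
                         background_sul = 0.5,
                         noise_sd = 0,
                         liver_center = c(40, 40, 40),
                         liver_radius_mm = 25,
                         liver_mean = 2.2,
                         liver_sd = 0.3,
                         lesions = list(),
                         liver_label = 1L,
                         lesion_profile = c("plateau", "gaussian"),
                         rng_seed = 1L) {
  lesion_profile <- match.arg(lesion_profile)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            all(voxel_spacing > 0), noise_sd >= 0, liver_sd >= 0,
            background_sul >= 0, liver_radius_mm > 0)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing = voxel_spacing,
               background_sul = background_sul, noise_sd = noise_sd,
               liver_center = liver_center, liver_radius_mm = liver_radius_mm,
               liver_mean = liver_mean, liver_sd = liver_sd,
               lesions = lesions, liver_label = as.integer(liver_label),
               lesion_profile = lesion_profile,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Specification of one ellipsoidal lesion
#'
#' @param center mm coordinates of the ellipsoid center (length 3).
#' @param radii mm semi-axes (scalar for a sphere, or length 3).
#' @param peak_sul peak SUL of the lesion, `> 0`.
#' @param organ_label integer organ label the lesion belongs to.
#' @param id token identifying the lesion in ground truth.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radii, peak_sul, organ_label, id) {
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  stopifnot(length(center) == 3L, length(radii) == 3L,
            all(radii > 0), peak_sul > 0)
  structure(list(center = as.numeric(center), radii = radii,
                 peak_sul = peak_sul, organ_label = as.integer(organ_label),
                 id = as.character(id)),
            class = "lesion_spec")
}

# Logical mask of voxels whose centers lie inside an ellipsoid, plus the
# normalized squared radius of each inside voxel (for the gaussian profile).
ellipsoid_mask <- function(dims, spacing, center, radii) {
  cs <- axis_centers(dims, spacing)
  dx2 <- ((cs[[1]] - center[1]) / radii[1])^2
  dy2 <- ((cs[[2]] - center[2]) / radii[2])^2
  dz2 <- ((cs[[3]] - center[3]) / radii[3])^2
  rho2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  list(mask = rho2 <= 1, rho2 = rho2)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic SUL phantom with ground truth
#'
#' Builds the SUL volume, the aligned organ label map, and a ground-truth
#' table of each lesion's voxelized volume and peak SUL. Voxels whose centers
#' fall inside a lesion ellipsoid take the lesion profile value; liver-sphere
#' voxels are drawn from `N(liver_mean, liver_sd)`; everything else is the
#' uniform background. Additive Gaussian noise (sd `noise_sd`) is applied
#' last and the result clamped at 0.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` ([sul_volume()]), `organs`
#'   ([organ_label_map()]), and `ground_truth` (data.frame with one row per
#'   lesion: `id`, `organ_label`, `peak_sul`, `n_voxels`, `true_volume_cm3`,
#'   centroid mm coordinates).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape; spacing <- spec$voxel_spacing
  extent <- dims * spacing
  for (les in spec$lesions) {
    if (any(les$center - les$radii < 0) || any(les$center + les$radii > extent)) {
      stop("lesion '", les$id, "' extends outside the grid")
    }
  }
  with_seed(spec$rng_seed, {
    vals <- array(spec$background_sul, dim = dims)
    labs <- array(0L, dim = dims)

    liver <- ellipsoid_mask(dims, spacing, spec$liver_center,
                            rep(spec$liver_radius_mm, 3L))$mask
    n_liver <- sum(liver)
    vals[liver] <- pmax(stats::rnorm(n_liver, spec$liver_mean, spec$liver_sd), 0)
    labs[liver] <- spec$liver_label

    owner <- array(0L, dim = dims)  # which lesion claimed a voxel
    gt <- vector("list", length(spec$lesions))
    for (k in seq_along(spec$lesions)) {
      les <- spec$lesions[[k]]
      em <- ellipsoid_mask(dims, spacing, les$center, les$radii)
      inside <- em$mask
      clash <- inside & owner > 0L
      if (any(clash)) {
        prev <- spec$lesions[[owner[which(clash)[1]]]]
        if (prev$organ_label != les$organ_label) {
          stop("lesions '", prev$id, "' and '", les$id,
               "' overlap but carry different organ labels")
        }
      }
      prof <- if (spec$lesion_profile == "plateau") {
        rep(les$peak_sul, sum(inside))
      } else {
        les$peak_sul * 2^(-em$rho2[inside])  # half the peak at the boundary
      }
      vals[inside] <- pmax(vals[inside], prof)
      labs[inside] <- les$organ_label
      owner[inside] <- k
      cs <- axis_centers(dims, spacing)
      ijk <- arrayInd(which(inside), dims)
      gt[[k]] <- data.frame(
        id = les$id, organ_label = les$organ_label, peak_sul = les$peak_sul,
        n_voxels = sum(inside),
        true_volume_cm3 = sum(inside) * prod(spacing) / 1000,
        cx = mean(cs[[1]][ijk[, 1]]), cy = mean(cs[[2]][ijk[, 2]]),
        cz = mean(cs[[3]][ijk[, 3]]))
    }
    if (spec$noise_sd > 0) {
      vals <- pmax(vals + stats::rnorm(length(vals), 0, spec$noise_sd), 0)
    }
    ground_truth <- if (length(gt)) do.call(rbind, gt) else
      data.frame(id = character(), organ_label = integer(),
                 peak_sul = numeric(), n_voxels = integer(),
                 true_volume_cm3 = numeric(),
                 cx = numeric(), cy = numeric(), cz = numeric())
    list(volume = sul_volume(vals, spacing),
         organs = organ_label_map(labs, spacing),
         ground_truth = ground_truth)
  })
}

#' Specification of a follow-up scan
#'
#' The follow-up lesion set is the baseline set with each lesion's peak SUL
#' multiplied by a non-negative response factor (0 = complete resolution of
#' that lesion's uptake) plus any new lesions, which appear only in the
#' follow-up.
#'
#' @param factors named numeric vector of multiplicative response factors,
#'   one per baseline lesion id; all `>= 0`.
#' @param new_lesions list of [lesion_spec()] present only at follow-up.
#' @param rng_seed seed for the follow-up noise realization.
#' @return A `followup_spec` list.
#' @export
followup_spec <- function(factors, new_lesions = list(), rng_seed = 2L) {
  factors <- unlist(factors)
  if (any(factors < 0)) stop("response factors must be >= 0")
  structure(list(factors = factors, new_lesions = new_lesions,
                 rng_seed = as.integer(rng_seed)),
            class = "followup_spec")
}

#' Generate the follow-up phantom for a baseline specification
#'
#' @param spec the baseline [phantom_spec()].
#' @param followup a [followup_spec()].
#' @return Same structure as [make_phantom()]; the ground truth additionally
#'   carries a `baseline_id` column (`NA` for new lesions).
#' @export
make_followup <- function(spec, followup) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(followup, "followup_spec"))
  ids <- vapply(spec$lesions, `[[`, character(1), "id")
  missing <- setdiff(ids, names(followup$factors))
  if (length(missing)) {
    stop("no response factor for baseline lesion(s): ",
         paste(missing, collapse = ", "))
  }
  fu_lesions <- list()
  baseline_id <- character()
  for (les in spec$lesions) {
    f <- followup$factors[[les$id]]
    if (f == 0) next  # complete resolution: lesion absent at follow-up
    scaled <- les
    scaled$peak_sul <- les$peak_sul * f
    fu_lesions[[length(fu_lesions) + 1L]] <- scaled
    baseline_id <- c(baseline_id, les$id)
  }
  for (les in followup$new_lesions) {
    fu_lesions[[length(fu_lesions) + 1L]] <- les
    baseline_id <- c(baseline_id, NA_character_)
  }
  fu_spec <- spec
  fu_spec$lesions <- fu_lesions
  fu_spec$rng_seed <- followup$rng_seed
  out <- make_phantom(fu_spec)
  if (nrow(out$ground_truth)) out$ground_truth$baseline_id <- baseline_id
  else out$ground_truth$baseline_id <- character()
  out
}
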