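#' SUL volume container
#'
#' A `sul_volume` is a 3-D numeric array of SUL values (standardized uptake
#' value normalized to lean body mass, dimensionless g/mL-normalized) with
#' physical voxel spacing in mm. World coordinates are in mm with the origin
#' at the corner of the grid; the voxel with 0-based index `i` along an axis
#' with spacing `s` has its center at `(i + 0.5) * s`. A voxel belongs to a
#' geometric region if and only if its center does.
#'
#' @param values 3-D numeric array of SUL values (all `>= 0`).
#' @param spacing numeric length-3, voxel edge length in mm per axis (`> 0`).
#' @return An object of class `sul_volume`: a list with elements `values`,
#'   `spacing` and `origin`.
#' @export
sul_volume <- function(values, spacing) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (mm)")
  }
  if (any(values < 0, na.rm = TRUE)) stop("SUL values must be non-negative")
  structure(list(values = values, spacing = spacing, origin = c(0, 0, 0)),
            class = "sul_volume")
}

#' Organ label map aligned with a SUL volume
#'
#' Integer labels on the same grid as a companion [sul_volume()]; label 0 is
#' background. The legend maps label values to organ names. Paired organs
#' (e.g. left/right lung) are distinct labels by convention, so the
#' two-lesions-per-organ cap treats them separately.
#'
#' @param labels 3-D integer array.
#' @param spacing voxel spacing in mm (as for [sul_volume()]).
#' @param legend named integer vector or named list mapping organ name ->
#'   label value; optional.
#' @return An object of class `organ_label_map`.
#' @export
organ_label_map <- function(labels, spacing, legend = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, legend = legend),
            class = "organ_label_map")
}

#' @export
print.sul_volume <- function(x, ...) {
  cat(sprintf("<sul_volume> %s voxels, spacing %s mm, SUL range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.organ_label_map <- function(x, ...) {
  cat(sprintf("<organ_label_map> %s voxels, labels: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sort(unique(as.vector(x$labels))), collapse = ", ")))
  invisible(x)
}

# Voxel-center world coordinates (mm) for a grid; one row per voxel is never
# materialized -- returns per-axis center vectors.
axis_centers <- function(dims, spacing) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
}

check_aligned <- function(vol, organs) {
  if (!identical(dim(vol$values), dim(organs$labels))) {
    stop("SUL volume and organ label map have different grid shapes")
  }
  if (max(abs(vol$spacing - organs$spacing)) > 1e-9) {
    stop("SUL volume and organ label map have different voxel spacings")
  }
  invisible(TRUE)
}

#' Read a NIfTI volume as a SUL volume or label map
#'
#' @param path path to a NIfTI-1 file.
#' @param what `"sul"` for a [sul_volume()], `"labels"` for an
#'   [organ_label_map()].
#' @return A `sul_volume` or `organ_label_map`.
#' @export
read_volume <- function(path, what = c("sul", "labels")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  if (what == "sul") sul_volume(arr, spacing)
  else organ_label_map(arr, spacing)
}

#' Write a SUL volume or label map to NIfTI-1
#'
#' SUL volumes are stored as float64 so that a write/read round trip is
#' bit-identical; label maps as int32.
#'
#' @param x a [sul_volume()] or [organ_label_map()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "sul_volume")) {
    arr <- x$values; dt <- "double"; spacing <- x$spacing
  } else if (inherits(x, "organ_label_map")) {
    arr <- x$labels; dt <- "int32"; spacing <- x$spacing
  } else stop("x must be a sul_volume or organ_label_map")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
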