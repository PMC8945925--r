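# 26-connected component labeling on a 3-D logical mask.
# Vectorized frontier BFS; returns an integer array of component labels
# (0 = background). Foreground counts in PET segmentations are small
# relative to the grid, so this stays fast without compiled code.
label_components_26 <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]  # 26 neighbors
  visited <- array(FALSE, dim = dims)
  comp <- 0L
  for (seed in fg) {
    if (visited[seed]) next
    comp <- comp + 1L
    visited[seed] <- TRUE
    labels[seed] <- comp
    frontier <- arrayInd(seed, dims)
    while (nrow(frontier)) {
      n <- nrow(frontier)
      nb <- frontier[rep(seq_len(n), each = 26L), , drop = FALSE] +
        off[rep(1:26, times = n), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
      lin <- unique(lin[mask[lin] & !visited[lin]])
      if (!length(lin)) break
      visited[lin] <- TRUE
      labels[lin] <- comp
      frontier <- arrayInd(lin, dims)
    }
  }
  labels
}

#' Segment measurable lesions from a SUL volume
#'
#' Lesion volumes of interest are the 26-connected components of voxels at or
#' above the segmentation threshold (liver mean + 2 SD), excluding voxels in
#' physiologic-uptake organs (`exclude_labels`, e.g. brain, bladder). A
#' component is kept only if its SUL_max passes the measurability gate
#' (1.5 x liver mean + 2 SD by default). Per-lesion metrics follow the VOI
#' identities: `mtv = n_voxels * voxel_volume` (cm^3),
#' `tlg = sul_mean * mtv` (g), which hold exactly.
#'
#' @param vol a [sul_volume()].
#' @param organs an aligned [organ_label_map()].
#' @param bg a [liver_background()].
#' @param exclude_labels integer organ labels whose voxels are excluded from
#'   segmentation (default none; synthetic phantoms have no physiologic foci).
#' @param measurability_parse passed to [measurability_threshold()].
#' @return A data.frame of class `lesion_table`, one row per measurable
#'   lesion, ordered hottest first (descending `sul_max`, ties by larger
#'   `mtv`, then smallest centroid in lexicographic mm order): `id`,
#'   `organ_label`, `sul_max`, `sul_mean`, `mtv_cm3`, `tlg_g`, `n_voxels`,
#'   `cx`, `cy`, `cz`; the voxel index sets are kept in the `voxels`
#'   list column.
#' @export
find_lesions <- function(vol, organs, bg, exclude_labels = integer(0),
                         measurability_parse = c("percist", "grouped")) {
  measurability_parse <- match.arg(measurability_parse)
  stopifnot(inherits(vol, "sul_volume"), inherits(organs, "organ_label_map"))
  check_aligned(vol, organs)
  seg_thr <- segmentation_threshold(bg)
  meas_thr <- measurability_threshold(bg, measurability_parse)
  mask <- vol$values >= seg_thr
  if (length(exclude_labels)) {
    mask <- mask & !(organs$labels %in% exclude_labels)
  }
  comp <- label_components_26(mask)
  ncomp <- max(comp)
  dims <- dim(vol$values)
  cs <- axis_centers(dims, vol$spacing)
  voxvol_cm3 <- prod(vol$spacing) / 1000
  rows <- list(); voxsets <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    v <- vol$values[idx]
    if (max(v) < meas_thr) next  # below the measurability gate
    ijk <- arrayInd(idx, dims)
    lab <- organs$labels[idx]
    tab <- table(lab)
    organ <- as.integer(names(tab)[which.max(tab)])  # majority organ label
    sul_mean <- mean(v)
    mtv <- length(idx) * voxvol_cm3
    rows[[length(rows) + 1L]] <- data.frame(
      organ_label = organ, sul_max = max(v), sul_mean = sul_mean,
      mtv_cm3 = mtv, tlg_g = sul_mean * mtv, n_voxels = length(idx),
      cx = mean(cs[[1]][ijk[, 1]]), cy = mean(cs[[2]][ijk[, 2]]),
      cz = mean(cs[[3]][ijk[, 3]]))
    voxsets[[length(rows)]] <- idx
  }
  if (!length(rows)) {
    out <- data.frame(id = character(), organ_label = integer(),
                      sul_max = numeric(), sul_mean = numeric(),
                      mtv_cm3 = numeric(), tlg_g = numeric(),
                      n_voxels = integer(),
                      cx = numeric(), cy = numeric(), cz = numeric())
    out$voxels <- list()
    class(out) <- c("lesion_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$voxels <- voxsets
  out <- out[lesion_order(out), , drop = FALSE]
  out <- cbind(id = sprintf("L%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("lesion_table", "data.frame")
  out
}

# Hotness ordering: descending sul_max, ties broken by larger mtv, then by
# smallest centroid in lexicographic (cx, cy, cz) order.
lesion_order <- function(lesions) {
  order(-lesions$sul_max, -lesions$mtv_cm3,
        lesions$cx, lesions$cy, lesions$cz)
}

#' The measurably hottest single lesion
#'
#' @param lesions a lesion table from [find_lesions()] (or any data.frame
#'   with `sul_max`, `mtv_cm3`, `cx`, `cy`, `cz`).
#' @return The single hottest lesion as a one-row data.frame.
#' @export
hottest_lesion <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0L) stop("no measurable lesion")
  lesions[lesion_order(lesions)[1], , drop = FALSE]
}

#' Select up to five target lesions, at most two per organ
#'
#' Greedy scan in hotness order (same tie-break as [hottest_lesion()]):
#' a lesion is skipped if its organ already holds two targets; selection
#' stops at five. Summed metrics are computed over the selected set. The
#' result is invariant to the input row order.
#'
#' @param lesions a lesion table.
#' @param max_lesions,max_per_organ caps (defaults 5 and 2).
#' @return A `target_set`: list with `lesions` (selected rows, hotness
#'   order), `sum_sul`, `sum_mtv`, `sum_tlg`, `n`.
#' @export
select_targets <- function(lesions, max_lesions = 5L, max_per_organ = 2L) {
  if (is.null(lesions) || nrow(lesions) == 0L) {
    sel <- lesions
    return(structure(list(lesions = sel, sum_sul = 0, sum_mtv = 0,
                          sum_tlg = 0, n = 0L), class = "target_set"))
  }
  ord <- lesion_order(lesions)
  per_organ <- integer(0)
  take <- integer(0)
  for (i in ord) {
    if (length(take) >= max_lesions) break
    org <- as.character(lesions$organ_label[i])
    cnt <- if (org %in% names(per_organ)) per_organ[[org]] else 0L
    if (cnt >= max_per_organ) next
    take <- c(take, i)
    per_organ[org] <- cnt + 1L
  }
  sel <- lesions[take, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(lesions = sel,
                 sum_sul = sum(sel$sul_max),
                 sum_mtv = sum(sel$mtv_cm3),
                 sum_tlg = sum(sel$tlg_g),
                 n = nrow(sel)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %d lesion(s); sumSUL %.2f, sumMTV %.2f cm3, sumTLG %.2f g\n",
              x$n, x$sum_sul, x$sum_mtv, x$sum_tlg))
  invisible(x)
}

#' Match baseline target lesions to follow-up lesions
#'
#' The study design measures the same target lesions on the post-treatment
#' scan; with rigidly aligned grids this is operationalized as greedy
#' nearest-centroid pairing: candidate pairs must share the organ label and
#' lie within `radius_mm`, and are accepted in ascending centroid distance,
#' each lesion at most once. Unmatched follow-up lesions are candidate new
#' lesions; unmatched baseline lesions have resolved.
#'
#' @param baseline a [select_targets()] result or lesion table.
#' @param followup_lesions a lesion table from the follow-up scan.
#' @param radius_mm maximum centroid distance for a match (default 20).
#' @return A `lesion_correspondence`: list with `pairs` (data.frame
#'   `baseline_id`, `followup_id`, `distance_mm`), `unmatched_baseline`,
#'   `unmatched_followup` (id vectors).
#' @export
match_lesions <- function(baseline, followup_lesions, radius_mm = 20) {
  base <- if (inherits(baseline, "target_set")) baseline$lesions else baseline
  fu <- followup_lesions
  pairs <- data.frame(baseline_id = character(), followup_id = character(),
                      distance_mm = numeric())
  if (nrow(base) && nrow(fu)) {
    d <- outer(seq_len(nrow(base)), seq_len(nrow(fu)), Vectorize(function(i, j) {
      sqrt((base$cx[i] - fu$cx[j])^2 + (base$cy[i] - fu$cy[j])^2 +
           (base$cz[i] - fu$cz[j])^2)
    }))
    same_organ <- outer(base$organ_label, fu$organ_label, "==")
    cand <- which(d <= radius_mm & same_organ, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_b <- logical(nrow(base)); used_f <- logical(nrow(fu))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_b[i] || used_f[j]) next
        used_b[i] <- TRUE; used_f[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          baseline_id = base$id[i], followup_id = fu$id[j],
          distance_mm = d[i, j]))
      }
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_baseline = setdiff(base$id, pairs$baseline_id),
    unmatched_followup = setdiff(fu$id, pairs$followup_id)),
    class = "lesion_correspondence")
}

#' Flag new lesions from a correspondence
#'
#' Any measurable follow-up lesion with no baseline counterpart is a new
#' lesion; its presence alone makes the PERCIST category progressive.
#'
#' @param corr a [match_lesions()] result.
#' @return List with `new_lesion` (logical) and `ids`.
#' @export
detect_new_lesions <- function(corr) {
  stopifnot(inherits(corr, "lesion_correspondence"))
  list(new_lesion = length(corr$unmatched_followup) > 0,
       ids = corr$unmatched_followup)
}

#' Follow-up sums over the matched baseline targets
#'
#' Builds the follow-up counterpart of a baseline target set: each baseline
#' target contributes its matched follow-up lesion's metrics, and a resolved
#' (unmatched) baseline target contributes zero to every sum.
#'
#' @param baseline the baseline [select_targets()] result.
#' @param followup_lesions the follow-up lesion table.
#' @param corr the [match_lesions()] correspondence between them.
#' @return A `target_set` with the follow-up sums.
#' @export
matched_target_set <- function(baseline, followup_lesions, corr) {
  stopifnot(inherits(baseline, "target_set"),
            inherits(corr, "lesion_correspondence"))
  fu_ids <- corr$pairs$followup_id[match(baseline$lesions$id,
                                         corr$pairs$baseline_id)]
  rows <- followup_lesions[match(fu_ids, followup_lesions$id), , drop = FALSE]
  sum0 <- function(x) sum(x, na.rm = TRUE)  # resolved lesions contribute 0
  structure(list(lesions = rows,
                 sum_sul = sum0(rows$sul_max),
                 sum_mtv = sum0(rows$mtv_cm3),
                 sum_tlg = sum0(rows$tlg_g),
                 n = sum(!is.na(rows$id))),
            class = "target_set")
}
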