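# Independent oracles the implementation is checked against. These stay
# brute-force on purpose: enumeration over all feasible subsets / cutoffs,
# not the greedy or median-outward paths under test.

# All feasible target subsets (size <= max_lesions, <= max_per_organ per
# organ); returns the one whose descending sul_max sequence is
# lexicographically maximal, as a set of row indices.
oracle_select_targets <- function(lesions, max_lesions = 5L, max_per_organ = 2L) {
  n <- nrow(lesions)
  best <- integer(0)
  best_key <- numeric(0)
  lex_greater <- function(a, b) {
    # compare descending sequences padded with -Inf
    len <- max(length(a), length(b))
    a <- c(a, rep(-Inf, len - length(a)))
    b <- c(b, rep(-Inf, len - length(b)))
    d <- a - b
    nz <- which(d != 0)
    if (!length(nz)) FALSE else d[nz[1]] > 0
  }
  for (k in 0:min(max_lesions, n)) {
    combs <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(n, k), 2)
    for (sub in combs) {
      sub <- as.integer(sub)
      if (length(sub) &&
          any(table(lesions$organ_label[sub]) > max_per_organ)) next
      key <- sort(lesions$sul_max[sub], decreasing = TRUE)
      if (lex_greater(key, best_key)) {
        best <- sub; best_key <- key
      }
    }
  }
  best
}

# Random lesion table for selection tests.
random_lesion_table <- function(n, n_organs = 3) {
  data.frame(
    id = sprintf("R%02d", seq_len(n)),
    organ_label = sample.int(n_organs, n, replace = TRUE),
    sul_max = round(stats::runif(n, 2, 12), 2),
    sul_mean = stats::runif(n, 1, 6),
    mtv_cm3 = stats::runif(n, 0.5, 30),
    tlg_g = NA_real_,
    n_voxels = NA_integer_,
    cx = stats::runif(n, 0, 100), cy = stats::runif(n, 0, 100),
    cz = stats::runif(n, 0, 100))
}

# Exhaustive minimum-p cutoff search: every distinct observed value whose
# dichotomization leaves both groups at or above the floor.
oracle_optimal_cutoff <- function(values, times, events, min_group = 0.15) {
  cand <- sort(unique(values))
  floor_n <- ceiling(min_group * length(values))
  ps <- sapply(cand, function(cc) {
    g <- values >= cc
    if (min(sum(g), sum(!g)) < floor_n) return(NA_real_)
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  })
  ps <- stats::pchisq(ps, 1, lower.tail = FALSE)
  if (all(is.na(ps))) return(NULL)
  list(p = min(ps, na.rm = TRUE),
       cutoffs = cand[!is.na(ps) & ps == min(ps, na.rm = TRUE)])
}

# Fisher two-sided p by full hypergeometric enumeration of tables with the
# same margins, summing probabilities <= that of the observed table.
oracle_fisher_p <- function(tp, fn, fp, tn) {
  r1 <- tp + fn; c1 <- tp + fp; n <- tp + fn + fp + tn
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(tp, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tiny noiseless phantom with one spherical plateau lesion; shared fixture.
simple_sphere_phantom <- function(radius_mm = 10, peak = 8, spacing = 2,
                                  noise_sd = 0, liver_sd = 0.25,
                                  seed = 11L) {
  phantom_spec(
    grid_shape = c(48L, 48L, 48L), voxel_spacing = spacing,
    background_sul = 0.5, noise_sd = noise_sd,
    liver_center = c(28, 28, 28), liver_radius_mm = 18,
    liver_mean = 2.0, liver_sd = liver_sd,
    lesions = list(lesion_spec(center = c(70, 70, 70),
                               radii = radius_mm, peak_sul = peak,
                               organ_label = 2L, id = "sphere")),
    rng_seed = seed)
}
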