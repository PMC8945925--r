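bg_fixture <- function(mu = 2.0, s = 0.25) {
  structure(list(mean_sul = mu, sd_sul = s), class = "liver_background")
}

test_that("a noiseless plateau lesion is recovered with exact metrics", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0)
  ph <- make_phantom(spec)
  bg <- liver_background(ph$volume, spec$liver_center)
  les <- find_lesions(ph$volume, ph$organs, bg)
  expect_equal(nrow(les), 1L)
  expect_equal(les$sul_max, 8)
  expect_equal(les$sul_mean, 8)           # plateau -> mean equals plateau
  expect_equal(les$tlg_g, les$sul_mean * les$mtv_cm3)  # exact identity
  expect_equal(les$organ_label, 2L)
  expect_equal(les$n_voxels, ph$ground_truth$n_voxels)
  # MTV against the analytic sphere volume (r = 10 mm, 2 mm voxels)
  expect_lt(abs(les$mtv_cm3 - 4 / 3 * pi) / (4 / 3 * pi), 0.15)
})

test_that("lesions below the measurability gate are dropped", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0, peak = 3.0)
  ph <- make_phantom(spec)
  bg <- bg_fixture(2.0, 0.25)  # measurability 3.5, segmentation 2.5
  les <- find_lesions(ph$volume, ph$organs, bg)
  expect_equal(nrow(les), 0L)
  expect_error(hottest_lesion(les), "no measurable lesion")
})

test_that("segmentation uses 26-connectivity and is threshold-monotone", {
  vals <- array(0.5, dim = c(12, 12, 12))
  vals[4, 4, 4] <- 6; vals[5, 5, 5] <- 6    # diagonal neighbors: one lesion
  vals[10, 10, 10] <- 6                      # separated: its own lesion
  vol <- sul_volume(vals, 2)
  organs <- organ_label_map(array(2L, dim = c(12, 12, 12)), 2)
  les <- find_lesions(vol, organs, bg_fixture())
  expect_equal(nrow(les), 2L)
  expect_setequal(les$n_voxels, c(2L, 1L))

  # raising the segmentation threshold never increases any lesion's MTV
  spec <- simple_sphere_phantom(noise_sd = 0.3, seed = 9L)
  spec$lesion_profile <- "gaussian"
  ph <- make_phantom(spec)
  mtv_at <- function(s) {
    l <- find_lesions(ph$volume, ph$organs, bg_fixture(2.0, s))
    if (nrow(l)) max(l$mtv_cm3) else 0
  }
  mtvs <- sapply(c(0.1, 0.3, 0.5, 0.8), mtv_at)
  expect_true(all(diff(mtvs) <= 1e-12))
})

test_that("excluded organ labels are not segmented", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0)
  ph <- make_phantom(spec)
  bg <- bg_fixture()
  les <- find_lesions(ph$volume, ph$organs, bg, exclude_labels = 2L)
  expect_equal(nrow(les), 0L)
  expect_error(find_lesions(ph$volume,
                            organ_label_map(array(0L, dim = c(3, 3, 3)), 2),
                            bg),
               "different grid shapes")
})

test_that("hottest lesion follows the tie-break rules", {
  les <- random_lesion_table(3)
  les$sul_max <- c(10.7, 6.2, 4.1)
  expect_equal(hottest_lesion(les)$sul_max, 10.7)
  expect_equal(hottest_lesion(les[2, ])$sul_max, 6.2)  # single lesion

  ties <- random_lesion_table(2)
  ties$sul_max <- c(7, 7); ties$mtv_cm3 <- c(5, 9)
  expect_equal(hottest_lesion(ties)$mtv_cm3, 9)  # larger MTV wins
  ties$mtv_cm3 <- c(5, 5); ties$cx <- c(40, 20)
  expect_equal(hottest_lesion(ties)$cx, 20)      # then smallest centroid
})

test_that("target selection caps at five lesions and two per organ", {
  set.seed(21)
  one_organ <- random_lesion_table(7, n_organs = 1)
  sel <- select_targets(one_organ)
  expect_equal(sel$n, 2L)
  expect_equal(sort(sel$lesions$sul_max, decreasing = TRUE),
               sort(one_organ$sul_max, decreasing = TRUE)[1:2])

  spread <- random_lesion_table(3, n_organs = 3)
  spread$organ_label <- 1:3
  sel3 <- select_targets(spread)
  expect_equal(sel3$n, 3L)
  expect_equal(sel3$sum_sul, sum(spread$sul_max))

  worked <- random_lesion_table(6)
  worked$sul_max <- c(9, 8, 7, 6, 5, 4)
  worked$organ_label <- c(1L, 1L, 1L, 2L, 2L, 3L)
  expect_setequal(select_targets(worked)$lesions$sul_max, c(9, 8, 6, 5, 4))

  empty <- select_targets(random_lesion_table(4)[0, ])
  expect_equal(empty$n, 0L)
  expect_equal(empty$sum_mtv, 0)
})

test_that("target selection is order-invariant and matches the subset oracle", {
  set.seed(33)
  for (rep in 1:40) {
    les <- random_lesion_table(sample(1:10, 1), n_organs = sample(1:4, 1))
    sel <- select_targets(les)
    shuffled <- les[sample(nrow(les)), ]
    expect_setequal(select_targets(shuffled)$lesions$id, sel$lesions$id)
    oracle <- oracle_select_targets(les)
    expect_setequal(sel$lesions$id, les$id[oracle])
  }
})

test_that("lesion matching pairs by organ and distance, greedily nearest-first", {
  base <- random_lesion_table(2)
  base$id <- c("B1", "B2"); base$organ_label <- c(1L, 2L)
  base$cx <- c(10, 50); base$cy <- c(10, 50); base$cz <- c(10, 50)
  fu <- base
  fu$id <- c("F1", "F2")
  corr <- match_lesions(base, fu)
  expect_equal(corr$pairs$followup_id[match(c("B1", "B2"), corr$pairs$baseline_id)],
               c("F1", "F2"))
  expect_length(corr$unmatched_followup, 0)

  # a follow-up lesion 50 mm from everything stays unmatched
  far <- fu[1, ]; far$id <- "F3"; far$cx <- 110; far$organ_label <- 1L
  corr2 <- match_lesions(base, rbind(fu, far))
  expect_equal(corr2$unmatched_followup, "F3")
  expect_true(detect_new_lesions(corr2)$new_lesion)

  # organ mismatch blocks a geometric match; the orphans surface as
  # candidate new lesions
  fu_wrong <- fu; fu_wrong$organ_label <- c(2L, 1L)
  corr3 <- match_lesions(base, fu_wrong)
  expect_equal(nrow(corr3$pairs), 0L)
  expect_setequal(corr3$unmatched_followup, c("F1", "F2"))
  expect_true(detect_new_lesions(corr3)$new_lesion)
})

test_that("matching recovers the generator's ground-truth correspondence", {
  spec <- phantom_spec(
    grid_shape = c(56L, 56L, 56L), voxel_spacing = 2, noise_sd = 0,
    liver_center = c(28, 28, 28), liver_radius_mm = 15, liver_sd = 0,
    lesions = list(
      lesion_spec(c(85, 30, 30), 9, 9.0, 2L, "a"),
      lesion_spec(c(30, 85, 30), 7, 6.5, 3L, "b"),
      lesion_spec(c(85, 85, 85), 6, 5.0, 4L, "c")),
    rng_seed = 3L)
  base <- make_phantom(spec)
  newles <- lesion_spec(c(30, 30, 85), 6, 7.0, 5L, "d")
  fu <- make_followup(spec, followup_spec(
    factors = c(a = 0.5, b = 0, c = 0.9), new_lesions = list(newles)))
  bg <- bg_fixture(2.0, 0)
  bl <- find_lesions(base$volume, base$organs, bg)
  fl <- find_lesions(fu$volume, fu$organs, bg)
  targets <- select_targets(bl)
  corr <- match_lesions(targets, fl)
  # organ labels identify the ground-truth lesions
  pair_organs <- function(ids, tab) tab$organ_label[match(ids, tab$id)]
  expect_setequal(pair_organs(corr$pairs$baseline_id, bl),
                  c(2L, 4L))                      # a and c persist
  nl <- detect_new_lesions(corr)
  expect_true(nl$new_lesion)
  expect_equal(pair_organs(nl$ids, fl), 5L)       # the injected new lesion
  # resolved lesion b: unmatched baseline with organ 3
  expect_equal(pair_organs(corr$unmatched_baseline, bl), 3L)
})

test_that("TLG identity holds for every lesion on a noisy phantom", {
  spec <- simple_sphere_phantom(noise_sd = 0.25, seed = 17L)
  ph <- make_phantom(spec)
  les <- find_lesions(ph$volume, ph$organs, bg_fixture(2.0, 0.3))
  expect_gt(nrow(les), 0)
  expect_equal(les$tlg_g, les$sul_mean * les$mtv_cm3)
  expect_true(all(les$sul_mean <= les$sul_max))
})
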