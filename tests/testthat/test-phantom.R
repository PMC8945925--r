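test_that("noiseless plateau construction sets lesion voxels to the peak", {
  spec <- simple_sphere_phantom(liver_sd = 0)
  ph <- make_phantom(spec)
  gt <- ph$ground_truth
  expect_equal(nrow(gt), 1L)
  lesion_vox <- ph$organs$labels == 2L
  expect_true(all(ph$volume$values[lesion_vox] == 8))
  expect_equal(sum(lesion_vox), gt$n_voxels)
  # elsewhere only background and liver values
  other <- ph$volume$values[!lesion_vox & ph$organs$labels != 1L]
  expect_true(all(other == 0.5))
})

test_that("identical seeds reproduce bit-identical phantoms", {
  spec <- simple_sphere_phantom(noise_sd = 0.2, seed = 42L)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$organs$labels, b$organs$labels)
  c <- make_phantom(simple_sphere_phantom(noise_sd = 0.2, seed = 43L))
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("voxelized sphere volume approximates the analytic volume", {
  ph <- make_phantom(simple_sphere_phantom(radius_mm = 10, spacing = 2))
  analytic <- 4 / 3 * pi * 10^3  # mm^3
  vox <- ph$ground_truth$n_voxels * 2^3
  expect_lt(abs(vox - analytic) / analytic, 0.15)
})

test_that("above-background voxels are exactly the voxelized lesions", {
  # conservation: no spurious voxels in a noiseless phantom (liver excluded)
  spec <- phantom_spec(
    grid_shape = c(40L, 40L, 40L), voxel_spacing = 2, background_sul = 0.5,
    noise_sd = 0, liver_center = c(20, 20, 20), liver_radius_mm = 10,
    liver_mean = 2, liver_sd = 0,
    lesions = list(
      lesion_spec(c(60, 60, 60), 8, 6, 2L, "a"),
      lesion_spec(c(20, 60, 20), 6, 4, 3L, "b")),
    rng_seed = 5L)
  ph <- make_phantom(spec)
  above <- ph$volume$values > 2  # above liver too
  expect_equal(sum(above), sum(ph$ground_truth$n_voxels))
})

test_that("ground-truth volume is monotone in lesion radius", {
  vols <- sapply(c(6, 8, 10, 12, 14), function(r) {
    make_phantom(simple_sphere_phantom(radius_mm = r))$ground_truth$true_volume_cm3
  })
  expect_true(all(diff(vols) > 0))
})

test_that("invalid phantom specs are rejected", {
  expect_error(make_phantom(phantom_spec(
    grid_shape = c(20L, 20L, 20L), voxel_spacing = 2,
    liver_center = c(20, 20, 20), liver_radius_mm = 8,
    lesions = list(lesion_spec(c(38, 38, 38), 5, 6, 2L, "out")))),
    "outside the grid")
  expect_error(make_phantom(phantom_spec(
    grid_shape = c(40L, 40L, 40L), voxel_spacing = 2,
    liver_center = c(20, 20, 20), liver_radius_mm = 8,
    lesions = list(lesion_spec(c(60, 60, 60), 8, 6, 2L, "a"),
                   lesion_spec(c(64, 60, 60), 8, 5, 3L, "b")))),
    "different organ labels")
  expect_error(lesion_spec(c(10, 10, 10), -3, 5, 2L, "neg"))
  expect_error(lesion_spec(c(10, 10, 10), 3, -5, 2L, "negpeak"))
})

test_that("follow-up with unit factors and no noise equals baseline", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0)
  base <- make_phantom(spec)
  fu <- make_followup(spec, followup_spec(factors = c(sphere = 1),
                                          rng_seed = spec$rng_seed))
  expect_identical(base$volume$values, fu$volume$values)
})

test_that("factor 0 removes the lesion, factors scale the peak", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0, peak = 10)
  fu0 <- make_followup(spec, followup_spec(factors = c(sphere = 0)))
  expect_equal(nrow(fu0$ground_truth), 0L)
  # voxels revert to background
  lesion_vox <- make_phantom(spec)$organs$labels == 2L
  expect_true(all(fu0$volume$values[lesion_vox] == 0.5))

  fu35 <- make_followup(spec, followup_spec(factors = c(sphere = 0.35)))
  expect_equal(max(fu35$volume$values[fu35$organs$labels == 2L]), 3.5)
  expect_equal(fu35$ground_truth$peak_sul, 3.5)
})

test_that("new lesions appear only in the follow-up", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0)
  newles <- lesion_spec(c(20, 70, 20), 6, 5, 3L, "new1")
  fu <- make_followup(spec, followup_spec(factors = c(sphere = 1),
                                          new_lesions = list(newles)))
  expect_setequal(fu$ground_truth$id, c("sphere", "new1"))
  expect_true(is.na(fu$ground_truth$baseline_id[fu$ground_truth$id == "new1"]))
  expect_false("new1" %in% make_phantom(spec)$ground_truth$id)
})

test_that("negative response factors and missing factors are rejected", {
  spec <- simple_sphere_phantom()
  expect_error(followup_spec(factors = c(sphere = -0.5)), ">= 0")
  expect_error(make_followup(spec, followup_spec(factors = c(other = 1))),
               "no response factor")
})

test_that("gaussian profile halves the peak at the boundary and stays below it", {
  spec <- simple_sphere_phantom(liver_sd = 0, noise_sd = 0)
  spec$lesion_profile <- "gaussian"
  ph <- make_phantom(spec)
  v <- ph$volume$values[ph$organs$labels == 2L]
  expect_true(all(v <= 8) && all(v >= 4 - 1e-9))
  expect_gt(max(v), 7.5)  # near-center voxel close to the peak
})
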