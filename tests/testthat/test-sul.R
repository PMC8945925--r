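test_that("lean body mass matches hand-computed values", {
  # male, 80 kg, 180 cm: BMI 24.69 -> 9270*80/(6680 + 216*24.69)
  expect_equal(lean_body_mass(80, 180, "male"), 61.73, tolerance = 1e-3)
  # female, 60 kg, 160 cm: BMI 23.4375 -> 556200 / 14498.75
  expect_equal(lean_body_mass(60, 160, "female"),
               9270 * 60 / (8780 + 244 * (60 / 1.6^2)), tolerance = 1e-9)
  expect_equal(lean_body_mass(60, 160, "female"), 38.36, tolerance = 1e-3)
})

test_that("lean body mass stays below total weight and rejects bad input", {
  for (w in c(45, 60, 80, 110)) for (h in c(150, 170, 190)) {
    expect_lt(lean_body_mass(w, h, "male"), w)
    expect_lt(lean_body_mass(w, h, "female"), w)
    expect_lt(lean_body_mass(w, h, "male", "james"), w)
  }
  expect_error(lean_body_mass(-70, 170, "male"), "positive")
  expect_error(lean_body_mass(70, 0, "female"), "positive")
  expect_error(scan_session(0, 70, 170, "male"), "positive")
})

test_that("activity-to-SUL conversion is the LBM/dose scaling and is linear", {
  sess <- scan_session(injected_dose_mbq = 370, body_weight_kg = 80,
                       height_cm = 180, sex = "male")
  arr <- array(0, dim = c(4, 4, 4))
  expect_true(all(activity_to_sul(arr, sess, spacing = 2)$values == 0))

  arr[] <- 0.01  # uniform c -> uniform c * L / D
  sul <- activity_to_sul(arr, sess, spacing = 2)
  expect_equal(unique(as.vector(sul$values)),
               0.01 * sess$lbm_kg * 1000 / 370)

  # linearity f(a x) = a f(x)
  arr2 <- array(runif(64), dim = c(4, 4, 4))
  s1 <- activity_to_sul(arr2, sess, spacing = 2)$values
  s3 <- activity_to_sul(3 * arr2, sess, spacing = 2)$values
  expect_equal(s3, 3 * s1)

  # doubling the dose halves every SUL
  sess2 <- scan_session(740, 80, 180, "male")
  expect_equal(activity_to_sul(arr2, sess2, spacing = 2)$values, s1 / 2)

  arr[1] <- -1
  expect_error(activity_to_sul(arr, sess, spacing = 2), "non-negative")
})

test_that("liver background measures mean and sample SD inside the sphere only", {
  vals <- array(2.0, dim = c(30, 30, 30))
  vol <- sul_volume(vals, 2)
  bg <- liver_background(vol, center = c(30, 30, 30), diameter_mm = 30)
  expect_equal(bg$mean_sul, 2.0)
  expect_equal(bg$sd_sul, 0)

  # invariance: voxels outside the sphere do not matter
  vals2 <- vals
  mask_out <- array(TRUE, dim = dim(vals))
  # corner voxel is far outside the 15 mm sphere at (30,30,30)
  vals2[1, 1, 1] <- 50
  vals2[30, 30, 30] <- 99
  bg2 <- liver_background(sul_volume(vals2, 2), c(30, 30, 30), 30)
  expect_equal(bg2$mean_sul, bg$mean_sul)
  expect_equal(bg2$sd_sul, bg$sd_sul)
})

test_that("liver ROI mean is consistent with the phantom liver distribution", {
  spec <- simple_sphere_phantom(liver_sd = 0.3, seed = 7L)
  spec$liver_mean <- 2.2
  ph <- make_phantom(spec)
  bg <- liver_background(ph$volume, center = spec$liver_center)
  # ~1767 voxels at 2 mm in a 15 mm sphere; mean within 3 SE of 2.2
  expect_gt(bg$n_voxels, 1500)
  expect_lt(abs(bg$mean_sul - 2.2), 3 * 0.3 / sqrt(bg$n_voxels))
  expect_equal(bg$sd_sul, 0.3, tolerance = 0.1)
})

test_that("liver ROI errors: out of bounds and exclusion overlap", {
  vol <- sul_volume(array(2, dim = c(10, 10, 10)), 2)  # 20 mm extent
  expect_error(liver_background(vol, c(10, 10, 10), diameter_mm = 40),
               "outside the volume")
  vol2 <- sul_volume(array(2, dim = c(30, 30, 30)), 2)
  excl <- array(FALSE, dim = c(30, 30, 30))
  excl[15, 15, 15] <- TRUE  # center of the ROI
  expect_error(liver_background(vol2, c(30, 30, 30), 30, exclusion = excl),
               "exclusion")
})

test_that("measurability and segmentation thresholds follow the liver stats", {
  bg <- structure(list(mean_sul = 2.0, sd_sul = 0.25), class = "liver_background")
  expect_equal(measurability_threshold(bg), 3.5)      # 1.5*2 + 2*0.25
  expect_equal(segmentation_threshold(bg), 2.5)       # 2 + 2*0.25
  expect_equal(measurability_threshold(bg, "grouped"), 1.5 * 2.5)

  bg0 <- structure(list(mean_sul = 1.8, sd_sul = 0), class = "liver_background")
  expect_equal(measurability_threshold(bg0), 1.5 * 1.8)
  expect_equal(segmentation_threshold(bg0), 1.8)

  # strictly increasing in both mu and sigma; segmentation <= measurability
  for (mu in c(1, 2, 3)) for (s in c(0, 0.2, 0.5)) {
    b <- structure(list(mean_sul = mu, sd_sul = s), class = "liver_background")
    bm <- structure(list(mean_sul = mu + 0.1, sd_sul = s), class = "liver_background")
    bs <- structure(list(mean_sul = mu, sd_sul = s + 0.1), class = "liver_background")
    expect_gt(measurability_threshold(bm), measurability_threshold(b))
    expect_gt(measurability_threshold(bs), measurability_threshold(b))
    expect_lte(segmentation_threshold(b), measurability_threshold(b))
  }
})
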