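test_that("well detection recovers the rendered layout within two pixels", {
  m <- default_dye_model()
  deltas <- matrix(3, 8, 3)
  pair <- render_image_pair(deltas, m, pixel_noise_sd = 1, seed = 2)
  wells <- detect_wells(pair$before)
  expect_equal(nrow(wells), 8)
  expect_true(all(abs(wells$x - pair$layout$centers[, "x"]) <= 2))
  expect_true(all(abs(wells$y - pair$layout$centers[, "y"]) <= 2))
  expect_true(all(abs(wells$radius - pair$layout$radius) <= 2))
})

test_that("detection fails informatively on a featureless image", {
  blank <- array(30, dim = c(100, 200, 3))
  expect_error(detect_wells(blank), "found 0")
})

test_that("a 180-degree rotated image yields the same wells in reverse order", {
  m <- default_dye_model()
  pair <- render_image_pair(matrix(2, 8, 3), m, pixel_noise_sd = 0)
  img <- pair$before
  rot <- img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), ]
  wells <- detect_wells(img)
  wells_rot <- detect_wells(rot)
  # rotation maps (x, y) to (w + 1 - x, h + 1 - y); row-major sort then
  # enumerates the same physical wells in reverse
  expect_true(all(abs(wells_rot$x - rev(dim(img)[2] + 1 - wells$x)) < 0.5))
  expect_true(all(abs(wells_rot$y - rev(dim(img)[1] + 1 - wells$y)) < 0.5))
})

test_that("detection round-trips rendered panels within two pixels", {
  m <- default_dye_model()
  for (s in 1:12) {
    deltas <- with_seed_test(s, matrix(stats::runif(24, -25, 25), 8, 3))
    pair <- suppressWarnings(
      render_image_pair(deltas, m, pixel_noise_sd = 1.5, seed = s))
    wells <- detect_wells(pair$before)
    expect_true(all(abs(wells$x - pair$layout$centers[, "x"]) <= 2))
    expect_true(all(abs(wells$y - pair$layout$centers[, "y"]) <= 2))
  }
})

test_that("feature extraction is exact, antisymmetric and translation invariant", {
  m <- default_dye_model()
  deltas <- matrix(seq(-12, 11, by = 1), 8, 3)
  pair <- render_image_pair(deltas, m, pixel_noise_sd = 0)

  same <- extract_features(pair$before, pair$before, pair$layout)
  expect_equal(unname(same), rep(0, 24))

  feats <- extract_features(pair$before, pair$after, pair$layout)
  expect_length(feats, 24)
  expect_equal(unname(feats), as.numeric(t(deltas)))
  expect_match(names(feats)[1], "_R$")

  swapped <- extract_features(pair$after, pair$before, pair$layout)
  expect_equal(unname(swapped), -unname(feats))

  # shift both images and the layout by the same offset
  shift <- 7
  h <- dim(pair$before)[1]; w <- dim(pair$before)[2]
  shift_img <- function(img) {
    out <- array(pair$background[1], dim = dim(img))
    out[, (shift + 1):w, ] <- img[, 1:(w - shift), ]
    out
  }
  wells <- data.frame(x = pair$layout$centers[, "x"] + shift,
                      y = pair$layout$centers[, "y"],
                      radius = pair$layout$radius)
  shifted <- extract_features(shift_img(pair$before), shift_img(pair$after),
                              wells)
  expect_equal(shifted, feats)
})

test_that("empty well regions are rejected", {
  img <- array(0, dim = c(50, 50, 3))
  wells <- data.frame(x = 25.5, y = 25.5, radius = 0.1)
  expect_error(extract_features(img, img, wells), "no pixels")
  expect_error(extract_features(img, array(0, dim = c(40, 50, 3)),
                                wells), "dimensions")
})

test_that("band averages behave like means over inclusive wavelength windows", {
  wl <- 400:780
  flat <- setNames(rep(0.5, length(wl)), wl)
  for (band in names(color_bands))
    expect_equal(band_average(flat, band), 0.5)

  # spectrum supported only outside the green band
  outside <- setNames(ifelse(wl >= 500 & wl <= 580, 0, 1), wl)
  expect_equal(band_average(outside, "green"), 0)

  # linear ramp: the mean is the midpoint value
  ramp <- setNames(seq(0, 1, length.out = length(wl)), wl)
  expect_equal(band_average(ramp, c(500, 580)),
               mean(ramp[wl >= 500 & wl <= 580]))
  expect_equal(band_average(ramp, c(500, 580)),
               (ramp[["500"]] + ramp[["580"]]) / 2)

  expect_error(band_average(flat, c(300, 500)), "support")
})

test_that("concentration-response R2 matches a normal-equations oracle", {
  concs <- c(0, 250, 500, 1000, 2500, 5000)
  m <- tiny_dye_model()
  abs_g <- vapply(concs, function(cc)
    band_average(simulate_spectrum("dyeA", "glucose", cc, m), "green"),
    numeric(1))
  r2 <- concentration_response_r2(concs, abs_g)

  # brute-force simple-regression oracle via the normal equations
  X <- cbind(1, concs)
  beta <- solve(t(X) %*% X, t(X) %*% abs_g)
  fitted <- X %*% beta
  oracle <- 1 - sum((abs_g - fitted)^2) / sum((abs_g - mean(abs_g))^2)
  expect_equal(r2, oracle, tolerance = 1e-10)
  expect_gt(r2, 0.7)  # saturating yet clearly concentration-correlated

  expect_equal(concentration_response_r2(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_warning(z <- concentration_response_r2(c(1, 2, 3), c(5, 5, 5)),
                 "zero variance")
  expect_equal(z, 0)
  expect_error(concentration_response_r2(c(1, 2), c(1, 2)), "3")
})

test_that("feature matrices survive the CSV round trip", {
  m <- default_dye_model()
  pair <- render_image_pair(matrix(1:24 / 10, 8, 3), m)
  feats <- rbind(s1 = extract_features(pair$before, pair$after, pair$layout))
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, f)
  back <- read_features(f)
  expect_equal(back, feats, tolerance = 1e-12)
})
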