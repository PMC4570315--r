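test_that("generate_panel returns the requested panel, deterministically", {
  panel <- generate_panel(23, 22, seed = 1)
  expect_s3_class(panel, "chem_panel")
  expect_equal(nrow(panel), 45)
  expect_true(all(wine_chemicals %in% names(panel)))
  expect_true(all(as.matrix(panel[, wine_chemicals]) >= 0))
  expect_equal(sum(panel$cluster == "sweet"), 7)
  expect_equal(sum(panel$cluster == "mixture"), 22)

  again <- generate_panel(23, 22, seed = 1)
  expect_identical(panel, again)
  other <- generate_panel(23, 22, seed = 2)
  expect_false(identical(panel, other))

  expect_error(generate_panel(1, 0), "n_base")
  expect_error(generate_panel(5, -1), "n_mixtures")
})

test_that("mixtures are convex combinations of two base profiles", {
  panel <- generate_panel(2, 6, seed = 7)
  base <- as.matrix(panel[1:2, wine_chemicals])
  lo <- pmin(base[1, ], base[2, ]); hi <- pmax(base[1, ], base[2, ])
  for (m in 3:8) {
    conc <- unlist(panel[m, wine_chemicals])
    expect_true(all(conc >= lo - 1e-9 & conc <= hi + 1e-9))
  }
})

test_that("sweet-cluster taste scores sit strictly above dry-cluster scores", {
  panel <- generate_panel(23, 0, seed = 11)
  sc <- taste_scores(panel)
  sweet <- panel$cluster == "sweet"
  expect_gt(min(sc$sweetness[sweet]), max(sc$sweetness[!sweet]))
  expect_gt(min(sc$sourness[sweet]), max(sc$sourness[!sweet]))
  rng <- rbind(
    sweetness = c(1029, 123019), sourness = c(36, 478),
    astringency = c(72, 573))
  expect_true(all(sc$sweetness >= rng["sweetness", 1] &
                    sc$sweetness <= rng["sweetness", 2]))
  expect_true(all(sc$sourness >= rng["sourness", 1] - 1e-9 &
                    sc$sourness <= rng["sourness", 2] + 1e-9))
  expect_true(all(sc$astringency >= rng["astringency", 1] &
                    sc$astringency <= rng["astringency", 2]))
})

test_that("mixture scores lie between parent scores at zero noise", {
  panel <- generate_panel(2, 4, seed = 13)
  sc <- taste_scores(panel)
  for (col in c("sweetness", "sourness", "astringency")) {
    lo <- min(sc[[col]][1:2]); hi <- max(sc[[col]][1:2])
    expect_true(all(sc[[col]][3:6] >= lo - 1e-9 & sc[[col]][3:6] <= hi + 1e-9))
  }
})

test_that("colour response follows the saturating dose-response model", {
  m <- tiny_dye_model()
  expect_equal(simulate_color_response(zero_profile(), m, noise_sd = 0),
               matrix(0, 2, 3, dimnames = list(c("dyeA", "dyeB"),
                                               c("R", "G", "B"))))
  # at conc = K the Langmuir term is exactly 1/2
  p <- zero_profile(); p["glucose"] <- 1000
  d <- simulate_color_response(p, m, noise_sd = 0)
  expect_equal(d["dyeA", ], c(R = 5, G = -10, B = 15))
  expect_equal(d["dyeB", ], c(R = 0, G = 0, B = 0))
  # saturation limit: delta approaches the sensitivity column
  p["glucose"] <- 1e12
  d <- simulate_color_response(p, m, noise_sd = 0)
  expect_equal(unname(d["dyeA", ]), c(10, -20, 30), tolerance = 1e-6)

  expect_error(simulate_color_response(c(unobtainium = 5), m),
               "unobtainium")
  expect_error(simulate_color_response(p, m, noise_sd = -1), "noise_sd")

  # seeded determinism of the noisy response
  n1 <- simulate_color_response(p, m, noise_sd = 2, seed = 5)
  n2 <- simulate_color_response(p, m, noise_sd = 2, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, simulate_color_response(p, m, noise_sd = 2,
                                                     seed = 6)))
})

test_that("rendered image pairs carry exact well colours at zero pixel noise", {
  m <- default_dye_model()
  deltas <- matrix(seq(-20, 26, by = 2), 8, 3)
  layout <- well_layout()
  pair <- render_image_pair(deltas, m, pixel_noise_sd = 0, layout = layout)
  expect_identical(dim(pair$before), dim(pair$after))
  expect_equal(pair$truth_delta, deltas)
  expect_false(any(pair$clipped))

  feats <- extract_features(pair$before, pair$after, layout)
  expect_equal(unname(feats), as.numeric(t(deltas)))

  # zero delta means identical rasters
  still <- render_image_pair(matrix(0, 8, 3), m, pixel_noise_sd = 0)
  expect_identical(still$before, still$after)
})

test_that("well means under pixel noise stay within three standard errors", {
  m <- default_dye_model()
  deltas <- matrix(5, 8, 3)
  layout <- well_layout(radius = 20)
  pair <- render_image_pair(deltas, m, pixel_noise_sd = 2, seed = 21,
                            layout = layout)
  # >= 1000 pixels per full well: se of the mean <= 2/sqrt(1000)
  feats <- extract_features(pair$before, pair$after, layout,
                            inner_fraction = 1)
  expect_true(all(abs(feats - as.numeric(t(deltas))) < 0.2))
})

test_that("out-of-range colour changes are clipped and flagged", {
  m <- default_dye_model()
  deltas <- matrix(0, 8, 3); deltas[1, 1] <- 500
  expect_warning(pair <- render_image_pair(deltas, m), "clip")
  expect_true(pair$clipped[1])
  expect_false(any(pair$clipped[-1]))
  expect_lte(max(pair$after), 255)
  # ground truth keeps the unclipped value
  expect_equal(pair$truth_delta[1, 1], 500)
})

test_that("simulated spectra are non-negative, baseline at zero conc, monotone in conc", {
  m <- tiny_dye_model()
  s0 <- simulate_spectrum("dyeA", "glucose", 0, m)
  expect_length(s0, 381)
  expect_true(all(s0 >= 0))
  # baseline: single Gaussian peak, mode at its centre
  expect_equal(unname(s0["550"]), 1)
  expect_equal(max(s0), unname(s0["550"]))
  expect_equal(unname(s0["400"]), exp(-(150^2) / (2 * 30^2)), tolerance = 1e-12)

  s1 <- simulate_spectrum("dyeA", "glucose", 500, m)
  s2 <- simulate_spectrum("dyeA", "glucose", 5000, m)
  expect_true(all(s2 >= s1 & s1 >= s0))

  expect_error(simulate_spectrum("nope", "glucose", 1, m), "nope")
  expect_error(simulate_spectrum("dyeA", "glucose", -1, m), "conc")
})

test_that("the default dye model is valid and reproducible", {
  m1 <- default_dye_model(); m2 <- default_dye_model()
  expect_identical(m1, m2)
  expect_equal(dim(m1$sensitivity), c(8, 3, 11))
  rows <- apply(m1$sensitivity, 1, paste, collapse = ",")
  expect_false(anyDuplicated(rows) > 0)
  expect_true(all(m1$half_saturation > 0))
})

test_that("panel and dye model survive CSV/YAML round trips", {
  panel <- generate_panel(5, 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_equal(as.matrix(back[, wine_chemicals]),
               as.matrix(panel[, wine_chemicals]), tolerance = 1e-12)

  m <- default_dye_model()
  y <- withr::local_tempfile(fileext = ".yaml")
  write_dye_model(m, y)
  m2 <- read_dye_model(y)
  expect_equal(m2$sensitivity, m$sensitivity, tolerance = 1e-10)
  expect_equal(m2$half_saturation, m$half_saturation, tolerance = 1e-10)
  expect_equal(m2$baseline_rgb, m$baseline_rgb)
})
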