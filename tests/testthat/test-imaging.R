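test_that("spot detection finds constructed geometry", {
  # one synthetic ellipse of known axes inside a cytoplasm
  img_m <- matrix(10, 200, 200)
  xs <- matrix(seq_len(200), 200, 200)
  ys <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  ell <- ((xs - 100) / 30)^2 + ((ys - 100) / 6)^2 <= 1
  img_m[ell] <- 200
  img <- cell_image(list(nucleus = matrix(c(100, rep(0, 200 * 200 - 1)),
                                          200, 200),
                         green = img_m, red = img_m))
  masks <- structure(list(nucleus = matrix(FALSE, 200, 200),
                          cytoplasm = matrix(TRUE, 200, 200),
                          spots = matrix(0L, 200, 200),
                          aggregates = matrix(0L, 200, 200)),
                     class = "segmentation_masks")
  det <- detect_spots(img, "green", masks)
  expect_equal(nrow(det$spots), 1L)
  expect_equal(det$spots$ratio, 6 / 30, tolerance = 0.05)
  expect_equal(det$spots$area, sum(ell), tolerance = 0.05)

  # two disjoint blobs give two labels
  img2 <- matrix(10, 200, 200)
  img2[20:30, 20:30] <- 300
  img2[120:130, 150:160] <- 300
  det2 <- detect_spots(cell_image(list(nucleus = img$channels$nucleus,
                                       green = img2, red = img2)),
                       "green", masks)
  expect_equal(nrow(det2$spots), 2L)

  # blank channel: zero spots
  blank <- cell_image(list(nucleus = img$channels$nucleus,
                           green = matrix(10, 200, 200),
                           red = matrix(10, 200, 200)))
  expect_equal(nrow(detect_spots(blank, "green", masks)$spots), 0L)

  # empty cytoplasm is a segmentation error
  empty <- masks; empty$cytoplasm[] <- FALSE
  expect_error(detect_spots(img, "green", empty), "cytoplasm")
})

test_that("spot filters apply strict thresholds", {
  spots <- data.frame(label = 1:3, area = c(10, 50, 400),
                      ratio = c(0.2, 0.2, 0.2))
  kept <- filter_spots(spots)
  expect_equal(kept$label, 2L)

  # boundary semantics: exactly 20 px^2 is removed
  expect_equal(nrow(filter_spots(data.frame(label = 1, area = 20,
                                            ratio = 0.2))), 0L)
  expect_equal(nrow(filter_spots(data.frame(label = 1, area = 300,
                                            ratio = 0.2))), 0L)
  expect_equal(nrow(filter_spots(data.frame(label = 1, area = 50,
                                            ratio = 0.3))), 0L)

  # subset of input and idempotent
  set.seed(4)
  many <- data.frame(label = 1:50, area = runif(50, 0, 500),
                     ratio = runif(50))
  once <- filter_spots(many)
  expect_true(all(once$label %in% many$label))
  expect_identical(filter_spots(once), once)
  expect_equal(nrow(filter_spots(many[0, ])), 0L)
})

test_that("enrichment is the spot/cytoplasm mean ratio with a guard", {
  expect_equal(enrichment(100, 100), 1)
  expect_equal(enrichment(200, 100), 2)
  expect_error(enrichment(200, 0), "positive")

  # constructed image: spot mean 200, cytoplasm mean 100
  img_m <- matrix(100, 64, 64)
  img_m[10:19, 30:31] <- 200
  img <- cell_image(list(nucleus = matrix(0, 64, 64),
                         green = img_m, red = img_m))
  masks <- structure(list(nucleus = matrix(FALSE, 64, 64),
                          cytoplasm = matrix(TRUE, 64, 64),
                          spots = matrix(0L, 64, 64),
                          aggregates = matrix(0L, 64, 64)),
                     class = "segmentation_masks")
  det <- detect_spots(img, "green", masks)
  expect_equal(det$spots$enr_green, 2, tolerance = 1e-12)
})

test_that("mixing score is the regression R2 with guards", {
  # perfect linearity
  sp <- data.frame(enr_red = seq(1, 3, length.out = 40))
  sp$enr_green <- 2 * sp$enr_red
  ms <- mixing_score(sp)
  expect_equal(ms$r_squared, 1)
  expect_equal(ms$slope, 2)

  # independent channels: R2 small (E[R2] ~ 1/(n-1))
  set.seed(6)
  ind <- data.frame(enr_red = rnorm(200, 2.5, .5),
                    enr_green = rnorm(200, 2.5, .5))
  expect_lte(mixing_score(ind)$r_squared, 0.05)

  # rho = 0.8 bivariate: R2 ~ rho^2 = 0.64 within sampling error
  z1 <- rnorm(500); z2 <- rnorm(500)
  bv <- data.frame(enr_red = 2.5 + .5 * z1,
                   enr_green = 2.5 + .5 * (.8 * z1 + .6 * z2))
  expect_equal(mixing_score(bv)$r_squared, 0.64, tolerance = 0.08)

  # affine-invariance of R2
  aff <- bv
  aff$enr_green <- 3 * aff$enr_green - 1
  aff$enr_red <- 0.5 * aff$enr_red + 2
  expect_equal(mixing_score(aff)$r_squared, mixing_score(bv)$r_squared,
               tolerance = 1e-12)

  expect_equal(mixing_score(sp[1:3, ], min_spots = 10)$status,
               "insufficient_spots")
  flat <- data.frame(enr_red = rep(2, 20), enr_green = rnorm(20))
  expect_equal(mixing_score(flat)$status, "undefined")
})

test_that("aggregate scores match the constructed fixture", {
  fx <- aggregate_fixture()
  sc <- aggregate_scores(fx$image, fx$masks, channel = "green",
                         fish_channel = "fish")
  expect_equal(sc$relative_intensity, fx$expected, tolerance = 1e-6)
  # uniform FISH channel: enrichment exactly 1
  expect_equal(sc$mrna_enrichment, 1, tolerance = 1e-12)
  expect_equal(sc$n_aggregates, 1L)

  # no aggregates: relative intensity 0
  none <- fx$masks; none$aggregates[] <- 0L
  sc0 <- aggregate_scores(fx$image, none)
  expect_equal(sc0$relative_intensity, 0)

  # relative intensity stays in [0, 1] under random fixtures
  set.seed(13)
  for (i in 1:5) {
    ch <- matrix(runif(100 * 100, 5, 50), 100, 100)
    m <- fx$masks
    sc_r <- aggregate_scores(cell_image(list(green = ch)), m)
    expect_gte(sc_r$relative_intensity, 0)
    expect_lte(sc_r$relative_intensity, 1)
  }

  empty <- fx$masks; empty$nucleus[] <- FALSE
  expect_error(aggregate_scores(fx$image, empty), "nucleus")
})

test_that("generated aggregate images score near their construction", {
  img <- gen_images(image_scenario(n_aggregates = 4, noise_sd = 0,
                                   seed = 17))
  masks <- segment_cell(img, aggregate_channel = "green")
  sc <- aggregate_scores(img, masks, channel = "green",
                         fish_channel = "fish")
  expect_equal(sc$n_aggregates, 4L)
  tr <- attr(img, "truth")$aggregates
  # hand-computable ratio on the rendered geometry: aggregates cover
  # n * pi r^2 pixels at (contrast-1) * base above background
  r_a <- tr$radius[1]
  n_agg_px <- 4 * sum(outer(-r_a:r_a, -r_a:r_a,
                            function(a, b) a^2 + b^2 <= r_a^2))
  nuc_px <- sum(masks$nucleus)
  base <- 200                      # nuclear baseline = 2 x cytoplasm
  expected <- n_agg_px * (tr$contrast[1] - 1) * base /
    (nuc_px * base + n_agg_px * (tr$contrast[1] - 1) * base)
  expect_equal(sc$relative_intensity, expected, tolerance = 0.1)
  expect_gt(sc$mrna_enrichment, 1.3)
})

test_that("end-to-end mixing recovery matches the drawn correlation", {
  # single-seed sanity at the extremes; the multi-rho sweep lives in the
  # acceptance suite
  r2_perfect <- mixing_pipeline(gen_images(
    image_scenario(rho = 1, noise_sd = 0, seed = 2)))$r_squared
  expect_equal(r2_perfect, 1, tolerance = 1e-6)

  img <- gen_images(image_scenario(rho = 0.8, seed = 3))
  truth <- attr(img, "truth")$spots
  ms <- mixing_pipeline(img)
  expect_equal(ms$status, "ok")
  expect_gt(ms$n, 80)
  sample_r2 <- cor(truth$enr_green, truth$enr_red)^2
  expect_equal(ms$r_squared, sample_r2, tolerance = 0.05)
})
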