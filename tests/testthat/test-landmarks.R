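test_that("midline fitting recovers vertical lines, with and without offset", {
  cfg <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 0, rx = 10, ry = 0))
  ax <- fit_midline(cfg)
  expect_equal(abs(ax$direction), c(0, 1), tolerance = 1e-12)
  expect_equal(abs(ax$normal), c(1, 0), tolerance = 1e-12)

  cfg2 <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 0, rx = 10, ry = 0),
                        midline_x = 3)
  ax2 <- fit_midline(cfg2)
  expect_equal(ax2$point[1], 3, tolerance = 1e-12)

  # noisy near-collinear points stay within angular tolerance
  set.seed(1)
  pts <- rbind(data.frame(name = c("a_l", "a_r"), x = c(-10, 10), y = 0),
               data.frame(name = paste0("m", 1:20), x = rnorm(20, 0, 0.01),
                          y = seq(-10, 10, length.out = 20)))
  cfg3 <- landmark_config(pts, data.frame(left = "a_l", right = "a_r"),
                          paste0("m", 1:20))
  ax3 <- fit_midline(cfg3)
  expect_lt(acos(min(abs(ax3$direction[2]), 1)), 0.01)

  expect_error(fit_midline(landmark_config(
    data.frame(name = c("a_l", "a_r", "m1", "m2"),
               x = c(-1, 1, 0, 0), y = c(0, 0, 0, 1)),
    data.frame(left = "a_l", right = "a_r"), "m1")), "midline")
})

test_that("horizontal FA aggregates absolute left-right distance differences", {
  sym <- toy_config_2d(data.frame(name = c("a", "b"),
                                  lx = c(-10, -5), ly = c(0, 4),
                                  rx = c(10, 5), ry = c(0, 4)))
  expect_equal(horizontal_fa(sym), 0, tolerance = 1e-12)

  one <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 0, rx = 12, ry = 0))
  expect_equal(horizontal_fa(one), 2, tolerance = 1e-12)

  three <- toy_config_2d(data.frame(name = c("a", "b", "c"),
                                    lx = c(-10, -5, -7), ly = c(0, 3, -3),
                                    rx = c(11, 5, 9), ry = c(0, 3, -3)))
  expect_equal(horizontal_fa(three), 1 + 0 + 2, tolerance = 1e-12)
})

test_that("vertical FA sums absolute vertical offsets within pairs", {
  sym <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 2, rx = 10, ry = 2))
  expect_equal(vertical_fa(sym), 0, tolerance = 1e-12)

  one <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 1.5, rx = 10, ry = 0))
  expect_equal(vertical_fa(one), 1.5, tolerance = 1e-12)

  two <- toy_config_2d(data.frame(name = c("a", "b"),
                                  lx = c(-10, -6), ly = c(0.5, 0.25),
                                  rx = c(10, 6), ry = c(0, 0)))
  expect_equal(vertical_fa(two), 0.75, tolerance = 1e-12)
})

test_that("comprehensive FA is the distance to the reflected counterpart", {
  one <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 0, rx = 11, ry = 0))
  expect_equal(comprehensive_fa(one), 1, tolerance = 1e-12)

  sym <- toy_config_2d(data.frame(name = "a", lx = -8, ly = 1, rx = 8, ry = 1))
  expect_equal(comprehensive_fa(sym), 0, tolerance = 1e-12)

  # per-pair identity: comprehensive^2 = hfa^2 + vfa^2 for one pair with an
  # axis-aligned midline
  cfg <- toy_config_2d(data.frame(name = "a", lx = -10, ly = 2, rx = 11, ry = 0.5))
  expect_equal(comprehensive_fa(cfg)^2,
               horizontal_fa(cfg)^2 + vertical_fa(cfg)^2, tolerance = 1e-12)

  expect_equal(comprehensive_fa(one, normalize_by = 2), 0.5, tolerance = 1e-12)
})

test_that("landmark indices are rigid-invariant and scale linearly", {
  cfg <- toy_config_2d(data.frame(name = c("a", "b", "c"),
                                  lx = c(-10, -5, -7), ly = c(1, 3, -3),
                                  rx = c(11, 5, 9), ry = c(0, 3.5, -3)))
  base <- landmark_fa_indices(cfg)
  # rotate + translate the whole configuration
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  pts <- cfg$points
  xy <- as.matrix(pts[, c("x", "y")]) %*% t(R)
  pts$x <- xy[, 1] + 13; pts$y <- xy[, 2] - 4
  moved <- landmark_config(pts, cfg$pairs, cfg$midline)
  rot <- landmark_fa_indices(moved)
  expect_equal(rot$hfa, base$hfa, tolerance = 1e-9)
  expect_equal(rot$vfa, base$vfa, tolerance = 1e-9)
  expect_equal(rot$comprehensive, base$comprehensive, tolerance = 1e-9)

  # uniform scaling scales the unnormalized indices linearly
  pts2 <- cfg$points
  pts2$x <- pts2$x * 2.5; pts2$y <- pts2$y * 2.5
  scaled <- landmark_fa_indices(landmark_config(pts2, cfg$pairs, cfg$midline))
  expect_equal(scaled$hfa, 2.5 * base$hfa, tolerance = 1e-9)
  expect_equal(scaled$vfa, 2.5 * base$vfa, tolerance = 1e-9)
  expect_equal(scaled$comprehensive, 2.5 * base$comprehensive, tolerance = 1e-9)
})

test_that("3D landmark FA works with a sagittal-plane midline", {
  scheme <- data.frame(left = c("a_l", "b_l"), right = c("a_r", "b_r"))
  pts <- data.frame(
    name = c("a_l", "a_r", "b_l", "b_r", "m1", "m2"),
    x = c(-10, 10, -6, 7, 0, 0),
    y = c(0, 0, 5, 5, -8, 8),
    z = c(2, 2, 1, 1, 3, 3))
  cfg <- landmark_config(pts, scheme, c("m1", "m2"))
  expect_equal(horizontal_fa(cfg), 1, tolerance = 1e-9)
  expect_equal(vertical_fa(cfg), 0, tolerance = 1e-9)
  expect_equal(comprehensive_fa(cfg), 1, tolerance = 1e-9)
})

test_that("landmark CSV reader works with the default scheme", {
  scheme <- default_landmark_scheme()
  nm <- c(scheme$pairs$left, scheme$pairs$right, scheme$midline)
  set.seed(3)
  df <- data.frame(name = nm, x = rnorm(17), y = rnorm(17))
  df$x[df$name %in% scheme$midline] <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  cfg <- read_landmarks(path)
  expect_s3_class(cfg, "landmark_config")
  expect_equal(nrow(cfg$pairs), 7L)
  expect_gte(horizontal_fa(cfg), 0)
})
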