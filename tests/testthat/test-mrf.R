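# Hand-built observation stacks for controlled MRF behaviour.
toy_obs <- function(intensity, fg_mean, bg_mean, fg_var = 1, bg_var = 1) {
  zero <- matrix(0, nrow(intensity), ncol(intensity))
  structure(list(
    planes = list(intensity = intensity, structural = zero, stochastic = zero),
    fg = tibble::tibble(plane = c("intensity", "structural", "stochastic"),
                        mean = c(fg_mean, 0, 0), variance = c(fg_var, 1, 1)),
    bg = tibble::tibble(plane = c("intensity", "structural", "stochastic"),
                        mean = c(bg_mean, 0, 0), variance = c(bg_var, 1, 1)),
    mode = "nucleus", dim = dim(intensity)),
    class = "observation_stack")
}

test_that("beta = 0 reproduces the per-pixel maximum-likelihood labelling", {
  set.seed(2)
  intensity <- matrix(rnorm(32 * 32, 50, 30), 32)
  obs <- toy_obs(intensity, fg_mean = 30, bg_mean = 80, fg_var = 100,
                 bg_var = 100)
  lf <- icm_map_estimate(obs, beta = 0)
  ml <- (intensity - 30)^2 / 200 < (intensity - 80)^2 / 200
  expect_identical(lf$labels, matrix(as.integer(ml), 32, 32))
})

test_that("noise-free two-class images are recovered exactly for any beta", {
  truth <- make_disc(40, 20, 20, 10)
  intensity <- ifelse(truth, 30, 80)
  obs <- toy_obs(intensity, 30, 80)
  for (beta in c(0, 0.5, 1.5, 4)) {
    lf <- icm_map_estimate(obs, beta = beta)
    expect_identical(lf$labels == 1L, truth)
  }
})

test_that("ICM energy is non-increasing and improves on the ML start", {
  set.seed(7)
  truth <- make_rect(32, 8, 24, 8, 24)
  intensity <- ifelse(truth, 40, 60) + matrix(rnorm(32 * 32, 0, 12), 32)
  obs <- toy_obs(intensity, 40, 60, fg_var = 144, bg_var = 144)
  lf <- icm_map_estimate(obs, beta = 1.5, max_sweeps = 20)
  expect_true(all(diff(lf$energy) <= 1e-9))
  ml <- icm_map_estimate(obs, beta = 0)
  acc <- function(lab) mean((lab == 1L) == truth)
  expect_gte(acc(lf$labels), acc(ml$labels))
  # energy oracle: recompute both labelings' global energy directly (the
  # texture planes have identical class parameters here, so their term is
  # label-independent and drops out of the comparison)
  energy_of <- function(lab) {
    nll <- function(x, m, v) 0.5 * log(2 * pi * v) + (x - m)^2 / (2 * v)
    e <- sum(ifelse(lab == 1, nll(intensity, 40, 144), nll(intensity, 60, 144)))
    nr <- nrow(lab); nc <- ncol(lab)
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r1 <- 1:(nr - d[1]); c1 <- max(1, 1 - d[2]):min(nc, nc - d[2])
      e <- e + 1.5 * sum(lab[r1, c1] != lab[r1 + d[1], c1 + d[2]])
    }
    e
  }
  expect_lte(energy_of(lf$labels), energy_of(ml$labels))
})

test_that("label-flip symmetry: swapping class parameters inverts the mask", {
  truth <- make_disc(30, 15, 15, 8)
  intensity <- ifelse(truth, 30, 80)
  obs <- toy_obs(intensity, 30, 80)
  swapped <- obs
  swapped$fg <- obs$bg; swapped$bg <- obs$fg
  a <- icm_map_estimate(obs, beta = 1)$labels
  b <- icm_map_estimate(swapped, beta = 1)$labels
  expect_identical(a, 1L - b)
})

test_that("icm rejects invalid sweep counts and betas", {
  obs <- toy_obs(matrix(c(1, 2, 50, 51), 2), 1, 50)
  expect_error(icm_map_estimate(obs, max_sweeps = 0), "max_sweeps")
  expect_error(icm_map_estimate(obs, beta = -1), "beta")
})

test_that("build_observations wires modes, textures and class statistics", {
  sm <- generate_smear(smear_spec(image_size = 96, n_leukocytes = 1,
                                  n_erythrocytes = 2, seed = 3))
  lab <- rgb_to_lab(sm$image)
  fields <- wold_decompose(lab$L)
  gn <- cluster_channel(lab$L, k = 2)
  gn$foreground_group <- select_foreground_group(gn, "nucleus")
  on <- suppressWarnings(build_observations(lab, fields, gn, "nucleus"))
  gc <- cluster_channel(lab$b, k = 3)
  gc$foreground_group <- select_foreground_group(gc, "cell")
  oc <- suppressWarnings(build_observations(lab, fields, gc, "cell"))
  expect_identical(on$planes$intensity, lab$L)
  expect_identical(oc$planes$intensity, lab$b)
  expect_false(identical(on$planes$intensity, oc$planes$intensity))
  expect_true(all(on$fg$variance > 0) && all(on$bg$variance > 0))

  # textured foreground on flat background raises structural energy inside
  n <- 64
  tex <- matrix(0, n, n)
  fgm <- make_rect(n, 17, 48, 17, 48)
  tex[fgm] <- (30 * cos(2 * pi * 8 * col(tex) / n))[fgm]
  lab2 <- list(L = tex + 50, a = tex * 0, b = tex * 0, dim = c(n, n))
  class(lab2) <- "lab_image"
  f2 <- wold_decompose(lab2$L)
  g2 <- cluster_channel(lab2$L, k = 2)
  g2$foreground_group <- 1L
  o2 <- suppressWarnings(build_observations(lab2, f2, g2, "nucleus"))
  expect_gt(mean(o2$planes$structural[fgm]), mean(o2$planes$structural[!fgm]))
})

test_that("zero-variance classes are floored with a warning", {
  lab <- list(L = matrix(c(rep(10, 32), rep(90, 32)), 8), a = matrix(0, 8, 8),
              b = matrix(0, 8, 8), dim = c(8, 8))
  class(lab) <- "lab_image"
  fields <- wold_decompose(lab$L)
  g <- cluster_channel(lab$L, k = 2)
  g$foreground_group <- 1L
  w <- testthat::capture_warnings(
    obs <- build_observations(lab, fields, g, "nucleus"))
  expect_true(any(grepl("floored", w)))
  expect_true(all(obs$fg$variance >= 1e-6))
})

test_that("segmentation metrics follow the predicted-count definitions", {
  truth <- matrix(FALSE, 4, 4); truth[, 1:2] <- TRUE  # left 8 pixels
  pred <- matrix(FALSE, 4, 4); pred[1:2, ] <- TRUE    # top 8 pixels
  s <- score_segmentation(pred, truth)
  expect_equal(s$precision, 50)
  expect_equal(s$fp_rate, 50)
  expect_equal(s$fn_rate, 50)
  expect_equal(s$precision + s$fp_rate, 100)

  perfect <- score_segmentation(truth, truth)
  expect_equal(unlist(perfect), c(precision = 100, fp_rate = 0, fn_rate = 0))

  expect_warning(none <- score_segmentation(matrix(FALSE, 4, 4), truth),
                 "undefined")
  expect_true(is.na(none$precision))
  expect_equal(none$fn_rate, 100 * 8 / 16)
})

test_that("end-to-end segmentation handles plain and empty scenes", {
  sm <- generate_smear(smear_spec(image_size = 128, n_leukocytes = 2,
                                  n_erythrocytes = 4, noise_sd = 0, seed = 12))
  nm <- suppressWarnings(segment_image(sm$image, "nucleus"))
  s <- score_segmentation(nm, sm$truth$nucleus_mask > 0)
  expect_gte(s$precision, 99)

  # all-background image: constant plane is degenerate for clustering
  flat <- array(rep(c(200, 180, 190), each = 64 * 64), dim = c(64, 64, 3))
  expect_error(suppressWarnings(segment_image(flat, "nucleus")), "degenerate")
})
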