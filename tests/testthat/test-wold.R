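sinusoid_plane <- function(n, freq, A, axis = "col") {
  m <- matrix(0, n, n)
  if (axis == "col") A * cos(2 * pi * freq * col(m) / n)
  else A * cos(2 * pi * freq * row(m) / n)
}

test_that("harmonic peaks: constant, strong and sub-threshold sinusoids", {
  expect_equal(nrow(detect_harmonic_peaks(texture_spectrum(matrix(3, 32, 32)))), 0)

  ch <- sinusoid_plane(64, 4, 20)
  pk <- detect_harmonic_peaks(texture_spectrum(ch))
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$v, c(4, -4))
  expect_equal(pk$u, c(0, 0))
  expect_equal(pk$amplitude, c(20, 20), tolerance = 1e-9)

  weak <- sinusoid_plane(64, 4, 5)
  expect_equal(nrow(detect_harmonic_peaks(texture_spectrum(weak))), 0)
})

test_that("harmonic field reconstruction is analytic for pure sinusoids", {
  ch <- sinusoid_plane(64, 5, 30)
  sp <- texture_spectrum(ch)
  hf <- extract_harmonic_field(sp, detect_harmonic_peaks(sp))
  expect_gt(cor(as.vector(hf$field), as.vector(ch)), 0.999)

  expect_equal(extract_harmonic_field(sp, detect_harmonic_peaks(sp, 1e9))$field,
               matrix(0, 64, 64))

  two <- sinusoid_plane(64, 3, 25) + sinusoid_plane(64, 9, 15, axis = "row")
  sp2 <- texture_spectrum(two)
  pk2 <- detect_harmonic_peaks(sp2)
  expect_setequal(unique(abs(pk2$v[pk2$u == 0])), 3)
  expect_setequal(unique(abs(pk2$u[pk2$v == 0])), 9)
  hf2 <- extract_harmonic_field(sp2, pk2)
  resid <- two - mean(two) - hf2$field
  expect_lt(sum(resid^2) / sum((two - mean(two))^2), 0.01)
})

test_that("peak detection agrees with an exhaustive spectrum scan", {
  set.seed(21)
  for (t in 1:5) {
    plane <- matrix(rnorm(32 * 32, 0, 2), 32) +
      sinusoid_plane(32, sample(3:10, 1), runif(1, 12, 40)) +
      sinusoid_plane(32, sample(3:10, 1), runif(1, 12, 40), axis = "row")
    sp <- texture_spectrum(plane)
    pk <- detect_harmonic_peaks(sp, amplitude_threshold = 10)
    hits <- oracle_scan_peaks(sp$amplitude, 10)
    # every implementation peak is an oracle hit, and every oracle hit is
    # covered by an accepted peak or suppressed by one within the
    # min-separation radius of a stronger accepted peak
    expect_true(all(paste(pk$i, pk$j) %in% paste(hits[, 1], hits[, 2])))
    for (r in seq_len(nrow(hits))) {
      d <- pmin(abs(pk$i - hits[r, 1]), 32 - abs(pk$i - hits[r, 1]))
      e <- pmin(abs(pk$j - hits[r, 2]), 32 - abs(pk$j - hits[r, 2]))
      expect_true(any(pmax(d, e) < 2))
    }
  }
})

test_that("threshold monotonicity: higher thresholds never add peaks", {
  set.seed(8)
  plane <- matrix(rnorm(64 * 64, 0, 3), 64) + sinusoid_plane(64, 6, 25) +
    sinusoid_plane(64, 11, 14, axis = "row")
  sp <- texture_spectrum(plane)
  counts <- vapply(c(2, 5, 10, 20, 30),
                   function(th) nrow(detect_harmonic_peaks(sp, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("evanescent lines: directional energy, white noise, empty residual", {
  n <- 64
  g <- matrix(0, n, n)
  for (f in 3:10) g <- g + 8 * cos(2 * pi * f * row(g) / n + f)
  ev <- detect_evanescent_lines(texture_spectrum(g), amplitude_threshold = 5)
  expect_equal(nrow(ev$lines), 1)
  # all supporting bins lie on the v = 0 spectral line (u axis)
  expect_true(all(abs(oracle_signed_freq(ev$bins$j, n)) <= 1))

  set.seed(4)
  wn <- matrix(rnorm(n * n, 0, 4), n, n)
  spw <- texture_spectrum(wn)
  # isotropic spectrum: threshold at the top tail, no direction dominates
  evw <- detect_evanescent_lines(spw,
                                 amplitude_threshold = quantile(spw$amplitude,
                                                                0.95))
  tot <- sum(spw$amplitude^2)
  if (nrow(evw$lines)) {
    for (l in evw$lines$line) {
      bins <- evw$bins[evw$bins$line == l, ]
      expect_lt(sum(spw$amplitude[cbind(bins$i, bins$j)]^2) / tot, 0.05)
    }
  }

  ev0 <- detect_evanescent_lines(texture_spectrum(matrix(1, 32, 32)))
  expect_equal(nrow(ev0$lines), 0)
})

test_that("decomposition is additive with disjoint support and conserves energy", {
  set.seed(14)
  for (t in 1:4) {
    plane <- matrix(rnorm(48 * 48, 100, 8), 48) + sinusoid_plane(48, 5, 20)
    w <- wold_decompose(plane)
    recon <- w$harmonic + w$evanescent + w$stochastic + w$mean
    expect_lt(max(abs(recon - plane)), 1e-6)
    # disjoint frequency support
    if (nrow(w$harmonic_params) && nrow(w$evanescent_bins))
      expect_equal(length(intersect(
        paste(w$harmonic_params$i, w$harmonic_params$j),
        paste(w$evanescent_bins$i, w$evanescent_bins$j))), 0)
    # Parseval: component energies add to the centred input energy
    e_in <- sum((plane - mean(plane))^2)
    e_parts <- sum(w$harmonic^2) + sum(w$evanescent^2) + sum(w$stochastic^2)
    expect_equal(e_parts, e_in, tolerance = 1e-6)
  }
})

test_that("pure sinusoid is captured structurally; noise stays stochastic", {
  ch <- sinusoid_plane(64, 7, 25)
  w <- wold_decompose(ch)
  expect_lt(sum(w$stochastic^2) / sum((ch - mean(ch))^2), 0.01)

  set.seed(31)
  fracs <- vapply(1:20, function(s) {
    wn <- matrix(rnorm(32 * 32, 0, 5), 32)
    w <- wold_decompose(wn)
    (sum(w$harmonic^2) + sum(w$evanescent^2)) / sum((wn - mean(wn))^2)
  }, numeric(1))
  expect_lt(max(fracs), 0.10)

  wc <- wold_decompose(matrix(9, 32, 32))
  expect_equal(nrow(wc$harmonic_params), 0)
  expect_equal(nrow(wc$evanescent_lines), 0)
  expect_equal(max(abs(wc$stochastic)), 0)
  expect_equal(wc$mean, 9)
})
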