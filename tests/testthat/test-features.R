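test_that("morphology matches closed forms for elementary shapes", {
  sq <- morphological_features(make_rect(20, 6, 15, 6, 15))
  expect_equal(unname(sq[c("area", "width", "length", "elongation", "extent",
                           "solidity", "euler_number", "convex_area")]),
               c(100, 10, 10, 1, 1, 1, 1, 100))

  ann <- make_disc(50, 25, 25, 15) & !make_disc(50, 25, 25, 6)
  expect_equal(unname(morphological_features(ann)["euler_number"]), 0)

  rect <- morphological_features(make_rect(40, 11, 30, 11, 20))
  expect_equal(unname(rect["elongation"]), 2)
  expect_equal(unname(rect["equiv_diameter"]), sqrt(4 * 200 / pi))
  expect_error(morphological_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("intensity statistics follow the population conventions", {
  s <- statistical_features(rep(7, 50))
  expect_equal(unname(s), c(7, 7, 0, 0, 350))

  s2 <- statistical_features(c(1, 2, 2, 3))
  expect_equal(unname(s2[c("mode", "mean", "variance", "sum")]), c(2, 2, 0.5, 8))
  expect_equal(unname(s2["sd"])^2, unname(s2["variance"]))

  expect_equal(unname(statistical_features(c(1, 1, 2, 2))["mode"]), 1)
})

test_that("GLCM statistics are exact on constructed patterns", {
  m <- matrix(TRUE, 4, 4)
  const <- glcm_features(matrix(100, 4, 4), m)
  expect_equal(unname(const[c("glcm_contrast", "glcm_homogeneity",
                              "glcm_energy", "glcm_entropy")]), c(0, 1, 1, 0))
  expect_true(is.na(const["glcm_correlation"]))

  # strict two-value column stripes: all (0,1) pairs at offset (0,1)
  stripes <- matrix(rep(c(0, 255), 8), 4, 4, byrow = TRUE)
  st <- glcm_features(stripes, m)
  expect_equal(unname(st["glcm_correlation"]), -1)

  # uniform GLCM over 4 entries -> entropy of 2 bits
  # pairs: (0,0) and (0,255) in row 1, (255,255) and (255,0) in row 2
  pat <- matrix(c(0, 0, 255, 255, 255, 0), 2, 3, byrow = TRUE)
  u <- glcm_features(pat, matrix(TRUE, 2, 3))
  expect_equal(unname(u["glcm_entropy"]), 2)
  expect_equal(unname(u["glcm_energy"]), 0.25)

  # hand-tabulated oracle on a small random patch
  set.seed(6)
  patch <- matrix(sample(0:255, 20, TRUE), 4, 5)
  g <- marrowdx:::glcm_matrix(patch, matrix(TRUE, 4, 5))
  q <- floor(patch / 8)
  counts <- matrix(0, 32, 32)
  for (r in 1:4) for (cc in 1:4) {
    counts[q[r, cc] + 1, q[r, cc + 1] + 1] <-
      counts[q[r, cc] + 1, q[r, cc + 1] + 1] + 1
    counts[q[r, cc + 1] + 1, q[r, cc] + 1] <-
      counts[q[r, cc + 1] + 1, q[r, cc] + 1] + 1
  }
  expect_equal(g, counts / sum(counts))
  expect_error(glcm_features(patch, matrix(FALSE, 4, 5)), "pairs")
})

test_that("eigen features are non-negative, sorted and capture rank", {
  base <- matrix(runif(12, 0, 255), 1)[rep(1, 8), ] * seq(0.5, 1.2, length.out = 8)
  mask <- matrix(TRUE, 8, 12)
  ev <- eigen_features(base, mask)
  expect_gt(ev[1] / sum(ev), 0.999)

  set.seed(17)
  for (t in 1:10) {
    crop <- matrix(runif(15 * 9, 0, 255), 15)
    ev <- eigen_features(crop, matrix(TRUE, 15, 9))
    expect_true(all(ev >= 0))
    expect_true(all(diff(ev) <= 1e-9))
  }
  expect_warning(one <- eigen_features(matrix(1:5, 1), matrix(TRUE, 1, 5)),
                 "degenerate")
  expect_equal(one, rep(0, 10))
})

test_that("size ratios follow the printed formulas", {
  nuc <- make_rect(30, 11, 16, 11, 20)   # 6x10 = 60 px
  cell <- make_rect(30, 9, 18, 9, 23)    # 10x15 = 150... use containing rect
  cell <- cell | nuc
  sr <- size_ratio_features(nuc, cell)
  na <- sum(nuc); ca <- sum(cell)
  expect_equal(unname(sr["n_cell_area"]), na / ca)
  expect_equal(unname(sr["n_cyto_area"]), na / (ca - na))

  expect_warning(deg <- size_ratio_features(nuc, nuc), "no cytoplasm")
  expect_true(is.na(deg["n_cyto_area"]))
  expect_equal(unname(deg["n_cell_area"]), 1)

  conc <- size_ratio_features(make_disc(60, 30, 30, 10), make_disc(60, 30, 30, 20))
  expect_equal(unname(conc["n_cell_perimeter"]), 0.5, tolerance = 0.05)
})

test_that("the extracted vector matches the schema and basic invariances", {
  sch <- mdx_feature_schema("expanded")
  expect_equal(nrow(sch), 232)
  expect_equal(nrow(mdx_feature_schema("table1")), 67)
  expect_equal(anyDuplicated(sch$column), 0)

  sm <- generate_smear(smear_spec(image_size = 96, n_leukocytes = 1,
                                  n_erythrocytes = 2, noise_sd = 0, seed = 4))
  cellm <- sm$truth$cell_mask == 1
  nucm <- sm$truth$nucleus_mask == 1
  fv <- extract_feature_vector(sm$image, cellm, nucm)
  expect_identical(names(fv), sch$column)
  expect_true(all(is.finite(fv)))
  # variance-SD consistency in every statistical block
  for (reg in c("nucleus", "cytoplasm", "cell")) for (ch in c("R", "G", "B", "gray"))
    expect_equal(fv[paste(reg, "sd", ch, sep = "_")]^2,
                 unname(fv[paste(reg, "variance", ch, sep = "_")]),
                 ignore_attr = TRUE)

  # translation invariance: shift the scene by (7, 5)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- array(85, dim = dim(sm$image))
  for (k in 1:3) img2[(1 + 7):96, (1 + 5):96, k] <-
    sm$image[1:(96 - 7), 1:(96 - 5), k]
  fv2 <- extract_feature_vector(img2, shift(cellm, 7, 5), shift(nucm, 7, 5))
  expect_equal(fv2, fv, tolerance = 1e-9)
})

test_that("doubling the scale scales area ~4x, perimeter ~2x, ratios stable", {
  d1 <- make_disc(70, 35, 35, 16)
  d2 <- make_disc(140, 70, 70, 32)
  f1 <- morphological_features(d1); f2 <- morphological_features(d2)
  expect_equal(unname(f2["area"] / f1["area"]), 4, tolerance = 0.05)
  expect_equal(unname(f2["perimeter"] / f1["perimeter"]), 2, tolerance = 0.05)
  for (nm in c("elongation", "solidity"))
    expect_equal(unname(f2[nm] / f1[nm]), 1, tolerance = 0.02)
  # extent of a digital disc converges to pi/4 only as O(1/r): the odd
  # bounding-box diameter (2r + 1) biases small radii, so allow 5%
  expect_equal(unname(f2["extent"] / f1["extent"]), 1, tolerance = 0.05)
})

test_that("extract_features emits one row per accepted record", {
  sm <- generate_smear(smear_spec(image_size = 150, n_leukocytes = 2,
                                  n_erythrocytes = 3, noise_sd = 0, seed = 6))
  lab <- rgb_to_lab(sm$image)
  nr <- identify_nuclei(compute_region_descriptors(sm$truth$nucleus_mask > 0,
                                                   lab$L))
  rec <- identify_cells(compute_region_descriptors(sm$truth$cell_mask > 0,
                                                   lab$L), nr, lab$L)
  ft <- extract_features(rec, sm$image)
  expect_equal(nrow(ft), 2)
  expect_equal(ncol(ft), 233)
  expect_true(all(is.finite(as.matrix(ft[, -1]))))
})
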