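# Synthetic Wright-stain smear generator. Scenes are composed directly in
# CIE L*a*b* so the stain's diagnostic orderings hold by construction:
# leukocyte nuclei are dark purple (low L*, negative b*), cytoplasm pale
# blue-lavender (higher L*, negative b*), erythrocytes orange/rose (positive
# b*), background near-white. Cells are randomly rotated ellipses with
# low-order Fourier boundary jitter; nuclei are smaller, slightly offset
# concentric shapes. Stain heterogeneity is a per-image additive Lab shift
# plus Gaussian sensor noise in RGB.

# Class-conditional rendering parameters. The subtype differences (cell size,
# nucleus/cell ratio, chroma, grain) are statistical knobs that make subtype
# separability controllable; no cytological realism is attempted.
subtype_render_params <- function() {
  tibble(
    class     = c("L1", "L2", "M2", "M3", "M5"),
    cell_r    = c(11, 14, 13, 15, 16),
    nuc_ratio = c(0.78, 0.68, 0.60, 0.55, 0.65),
    cyto_b    = c(-24, -26, -22, -20, -25),
    nuc_L     = c(36, 38, 40, 39, 37),
    grain_sd  = c(1.6, 1.8, 2.2, 2.6, 2.0),
    ecc       = c(1.05, 1.12, 1.10, 1.20, 1.15)
  )
}

#' Specify a synthetic smear
#'
#' Bundles and validates the generator's knobs. Defaults are the package's
#' reference imaging conditions: 256 x 256 crops, four leukocytes among a
#' dozen erythrocytes, mild sensor noise (sd 4 on the 8-bit scale) and a
#' random per-image stain shift.
#'
#' @param image_size Square image side in pixels.
#' @param n_leukocytes,n_erythrocytes Cell counts (non-negative).
#' @param overlap_fraction Proportion in `[0, 1]` of leukocytes forced to
#'   overlap another leukocyte by 10-30 percent of the smaller cell's area.
#' @param stain_shift Additive Lab offset `c(L, a, b)` applied to the whole
#'   image, or `NULL` to draw one from `N(0, c(3, 2, 2))` under `seed`.
#' @param noise_sd Per-channel Gaussian noise sd in 8-bit units.
#' @param seed Integer seed; identical spec + seed is bit-reproducible.
#' @return A `smear_spec` list.
#' @export
smear_spec <- function(image_size = 256, n_leukocytes = 4, n_erythrocytes = 12,
                       overlap_fraction = 0, stain_shift = NULL, noise_sd = 4,
                       seed = 1) {
  if (image_size < 32) abort("image_size must be at least 32")
  if (n_leukocytes < 0 || n_erythrocytes < 0) abort("cell counts must be >= 0")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort("overlap_fraction must be in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.null(stain_shift) && length(stain_shift) != 3)
    abort("stain_shift must be NULL or length-3 numeric")
  structure(list(image_size = image_size, n_leukocytes = n_leukocytes,
                 n_erythrocytes = n_erythrocytes,
                 overlap_fraction = overlap_fraction,
                 stain_shift = stain_shift, noise_sd = noise_sd, seed = seed),
            class = "smear_spec")
}

# A jittered-ellipse shape: random rotation, axis ratio, and low-order
# Fourier perturbation of the boundary radius.
make_shape <- function(r0, ecc, jitter_sd = 0.02) {
  list(a = r0 * sqrt(ecc), b = r0 / sqrt(ecc), rot = runif(1, 0, pi),
       ch = rnorm(4, 0, jitter_sd), ph = runif(4, 0, 2 * pi))
}

shape_radius <- function(shape, theta) {
  phi <- theta - shape$rot
  re <- shape$a * shape$b /
    sqrt((shape$b * cos(phi))^2 + (shape$a * sin(phi))^2)
  mod <- 1
  for (h in 2:5) mod <- mod + shape$ch[h - 1] * cos(h * theta + shape$ph[h - 1])
  re * pmax(mod, 0.5)
}

shape_rmax <- function(shape) max(shape$a, shape$b) * (1 + sum(abs(shape$ch)))

# Rasterize a shape at centre (cr, cc) into a full-frame logical matrix.
rasterize_shape <- function(shape, cr, cc, n) {
  rm <- ceiling(shape_rmax(shape)) + 1
  r1 <- max(1, floor(cr - rm)); r2 <- min(n, ceiling(cr + rm))
  c1 <- max(1, floor(cc - rm)); c2 <- min(n, ceiling(cc + rm))
  out <- matrix(FALSE, n, n)
  if (r2 < r1 || c2 < c1) return(out)
  rr <- r1:r2; cc2 <- c1:c2
  dr <- matrix(rr - cr, length(rr), length(cc2))
  dc <- matrix(cc2 - cc, length(rr), length(cc2), byrow = TRUE)
  th <- atan2(dc, dr)
  dist <- sqrt(dr^2 + dc^2)
  out[rr, cc2] <- dist <= shape_radius(shape, th)
  out
}

overlap_frac <- function(m1, m2) sum(m1 & m2) / min(sum(m1), sum(m2))

#' Generate a synthetic bone-marrow smear with ground truth
#'
#' Renders leukocytes (nucleus + cytoplasm), erythrocytes and textured
#' background under the conditions in `spec`, returning the 8-bit RGB raster
#' together with instance-labelled ground-truth masks, per-cell subtype
#' labels and the list of overlapping leukocyte pairs.
#'
#' Later-placed cells are drawn on top in overlap zones, except that a
#' nucleus is never painted over, so every nucleus instance stays wholly
#' inside its own cell instance and the masks agree with the rendered
#' geometry.
#'
#' @param spec A [smear_spec()].
#' @param classes Optional character vector of subtype labels (recycled);
#'   default samples from `L1, L2, M2, M3, M5`.
#' @return Object of class `smear`: list with `image` (H x W x 3 array,
#'   0..255), `truth` (list: `nucleus_mask`, `cell_mask`, `class_label`,
#'   `overlap_pairs`), and `spec`.
#' @export
generate_smear <- function(spec, classes = NULL) {
  stopifnot(inherits(spec, "smear_spec"))
  pars <- subtype_render_params()
  n <- spec$image_size
  with_local_seed(spec$seed, {
    labels <- if (is.null(classes)) sample(pars$class, spec$n_leukocytes, TRUE)
              else rep_len(classes, spec$n_leukocytes)
    stain <- spec$stain_shift %||% rnorm(3, 0, c(3, 2, 2))

    # smooth zero-mean unit-sd grain fields for background / region texture
    smooth_field <- function() {
      g <- box_mean(matrix(rnorm(n * n), n, n), 5)
      g / max(sd(g), 1e-9)
    }
    grain <- smooth_field(); bg_grain <- smooth_field()

    margin <- 20
    place_budget <- 200

    # --- erythrocytes (distractors; not part of the ground truth masks) ---
    ery <- list()
    for (e in seq_len(spec$n_erythrocytes)) {
      shp <- make_shape(rnorm(1, 9, 0.8), runif(1, 1.02, 1.15))
      placed <- FALSE
      for (try in seq_len(place_budget)) {
        cr <- runif(1, margin, n - margin); cc <- runif(1, margin, n - margin)
        ok <- TRUE
        for (o in ery)
          if (sqrt((o$cr - cr)^2 + (o$cc - cc)^2) <
              shape_rmax(shp) + shape_rmax(o$shape) - 2) { ok <- FALSE; break }
        if (ok) { ery[[e]] <- list(shape = shp, cr = cr, cc = cc); placed <- TRUE; break }
      }
      if (!placed) abort("placement failure: too many erythrocytes for the frame")
    }

    # --- leukocytes: standalone extents first, then instance assembly ---
    nl <- spec$n_leukocytes
    n_overlap <- ceiling(spec$overlap_fraction * nl)
    cells <- vector("list", nl)
    for (i in seq_len(nl)) {
      p <- pars[pars$class == labels[i], ]
      shp <- make_shape(rnorm(1, p$cell_r, 0.7), runif(1, 1, p$ecc))
      force_overlap <- nl > 1 && i > nl - n_overlap
      placed <- FALSE
      for (try in seq_len(place_budget)) {
        if (force_overlap) {
          partner <- cells[[sample(i - 1, 1)]]
          dir <- runif(1, 0, 2 * pi)
          lo <- 0.35 * (shape_rmax(shp) + shape_rmax(partner$shape))
          hi <- 1.20 * (shape_rmax(shp) + shape_rmax(partner$shape))
          target <- runif(1, 0.10, 0.30)
          pm <- partner$mask
          fr_at <- function(d) {
            m <- rasterize_shape(shp, partner$cr + d * cos(dir),
                                 partner$cc + d * sin(dir), n)
            if (!sum(m)) 1 else overlap_frac(m, pm)
          }
          if (fr_at(hi) > target || fr_at(lo) < target) next
          for (it in 1:20) {
            mid <- (lo + hi) / 2
            if (fr_at(mid) > target) lo <- mid else hi <- mid
          }
          cr <- partner$cr + lo * cos(dir); cc <- partner$cc + lo * sin(dir)
          if (cr < margin || cr > n - margin || cc < margin || cc > n - margin) next
          m <- rasterize_shape(shp, cr, cc, n)
        } else {
          cr <- runif(1, margin, n - margin); cc <- runif(1, margin, n - margin)
          ok <- TRUE
          for (k in seq_len(i - 1)) {
            o <- cells[[k]]
            if (sqrt((o$cr - cr)^2 + (o$cc - cc)^2) <
                shape_rmax(shp) + shape_rmax(o$shape) + 2) { ok <- FALSE; break }
          }
          if (!ok) next
          m <- rasterize_shape(shp, cr, cc, n)
        }
        if (sum(m) < 30) next
        # nucleus: concentric, slightly offset, clipped to the cell
        nshp <- make_shape(p$nuc_ratio * mean(c(shp$a, shp$b)),
                           runif(1, 1, 1.1), jitter_sd = 0.015)
        off <- runif(2, -0.08, 0.08) * p$cell_r
        nm <- rasterize_shape(nshp, cr + off[1], cc + off[2], n) & m
        if (sum(nm) < 20) next
        cells[[i]] <- list(shape = shp, cr = cr, cc = cc, mask = m,
                           nucleus = nm, class = labels[i])
        placed <- TRUE
        break
      }
      if (!placed) abort("placement failure: could not place all leukocytes")
    }

    # overlap pairs from standalone extents (exhaustive pairwise scan)
    pairs <- matrix(integer(0), ncol = 2)
    if (nl > 1)
      for (i in 1:(nl - 1)) for (j in (i + 1):nl)
        if (any(cells[[i]]$mask & cells[[j]]$mask))
          pairs <- rbind(pairs, c(i, j))

    # --- assembly: instance masks + a render-class map ---
    cell_lab <- matrix(0L, n, n); nuc_lab <- matrix(0L, n, n)
    render <- matrix(0L, n, n) # 0 bg, 1 ery, 2 cyto, 3 nucleus
    which_cell <- matrix(0L, n, n)
    for (e in seq_along(ery))
      render[rasterize_shape(ery[[e]]$shape, ery[[e]]$cr, ery[[e]]$cc, n)] <- 1L
    for (i in seq_len(nl)) {
      ci <- cells[[i]]
      paint <- ci$mask & nuc_lab == 0L # never paint over an earlier nucleus
      cell_lab[paint] <- i; render[paint] <- 2L; which_cell[paint] <- i
      nuc <- ci$nucleus & paint
      nuc_lab[nuc] <- i; render[nuc] <- 3L
    }

    # --- Lab composition ---
    L <- 88 + 1.4 * bg_grain; a <- 4 + 0.6 * bg_grain; b <- 6 + 0.9 * bg_grain
    idx <- render == 1L
    L[idx] <- 76 + 1.5 * grain[idx]; a[idx] <- 20 + 1.0 * grain[idx]
    b[idx] <- 16 + 1.2 * grain[idx]
    for (i in seq_len(nl)) {
      ci <- cells[[i]]; p <- pars[pars$class == ci$class, ]
      jit <- rnorm(3, 0, 1.2)
      cy <- cell_lab == i & nuc_lab != i
      L[cy] <- 72 + jit[1] + 0.8 * p$grain_sd * grain[cy]
      a[cy] <- 16 + jit[2] + 0.6 * p$grain_sd * grain[cy]
      b[cy] <- p$cyto_b + jit[3] + 0.7 * p$grain_sd * grain[cy]
      nu <- nuc_lab == i
      L[nu] <- p$nuc_L + jit[1] + p$grain_sd * grain[nu]
      a[nu] <- 30 + jit[2] + 0.7 * p$grain_sd * grain[nu]
      b[nu] <- -34 + jit[3] + 0.8 * p$grain_sd * grain[nu]
    }
    L <- L + stain[1]; a <- a + stain[2]; b <- b + stain[3]
    img <- lab_to_rgb(L, a, b)
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))

    structure(list(
      image = img,
      truth = list(nucleus_mask = nuc_lab, cell_mask = cell_lab,
                   class_label = setNames(labels, seq_len(nl)),
                   overlap_pairs = pairs),
      spec = spec
    ), class = "smear")
  })
}

#' @export
print.smear <- function(x, ...) {
  cat("synthetic smear:", paste(dim(x$image)[1:2], collapse = "x"),
      "px,", max(x$truth$cell_mask), "leukocytes,",
      nrow(x$truth$overlap_pairs), "overlapping pairs\n")
  invisible(x)
}

# Orthonormal class-mean directions over the signal columns; pairwise
# distance between class means equals `separation` exactly.
class_mean_model <- function(classes, columns, separation, signal_cols,
                             structure_seed) {
  p <- length(columns); k <- length(classes)
  if (length(signal_cols) < k)
    abort("need at least as many signal features as classes")
  with_local_seed(structure_seed, {
    M <- matrix(0, p, k)
    M[signal_cols, ] <- rnorm(length(signal_cols) * k)
    Q <- qr.Q(qr(M))
  })
  mu <- t(Q) * separation / sqrt(2)
  rownames(mu) <- classes
  colnames(mu) <- columns
  mu
}

#' Generate a labelled synthetic feature dataset
#'
#' Draws class-conditional Gaussian feature vectors over the cell-description
#' schema: unit-variance features whose class means sit at pairwise distance
#' `class_separation` (in pooled-SD units) along random orthonormal
#' directions. The class structure is controlled by `structure_seed`
#' separately from the sampling `seed`, so train and test sets can share one
#' population.
#'
#' @param n_per_class Rows per class (at least 2).
#' @param class_separation Non-negative pairwise mean separation.
#' @param seed Sampling seed.
#' @param classes Class labels (default the five FAB subtypes).
#' @param schema `"table1"` (the 67 named descriptors) or `"expanded"` (one
#'   column per descriptor/region/channel combination, as extracted from
#'   images).
#' @param signal_regions For the expanded schema, which regions carry the
#'   class signal: `"all"`, or a subset of `c("nucleus", "cytoplasm",
#'   "cell", "ratio")`.
#' @param structure_seed Seed fixing the class-mean directions.
#' @return Tibble with a `class` factor column and one column per feature.
#' @export
generate_feature_dataset <- function(n_per_class, class_separation, seed = 1,
                                     classes = c("L1", "L2", "M2", "M3", "M5"),
                                     schema = c("table1", "expanded"),
                                     signal_regions = "all",
                                     structure_seed = 1) {
  schema <- match.arg(schema)
  if (n_per_class < 2) abort("n_per_class must be at least 2")
  if (class_separation < 0) abort("class_separation must be non-negative")
  sch <- mdx_feature_schema(schema)
  cols <- sch$column
  signal_cols <- if (identical(signal_regions, "all")) seq_along(cols)
                 else which(sch$region %in% signal_regions)
  if (!length(signal_cols)) abort("signal_regions matches no schema columns")
  mu <- class_mean_model(classes, cols, class_separation, signal_cols,
                         structure_seed)
  with_local_seed(seed, {
    X <- do.call(rbind, lapply(classes, function(cl) {
      sweep(matrix(rnorm(n_per_class * length(cols)), n_per_class), 2,
            mu[cl, ], "+")
    }))
  })
  colnames(X) <- cols
  dplyr::bind_cols(tibble(class = factor(rep(classes, each = n_per_class),
                                         levels = classes)),
                   as_tibble(X))
}

#' Generate a synthetic patient cohort
#'
#' Builds a patient manifest and per-sample feature rows: each patient's
#' samples share one ground-truth family/subtype and are drawn from the same
#' class-conditional feature model as [generate_feature_dataset()] (matched
#' via `structure_seed`).
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Cell samples per patient (at least 1).
#' @param subtypes Subtype per patient (recycled; default cycles the five).
#' @param class_separation Pairwise class-mean separation.
#' @param seed Sampling seed.
#' @inheritParams generate_feature_dataset
#' @return List with `manifest` (tibble: `patient_id`, `sample_id`, `family`,
#'   `subtype`) and `features` (tibble: `sample_id`, `patient_id`, feature
#'   columns).
#' @export
generate_patient_set <- function(n_patients, samples_per_patient,
                                 subtypes = NULL, class_separation = 5,
                                 seed = 1, schema = c("table1", "expanded"),
                                 structure_seed = 1) {
  schema <- match.arg(schema)
  if (samples_per_patient < 1) abort("samples_per_patient must be >= 1")
  all_classes <- c("L1", "L2", "M2", "M3", "M5")
  subtypes <- rep_len(subtypes %||% all_classes, n_patients)
  if (!all(subtypes %in% all_classes)) abort("unknown subtype label")
  sch <- mdx_feature_schema(schema)
  mu <- class_mean_model(all_classes, sch$column, class_separation,
                         seq_len(nrow(sch)), structure_seed)
  manifest <- tibble(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                     each = samples_per_patient),
    sample_id = sprintf("S%04d", seq_len(n_patients * samples_per_patient)),
    subtype = rep(subtypes, each = samples_per_patient)
  ) |>
    mutate(family = ifelse(startsWith(.data$subtype, "L"), "ALL", "AML"),
           .before = "subtype")
  X <- with_local_seed(seed, {
    t(vapply(manifest$subtype, function(cl)
      mu[cl, ] + rnorm(nrow(sch)), numeric(nrow(sch))))
  })
  colnames(X) <- sch$column
  features <- dplyr::bind_cols(manifest[, c("sample_id", "patient_id")],
                               as_tibble(X))
  list(manifest = dplyr::distinct(manifest[, c("patient_id", "family", "subtype")]),
       samples = manifest, features = features)
}
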