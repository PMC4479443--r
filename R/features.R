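# Cell description: the 67-descriptor panel (morphology, intensity
# statistics, GLCM texture, eigen values, size ratios). Images are NOT
# normalized before extraction — absolute size and colour carry diagnostic
# signal. In the flat extracted table the statistical/GLCM/eigen blocks
# expand per region (nucleus, cytoplasm, cell) and channel (R, G, B, gray);
# the schema below is the single source of truth for column names and order.

table1_features <- function() {
  c("area", "perimeter", "circularity", "width", "length", "elongation",
    "major_axis", "minor_axis", "eccentricity", "extent", "equiv_diameter",
    "euler_number", "convex_area", "solidity",
    "mode", "mean", "sd", "variance", "sum",
    "glcm_homogeneity", "glcm_contrast", "glcm_correlation", "glcm_energy",
    "glcm_entropy",
    sprintf("eigen_R_%02d", 1:10), sprintf("eigen_G_%02d", 1:10),
    sprintf("eigen_B_%02d", 1:10), sprintf("eigen_gray_%02d", 1:10),
    "n_cyto_area", "n_cell_area", "n_cell_perimeter")
}

#' The cell-description feature schema
#'
#' Returns the canonical column list for feature tables. `"table1"` is the
#' 67-descriptor panel by name; `"expanded"` is the flat extracted layout
#' with one column per (descriptor, region, channel) combination: morphology
#' for nucleus and cell, area only for the cytoplasm, statistical and GLCM
#' blocks for nucleus/cytoplasm/cell over R, G, B and gray, eigen values for
#' the nucleus and cell crops, and the three size ratios (232 columns).
#'
#' @param schema `"table1"` or `"expanded"`.
#' @return Tibble with columns `column`, `feature`, `region`, `channel`,
#'   `block`.
#' @export
mdx_feature_schema <- function(schema = c("expanded", "table1")) {
  schema <- match.arg(schema)
  morph <- table1_features()[1:14]
  stats5 <- table1_features()[15:19]
  glcm5 <- table1_features()[20:24]
  ratios <- c("n_cyto_area", "n_cell_area", "n_cell_perimeter")
  if (schema == "table1") {
    f <- table1_features()
    block <- c(rep("morphologic", 14), rep("statistical", 5),
               rep("texture", 5), rep("eigen", 40), rep("size_ratio", 3))
    return(tibble(column = f, feature = f, region = NA_character_,
                  channel = NA_character_, block = block))
  }
  chans <- c("R", "G", "B", "gray")
  rows <- list()
  add <- function(column, feature, region, channel, block)
    rows[[length(rows) + 1]] <<- tibble(column = column, feature = feature,
                                        region = region, channel = channel,
                                        block = block)
  for (reg in c("nucleus", "cell"))
    add(paste(reg, morph, sep = "_"), morph, reg, NA_character_, "morphologic")
  add("cytoplasm_area", "area", "cytoplasm", NA_character_, "morphologic")
  for (reg in c("nucleus", "cytoplasm", "cell")) for (ch in chans) {
    add(paste(reg, stats5, ch, sep = "_"), stats5, reg, ch, "statistical")
    add(paste(reg, glcm5, ch, sep = "_"), glcm5, reg, ch, "texture")
  }
  for (reg in c("nucleus", "cell")) for (ch in chans)
    add(sprintf("%s_eigen_%s_%02d", reg, ch, 1:10),
        sprintf("eigen_%s_%02d", ch, 1:10), reg, ch, "eigen")
  add(ratios, ratios, "ratio", NA_character_, "size_ratio")
  bind_rows(rows)
}

#' Morphological descriptors of a region
#'
#' The 14 shape descriptors: area, boundary-step perimeter, circularity,
#' axis-aligned bounding-box width/length (length is the larger side),
#' elongation, second-moment-ellipse major/minor axis and eccentricity,
#' extent, equivalent diameter, Euler number, convex area and solidity.
#'
#' @param mask Logical mask of a single region.
#' @return Named numeric vector of length 14.
#' @export
morphological_features <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) abort("empty region")
  area <- nrow(px)
  pts <- region_contour(mask)
  per <- contour_perimeter(pts)
  if (per == 0) warn("degenerate perimeter; circularity reported as 0")
  wd <- diff(range(px[, 2])) + 1
  lg <- diff(range(px[, 1])) + 1
  width <- min(wd, lg); length_ <- max(wd, lg)
  ell <- moment_ellipse(px[, 1], px[, 2])
  cva <- convex_pixel_area(px[, 1], px[, 2])
  c(area = area, perimeter = per,
    circularity = if (per > 0) per^2 / (4 * pi * area) else 0,
    width = width, length = length_, elongation = length_ / width,
    major_axis = ell$major, minor_axis = ell$minor,
    eccentricity = ell$eccentricity,
    extent = area / (width * length_),
    equiv_diameter = sqrt(4 * area / pi),
    euler_number = region_euler(mask),
    convex_area = cva, solidity = area / cva)
}

#' Intensity statistics of a region
#'
#' Mode (ties broken to the smallest value), mean, standard deviation,
#' variance (population convention, so `variance == sd^2`) and sum of the
#' region's pixel intensities.
#'
#' @param values Numeric vector of region pixel intensities.
#' @return Named numeric vector `mode, mean, sd, variance, sum`.
#' @export
statistical_features <- function(values) {
  if (!length(values)) abort("empty region")
  ux <- sort(unique(values))
  mode <- ux[which.max(tabulate(match(values, ux)))]
  mu <- mean(values)
  v <- mean((values - mu)^2)
  c(mode = mode, mean = mu, sd = sqrt(v), variance = v, sum = sum(values))
}

# Symmetric normalized GLCM at offset (0, 1), restricted to pixel pairs that
# are both inside the region; 32 gray levels over the 0..255 scale.
glcm_matrix <- function(plane, mask, levels = 32) {
  q <- pmin(pmax(floor(plane * levels / 256), 0), levels - 1)
  nc <- ncol(mask)
  pair_ok <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  if (!any(pair_ok)) return(NULL)
  v1 <- q[, -nc, drop = FALSE][pair_ok]
  v2 <- q[, -1, drop = FALSE][pair_ok]
  counts <- tabulate(v1 * levels + v2 + 1, nbins = levels^2) +
    tabulate(v2 * levels + v1 + 1, nbins = levels^2)
  matrix(counts / sum(counts), levels, levels)
}

#' GLCM texture statistics of a region
#'
#' Gray-level co-occurrence statistics at offset (0, 1), symmetric and
#' normalized, over 32 gray levels: homogeneity, contrast, correlation,
#' energy and entropy (bits). Correlation is `NA` for a constant region.
#'
#' @param plane Numeric intensity plane on the 0..255 scale.
#' @param mask Logical region mask.
#' @return Named numeric vector of the five statistics.
#' @export
glcm_features <- function(plane, mask) {
  p <- glcm_matrix(plane, mask)
  if (is.null(p)) abort("region has no horizontally adjacent pixel pairs")
  lv <- nrow(p)
  i <- matrix(0:(lv - 1), lv, lv)
  j <- t(i)
  pi_ <- rowSums(p)
  mu <- sum((0:(lv - 1)) * pi_)
  sig2 <- sum(((0:(lv - 1)) - mu)^2 * pi_)
  nz <- p[p > 0]
  c(glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = if (sig2 > 0)
      sum(p * (i - mu) * (j - mu)) / sig2 else NA_real_,
    glcm_energy = sum(p^2),
    glcm_entropy = -sum(nz * log2(nz)))
}

#' Eigen-value descriptors of a region crop
#'
#' Eigen values of the row-covariance matrix of the region's bounding-box
#' crop (rows as observations, columns as variables); out-of-region pixels
#' are filled with the region's mean intensity so background does not leak
#' in. Values are non-negative, sorted descending, and zero-padded to 10.
#'
#' @param plane Numeric intensity plane.
#' @param mask Logical region mask.
#' @return Numeric vector of the first 10 eigen values.
#' @export
eigen_features <- function(plane, mask) {
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) abort("empty region")
  r <- range(px[, 1]); cc <- range(px[, 2])
  crop <- plane[r[1]:r[2], cc[1]:cc[2], drop = FALSE]
  sub <- mask[r[1]:r[2], cc[1]:cc[2], drop = FALSE]
  crop[!sub] <- mean(plane[mask])
  if (nrow(crop) < 2 || ncol(crop) < 1) {
    warn("degenerate crop; eigen values zero-padded")
    return(rep(0, 10))
  }
  ev <- eigen(cov(crop), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  out <- rep(0, 10)
  out[seq_len(min(10, length(ev)))] <- ev[seq_len(min(10, length(ev)))]
  out
}

#' Nucleus/cytoplasm/cell size ratios
#'
#' `n_cyto_area = nucleus area / cytoplasm area`, `n_cell_area = nucleus
#' area / cell area`, `n_cell_perimeter = nucleus perimeter / cell
#' perimeter`. A cell with no cytoplasm yields `NA` for the first ratio with
#' a warning.
#'
#' @param nucleus_mask,cell_mask Logical masks (nucleus inside cell).
#' @return Named numeric vector of the three ratios.
#' @export
size_ratio_features <- function(nucleus_mask, cell_mask) {
  na <- sum(nucleus_mask); ca <- sum(cell_mask)
  cyto <- ca - na
  if (cyto <= 0) warn("cell has no cytoplasm; n_cyto_area is NA")
  np <- contour_perimeter(region_contour(nucleus_mask))
  cp <- contour_perimeter(region_contour(cell_mask))
  c(n_cyto_area = if (cyto > 0) na / cyto else NA_real_,
    n_cell_area = na / ca,
    n_cell_perimeter = if (cp > 0) np / cp else NA_real_)
}

#' Extract the full feature vector for one cell
#'
#' Assembles the expanded cell-description vector: morphology for the
#' nucleus and the whole cell, area only for the cytoplasm, statistical and
#' GLCM blocks for nucleus/cytoplasm/cell over the R, G, B and gray planes,
#' eigen values for the nucleus and cell crops, and the three size ratios.
#'
#' @param image RGB array (0..255 or 0..1).
#' @param cell_mask,nucleus_mask Logical masks of the cell and its nucleus.
#' @return Named numeric vector following `mdx_feature_schema("expanded")`.
#' @export
extract_feature_vector <- function(image, cell_mask, nucleus_mask) {
  image <- to_255(image)
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                gray = gray_plane(image))
  cyto_mask <- cell_mask & !nucleus_mask
  out <- c(
    setNames(morphological_features(nucleus_mask),
             paste0("nucleus_", table1_features()[1:14])),
    setNames(morphological_features(cell_mask),
             paste0("cell_", table1_features()[1:14])),
    cytoplasm_area = sum(cyto_mask)
  )
  masks <- list(nucleus = nucleus_mask, cytoplasm = cyto_mask,
                cell = cell_mask)
  for (reg in names(masks)) for (ch in names(chans)) {
    m <- masks[[reg]]
    vals <- chans[[ch]][m]
    out <- c(out,
             setNames(statistical_features(vals),
                      paste(reg, table1_features()[15:19], ch, sep = "_")),
             setNames(glcm_features(chans[[ch]], m),
                      paste(reg, table1_features()[20:24], ch, sep = "_")))
  }
  for (reg in c("nucleus", "cell")) for (ch in names(chans))
    out <- c(out, setNames(eigen_features(chans[[ch]], masks[[reg]]),
                           sprintf("%s_eigen_%s_%02d", reg, ch, 1:10)))
  out <- c(out, size_ratio_features(nucleus_mask, cell_mask))
  out[mdx_feature_schema("expanded")$column]
}

#' Extract features for every accepted cell record
#'
#' @param records `cell_records` from [identify_cells()].
#' @param image RGB array of the source smear.
#' @return Tibble with `cell_id` plus the expanded feature columns, one row
#'   per `ok`-flagged record.
#' @export
extract_features <- function(records, image) {
  cl <- attr(records, "cell_labels")
  nl <- attr(records, "nucleus_labels")
  ok <- dplyr::filter(as_tibble(records), .data$flag == "ok")
  purrr::map_dfr(seq_len(nrow(ok)), function(r) {
    fv <- extract_feature_vector(image, cl == ok$cell_id[r],
                                 nl == ok$nucleus_id[r])
    bind_cols(tibble(cell_id = ok$cell_id[r]), as_tibble(as.list(fv)))
  })
}
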