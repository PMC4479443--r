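# Colour model: CIE L*a*b* conversion and k-means channel grouping.
#
# Wright-stained marrow smears put most of the diagnostic contrast into two
# Lab channels: L* (nuclei are markedly darker than cytoplasm, erythrocytes
# and background) and b* (purple/blue leukocyte chroma sits at negative b*,
# orange/rose erythrocytes at positive b*). The segmentation model therefore
# reads its colour observations from those two planes.

#' Convert an RGB raster to CIE L*a*b*
#'
#' Applies the standard sRGB (D65) to XYZ to CIE L*a*b* transform per pixel:
#' channels are gamma-expanded, mixed through the sRGB primary matrix and
#' normalized against the D65 white point.
#'
#' @param rgb Numeric array `H x W x 3`, 8-bit values in `[0, 255]` (values in
#'   `[0, 1]` are also accepted and rescaled).
#' @return An object of class `lab_image`: a list with matrices `L` (in
#'   `[0, 100]`), `a`, `b`, and the source `dim`.
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_lab(img)$L
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- to_255(rgb) / 255
  d <- dim(rgb)
  v <- matrix(rgb, ncol = 3)
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  wp <- c(0.95047, 1, 1.08883)
  xyz <- sweep(xyz, 2, wp, "/")
  d0 <- (6 / 29)^3
  f <- ifelse(xyz > d0, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  out <- list(
    L = matrix(116 * f[, 2] - 16, d[1], d[2]),
    a = matrix(500 * (f[, 1] - f[, 2]), d[1], d[2]),
    b = matrix(200 * (f[, 2] - f[, 3]), d[1], d[2]),
    dim = d[1:2]
  )
  structure(out, class = "lab_image")
}

#' Convert CIE L*a*b* planes back to an sRGB raster
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to `[0, 255]`.
#' Used mainly by the synthetic smear renderer, which composes scenes directly
#' in Lab so that luminance/chroma orderings hold by construction.
#'
#' @param L,a,b Numeric matrices of equal dimension.
#' @return Numeric array `H x W x 3` on the 0..255 scale.
#' @export
lab_to_rgb <- function(L, a, b) {
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  wp <- c(0.95047, 1, 1.08883)
  xyz <- cbind(finv(c(fx)) * wp[1], finv(c(fy)) * wp[2], finv(c(fz)) * wp[3])
  minv <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                   -0.9692660, 1.8760108, 0.0415560,
                   0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
  lin <- xyz %*% t(minv)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  v <- pmin(pmax(v, 0), 1)
  array(v * 255, dim = c(dim(L), 3))
}

#' Group a channel plane by intensity with k-means
#'
#' Clusters scalar channel intensities into `k` groups (the paper's k = 2 and
#' k = 3 readings of the L* and b* planes) and reports per-group mean,
#' variance and standard deviation, the colour statistics consumed by the
#' segmentation model. Groups are relabelled in ascending order of their mean
#' so the grouping is deterministic for a fixed seed.
#'
#' Because the observations are scalar, the k-means optimum has contiguous
#' groups in sorted order; the solver exploits this with an exact weighted
#' dynamic program over the (binned) intensity distribution followed by
#' Lloyd iterations on the full data, so it attains the global
#' within-group-sum-of-squares optimum rather than a restart-dependent local
#' one.
#'
#' @param plane Numeric matrix of channel intensities.
#' @param k Number of groups, 2 or 3.
#' @param seed,restarts Retained for interface compatibility; the scalar
#'   solver is exact and deterministic, so they do not affect the result.
#' @return An object of class `channel_groups`: list with `k`, `assignments`
#'   (integer matrix of group indices), and `stats`, a tibble with one row per
#'   group (`group`, `mean`, `variance`, `sd`, `size`).
#' @export
cluster_channel <- function(plane, k = 2, seed = 1, restarts = 10) {
  if (!length(plane)) abort("empty channel plane")
  if (k < 2) abort("k must be at least 2")
  x <- as.vector(plane)
  if (length(unique(x)) < k)
    abort(sprintf("degenerate plane: fewer than %d distinct intensity values", k))
  centers <- sort(kmeans_1d(x, k))
  # deterministic Lloyd polish on the full data
  for (it in 1:50) {
    cuts <- (centers[-k] + centers[-1]) / 2
    grp <- findInterval(x, cuts) + 1L
    newc <- vapply(seq_len(k), function(g)
      if (any(grp == g)) mean(x[grp == g]) else centers[g], numeric(1))
    if (max(abs(newc - centers)) < 1e-10) { centers <- newc; break }
    centers <- newc
  }
  cuts <- (centers[-k] + centers[-1]) / 2
  assign <- matrix(findInterval(x, cuts) + 1L, nrow(plane), ncol(plane))
  stats <- purrr::map_dfr(seq_len(k), function(g) {
    vals <- x[assign == g]
    tibble(group = g, mean = mean(vals),
           variance = mean((vals - mean(vals))^2),
           sd = sqrt(mean((vals - mean(vals))^2)), size = length(vals))
  })
  structure(list(k = k, assignments = assign, stats = stats,
                 foreground_group = NA_integer_),
            class = "channel_groups")
}

# Exact 1-D k-means centers by weighted interval dynamic programming. When
# the data carry more than `max_bins` distinct values they are histogrammed
# first (the subsequent Lloyd polish runs on the full data).
kmeans_1d <- function(x, k, max_bins = 1024) {
  ux <- sort(unique(x))
  if (length(ux) > max_bins) {
    br <- seq(min(x), max(x), length.out = max_bins + 1)
    bin <- pmin(findInterval(x, br, rightmost.closed = TRUE), max_bins)
    w <- tabulate(bin, max_bins)
    v <- (br[-1] + br[-(max_bins + 1)]) / 2
    keep <- w > 0
    v <- v[keep]; w <- w[keep]
  } else {
    v <- ux
    w <- tabulate(match(x, ux), length(ux))
  }
  B <- length(v)
  if (B <= k) return(c(v, rep(v[B], k - B)))
  cw <- c(0, cumsum(w)); cs <- c(0, cumsum(w * v)); cs2 <- c(0, cumsum(w * v^2))
  # cost[i, j]: WSS of bins i..j
  cost <- function(i, j) {
    W <- cw[j + 1] - cw[i]; S <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - S^2 / W
  }
  ii <- rep(seq_len(B), each = B); jj <- rep(seq_len(B), B)
  Cm <- matrix(ifelse(ii <= jj, cost(ii, jj), Inf), B, B, byrow = TRUE)
  dp <- Cm[1, ]          # dp over 1 cluster ending at j
  split <- matrix(0L, k, B)
  for (m in 2:k) {
    nd <- rep(Inf, B); sp <- integer(B)
    for (j in m:B) {
      cand <- dp[(m - 1):(j - 1)] + Cm[m:j, j]
      best <- which.min(cand)
      nd[j] <- cand[best]; sp[j] <- best + m - 2L
    }
    dp <- nd; split[m, ] <- sp
  }
  bounds <- integer(k + 1); bounds[k + 1] <- B
  for (m in k:2) bounds[m] <- split[m, bounds[m + 1]]
  bounds[1] <- 0
  vapply(seq_len(k), function(m) {
    i <- bounds[m] + 1; j <- bounds[m + 1]
    sum(w[i:j] * v[i:j]) / sum(w[i:j])
  }, numeric(1))
}

#' Pick the channel group representing the foreground
#'
#' Operationalizes the qualitative selection rule: in nucleus mode the darkest
#' L* group (lowest mean) is the nucleus; in cell mode the most blue/purple
#' b* group (lowest mean) is the leukocyte. Ties break to the lowest group
#' index.
#'
#' @param groups A `channel_groups` object.
#' @param mode `"nucleus"` (L* plane) or `"cell"` (b* plane).
#' @return Integer group index.
#' @export
select_foreground_group <- function(groups, mode = c("nucleus", "cell")) {
  mode <- match.arg(mode)
  means <- groups$stats$mean
  idx <- which(means == min(means))
  if (length(idx) > 1)
    warn("tie in group means; breaking to the lowest group index")
  groups$stats$group[min(idx)]
}
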