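# Shared low-level helpers: local RNG scoping, windowed means, polygon
# rasterization and small mask utilities used across the pipeline.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so package functions never perturb user code.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(code)
}

# Mean of `mat` over a centred w x w window, edge-replicated, via integral image.
box_mean <- function(mat, w) {
  stopifnot(w >= 1)
  if (w == 1) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
  ri <- pmin(pmax(seq_len(nr + w - 1) - lo, 1), nr)
  ci <- pmin(pmax(seq_len(nc + w - 1) - lo, 1), nc)
  pad <- mat[ri, ci, drop = FALSE]
  ii <- rbind(0, apply(pad, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (ii[r1 + w, c1 + w, drop = FALSE] - ii[r1, c1 + w, drop = FALSE] -
     ii[r1 + w, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / (w * w)
}

# Even-odd scanline fill of a closed polygon given in (row, col) vertex order.
# Pixels are sampled at integer centres; returns a logical nr x nc matrix.
rasterize_polygon <- function(pr, pc, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  np <- length(pr)
  if (np < 3) return(out)
  r2 <- c(pr[-1], pr[1]); c2 <- c(pc[-1], pc[1])
  rmin <- max(1L, floor(min(pr))); rmax <- min(nr, ceiling(max(pr)))
  if (rmax < rmin) return(out)
  for (y in rmin:rmax) {
    # half-open rule: edge spans [min(y1,y2), max(y1,y2))
    cross <- which((pr <= y & r2 > y) | (r2 <= y & pr > y))
    if (!length(cross)) next
    xs <- pc[cross] + (y - pr[cross]) * (c2[cross] - pc[cross]) / (r2[cross] - pr[cross])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1] + 1e-9)
      a <- max(1L, a); b <- min(nc, b)
      if (b >= a) out[y, a:b] <- TRUE
    }
  }
  out
}

# 8-connected (or 4-connected) components as an integer label matrix.
label_components <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "logical"
  label_components_cpp(mask, as.integer(connectivity))
}

# Fill enclosed background holes smaller than `max_hole` pixels (4-connected
# background, so it is the dual of 8-connected foreground).
fill_small_holes <- function(mask, max_hole) {
  bg <- label_components(!mask, connectivity = 4)
  if (max(bg) == 0) return(mask)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg, nbins = max(bg))
  fill_ids <- setdiff(which(sizes > 0 & sizes < max_hole), border_ids)
  if (length(fill_ids)) mask[bg %in% fill_ids] <- TRUE
  mask
}

# Drop 8-connected foreground objects smaller than `min_object` pixels.
remove_small_objects <- function(mask, min_object) {
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_object)
  lab %in% keep & mask
}

# Coerce an RGB raster (H x W x 3, values in [0,1] or [0,255]) to 0..255 scale.
to_255 <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    abort("expected an RGB raster with three channels")
  if (max(rgb, na.rm = TRUE) <= 1) rgb * 255 else rgb
}

# Luma plane on the 0..255 scale.
gray_plane <- function(rgb) {
  rgb <- to_255(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

mask_of <- function(labels, id) labels == id
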