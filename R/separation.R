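# Separation of overlapped cells. An aggregate is cut at concave points
# (convexity-defect apexes marking the waist between cells) and each open
# boundary fragment is re-closed by linear interpolation of the boundary
# radius over angle about the fragment centroid — which maps back to a
# smooth conic-like arc in cartesian space — followed by a 3x3 morphological
# closing. Pixels claimed by both children go to the nearer fragment
# centroid, so children are disjoint while keeping the original (non-gap)
# boundary.

#' Detect concave points on a closed contour
#'
#' Convexity-defect apexes: for each convex-hull chord, the boundary point of
#' maximal perpendicular depth below the chord, kept when the depth reaches
#' `depth_min`. A convex contour yields no points; two fused discs yield one
#' point per side of the waist.
#'
#' @param contour Two-column (row, col) matrix of ordered boundary points.
#' @param depth_min Minimum defect depth in pixels (default 3).
#' @return Integer vector of contour indices (possibly empty), ordered by
#'   decreasing depth; depths in attribute `depth`.
#' @export
detect_concave_points <- function(contour, depth_min = 3) {
  n <- nrow(contour)
  if (n < 20) abort("contour too short for concavity analysis")
  h <- sort(chull(contour[, 2], contour[, 1]))
  idx <- integer(0); depth <- numeric(0)
  hs <- c(h, h[1] + n)
  for (k in seq_along(h)) {
    a <- hs[k]; b <- hs[k + 1]
    if (b - a < 2) next
    between <- ((a + 1):(b - 1) - 1) %% n + 1
    pa <- contour[(a - 1) %% n + 1, ]; pb <- contour[(b - 1) %% n + 1, ]
    chord <- pb - pa
    len <- sqrt(sum(chord^2))
    if (len == 0) next
    d <- abs((contour[between, 1] - pa[1]) * chord[2] -
               (contour[between, 2] - pa[2]) * chord[1]) / len
    # all sufficiently deep local maxima of the depth profile along the
    # chord (a chord spanning several waists carries one apex per waist)
    m <- length(d)
    win <- 5
    for (t in seq_len(m)) {
      if (d[t] < depth_min) next
      lo <- max(1, t - win); hi <- min(m, t + win)
      if (t != which.max(d[lo:hi]) + lo - 1) next # window argmax only
      idx <- c(idx, between[t])
      depth <- c(depth, d[t])
    }
  }
  ord <- order(depth, decreasing = TRUE)
  structure(idx[ord], depth = depth[ord])
}

# Close an open boundary fragment: keep its points verbatim as polygon
# vertices and bridge the gap between its two endpoints with an arc obtained
# by linear interpolation of radius over angle about the fragment centroid.
close_fragment <- function(pts, angle_res = 1) {
  ctr <- colMeans(pts)
  n <- nrow(pts)
  th <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  # winding direction of the fragment
  dth <- diff(th)
  dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
  dir <- sign(sum(dth))
  if (dir == 0) dir <- 1
  gap <- (th[1] - th[n]) * dir
  gap <- gap %% (2 * pi)
  if (gap < 1e-9) gap <- gap + 2 * pi
  steps <- max(2, ceiling(gap / (angle_res * pi / 180)))
  tseq <- seq_len(steps - 1) / steps
  arc_th <- th[n] + dir * gap * tseq
  arc_r <- r[n] + (r[1] - r[n]) * tseq
  rbind(pts, cbind(ctr[1] + arc_r * cos(arc_th), ctr[2] + arc_r * sin(arc_th)))
}

# 3x3 box morphological closing.
close3 <- function(mask) {
  k <- EBImage::makeBrush(3, shape = "box")
  EBImage::closing(ifelse(mask, 1, 0), k) > 0.5
}

#' Split an overlapped region into individual cells
#'
#' Cuts the region's boundary at the deepest concave-point pair (the pair is
#' the deepest defect and its nearest defect across the waist), closes each
#' fragment with the polar interpolation arc, rasterizes and 3x3-closes the
#' children, assigns contested pixels to the nearer fragment centroid, and
#' recurses on children that still carry concave waists. A region without at
#' least two concave points is returned unchanged.
#'
#' @param mask Logical mask of one region.
#' @param depth_min Minimum defect depth (default 3).
#' @param angle_res Angular resolution of the closing arc in degrees.
#' @param min_area Children smaller than this are discarded (default 30).
#' @param max_depth Recursion limit (default 4).
#' @return List of logical child masks (full frame, pairwise disjoint).
#' @export
split_overlapped <- function(mask, depth_min = 3, angle_res = 1,
                             min_area = 30, max_depth = 4) {
  if (max_depth <= 0 || sum(mask) < min_area) return(list(mask))
  pts <- region_contour(mask)
  if (nrow(pts) < 20) return(list(mask))
  cp <- detect_concave_points(pts, depth_min)
  if (length(cp) < 2) return(list(mask))
  n <- nrow(pts)
  # deepest defect paired with its euclidean-nearest defect across the waist
  # (partners closer than 5 contour steps would cut off a sliver)
  p1 <- cp[1]
  cand <- cp[-1]
  steps <- pmin(abs(cand - p1), n - abs(cand - p1))
  cand <- cand[steps >= 5]
  if (!length(cand)) return(list(mask))
  d2 <- (pts[cand, 1] - pts[p1, 1])^2 + (pts[cand, 2] - pts[p1, 2])^2
  p2 <- cand[which.min(d2)]
  i <- min(p1, p2); j <- max(p1, p2)
  fragA <- pts[i:j, , drop = FALSE]
  fragB <- pts[c(j:n, 1:i), , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  children <- lapply(list(fragA, fragB), function(fr) {
    poly <- close_fragment(fr, angle_res)
    child <- rasterize_polygon(poly[, 1], poly[, 2], nr, nc)
    child[cbind(round(fr[, 1]), round(fr[, 2]))] <- TRUE
    close3(child) & mask
  })
  both <- children[[1]] & children[[2]]
  if (any(both)) {
    cA <- colMeans(fragA); cB <- colMeans(fragB)
    px <- which(both, arr.ind = TRUE)
    nearerA <- (px[, 1] - cA[1])^2 + (px[, 2] - cA[2])^2 <=
      (px[, 1] - cB[1])^2 + (px[, 2] - cB[2])^2
    children[[1]][px[!nearerA, , drop = FALSE]] <- FALSE
    children[[2]][px[nearerA, , drop = FALSE]] <- FALSE
  }
  children <- purrr::keep(children, ~ sum(.x) >= min_area)
  if (length(children) < 2) return(list(mask))
  out <- list()
  for (ch in children) {
    # children may disconnect at the cut; keep each component separately
    labs <- label_components(ch, connectivity = 8)
    for (id in setdiff(unique(as.vector(labs)), 0L)) {
      comp <- labs == id
      if (sum(comp) < min_area) next
      out <- c(out, split_overlapped(comp, depth_min, angle_res, min_area,
                                     max_depth - 1))
    }
  }
  if (!length(out)) list(mask) else out
}

#' Separate all overlapped records of a segmentation
#'
#' Applies [split_overlapped()] to every record flagged `overlapped` and
#' rebuilds the cell instance label matrix with the children appended as new
#' instances.
#'
#' @param records `cell_records` from [identify_cells()].
#' @param ... Passed to [split_overlapped()].
#' @return Updated integer cell label matrix.
#' @export
separate_overlapped_records <- function(records, ...) {
  cl <- attr(records, "cell_labels")
  over <- unique(records$cell_id[records$flag == "overlapped"])
  over <- over[!is.na(over)]
  next_id <- max(cl) + 1L
  for (cid in over) {
    children <- split_overlapped(cl == cid, ...)
    if (length(children) < 2) next
    cl[cl == cid] <- 0L
    for (ch in children) {
      cl[ch] <- next_id
      next_id <- next_id + 1L
    }
  }
  cl
}
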