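# Region identification: descriptors for connected regions, the shape /
# colour-relation / containment rules that label regions as nucleus, cell or
# overlapped aggregate, and nucleus-to-cell matching.

# Ordered boundary of a single-region mask, 1-based (row, col) matrix.
region_contour <- function(mask) {
  oc <- EBImage::ocontour(ifelse(mask, 1L, 0L))
  if (!length(oc)) return(matrix(numeric(0), ncol = 2))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  cbind(pts[, 1] + 1, pts[, 2] + 1)
}

# Boundary-step perimeter: unit steps for 4-neighbour moves, sqrt(2) for
# diagonal moves, including the closing step.
contour_perimeter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# Second-moment ellipse of a pixel set: major/minor axis lengths and
# eccentricity (foci distance / major axis, in [0, 1)).
moment_ellipse <- function(rows, cols) {
  if (length(rows) < 2)
    return(list(major = 0, minor = 0, eccentricity = 0))
  cv <- cov(cbind(rows, cols)) * (length(rows) - 1) / length(rows)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]),
       eccentricity = if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0)
}

# Pixel area of the convex hull of a pixel set (hull of pixel centres,
# rasterized at pixel centres).
convex_pixel_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  h <- chull(cols, rows)
  r0 <- min(rows) - 1; c0 <- min(cols) - 1
  poly_r <- rows[h] - r0; poly_c <- cols[h] - c0
  sum(rasterize_polygon(poly_r, poly_c, max(rows) - r0, max(cols) - c0) |
        # hull boundary pixels themselves always count
        {m <- matrix(FALSE, max(rows) - r0, max(cols) - c0)
         m[cbind(rows - r0, cols - c0)] <- TRUE; m})
}

# Euler number of a single region: 1 minus the number of enclosed holes.
region_euler <- function(mask) {
  bb <- which(mask, arr.ind = TRUE)
  r <- range(bb[, 1]); c <- range(bb[, 2])
  sub <- matrix(FALSE, diff(r) + 3, diff(c) + 3)
  sub[cbind(bb[, 1] - r[1] + 2, bb[, 2] - c[1] + 2)] <- TRUE
  bg <- label_components(!sub, connectivity = 4)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(setdiff(unique(as.vector(bg)), 0L), border_ids)
  1L - length(holes)
}

#' Compute shape and colour descriptors for mask regions
#'
#' Labels the 8-connected components of a binary mask (or accepts an
#' instance-labelled integer mask) and computes, per region: area, perimeter
#' (boundary steps, diagonal steps counting sqrt(2)), centroid, bounding box,
#' circularity `perimeter^2 / (4 pi area)`, second-moment-ellipse axes and
#' eccentricity, and optionally the mean of an intensity plane (used for the
#' "darker than" colour relation).
#'
#' @param mask Logical/binary matrix, or integer instance-label matrix.
#' @param intensity Optional numeric plane (e.g. L*) for `mean_intensity`.
#' @return Tibble of class `region_table` with one row per region; the
#'   instance label matrix travels in attribute `labels`.
#' @export
compute_region_descriptors <- function(mask, intensity = NULL) {
  labels <- if (is.logical(mask) || all(mask %in% c(0, 1)))
    label_components(mask != 0, connectivity = 8)
  else {
    storage.mode(mask) <- "integer"
    mask
  }
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- purrr::map_dfr(ids, function(id) {
    m <- labels == id
    px <- which(m, arr.ind = TRUE)
    pts <- region_contour(m)
    per <- contour_perimeter(pts)
    area <- nrow(px)
    ell <- moment_ellipse(px[, 1], px[, 2])
    circ <- if (per > 0) per^2 / (4 * pi * area) else {
      warn("region with degenerate perimeter; circularity reported as 0")
      0
    }
    tibble(
      id = id, area = area, perimeter = per, circularity = circ,
      eccentricity = ell$eccentricity, major_axis = ell$major,
      minor_axis = ell$minor,
      centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
      bbox_r1 = min(px[, 1]), bbox_r2 = max(px[, 1]),
      bbox_c1 = min(px[, 2]), bbox_c2 = max(px[, 2]),
      mean_intensity = if (is.null(intensity)) NA_real_ else mean(intensity[m])
    )
  })
  if (!nrow(rows)) rows <- tibble(
    id = integer(0), area = numeric(0), perimeter = numeric(0),
    circularity = numeric(0), eccentricity = numeric(0),
    major_axis = numeric(0), minor_axis = numeric(0),
    centroid_r = numeric(0), centroid_c = numeric(0),
    bbox_r1 = numeric(0), bbox_r2 = numeric(0), bbox_c1 = numeric(0),
    bbox_c2 = numeric(0), mean_intensity = numeric(0))
  structure(rows, labels = labels, class = c("region_table", class(rows)))
}

#' Containment proportion of one region inside another
#'
#' The fraction of the inner region's pixels that also belong to the outer
#' region, `|inner & outer| / |inner|`. A containment of at least 0.95 pairs
#' a nucleus with its cell.
#'
#' @param inner,outer Logical masks in the same frame.
#' @return Proportion in `[0, 1]`.
#' @export
containment_proportion <- function(inner, outer) {
  ni <- sum(inner)
  if (ni == 0) abort("containment is undefined for an empty inner region")
  sum(inner & outer) / ni
}

#' Default identification rule thresholds
#'
#' Shape-rule thresholds for [identify_nuclei()] and [identify_cells()]. The
#' containment threshold 0.95 is fixed by the method; area and shape bounds
#' are the re-derivable operating points (see [derive_shape_rules()]).
#'
#' @param min_area,max_area Plausible region area bounds (pixels).
#' @param circ_max Maximum circularity for a single (non-overlapped) region.
#' @param ecc_max Maximum eccentricity.
#' @param containment Nucleus-in-cell containment threshold.
#' @return Named list of thresholds.
#' @export
mdx_rules <- function(min_area = 50, max_area = 8000, circ_max = 1.5,
                      ecc_max = 0.95, containment = 0.95) {
  list(min_area = min_area, max_area = max_area, circ_max = circ_max,
       ecc_max = ecc_max, containment = containment)
}

#' Partition nucleus-mask regions into nucleus / overlapped / reject
#'
#' A region is a `nucleus` when its area lies within the plausible bounds and
#' both circularity and eccentricity stay below their maxima; a region that
#' fails the shape test but is no larger than twice the maximum plausible
#' area is an `overlapped` aggregate (routed to separation); anything else is
#' rejected.
#'
#' @param regions A `region_table` from [compute_region_descriptors()].
#' @param rules Thresholds from [mdx_rules()].
#' @return The region table with a `status` column added.
#' @export
identify_nuclei <- function(regions, rules = mdx_rules()) {
  out <- regions |>
    mutate(status = dplyr::case_when(
      .data$area < rules$min_area ~ "reject",
      .data$area <= rules$max_area & .data$circularity <= rules$circ_max &
        .data$eccentricity <= rules$ecc_max ~ "nucleus",
      .data$area <= 2 * rules$max_area ~ "overlapped",
      TRUE ~ "reject"
    ))
  structure(out, labels = attr(regions, "labels"),
            class = class(regions))
}

#' Match cell regions with their nuclei
#'
#' A cell-mask region is accepted (`ok`) when it contains at least one
#' identified nucleus with containment proportion at or above the threshold
#' and that nucleus is darker (lower mean L*) than the cell's cytoplasm. A
#' cell containing two or more matched nuclei is flagged `overlapped` and
#' routed to separation; nuclei contained by no cell are reported
#' `unmatched`. Matching is injective: a nucleus joins the cell that
#' contains the largest share of it.
#'
#' @param cell_regions `region_table` of the cell mask.
#' @param nuclei `region_table` from [identify_nuclei()] (rows with status
#'   `nucleus` are matched; `overlapped` nuclei pass through as such).
#' @param L Optional L* plane for the darker-than relation (skipped if NULL).
#' @param rules Thresholds from [mdx_rules()].
#' @return Tibble of class `cell_records` with columns `cell_id`,
#'   `nucleus_id`, `containment`, `flag`; label matrices travel in
#'   attributes `cell_labels` and `nucleus_labels`.
#' @export
identify_cells <- function(cell_regions, nuclei, L = NULL,
                           rules = mdx_rules()) {
  cl <- attr(cell_regions, "labels")
  nl <- attr(nuclei, "labels")
  nuc_ok <- dplyr::filter(nuclei, .data$status == "nucleus")
  # candidate pairs: best containing cell per nucleus
  cand <- purrr::map_dfr(nuc_ok$id, function(nid) {
    nm <- nl == nid
    counts <- tabulate(cl[nm], nbins = max(cl, 1))
    if (!any(counts > 0))
      return(tibble(nucleus_id = nid, cell_id = NA_integer_, containment = 0))
    best <- which.max(counts)
    tibble(nucleus_id = nid, cell_id = as.integer(best),
           containment = counts[best] / sum(nm))
  })
  records <- list()
  for (cid in cell_regions$id) {
    mine <- cand[!is.na(cand$cell_id) & cand$cell_id == cid &
                   cand$containment >= rules$containment, ]
    if (nrow(mine) && !is.null(L)) {
      keep <- vapply(mine$nucleus_id, function(nid) {
        nm <- nl == nid
        cyto <- cl == cid & !nm
        sum(cyto) > 0 && mean(L[nm]) < mean(L[cyto])
      }, logical(1))
      mine <- mine[keep, ]
    }
    flag <- if (nrow(mine) == 1) "ok" else if (nrow(mine) >= 2) "overlapped"
            else NA_character_
    if (is.na(flag)) {
      # no matched nucleus: an aggregate-shaped cell region is still routed
      # to separation, otherwise the region is dropped from the records
      shape_row <- cell_regions[cell_regions$id == cid, ]
      if (shape_row$circularity > rules$circ_max ||
          shape_row$eccentricity > rules$ecc_max)
        records[[length(records) + 1]] <-
          tibble(cell_id = cid, nucleus_id = NA_integer_,
                 containment = NA_real_, flag = "overlapped")
      next
    }
    if (flag == "ok")
      records[[length(records) + 1]] <-
        tibble(cell_id = cid, nucleus_id = mine$nucleus_id,
               containment = mine$containment, flag = "ok")
    else
      records[[length(records) + 1]] <-
        tibble(cell_id = cid, nucleus_id = mine$nucleus_id,
               containment = mine$containment, flag = "overlapped")
  }
  matched <- if (length(records)) bind_rows(records) else
    tibble(cell_id = integer(0), nucleus_id = integer(0),
           containment = numeric(0), flag = character(0))
  orphan <- setdiff(nuc_ok$id, matched$nucleus_id)
  if (length(orphan)) {
    warn(sprintf("%d nucleus region(s) matched no cell", length(orphan)))
    matched <- bind_rows(matched,
                         tibble(cell_id = NA_integer_, nucleus_id = orphan,
                                containment = NA_real_, flag = "unmatched"))
  }
  structure(matched, cell_labels = cl, nucleus_labels = nl,
            class = c("cell_records", class(matched)))
}

#' Re-derive shape-rule thresholds from labelled example regions
#'
#' Mirrors the rule-induction step of the identification design: fits a small
#' classification tree on (area, circularity, eccentricity) of regions
#' labelled regular vs irregular and reports the circularity/eccentricity
#' split points it finds, which can seed [mdx_rules()].
#'
#' @param regular,irregular `region_table`s of example regions.
#' @return List with the fitted `rpart` tree and the extracted `splits`.
#' @export
derive_shape_rules <- function(regular, irregular) {
  df <- bind_rows(mutate(as_tibble(regular), label = "regular"),
                  mutate(as_tibble(irregular), label = "irregular"))
  fit <- rpart::rpart(factor(label) ~ area + circularity + eccentricity,
                      data = df, method = "class",
                      control = rpart::rpart.control(minsplit = 5, cp = 0.01))
  sp <- fit$splits
  list(tree = fit,
       splits = if (is.null(sp)) tibble(variable = character(0),
                                        threshold = numeric(0))
       else tibble(variable = rownames(sp), threshold = sp[, "index"]))
}
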