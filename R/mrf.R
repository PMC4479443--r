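# Binary MRF segmentation. Each pixel carries three observations — channel
# intensity (L* for nuclei, b* for whole cells), structural texture energy
# and stochastic texture energy — modelled as class-conditional Gaussians
# (assumed independent, so log-likelihoods add), with an 8-neighbour Potts
# smoothness prior. The MAP label field is estimated by iterated conditional
# modes from a per-pixel maximum-likelihood start; ICM keeps the current
# label on ties, so the posterior energy is non-increasing sweep to sweep.

#' Assemble the observation stack for segmentation
#'
#' Builds the three observation planes and seeds the class-conditional
#' Gaussian parameters from the channel-group statistics: the intensity
#' plane is L* in nucleus mode and b* in cell mode; the texture planes are
#' windowed local mean energies of the structural and stochastic Wold
#' fields; foreground/background Gaussians are fitted over the pixels of the
#' selected foreground group and its complement.
#'
#' @param lab A `lab_image`.
#' @param fields A `wold_fields` decomposition of the texture channel.
#' @param groups A `channel_groups` with `foreground_group` set.
#' @param mode `"nucleus"` or `"cell"`.
#' @param window Texture energy window side (default 16).
#' @param var_floor Variance floor for degenerate classes (default 1e-6).
#' @return Object of class `observation_stack`: list of `planes` (intensity,
#'   structural, stochastic), `fg`/`bg` parameter tibbles and `dim`.
#' @export
build_observations <- function(lab, fields, groups, mode = c("nucleus", "cell"),
                               window = 16, var_floor = 1e-6) {
  mode <- match.arg(mode)
  intensity <- if (mode == "nucleus") lab$L else lab$b
  if (is.na(groups$foreground_group))
    abort("groups$foreground_group is not set; call select_foreground_group()")
  stopifnot(all(dim(intensity) == dim(groups$assignments)))
  # windowed local mean energies, log-transformed: energy maps are heavy-
  # tailed at region edges and the class-conditional Gaussians fit the log
  # scale far better
  planes <- list(
    intensity = intensity,
    structural = log(box_mean(structural_field(fields)^2, window) + 1e-3),
    stochastic = log(box_mean(fields$stochastic^2, window) + 1e-3)
  )
  fg_mask <- groups$assignments == groups$foreground_group
  # a plane that is constant everywhere carries no information: floor it
  # silently (both classes get the same Gaussian); warn only when an
  # informative plane has a degenerate class
  informative <- vapply(planes, function(p) stats::var(as.vector(p)) > 0,
                        logical(1))
  gauss <- function(mask) purrr::map_dfr(names(planes), function(p) {
    v <- planes[[p]][mask]
    vv <- mean((v - mean(v))^2)
    if (vv < var_floor) {
      if (informative[[p]])
        warn(sprintf("zero-variance class on plane %s; variance floored", p))
      vv <- var_floor
    }
    tibble(plane = p, mean = mean(v), variance = vv)
  })
  structure(list(planes = planes, fg = gauss(fg_mask), bg = gauss(!fg_mask),
                 mode = mode, dim = dim(intensity)),
            class = "observation_stack")
}

# Per-pixel Gaussian negative log-likelihood summed over the three planes.
stack_nll <- function(obs, params) {
  out <- 0
  for (k in seq_along(obs$planes)) {
    m <- params$mean[k]; v <- params$variance[k]
    out <- out + 0.5 * log(2 * pi * v) + (obs$planes[[k]] - m)^2 / (2 * v)
  }
  out
}

#' MAP label field by iterated conditional modes
#'
#' Minimizes `sum_sites NLL(label) + beta * #{disagreeing 8-neighbour
#' pairs}` by raster-scan ICM from the per-pixel maximum-likelihood
#' labelling, stopping at a label fixpoint or after `max_sweeps` sweeps.
#' With `beta = 0` the output equals the per-pixel ML labelling exactly.
#'
#' @param obs An `observation_stack`.
#' @param beta Non-negative smoothness weight (default 1.5).
#' @param max_sweeps Maximum ICM sweeps (default 20, must be positive).
#' @return Object of class `label_field`: `labels` (0/1 integer matrix),
#'   `energy` (trace including the initial labelling) and `sweeps`.
#' @export
icm_map_estimate <- function(obs, beta = 1.5, max_sweeps = 20) {
  if (max_sweeps <= 0) abort("max_sweeps must be positive")
  if (beta < 0) abort("beta must be non-negative")
  nll0 <- stack_nll(obs, obs$bg)
  nll1 <- stack_nll(obs, obs$fg)
  init <- matrix(as.integer(nll1 < nll0), obs$dim[1], obs$dim[2])
  if (beta == 0)
    return(structure(list(labels = init,
                          energy = sum(ifelse(init == 1, nll1, nll0)),
                          sweeps = 0L), class = "label_field"))
  res <- icm_cpp(init, nll0, nll1, beta, as.integer(max_sweeps))
  structure(list(labels = res$labels, energy = res$energy,
                 sweeps = res$sweeps), class = "label_field")
}

# Morphological cleanup: drop specks, fill small enclosed holes.
clean_mask <- function(mask, min_object = 50, max_hole = 200) {
  mask <- remove_small_objects(mask, min_object)
  fill_small_holes(mask, max_hole)
}

#' Segment a smear image into foreground and background
#'
#' End-to-end contextual segmentation of one raster: Lab conversion, k-means
#' channel grouping (k = 2 on L* for nuclei, k = 3 on b* for whole cells),
#' Wold texture decomposition of the texture channel, observation assembly,
#' ICM MAP estimation, and cleanup (small-object removal and hole filling).
#'
#' @param rgb RGB array (0..255 or 0..1).
#' @param mode `"nucleus"` or `"cell"`.
#' @param config Pipeline configuration from [mdx_config()].
#' @return Logical mask matrix; the `label_field` travels in attribute
#'   `label_field`.
#' @export
segment_image <- function(rgb, mode = c("nucleus", "cell"),
                          config = mdx_config()) {
  mode <- match.arg(mode)
  lab <- rgb_to_lab(rgb)
  channel <- if (mode == "nucleus") lab$L else lab$b
  k <- if (mode == "nucleus") config$color$k_L else config$color$k_b
  groups <- cluster_channel(channel, k = k, seed = config$color$seed,
                            restarts = config$color$restarts)
  groups$foreground_group <- select_foreground_group(groups, mode)
  tex_plane <- if (config$texture$channel == "L") lab$L else lab$b
  fields <- wold_decompose(tex_plane,
                           amplitude_threshold = config$texture$amplitude_threshold,
                           evanescent_threshold = config$texture$evanescent_threshold,
                           max_lines = config$texture$max_lines)
  obs <- build_observations(lab, fields, groups, mode,
                            window = config$texture$window,
                            var_floor = config$mrf$var_floor)
  lf <- icm_map_estimate(obs, beta = config$mrf$beta,
                         max_sweeps = config$mrf$max_sweeps)
  mask <- clean_mask(lf$labels == 1L, config$clean$min_object,
                     config$clean$max_hole)
  structure(mask, label_field = lf)
}

#' Score a predicted mask against ground truth
#'
#' The segmentation metrics with predicted-count denominators:
#' `precision = TP / P`, `fp_rate = FP / P`, `fn_rate = FN / N`, where P and
#' N are the predicted foreground and background pixel counts. Reported in
#' percent; precision and fp_rate share P and sum to 100.
#'
#' @param predicted,truth Logical masks of equal dimension.
#' @return Tibble with `precision`, `fp_rate`, `fn_rate` (percent). When no
#'   pixel is predicted foreground the P-denominated metrics are `NA` with a
#'   warning.
#' @export
score_segmentation <- function(predicted, truth) {
  stopifnot(all(dim(predicted) == dim(truth)))
  predicted <- predicted != 0; truth <- truth != 0
  P <- sum(predicted); N <- sum(!predicted)
  tp <- sum(predicted & truth); fp <- P - tp
  fn <- sum(!predicted & truth)
  if (P == 0) {
    warn("no pixels predicted as cellular elements; precision undefined")
    return(tibble(precision = NA_real_, fp_rate = NA_real_,
                  fn_rate = 100 * fn / N))
  }
  tibble(precision = 100 * tp / P, fp_rate = 100 * fp / P,
         fn_rate = if (N > 0) 100 * fn / N else NA_real_)
}
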