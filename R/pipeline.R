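# Pipeline wiring: a single nested configuration with per-module
# namespaces, and an end-to-end driver chaining segmentation,
# identification, separation and feature extraction over a set of smears.

#' Pipeline configuration
#'
#' Returns the default configuration, optionally overridden by a nested
#' list; unknown keys are rejected. The printed-threshold choices of the
#' method (harmonic amplitude 10, containment 0.95, 10 folds) live here so
#' every run is reproducible from its config.
#'
#' @param overrides Nested list of values to override, e.g.
#'   `list(mrf = list(beta = 2))`.
#' @return Nested configuration list of class `mdx_config`.
#' @export
mdx_config <- function(overrides = list()) {
  cfg <- list(
    color = list(k_L = 2, k_b = 3, restarts = 10, seed = 1),
    texture = list(window = 16, amplitude_threshold = 10,
                   evanescent_threshold = 5, max_lines = 4, channel = "L"),
    mrf = list(beta = 1.5, max_sweeps = 20, var_floor = 1e-6),
    clean = list(min_object = 50, max_hole = 200),
    rules = list(min_area = 50, max_area = 8000, circ_max = 1.5,
                 ecc_max = 0.95, containment = 0.95),
    separation = list(depth_min = 3, angle_res = 1, min_area = 30),
    classify = list(folds = 10, learner = "rf"),
    diagnosis = list(min_margin = 1e-9, learner = "rf")
  )
  for (section in names(overrides)) {
    if (!section %in% names(cfg))
      abort(sprintf("unknown config section '%s'", section))
    for (key in names(overrides[[section]])) {
      if (!key %in% names(cfg[[section]]))
        abort(sprintf("unknown config key '%s.%s'", section, key))
      cfg[[section]][[key]] <- overrides[[section]][[key]]
    }
  }
  structure(cfg, class = c("mdx_config", "list"))
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the image pipeline over a set of smears
#'
#' For each smear: segment the nucleus and cell masks, identify nuclei and
#' cells, separate overlapped aggregates, and extract the feature table.
#' Every artifact is stamped with the configuration hash and seed.
#'
#' @param smears List of `smear` objects (or a single one).
#' @param config Configuration from [mdx_config()].
#' @param stop_after One of `"segment"`, `"identify"`, `"separate"`,
#'   `"features"` (default: run everything).
#' @return List of class `mdx_run` with per-image artifacts and a pooled
#'   feature tibble (`features`), stamped with `config_hash`.
#' @export
run_pipeline <- function(smears, config = mdx_config(), stop_after = "features") {
  if (inherits(smears, "smear")) smears <- list(smears)
  stages <- c("segment", "identify", "separate", "features")
  stop_after <- match.arg(stop_after, stages)
  rules <- do.call(mdx_rules, config$rules)
  images <- vector("list", length(smears))
  for (k in seq_along(smears)) {
    sm <- smears[[k]]
    art <- list(index = k)
    step <- function(stage, expr) {
      tryCatch(expr, error = function(e)
        abort(sprintf("stage '%s' failed on image %d: %s", stage, k,
                      conditionMessage(e))))
    }
    art$nucleus_mask <- step("segment", segment_image(sm$image, "nucleus", config))
    art$cell_mask <- step("segment", segment_image(sm$image, "cell", config))
    if (stop_after != "segment") {
      lab <- rgb_to_lab(sm$image)
      nuc_reg <- step("identify",
                      identify_nuclei(compute_region_descriptors(art$nucleus_mask,
                                                                 lab$L), rules))
      cell_reg <- step("identify", compute_region_descriptors(art$cell_mask, lab$L))
      art$records <- step("identify",
                          identify_cells(cell_reg, nuc_reg, lab$L, rules))
      if (stop_after %in% c("separate", "features")) {
        art$cell_labels <- step("separate", separate_overlapped_records(
          art$records, depth_min = config$separation$depth_min,
          angle_res = config$separation$angle_res,
          min_area = config$separation$min_area))
        # re-identify over the separated instances so split cells become
        # ordinary records with their own features
        art$records <- step("separate", identify_cells(
          compute_region_descriptors(art$cell_labels, lab$L), nuc_reg, lab$L,
          rules))
        if (stop_after == "features")
          art$features <- step("features", extract_features(art$records, sm$image))
      }
    }
    images[[k]] <- art
  }
  features <- purrr::map_dfr(seq_along(images), function(k) {
    f <- images[[k]]$features
    if (is.null(f) || !nrow(f)) return(tibble())
    bind_cols(tibble(image = k), f)
  })
  structure(list(images = images, features = features,
                 config = config, config_hash = config_hash(config)),
            class = "mdx_run")
}

#' @export
print.mdx_run <- function(x, ...) {
  cat("pipeline run:", length(x$images), "image(s),",
      nrow(x$features), "cell feature row(s); config", x$config_hash, "\n")
  invisible(x)
}
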