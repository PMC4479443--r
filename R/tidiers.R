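# broom-style tidiers and ggplot2 visualisations for the result objects.

#' @describeIn train_and_crossvalidate Tidy the per-class CV metrics.
#' @param x A `leukemia_cv` object.
#' @param ... Unused.
#' @export
tidy.leukemia_cv <- function(x, ...) {
  conf <- as.matrix(x$confusion)
  purrr::map_dfr(rownames(conf), function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- sum(conf) - tp - fn - fp
    tibble(class = cl, n = sum(conf[cl, ]),
           recall = tp / (tp + fn),
           specificity = tn / (tn + fp),
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
}

#' @describeIn train_and_crossvalidate One-row summary (accuracy %, TPR,
#'   TNR, AUC).
#' @export
glance.leukemia_cv <- function(x, ...) {
  tibble(learner = x$learner, folds = x$folds, n = length(x$truth),
         accuracy = x$accuracy, tpr = x$tpr, tnr = x$tnr, auc = x$auc)
}

#' @describeIn diagnose_patients Tidy per-patient calls.
#' @param x A `diagnosis_set`.
#' @param ... Unused.
#' @export
tidy.diagnosis_set <- function(x, ...) {
  select(as_tibble(x), "patient_id", "scheme", "family_call", "subtype_call",
         "family_margin", "subtype_margin", "n_samples")
}

#' @describeIn diagnose_patients One-row scheme summary.
#' @export
glance.diagnosis_set <- function(x, ...) {
  tibble(scheme = x$scheme[1], n_patients = nrow(x),
         not_determined = sum(x$subtype_call == "not_determined"))
}

#' Plot a synthetic smear with optional ground-truth outlines
#'
#' @param object A `smear`.
#' @param ... Unused.
#' @return A ggplot object showing the rendered RGB raster.
#' @export
autoplot.smear <- function(object, ...) {
  img <- to_255(object$image) / 255
  nr <- dim(img)[1]; nc <- dim(img)[2]
  rast <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(rast) <- c(nr, nc)
  df <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  df$fill <- as.vector(rast)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot pooled CV metrics of one or more reports
#'
#' @param ... Named `leukemia_cv` objects.
#' @return A ggplot bar chart of accuracy/TPR/TNR/AUC per report.
#' @export
plot_cv_metrics <- function(...) {
  reports <- list(...)
  if (is.null(names(reports)) || any(names(reports) == ""))
    names(reports) <- paste0("model", seq_along(reports))
  df <- purrr::map_dfr(names(reports), function(nm) {
    g <- glance(reports[[nm]])
    tidyr::pivot_longer(
      tibble(model = nm, accuracy = g$accuracy / 100, tpr = g$tpr,
             tnr = g$tnr, auc = g$auc),
      -"model", names_to = "metric", values_to = "value")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL)
}
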