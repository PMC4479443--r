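# Patient diagnosis by majority vote. Two schemes over all of a patient's
# cell samples:
#   * cascade — decide the family (ALL/AML) first by majority over samples,
#     then consult only the winning family's subtype classifiers; a wrong
#     family call therefore forces a wrong subtype (the scheme's documented
#     failure mode);
#   * fusion — every classifier votes on every sample; each classifier's
#     vote is one unit split equally over the subtypes it supports, so the
#     tallies of a patient sum exactly to n_samples x n_classifiers.
# The winner needs a strict plurality: a top-two gap below `min_margin`
# (default: an epsilon, i.e. ties only) returns "not determined".

DX_SUBTYPES <- c("L1", "L2", "M2", "M3", "M5")
subtype_family <- function(s) ifelse(startsWith(s, "L"), "ALL", "AML")

#' Train the classifier bank used for diagnosis
#'
#' Fits, on a labelled training table, the classifiers consumed by both
#' diagnosis schemes: ALLvsAML, L1vsL2, the three one-vs-rest AML binaries,
#' the three-class AML model and the five-class subtype model.
#'
#' @param train Tibble with `class` (subtype labels) plus feature columns.
#' @param learner Learner id (see [train_and_crossvalidate()]).
#' @param seed Integer seed.
#' @return List of class `diagnosis_models`.
#' @export
train_diagnosis_models <- function(train, learner = "rf", seed = 1) {
  task_names <- c("ALLvsAML", "L1vsL2", "M2vs(M3&M5)", "M3vs(M2&M5)",
                  "M5vs(M2&M3)", "M2vsM3vsM5", "subtype")
  models <- lapply(task_names, function(tn) {
    d <- build_task_dataset(train, tn)
    x <- as.matrix(d[, setdiff(names(d), "class")])
    storage.mode(x) <- "double"
    y <- droplevels(d$class)
    list(task = leukemia_task(tn), fit = fit_learner(x, y, learner, seed),
         levels = levels(y))
  })
  names(models) <- task_names
  structure(list(models = models, learner = learner, seed = seed,
                 columns = setdiff(names(train), "class")),
            class = "diagnosis_models")
}

# Per-sample predicted label from one stored model.
predict_task <- function(models, task_name, newx) {
  m <- models$models[[task_name]]
  s <- m$fit$predict_scores(newx)
  m$levels[max.col(s, ties.method = "first")]
}

# Plurality call over a named tally; gap below min_margin -> not_determined.
tally_call <- function(tally, min_margin) {
  if (!length(tally) || all(tally == 0)) return("not_determined")
  ord <- sort(tally, decreasing = TRUE)
  gap <- if (length(ord) > 1) ord[1] - ord[2] else ord[1]
  if (gap < min_margin) "not_determined" else names(ord)[1]
}

#' Cascade diagnosis of one patient
#'
#' Family first: majority over the per-sample ALLvsAML predictions. Only the
#' winning family's subtype classifiers are then consulted — L1vsL2 for ALL;
#' the three one-vs-rest binaries for AML, a positive prediction casting one
#' vote for its subtype. A family tie yields `not_determined` and the
#' subtype is not evaluated.
#'
#' @param samples Feature tibble of the patient's cell samples (feature
#'   columns only, or with extra id columns which are ignored).
#' @param models A `diagnosis_models` bank.
#' @param min_margin Minimum winning top-two tally gap (default `1e-9`,
#'   i.e. only exact ties are undetermined).
#' @return List of class `patient_diagnosis` with calls, tallies and
#'   margins.
#' @export
cascade_diagnose <- function(samples, models, min_margin = 1e-9) {
  x <- sample_matrix(samples, models)
  if (!nrow(x)) abort("no samples for patient")
  fam_pred <- predict_task(models, "ALLvsAML", x)
  fam_tally <- table_tally(fam_pred, c("ALL", "AML"))
  family <- tally_call(fam_tally, min_margin)
  sub_tally <- setNames(numeric(5), DX_SUBTYPES)
  subtype <- "not_determined"
  if (family == "ALL") {
    p <- predict_task(models, "L1vsL2", x)
    sub_tally[c("L1", "L2")] <- table_tally(p, c("L1", "L2"))
    subtype <- tally_call(sub_tally[c("L1", "L2")], min_margin)
  } else if (family == "AML") {
    for (tn in c("M2vs(M3&M5)", "M3vs(M2&M5)", "M5vs(M2&M3)")) {
      pos <- leukemia_task(tn)$positive
      p <- predict_task(models, tn, x)
      sub_tally[pos] <- sub_tally[pos] + sum(p == pos)
    }
    subtype <- tally_call(sub_tally[c("M2", "M3", "M5")], min_margin)
  }
  new_patient_diagnosis("cascade", family, subtype, fam_tally, sub_tally,
                        n_samples = nrow(x))
}

#' Fused diagnosis of one patient
#'
#' Every classifier in the bank votes on every sample; each vote is one unit
#' split equally over the subtypes the classifier's prediction supports
#' (e.g. an ALLvsAML vote for ALL adds 1/2 to L1 and L2; an M2vs(M3&M5)
#' vote for the rest class adds 1/2 to M3 and M5). Subtype = strict
#' plurality of the pooled tally; the family call is the winning subtype's
#' family, falling back to the ALLvsAML majority when the subtype is
#' undetermined.
#'
#' @inheritParams cascade_diagnose
#' @return A `patient_diagnosis`.
#' @export
fused_diagnose <- function(samples, models, min_margin = 1e-9) {
  x <- sample_matrix(samples, models)
  if (!nrow(x)) abort("no samples for patient")
  support <- list(
    "subtype" = function(p) p,
    "M2vsM3vsM5" = function(p) p,
    "L1vsL2" = function(p) p,
    "ALLvsAML" = function(p) if (p == "ALL") c("L1", "L2") else c("M2", "M3", "M5"),
    "M2vs(M3&M5)" = function(p) if (p == "M2") "M2" else c("M3", "M5"),
    "M3vs(M2&M5)" = function(p) if (p == "M3") "M3" else c("M2", "M5"),
    "M5vs(M2&M3)" = function(p) if (p == "M5") "M5" else c("M2", "M3")
  )
  tally <- setNames(numeric(5), DX_SUBTYPES)
  for (tn in names(support)) {
    preds <- predict_task(models, tn, x)
    for (p in preds) {
      sup <- support[[tn]](p)
      tally[sup] <- tally[sup] + 1 / length(sup)
    }
  }
  subtype <- tally_call(tally, min_margin)
  fam_pred <- predict_task(models, "ALLvsAML", x)
  fam_tally <- table_tally(fam_pred, c("ALL", "AML"))
  family <- if (subtype != "not_determined") subtype_family(subtype)
            else tally_call(fam_tally, min_margin)
  new_patient_diagnosis("fused", family, subtype, fam_tally, tally,
                        n_samples = nrow(x))
}

sample_matrix <- function(samples, models) {
  cols <- intersect(models$columns, names(samples))
  if (length(cols) < length(models$columns))
    abort("samples lack feature columns the models were trained on")
  x <- as.matrix(samples[, models$columns, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

table_tally <- function(pred, levels) {
  t <- table(factor(pred, levels = levels))
  setNames(as.numeric(t), levels)
}

new_patient_diagnosis <- function(scheme, family, subtype, fam_tally,
                                  sub_tally, n_samples) {
  margin <- function(t) {
    o <- sort(t, decreasing = TRUE)
    if (length(o) > 1) o[1] - o[2] else o[1]
  }
  structure(list(scheme = scheme, family_call = family,
                 subtype_call = subtype, family_tally = fam_tally,
                 subtype_tally = sub_tally,
                 family_margin = margin(fam_tally),
                 subtype_margin = margin(sub_tally),
                 n_samples = n_samples),
            class = "patient_diagnosis")
}

#' @export
print.patient_diagnosis <- function(x, ...) {
  cat(sprintf("[%s] family %s, subtype %s (%d samples)\n", x$scheme,
              x$family_call, x$subtype_call, x$n_samples))
  invisible(x)
}

#' Diagnose every patient of a cohort
#'
#' @param features Per-sample feature tibble with `patient_id` (as produced
#'   by [generate_patient_set()]).
#' @param models A `diagnosis_models` bank.
#' @param scheme `"fused"` or `"cascade"`.
#' @param min_margin Passed to the per-patient scheme.
#' @return Tibble of class `diagnosis_set`: one row per patient with
#'   `family_call`, `subtype_call`, margins, and the tallies as list
#'   columns.
#' @export
diagnose_patients <- function(features, models, scheme = c("fused", "cascade"),
                              min_margin = 1e-9) {
  scheme <- match.arg(scheme)
  fun <- if (scheme == "fused") fused_diagnose else cascade_diagnose
  out <- purrr::map_dfr(unique(features$patient_id), function(pid) {
    d <- fun(features[features$patient_id == pid, , drop = FALSE], models,
             min_margin)
    tibble(patient_id = pid, scheme = scheme,
           family_call = d$family_call, subtype_call = d$subtype_call,
           family_margin = d$family_margin, subtype_margin = d$subtype_margin,
           n_samples = d$n_samples,
           family_tally = list(d$family_tally),
           subtype_tally = list(d$subtype_tally))
  })
  structure(out, class = c("diagnosis_set", class(out)))
}

#' Summarize diagnoses against ground truth
#'
#' Per family and per subtype (plus `Types` / `Subtypes` aggregate rows):
#' percent correct, percent not determined, percent failed. The three
#' percentages sum to 100 in every row.
#'
#' @param diagnoses A `diagnosis_set`.
#' @param manifest Truth tibble with `patient_id`, `family`, `subtype`.
#' @return Tibble with columns `level`, `class`, `n`, `correct_pct`,
#'   `not_determined_pct`, `failed_pct`.
#' @export
evaluate_diagnosis <- function(diagnoses, manifest) {
  unknown <- setdiff(diagnoses$patient_id, manifest$patient_id)
  if (length(unknown))
    abort(sprintf("unknown patient id(s): %s", paste(unknown, collapse = ", ")))
  d <- left_join(as_tibble(diagnoses),
                 manifest[, c("patient_id", "family", "subtype")],
                 by = "patient_id")
  row_of <- function(call, truth, label, level) {
    n <- length(call)
    nd <- sum(call == "not_determined")
    ok <- sum(call == truth)
    tibble(level = level, class = label, n = n,
           correct_pct = 100 * ok / n,
           not_determined_pct = 100 * nd / n,
           failed_pct = 100 * (n - ok - nd) / n)
  }
  fam_rows <- bind_rows(
    row_of(d$family_call, d$family, "Types", "family"),
    purrr::map_dfr(sort(unique(d$family)), function(f) {
      s <- d[d$family == f, ]
      row_of(s$family_call, s$family, f, "family")
    })
  )
  sub_rows <- bind_rows(
    row_of(d$subtype_call, d$subtype, "Subtypes", "subtype"),
    purrr::map_dfr(sort(unique(d$subtype)), function(st) {
      s <- d[d$subtype == st, ]
      row_of(s$subtype_call, s$subtype, st, "subtype")
    })
  )
  bind_rows(fam_rows, sub_rows)
}
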