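#' Name the five clusters as subtype archetypes
#'
#' Assigns the archetype labels SIDD, SIRD, MOD, MDH and MD to the unified
#' clusters of a five-cluster model by sequential argmax over the
#' sex-averaged z-centroids: the cluster with the highest HbA1c z-score is
#' SIDD (severe insulin-deficient); among the remaining, the highest
#' C-peptide is SIRD (severe insulin-resistant); then the highest BMI is MOD
#' (mild obesity-related); then the highest HDL-cholesterol is MDH (mild
#' with high HDL); the last is MD (mild, no extreme characteristic).  The
#' sex-averaged centroid matrix is stored as evidence for audit.  The
#' mapping depends only on the centroids, not on the cluster indices.
#'
#' @param model A `cluster_model` with `k = 5`.
#' @return The model with `$archetypes` (archetype per unified cluster id)
#'   and `$naming_evidence` (the sex-averaged z-centroid matrix) filled in.
#' @export
name_archetypes <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 5) {
    abort_diabclust("archetype naming is defined only for k = 5",
                    "diabclust_usage_error")
  }
  avg <- (model$centroids$male + model$centroids$female) / 2
  colnames(avg) <- model$variables
  nm <- character(5)
  left <- 1:5
  take <- function(var) {
    i <- left[which.max(avg[left, var])]
    left <<- setdiff(left, i)
    i
  }
  nm[take("hba1c_mmol_mol")] <- "SIDD"
  nm[take("c_peptide_nmol_l")] <- "SIRD"
  nm[take("bmi")] <- "MOD"
  nm[take("hdl_mmol_l")] <- "MDH"
  nm[left] <- "MD"
  model$archetypes <- nm
  model$naming_evidence <- avg
  model
}

#' Assign subjects to the clusters of a fitted model
#'
#' Classifies each subject by standardizing the five clustering variables
#' with the model's own per-sex scaler and labelling with the nearest
#' centroid under squared-Euclidean distance (ties go to the lowest cluster
#' index).  The model is a self-contained classifier, so a cohort can be
#' assigned with another cohort's model unchanged.
#'
#' @param cohort A cohort tibble with complete clustering variables.
#' @param model A `cluster_model`.
#' @return A tibble `subject_id`, `cluster` (unified id), and `archetype`
#'   (when the model has been named via [name_archetypes()]).
#' @export
assign_clusters <- function(cohort, model) {
  stopifnot(inherits(model, "cluster_model"))
  assert_cols(cohort, c("subject_id", "sex", CLUSTER_VARS), "cohort")
  bad_sex <- setdiff(unique(cohort$sex), names(model$scalers))
  if (length(bad_sex) > 0) {
    abort_diabclust(sprintf("model has no scaler for sex '%s'", bad_sex[1]),
                    "diabclust_usage_error")
  }
  incomplete <- !complete.cases(cohort[CLUSTER_VARS])
  if (any(incomplete)) {
    abort_diabclust(sprintf("subject %s has incomplete clustering variables",
                            cohort$subject_id[which(incomplete)[1]]),
                    "diabclust_data_error")
  }
  out <- vector("list", 2)
  for (sx in unique(cohort$sex)) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    Z <- apply_scaler(model$scalers[[sx]], sub)
    C <- model$centroids[[sx]]
    D <- outer(rowSums(Z^2), rep(1, nrow(C))) - 2 * Z %*% t(C) +
      outer(rep(1, nrow(Z)), rowSums(C^2))
    cl <- max.col(-D, ties.method = "first")
    out[[sx]] <- tibble(subject_id = sub$subject_id, cluster = cl)
  }
  res <- bind_rows(out)
  res <- res[match(cohort$subject_id, res$subject_id), , drop = FALSE]
  if (!is.null(model$archetypes)) res$archetype <- model$archetypes[res$cluster]
  as_tibble(res)
}

# Clopper-Pearson exact binomial interval
clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

# Build a confusion_result from a reference/predicted label pairing.
# `match_map`: named character vector mapping each reference class to the
# predicted class that counts as its true positive.
confusion_from_labels <- function(reference, predicted, ref_levels, pred_levels,
                                  match_map, level = 0.95) {
  tab <- table(factor(reference, levels = ref_levels),
               factor(predicted, levels = pred_levels))
  n <- sum(tab)
  metrics <- purrr::map_dfr(ref_levels, function(cls) {
    pred_cls <- match_map[[cls]]
    tp <- if (is.na(pred_cls)) 0L else tab[cls, pred_cls]
    fn <- sum(tab[cls, ]) - tp
    fp <- if (is.na(pred_cls)) 0L else sum(tab[, pred_cls]) - tp
    tn <- n - tp - fn - fp
    sens_ci <- clopper_pearson(tp, tp + fn, level)
    spec_ci <- clopper_pearson(tn, tn + fp, level)
    tibble(archetype = cls, matched_prediction = unname(pred_cls),
           tp = as.integer(tp), fn = as.integer(fn),
           fp = as.integer(fp), tn = as.integer(tn),
           sensitivity = tp / (tp + fn),
           sens_lo = sens_ci[1], sens_hi = sens_ci[2],
           specificity = tn / (tn + fp),
           spec_lo = spec_ci[1], spec_hi = spec_ci[2])
  })
  structure(list(table = unclass(tab), metrics = metrics, n = n, level = level),
            class = "confusion_result")
}

#' Cross-validate cluster assignments between two cohort models
#'
#' Subjects of cohort A are labelled twice: with their own cohort's model
#' (the reference clusters) and with another cohort's model (the predicted
#' clusters; cohort A is standardized with model B's scalers, since the
#' model is a self-contained classifier).  Both models must have been named
#' with [name_archetypes()]; columns are aligned by archetype, which makes
#' the result invariant to each model's internal cluster indexing.  Reports
#' the confusion matrix and per-archetype sensitivity `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)` (one-vs-rest over all subjects) with exact
#' Clopper-Pearson confidence intervals.
#'
#' @param cohort_a The cohort to be re-assigned.
#' @param model_a Its own fitted, named model (reference labels).
#' @param model_b The other cohort's fitted, named model (predicted labels).
#' @param level Confidence level (default 0.95).
#' @return A `confusion_result`: `$table` (reference x predicted counts),
#'   `$metrics` (per-archetype estimates and CIs), `$n`.
#' @export
cross_validate <- function(cohort_a, model_a, model_b, level = 0.95) {
  if (is.null(model_a$archetypes) || is.null(model_b$archetypes)) {
    abort_diabclust("both models must be named with name_archetypes() first",
                    "diabclust_usage_error")
  }
  if (model_a$k != model_b$k ||
      !identical(model_a$variables, model_b$variables)) {
    abort_diabclust("models must share k and variable order",
                    "diabclust_usage_error")
  }
  reference <- assign_clusters(cohort_a, model_a)$archetype
  predicted <- assign_clusters(cohort_a, model_b)$archetype
  confusion_from_labels(reference, predicted,
                        ref_levels = ARCHETYPES, pred_levels = ARCHETYPES,
                        match_map = setNames(ARCHETYPES, ARCHETYPES),
                        level = level)
}

#' Compare predicted archetypes against an external labelling
#'
#' Confronts the pipeline's archetype labels with an external reference
#' labelling of the same subjects (for instance a published clustering),
#' optionally pooling a set of archetypes into one predicted class first —
#' e.g. `merge = c("MD", "MDH")` treats the two mild clusters as a single
#' class when the external labelling has one combined mild/age-related
#' group.  Reference classes are matched to predicted classes by name when
#' the names coincide, otherwise by greatest overlap (greedy, largest
#' reference class first).
#'
#' @param predicted Tibble `subject_id`, `archetype` (the pipeline labels).
#' @param external Tibble `subject_id`, `label` (the reference labels).
#' @param merge Optional character vector of archetypes pooled into one
#'   predicted class (named by joining with `+`).
#' @param level Confidence level.
#' @return A `confusion_result` with rows = external classes.
#' @export
compare_to_external <- function(predicted, external, merge = NULL, level = 0.95) {
  assert_cols(predicted, c("subject_id", "archetype"), "predicted labels")
  assert_cols(external, c("subject_id", "label"), "external labels")
  missing <- setdiff(external$subject_id, predicted$subject_id)
  extra <- setdiff(predicted$subject_id, external$subject_id)
  if (length(missing) > 0 || length(extra) > 0) {
    abort_diabclust(sprintf(
      "label sets cover different subjects (%d missing from predictions: %s%s)",
      length(missing), paste(head(missing, 3), collapse = ", "),
      if (length(extra) > 0) sprintf("; %d extra", length(extra)) else ""),
      "diabclust_usage_error")
  }
  pred <- predicted$archetype[match(external$subject_id, predicted$subject_id)]
  if (!is.null(merge)) {
    pooled_name <- paste(sort(merge), collapse = "+")
    pred[pred %in% merge] <- pooled_name
  }
  ref_levels <- unique(external$label)
  pred_levels <- unique(pred)
  ## match reference classes to predicted classes
  if (all(ref_levels %in% pred_levels)) {
    match_map <- setNames(ref_levels, ref_levels)
  } else {
    tab <- table(factor(external$label, ref_levels), factor(pred, pred_levels))
    match_map <- setNames(rep(NA_character_, length(ref_levels)), ref_levels)
    free <- pred_levels
    for (cls in ref_levels[order(-rowSums(tab))]) {
      if (length(free) == 0) break
      best <- free[which.max(tab[cls, free])]
      match_map[cls] <- best
      free <- setdiff(free, best)
    }
  }
  confusion_from_labels(external$label, pred, ref_levels, pred_levels,
                        match_map, level)
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("Confusion (n = %d), reference rows vs predicted columns:\n", x$n))
  print(x$table)
  cat("\n")
  print(select(x$metrics, "archetype", "sensitivity", "sens_lo", "sens_hi",
               "specificity", "spec_lo", "spec_hi"), n = Inf)
  invisible(x)
}

#' @export
tidy.confusion_result <- function(x, ...) x$metrics

#' @export
glance.confusion_result <- function(x, ...) {
  tibble(n = x$n,
         accuracy = sum(x$metrics$tp) / x$n,
         min_sensitivity = min(x$metrics$sensitivity),
         mean_sensitivity = mean(x$metrics$sensitivity))
}

#' Serialize a confusion result
#'
#' Writes the counts as a flat CSV (`reference,predicted,count`), the
#' per-archetype metrics as CSV, and everything as one JSON document.
#'
#' @param x A `confusion_result`.
#' @param path_prefix Path prefix; writes `<prefix>_counts.csv`,
#'   `<prefix>_metrics.csv` and `<prefix>.json`.
#' @return The JSON path, invisibly.
#' @export
write_confusion <- function(x, path_prefix) {
  stopifnot(inherits(x, "confusion_result"))
  counts <- as.data.frame(as.table(x$table), stringsAsFactors = FALSE)
  names(counts) <- c("reference", "predicted", "count")
  readr::write_csv(as_tibble(counts), paste0(path_prefix, "_counts.csv"),
                   progress = FALSE)
  readr::write_csv(x$metrics, paste0(path_prefix, "_metrics.csv"),
                   progress = FALSE)
  jsonlite::write_json(list(n = x$n, level = x$level, counts = counts,
                            metrics = x$metrics),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(path_prefix, ".json"))
}

#' Plot per-cluster clinical profiles
#'
#' Median of each clustering variable per assigned cluster, faceted by
#' variable — the tabular equivalent of the per-cluster profile figures.
#'
#' @param cohort A cohort tibble.
#' @param labels Assignment tibble from [assign_clusters()] (or truth labels
#'   with an `archetype` column).
#' @return A ggplot.
#' @export
plot_cluster_profiles <- function(cohort, labels) {
  dat <- inner_join(cohort, labels, by = "subject_id") |>
    tidyr::pivot_longer(dplyr::all_of(CLUSTER_VARS),
                        names_to = "variable", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$archetype, y = .data$value,
                                    fill = .data$archetype)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, show.legend = FALSE) +
    ggplot2::facet_wrap(~ variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
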