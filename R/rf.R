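#' Build the voxel-wise feature table for a progression task
#'
#' One row per eligible in-band voxel. For the CEL task, positives are
#' voxels that become enhancing (`NAV_to_CEL` or `NEL_to_CEL`) and
#' negatives are stable NAV voxels; for the NEL task, positives are
#' `NAV_to_NEL` voxels against the same negatives. Channels are min-max
#' normalized within the brain per case. The MRSI coverage flag is kept
#' as a column: voxels outside the PRESS box carry the generator's
#' baseline fill in the metabolic channels, and the flag lets a model
#' down-weight them without dropping rows.
#'
#' @param cases list of `case_record`s.
#' @param task `"cel"` or `"nel"`.
#' @param band_mm analysis band width (mm).
#' @param downsample_stable per-case cap on stable-NAV rows (seeded
#'   sampling); `Inf` keeps all.
#' @param seed seed for the optional down-sampling.
#' @param normalize min-max normalize channels within brain first?
#' @return Tibble with `case_id`, `cohort`, `voxel`, one column per
#'   channel, `mrsi_covered`, `class`, and the binary outcome `y`.
#'   Provenance (task, cap, seed) is attached as attribute `"provenance"`.
#' @export
build_feature_table <- function(cases, task = c("cel", "nel"), band_mm = 40,
                                downsample_stable = Inf, seed = 1,
                                normalize = TRUE) {
  task <- match.arg(task)
  pos_classes <- if (task == "cel") c("NAV_to_CEL", "NEL_to_CEL") else "NAV_to_NEL"
  rows <- purrr::map2_dfr(cases, seq_along(cases), function(cs, i) {
    band <- band_mask(cs$pre_masks, band_mm)
    field <- label_transitions(cs$pre_masks, cs$prog_masks, band)
    lv <- attr(field, "levels")
    codes <- as.integer(field$values)
    cls <- rep(NA_character_, length(codes)) # code 0 = outside the brain
    cls[codes > 0] <- lv[codes[codes > 0]]
    keep_pos <- which(cls %in% pos_classes)
    keep_neg <- which(cls == "STABLE_NAV")
    if (length(keep_pos) == 0) {
      warning("case ", cs$case_id, " has no positive voxels for the ",
              task, " task; contributing negatives only")
    }
    if (is.finite(downsample_stable) && length(keep_neg) > downsample_stable) {
      set.seed(as.integer((seed * 7919 + i) %% 2147483647))
      keep_neg <- sort(sample(keep_neg, downsample_stable))
    }
    keep <- c(keep_pos, keep_neg)
    chans <- cs$channels
    if (normalize) {
      chans <- lapply(chans, minmax_normalize, within = cs$pre_masks$brain)
    }
    feat <- purrr::map_dfc(chans, function(v) v$values[keep])
    tibble::tibble(
      case_id = cs$case_id, cohort = cs$cohort, voxel = keep,
      !!!feat,
      mrsi_covered = as.numeric(cs$mrsi_coverage$values[keep] > 0.5),
      class = cls[keep],
      y = as.integer(cls[keep] %in% pos_classes)
    )
  })
  attr(rows, "provenance") <- list(task = task, band_mm = band_mm,
                                   downsample_stable = downsample_stable,
                                   seed = seed)
  rows
}

#' Patient-wise stratified k folds
#'
#' Each case lands in exactly one test fold; treatment-cohort proportions
#' are approximately preserved per fold by assigning shuffled cases
#' round-robin within each cohort label. Deterministic under `seed`.
#'
#' @param case_ids character case identifiers.
#' @param cohorts treatment labels, same length.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Tibble `case_id`, `cohort`, `fold`.
#' @export
stratified_group_folds <- function(case_ids, cohorts, k = 5, seed = 1) {
  n <- length(case_ids)
  stopifnot(length(cohorts) == n)
  if (k > n) stop("k = ", k, " folds but only ", n, " cases")
  set.seed(as.integer(seed))
  out <- tibble::tibble(case_id = case_ids, cohort = as.character(cohorts),
                        fold = NA_integer_)
  offset <- 0L
  for (g in unique(out$cohort)) {
    idx <- which(out$cohort == g)
    idx <- idx[sample.int(length(idx))]
    out$fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  out
}

#' Rank-based ROC AUC (ties counted half)
#'
#' Equivalent to the fraction of positive/negative score pairs ordered
#' correctly, with ties worth 1/2.
#' @param scores numeric predicted scores.
#' @param labels binary outcomes (0/1).
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

roc_points <- function(scores, labels, max_points = 256) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[ord]
  tpr <- cumsum(labels) / sum(labels)
  fpr <- cumsum(1 - labels) / sum(1 - labels)
  keep <- unique(round(seq(1, length(tpr), length.out = min(max_points, length(tpr)))))
  tibble::tibble(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Cross-validated random-forest progression classifier
#'
#' Fits a probability random forest per fold on the training cases only,
#' scores the held-out cases, and aggregates ROC/AUC and impurity-based
#' feature importances across folds. A fold whose test rows contain a
#' single class yields no AUC and is excluded from the mean with a
#' warning. Deterministic under `seed` (single-threaded forests).
#'
#' @param table a [build_feature_table()] tibble.
#' @param folds a [stratified_group_folds()] assignment.
#' @param num_trees trees per forest.
#' @param mtry variables per split; `NULL` for the ranger default.
#' @param seed integer seed.
#' @return An `rf_cv_result`: `fold_metrics`, `mean_auc`, `importance`,
#'   `roc`, `task`.
#' @export
run_rf_cv <- function(table, folds, num_trees = 200, mtry = NULL, seed = 1) {
  stopifnot(nrow(table) > 0)
  if (length(unique(table$y)) < 2) stop("both classes must be present overall")
  feat_cols <- setdiff(names(table), c("case_id", "cohort", "voxel", "class", "y"))
  tab <- dplyr::left_join(table, folds[, c("case_id", "fold")], by = "case_id")
  if (anyNA(tab$fold)) stop("fold assignment missing for some cases")
  ks <- sort(unique(folds$fold))
  fold_metrics <- list()
  rocs <- list()
  imps <- list()
  for (k in ks) {
    train <- tab[tab$fold != k, , drop = FALSE]
    test <- tab[tab$fold == k, , drop = FALSE]
    stopifnot(length(intersect(unique(train$case_id), unique(test$case_id))) == 0)
    n1 <- sum(train$y == 1)
    n0 <- sum(train$y == 0)
    fit <- ranger::ranger(
      x = as.data.frame(train[, feat_cols]),
      y = factor(train$y, levels = c(0, 1)),
      num.trees = num_trees, mtry = mtry, probability = TRUE,
      importance = "impurity",
      class.weights = c(`0` = (n0 + n1) / (2 * max(n0, 1)),
                        `1` = (n0 + n1) / (2 * max(n1, 1))),
      seed = as.integer(seed + k), num.threads = 1, verbose = FALSE
    )
    score <- stats::predict(fit, data = as.data.frame(test[, feat_cols]),
                            num.threads = 1)$predictions[, "1"]
    auc <- auc_rank(score, test$y)
    if (is.na(auc)) {
      warning("fold ", k, " has a single class in its test cases; AUC undefined")
    } else {
      rocs[[length(rocs) + 1L]] <- dplyr::mutate(roc_points(score, test$y),
                                                 fold = k, .before = 1)
    }
    imps[[length(imps) + 1L]] <- tibble::tibble(
      fold = k, feature = names(fit$variable.importance),
      importance = unname(fit$variable.importance)
    )
    fold_metrics[[length(fold_metrics) + 1L]] <- tibble::tibble(
      fold = k, n_test_cases = length(unique(test$case_id)),
      n_pos = sum(test$y == 1), n_neg = sum(test$y == 0), auc = auc
    )
  }
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  importance <- dplyr::bind_rows(imps) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(
      fold_metrics = fold_metrics,
      mean_auc = mean(fold_metrics$auc, na.rm = TRUE),
      importance = importance,
      roc = dplyr::bind_rows(rocs),
      task = attr(table, "provenance")$task %||% NA_character_
    ),
    class = "rf_cv_result"
  )
}

#' @export
print.rf_cv_result <- function(x, ...) {
  cat(sprintf("<rf_cv_result> %d folds, mean AUC %.3f (task: %s)\n",
              nrow(x$fold_metrics), x$mean_auc, x$task))
  cat("top features:", paste(utils::head(x$importance$feature, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Split cases at the median-style progression-time threshold
#'
#' Early progressors lie strictly below `threshold_months`; late
#' progressors at or above it (the boundary case is late).
#'
#' @param cases list of `case_record`s.
#' @param threshold_months boundary in months, default 7.
#' @return List with elements `early` and `late` (lists of cases).
#' @export
split_by_progression_time <- function(cases, threshold_months = 7) {
  ttp <- vapply(cases, function(cs) cs$time_to_progression, numeric(1))
  list(early = cases[ttp < threshold_months],
       late = cases[ttp >= threshold_months])
}
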