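#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for cross-validated random-forest results
#'
#' `tidy()` returns per-fold AUCs; `glance()` a one-row summary with the
#' mean AUC and the top-ranked features.
#' @param x an `rf_cv_result`.
#' @param ... unused.
#' @export
tidy.rf_cv_result <- function(x, ...) x$fold_metrics

#' @rdname tidy.rf_cv_result
#' @export
glance.rf_cv_result <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$fold_metrics),
    mean_auc = x$mean_auc,
    sd_auc = stats::sd(x$fold_metrics$auc, na.rm = TRUE),
    top_features = paste(utils::head(x$importance$feature, 3), collapse = ", "),
    task = x$task
  )
}

#' Tidiers for training runs
#'
#' `tidy()` returns the per-epoch history; `glance()` the best epoch and
#' its selection metric.
#' @param x a `training_run`.
#' @param ... unused.
#' @export
tidy.training_run <- function(x, ...) x$history

#' @rdname tidy.training_run
#' @export
glance.training_run <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_metric = x$best_metric, selection = x$cfg$selection,
    loss = x$cfg$loss, base_features = x$cfg$base_features,
    stages = x$cfg$stages, learning_rate = x$cfg$learning_rate,
    n_train = length(x$splits$train), n_val = length(x$splits$val),
    n_test = length(x$splits$test)
  )
}

#' Tidiers for cohort CTV evaluations
#'
#' `tidy()` returns the per-case metric table; `glance()` the per-
#' definition mean of each headline metric.
#' @param x a `cohort_eval`.
#' @param ... unused.
#' @export
tidy.cohort_eval <- function(x, ...) x$per_case

#' @rdname tidy.cohort_eval
#' @export
glance.cohort_eval <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary[x$summary$metric %in%
                c("sensitivity", "specificity", "dice", "pcc"), ],
    id_cols = "definition", names_from = "metric", values_from = "mean"
  )
}

#' Plot cross-validated ROC curves
#' @param object an `rf_cv_result`.
#' @param ... unused.
#' @export
autoplot.rf_cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = .data$fold, colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate", colour = "Fold",
      title = sprintf("Voxel-wise %s progression (mean AUC %.2f)",
                      toupper(object$task %||% ""), object$mean_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot training curves
#' @param object a `training_run`.
#' @param ... unused.
#' @export
autoplot.training_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-case metric distributions across CTV definitions
#' @param object a `cohort_eval`.
#' @param metrics metrics to facet over.
#' @param ... unused.
#' @export
autoplot.cohort_eval <- function(object,
                                 metrics = c("sensitivity", "specificity",
                                             "dice", "pcc"), ...) {
  dat <- object$per_case[object$per_case$metric %in% metrics, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$definition, .data$value,
                                    fill = .data$definition)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
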