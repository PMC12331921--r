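new_ctv <- function(mask, definition, provenance) {
  structure(list(mask = mask, definition = definition, provenance = provenance),
            class = "ctv_result")
}

#' @export
print.ctv_result <- function(x, ...) {
  cat(sprintf("<ctv_result> %s: %d voxels (%.1f cm^3)\n", x$definition,
              n_voxels(x$mask), mask_volume_mm3(x$mask) / 1000))
  invisible(x)
}

#' Deep-learning CTV from a probability field
#'
#' Binarizes the probability field, keeps the 26-connected components
#' anchored to the pre-RT disease (pre-RT T2L or resection cavity) —
#' or only the largest component when anchoring is off — fills internal
#' holes, and clips to the brain. Anchoring removes spurious distant
#' islands so the CTV is a clinically usable contiguous region.
#'
#' @param prob probability `vol_grid` in `[0, 1]`.
#' @param case the `case_record` providing anchor and brain masks.
#' @param threshold binarization threshold, default 0.5.
#' @param anchor keep all components touching the anchor region
#'   (`TRUE`), or just the largest component (`FALSE`)?
#' @param include_pre_lesion union the pre-RT lesion (CEL and T2L) into
#'   the CTV. A target volume must always cover visible disease; the
#'   prediction adds the anticipated growth around it.
#' @return A `ctv_result`.
#' @export
dl_ctv <- function(prob, case, threshold = 0.5, anchor = TRUE,
                   include_pre_lesion = TRUE) {
  if (any(prob$values < 0 | prob$values > 1)) {
    stop("probability field must lie in [0, 1]")
  }
  hard <- mask_intersect(as_mask(new_like(prob, as.numeric(prob$values >= threshold))),
                         case$pre_masks$brain)
  if (n_voxels(hard) == 0) {
    stop("thresholding left an empty prediction; review the threshold")
  }
  lab <- label_mask_components(hard, 26)
  anchor_mask <- mask_union(case$pre_masks$t2l, case$pre_masks$cavity)
  if (anchor) {
    keep <- setdiff(unique(lab$values[anchor_mask$values > 0.5]), 0)
    if (length(keep) == 0) {
      # nothing touches the anchor: degrade gracefully to the largest blob
      keep <- which.max(tabulate(lab$values[lab$values > 0]))
    }
  } else {
    keep <- which.max(tabulate(lab$values[lab$values > 0]))
  }
  out <- new_like(hard, as.numeric(lab$values %in% keep))
  if (include_pre_lesion) {
    out <- mask_union(out, mask_union(case$pre_masks$t2l, case$pre_masks$cel))
  }
  out <- mask_intersect(fill_holes(out), case$pre_masks$brain)
  new_ctv(out, "DL",
          list(threshold = threshold, anchor = anchor,
               include_pre_lesion = include_pre_lesion,
               n_components_kept = length(keep)))
}

#' RTOG-style clinical target volume
#'
#' Combined contrast-enhancing and T2 lesion plus a uniform 2 cm
#' expansion, clipped to the brain.
#'
#' @param case a `case_record`.
#' @param margin_mm expansion margin, default 20 mm.
#' @export
rtog_ctv <- function(case, margin_mm = 20) {
  lesion <- mask_union(case$pre_masks$cel, case$pre_masks$t2l)
  if (n_voxels(lesion) == 0) stop("empty pre-RT lesion; RTOG CTV undefined")
  new_ctv(isotropic_expand(lesion, margin_mm, clip = case$pre_masks$brain),
          "RTOG", list(margin_mm = margin_mm))
}

#' EORTC-style clinical target volume
#'
#' Residual contrast-enhancing tumor and resection cavity plus a 1.5 cm
#' isotropic margin, excluding vasogenic edema (operationalized as the
#' pre-RT non-enhancing T2 lesion). The exclusion is applied after the
#' expansion; `exclude_edema = FALSE` retains the edema.
#'
#' @param case a `case_record`.
#' @param margin_mm expansion margin, default 15 mm.
#' @param exclude_edema subtract the pre-RT NEL from the expanded CTV?
#' @export
eortc_ctv <- function(case, margin_mm = 15, exclude_edema = TRUE) {
  seed <- mask_union(case$pre_masks$cel, case$pre_masks$cavity)
  if (n_voxels(seed) == 0) {
    stop("CEL and cavity are both empty; EORTC CTV undefined")
  }
  ctv <- isotropic_expand(seed, margin_mm, clip = case$pre_masks$brain)
  if (exclude_edema) ctv <- mask_subtract(ctv, case$pre_masks$nel)
  new_ctv(ctv, "EORTC",
          list(margin_mm = margin_mm, exclude_edema = exclude_edema))
}

#' Remove critical structures from a CTV
#'
#' Set subtraction of organ-at-risk masks (e.g. brain stem, thalamus)
#' supplied by the user; erroring when nothing of the CTV survives.
#'
#' @param ctv a `ctv_result`.
#' @param structures binary `vol_grid` of voxels to spare.
#' @export
remove_critical_structures <- function(ctv, structures) {
  stopifnot(inherits(ctv, "ctv_result"))
  out <- mask_subtract(ctv$mask, structures)
  if (n_voxels(out) == 0) stop("removing critical structures emptied the CTV")
  new_ctv(out, ctv$definition,
          c(ctv$provenance, list(critical_structures_removed = n_voxels(
            mask_intersect(ctv$mask, structures)))))
}

#' Tune the DL binarization threshold on validation cases
#'
#' Off by default (the fixed 0.5 threshold is the reference behaviour).
#' When used, the threshold maximizing the mean per-case PCC of the
#' thresholded prediction is chosen on the *validation* cases of the
#' training run only, keeping test cases untouched.
#'
#' @param run a `training_run`.
#' @param cases the full case list the run was trained from.
#' @param grid candidate thresholds.
#' @return The selected threshold (numeric scalar).
#' @export
tune_dl_threshold <- function(run, cases,
                              grid = seq(0.2, 0.9, by = 0.05)) {
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  val_cases <- cases[match(run$splits$val, ids)]
  if (length(val_cases) == 0) return(0.5)
  probs <- lapply(val_cases, function(cs) predict_case(run, cs))
  score <- vapply(grid, function(th) {
    mean(vapply(seq_along(val_cases), function(i) {
      cs <- val_cases[[i]]
      hard <- as_mask(new_like(probs[[i]], as.numeric(probs[[i]]$values >= th)))
      tg <- make_target(cs)
      if (n_voxels(hard) == 0) return(0)
      pcc_score(hard, tg, cs$pre_masks$brain)
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(score)]
}

ctv_for_definition <- function(definition, case, run = NULL, threshold = 0.5) {
  switch(definition,
    RTOG = rtog_ctv(case),
    EORTC = eortc_ctv(case),
    PRERT_ONLY = {
      lesion <- mask_union(case$pre_masks$cel, case$pre_masks$t2l)
      if (n_voxels(lesion) == 0) stop("empty pre-RT lesion")
      new_ctv(lesion, "PRERT_ONLY", list())
    },
    DL = {
      if (is.null(run)) stop("DL CTV requires a trained model run")
      dl_ctv(predict_case(run, case), case, threshold = threshold)
    },
    stop("unknown CTV definition: ", definition)
  )
}

#' Evaluate CTV definitions over a cohort
#'
#' For each case and definition, computes the six evaluation metrics
#' against the composite progression target ([make_target()]), plus the
#' sensitivity restricted to new-growth voxels (target minus pre-RT
#' lesion) — the quantity on which a pre-RT-only pseudo-CTV collapses
#' despite its high Dice. Failed cases are recorded and excluded with a
#' warning, never dropped silently.
#'
#' @param cases list of `case_record`s (typically the test split).
#' @param definitions subset of `"DL"`, `"RTOG"`, `"EORTC"`,
#'   `"PRERT_ONLY"`.
#' @param run a `training_run` (required when `"DL"` is requested).
#' @param threshold DL binarization threshold.
#' @return A `cohort_eval` list: `per_case` (tidy tibble: one row per
#'   case, definition and metric) and `summary` (mean and sd per metric
#'   and definition).
#' @export
evaluate_cohort <- function(cases,
                            definitions = c("RTOG", "EORTC", "PRERT_ONLY"),
                            run = NULL, threshold = 0.5) {
  rows <- list()
  failed <- character()
  for (cs in cases) {
    target <- make_target(cs)
    pre_lesion <- mask_union(cs$pre_masks$cel, cs$pre_masks$t2l)
    new_growth <- mask_subtract(target, pre_lesion)
    for (def in definitions) {
      res <- tryCatch({
        ctv <- ctv_for_definition(def, cs, run, threshold)
        met <- evaluate_pair(ctv$mask, target, cs$pre_masks$brain)
        met$sens_new_growth <- if (n_voxels(new_growth) > 0) {
          ccng <- confusion_counts(ctv$mask, new_growth, cs$pre_masks$brain)
          ccng$tp / (ccng$tp + ccng$fn)
        } else {
          NA_real_
        }
        met$ctv_cm3 <- mask_volume_mm3(ctv$mask) / 1000
        met
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("case ", cs$case_id, ", ", def, ": ", conditionMessage(res),
                " (excluded)")
        failed <- c(failed, paste(cs$case_id, def))
        next
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(case_id = cs$case_id, definition = def), res
      )
    }
  }
  per_case <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(-c("case_id", "definition"),
                        names_to = "metric", values_to = "value")
  summary <- per_case |>
    dplyr::group_by(.data$definition, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(per_case = per_case, summary = summary, failed = failed),
            class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  cat("<cohort_eval>\n")
  wide <- tidyr::pivot_wider(
    x$summary[x$summary$metric %in%
                c("sensitivity", "specificity", "dice", "pcc"), ],
    id_cols = "definition", names_from = "metric", values_from = "mean"
  )
  print(wide)
  invisible(x)
}

#' Paired comparison of two CTV definitions
#'
#' Paired Wilcoxon signed-rank test on per-case values of one metric for
#' two definitions, with banded p-value reporting. All-zero differences
#' are reported as degenerate rather than tested.
#'
#' @param per_case the `per_case` tibble of [evaluate_cohort()].
#' @param def_a,def_b definition names.
#' @param metric metric name.
#' @param min_cases minimum paired cases, default 6.
#' @return One-row tibble: `metric`, `def_a`, `def_b`, `n`,
#'   `mean_diff`, `statistic`, `p_value`, `band`, `status`.
#' @export
compare_definitions <- function(per_case, def_a, def_b, metric,
                                min_cases = 6) {
  tab <- per_case[per_case$metric == metric &
                    per_case$definition %in% c(def_a, def_b), ]
  wide <- tidyr::pivot_wider(tab, id_cols = "case_id",
                             names_from = "definition", values_from = "value")
  res <- tibble::tibble(metric = metric, def_a = def_a, def_b = def_b,
                        n = NA_integer_, mean_diff = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        band = NA_character_, status = "ok")
  if (!all(c(def_a, def_b) %in% names(wide))) {
    res$n <- 0L; res$status <- "insufficient_cases"; return(res)
  }
  ok <- stats::complete.cases(wide[, c(def_a, def_b)])
  a <- wide[[def_a]][ok]
  b <- wide[[def_b]][ok]
  res$n <- length(a)
  if (length(a) < min_cases) {
    res$status <- "insufficient_cases"; return(res)
  }
  d <- a - b
  res$mean_diff <- mean(d)
  if (all(d == 0)) {
    res$status <- "degenerate_all_ties"; res$p_value <- 1; res$band <- "ns"
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  res$statistic <- unname(wt$statistic)
  res$p_value <- wt$p.value
  res$band <- p_band(wt$p.value)
  res
}
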