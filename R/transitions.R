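#' Transition class labels
#'
#' Voxel categories between the pre-RT and progression timepoints, inside
#' the analysis band around the pre-RT lesion.
#' @export
transition_levels <- function() {
  c("STABLE_NAV", "NAV_to_NEL", "NAV_to_CEL", "NEL_to_CEL",
    "OTHER", "OUTSIDE_BAND")
}

#' Channels whose values only exist inside the MRSI coverage box
#' @export
metabolic_channels <- function() {
  c("cni", "ccri", "crni", "ncho", "ncre", "nnaa", "nlac", "nlip")
}

#' Derive the composite region-of-interest set for one timepoint
#'
#' Computes the non-enhancing lesion `NEL = T2L \ CEL` and the
#' normal-appearing voxels `NAV = brain \ (cavity | ventricles | T2L)`
#' from the primary masks. A CEL voxel outside the T2L violates the
#' nesting assumption; it is reported and corrected by intersecting CEL
#' with T2L. All outputs are clipped to the brain.
#'
#' @param cel,t2l,cavity,ventricles,brain binary `vol_grid`s on one grid.
#' @return A `mask_set` list: `cel`, `t2l`, `nel`, `cavity`, `ventricles`,
#'   `brain`, `nav`.
#' @export
derive_masks <- function(cel, t2l, cavity, ventricles, brain) {
  nm <- c("cel", "t2l", "cavity", "ventricles", "brain")
  vols <- list(cel, t2l, cavity, ventricles, brain)
  for (i in seq_along(vols)) {
    if (!inherits(vols[[i]], "vol_grid")) stop("'", nm[i], "' is not a vol_grid")
    if (!same_geometry(vols[[1]], vols[[i]])) {
      stop("geometry mismatch: mask '", nm[i], "' does not share the case grid")
    }
  }
  if (n_voxels(brain) == 0) stop("brain mask is empty")
  cel <- mask_intersect(as_mask(cel), brain)
  t2l <- mask_intersect(as_mask(t2l), brain)
  cavity <- mask_intersect(as_mask(cavity), brain)
  ventricles <- mask_intersect(as_mask(ventricles), brain)
  stray <- sum(cel$values > 0.5 & t2l$values <= 0.5)
  if (stray > 0) {
    warning(stray, " CEL voxel(s) outside the T2L; intersecting CEL with T2L")
    cel <- mask_intersect(cel, t2l)
  }
  nel <- mask_subtract(t2l, cel)
  nav <- mask_subtract(brain, mask_union(mask_union(cavity, ventricles), t2l))
  structure(
    list(cel = cel, t2l = t2l, nel = nel, cavity = cavity,
         ventricles = ventricles, brain = brain, nav = nav),
    class = "mask_set"
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat("<mask_set>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %d voxels\n", nm, n_voxels(x[[nm]])))
  invisible(x)
}

#' Analysis band around the pre-RT lesion
#'
#' Uniform expansion of the pre-RT lesion (T2L plus CEL) clipped to the
#' brain. The default 40 mm reflects the furthest distance at which
#' progression is observed (and that clinicians would treat), and keeps
#' the stable-voxel class from dwarfing the progressed classes.
#'
#' @param pre a pre-RT `mask_set`.
#' @param margin_mm band width in mm, default 40.
#' @export
band_mask <- function(pre, margin_mm = 40) {
  stopifnot(inherits(pre, "mask_set"))
  lesion <- mask_union(pre$t2l, pre$cel)
  if (n_voxels(lesion) == 0) stop("pre-RT lesion is empty; band undefined")
  isotropic_expand(lesion, margin_mm, clip = pre$brain)
}

#' Label voxel transitions between the two timepoints
#'
#' Every brain voxel receives exactly one label: inside the band,
#' pre-NAV voxels becoming CEL/NEL at progression are `NAV_to_CEL` /
#' `NAV_to_NEL`, pre-NEL voxels becoming CEL are `NEL_to_CEL`, pre-NAV
#' voxels staying NAV are `STABLE_NAV`, and anything else in-band is
#' `OTHER`; brain voxels outside the band are `OUTSIDE_BAND`.
#'
#' @param pre,prog `mask_set`s for the two timepoints.
#' @param band binary `vol_grid`, usually [band_mask()] of `pre`.
#' @return A `transition_field`: a `vol_grid` of integer codes with a
#'   `levels` attribute mapping codes to [transition_levels()].
#' @export
label_transitions <- function(pre, prog, band) {
  stopifnot(inherits(pre, "mask_set"), inherits(prog, "mask_set"))
  check_geometry(pre$brain, prog$brain, band,
                 .names = c("pre$brain", "prog$brain", "band"))
  brain <- pre$brain$values > 0.5
  inb <- brain & band$values > 0.5
  pre_nav <- pre$nav$values > 0.5
  pre_nel <- pre$nel$values > 0.5
  prog_cel <- prog$cel$values > 0.5
  prog_nel <- prog$nel$values > 0.5
  prog_nav <- prog$nav$values > 0.5
  lv <- transition_levels()
  code <- array(0L, dim(pre$brain$values))
  code[brain & !inb] <- match("OUTSIDE_BAND", lv)
  code[inb] <- match("OTHER", lv)
  code[inb & pre_nav & prog_nav] <- match("STABLE_NAV", lv)
  code[inb & pre_nav & prog_nel] <- match("NAV_to_NEL", lv)
  code[inb & pre_nav & prog_cel] <- match("NAV_to_CEL", lv)
  code[inb & pre_nel & prog_cel] <- match("NEL_to_CEL", lv)
  out <- new_like(pre$brain, code)
  attr(out, "levels") <- lv
  class(out) <- c("transition_field", class(out))
  out
}

#' Tally a transition field
#' @param field a `transition_field`.
#' @return A tibble with one row per transition class and its voxel count.
#' @export
transition_counts <- function(field) {
  lv <- attr(field, "levels")
  tibble::tibble(
    class = lv,
    n_voxels = vapply(seq_along(lv), function(i) sum(field$values == i), integer(1))
  )
}

#' Per-patient per-class channel medians
#'
#' For every transition class carrying at least `min_voxels` voxels, the
#' median of each (normalized) channel over that class. Metabolic
#' channels are evaluated only inside the MRSI coverage box, and the
#' covered voxel count must itself reach `min_voxels`; classes below the
#' threshold are absent from the table, not zero.
#'
#' @param case a `case_record`.
#' @param field a `transition_field` for the case.
#' @param min_voxels smallest class size that still yields a median.
#' @param normalize min-max normalize channels within the brain first?
#' @return Tibble with columns `case_id`, `class`, `channel`, `n_voxels`,
#'   `median`.
#' @export
per_patient_medians <- function(case, field, min_voxels = 5, normalize = TRUE) {
  stopifnot(inherits(case, "case_record"))
  lv <- attr(field, "levels")
  brain <- case$pre_masks$brain
  covered <- case$mrsi_coverage$values > 0.5
  chans <- case$channels
  if (normalize) chans <- lapply(chans, minmax_normalize, within = brain)
  rows <- list()
  for (cls_i in seq_along(lv)) {
    if (lv[cls_i] == "OUTSIDE_BAND") next
    in_cls <- field$values == cls_i
    for (ch in names(chans)) {
      sel <- if (ch %in% metabolic_channels()) in_cls & covered else in_cls
      n <- sum(sel)
      if (n < min_voxels) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        case_id = case$case_id, class = lv[cls_i], channel = ch,
        n_voxels = n, median = stats::median(chans[[ch]]$values[sel])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(case_id = character(), class = character(),
                          channel = character(), n_voxels = integer(),
                          median = double()))
  }
  dplyr::bind_rows(rows)
}

#' Cohort-wide per-patient median table
#'
#' Runs [derive_masks()] (already done by the generator), [band_mask()],
#' [label_transitions()] and [per_patient_medians()] over a list of
#' cases and binds the results.
#'
#' @param cases list of `case_record`s.
#' @param band_mm analysis band width in mm.
#' @inheritParams per_patient_medians
#' @export
cohort_median_table <- function(cases, band_mm = 40, min_voxels = 5,
                                normalize = TRUE) {
  purrr::map_dfr(cases, function(cs) {
    band <- band_mask(cs$pre_masks, band_mm)
    field <- label_transitions(cs$pre_masks, cs$prog_masks, band)
    per_patient_medians(cs, field, min_voxels, normalize)
  })
}

#' Compare two transition classes across patients
#'
#' Paired Wilcoxon signed-rank test (default) on per-patient medians of
#' one channel for two transition classes; only patients contributing
#' both classes enter. The unpaired rank-sum variant is available via
#' `paired = FALSE`. The signed effect is reported as the median of the
#' per-patient differences `class_a - class_b`.
#'
#' @param median_table output of [cohort_median_table()].
#' @param class_a,class_b transition class names.
#' @param channel channel name.
#' @param paired use the paired signed-rank test?
#' @param min_patients minimum number of (paired) patients required.
#' @return One-row tibble: `channel`, `class_a`, `class_b`, `n`,
#'   `statistic`, `median_diff`, `p_value`, `band`, `status`.
#' @export
compare_groups <- function(median_table, class_a, class_b, channel,
                           paired = TRUE, min_patients = 5) {
  stopifnot(all(c(class_a, class_b) %in% transition_levels()))
  tab <- dplyr::filter(median_table, .data$channel == .env$channel,
                       .data$class %in% c(class_a, class_b))
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, "case_id", "class", "median"),
    names_from = "class", values_from = "median"
  )
  res <- tibble::tibble(
    channel = channel, class_a = class_a, class_b = class_b,
    n = NA_integer_, statistic = NA_real_, median_diff = NA_real_,
    p_value = NA_real_, band = NA_character_, status = "ok"
  )
  if (paired) {
    if (!all(c(class_a, class_b) %in% names(wide))) {
      res$n <- 0L; res$status <- "insufficient_patients"; return(res)
    }
    ok <- stats::complete.cases(wide[, c(class_a, class_b)])
    a <- wide[[class_a]][ok]
    b <- wide[[class_b]][ok]
    res$n <- length(a)
    if (length(a) < min_patients) {
      res$status <- "insufficient_patients"; return(res)
    }
    d <- a - b
    res$median_diff <- stats::median(d)
    if (all(d == 0)) {
      res$status <- "degenerate_all_ties"; res$p_value <- 1
      res$band <- "ns"; return(res)
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  } else {
    a <- tab$median[tab$class == class_a]
    b <- tab$median[tab$class == class_b]
    res$n <- min(length(a), length(b))
    if (length(a) < min_patients || length(b) < min_patients) {
      res$status <- "insufficient_patients"; return(res)
    }
    res$median_diff <- stats::median(a) - stats::median(b)
    if (length(unique(c(a, b))) == 1L) {
      res$status <- "degenerate_all_ties"; res$p_value <- 1
      res$band <- "ns"; return(res)
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = FALSE, exact = FALSE))
  }
  res$statistic <- unname(wt$statistic)
  res$p_value <- wt$p.value
  res$band <- p_band(wt$p.value)
  res
}
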