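test_that("geometric CTVs: supersets, margins, and the distance oracle", {
  tc <- toy_case()
  r <- rtog_ctv(tc)
  expect_s3_class(r, "ctv_result")
  lesion <- mask_union(tc$pre_masks$cel, tc$pre_masks$t2l)
  expect_true(all(lesion$values <= r$mask$values))
  expect_true(all(r$mask$values <= tc$pre_masks$brain$values))
  # margin 0: the lesion itself
  r0 <- rtog_ctv(tc, margin_mm = 0)
  expect_identical(r0$mask$values,
                   mask_intersect(lesion, tc$pre_masks$brain)$values)

  # single-voxel lesion: voxel count equals the brute-force ball count
  shape <- c(12, 12, 12); sp <- c(3, 3, 3)
  sv <- vol_grid(array(0, shape), sp); sv$values[6, 6, 6] <- 1
  brain <- all_mask(shape, sp)
  zero <- vol_grid(array(0, shape), sp)
  ms <- derive_masks(sv, sv, zero, zero, brain)
  tiny <- structure(list(case_id = "sv", cohort = "SOC",
                         time_to_progression = 5, channels = list(),
                         pre_masks = ms, prog_masks = ms,
                         mrsi_coverage = brain),
                    class = "case_record")
  rt <- rtog_ctv(tiny, margin_mm = 20)
  expect_identical(rt$mask$values, bf_expand(sv, 20, brain)$values)

  empty_case <- tiny
  empty_case$pre_masks$cel$values[] <- 0
  empty_case$pre_masks$t2l$values[] <- 0
  expect_error(rtog_ctv(empty_case), "empty")
})

test_that("EORTC CTV excludes edema behind the toggle", {
  tc <- toy_case()
  on <- eortc_ctv(tc, exclude_edema = TRUE)
  off <- eortc_ctv(tc, exclude_edema = FALSE)
  nel <- tc$pre_masks$nel
  expect_equal(sum(on$mask$values > 0.5 & nel$values > 0.5), 0)
  expect_gt(sum(off$mask$values > 0.5 & nel$values > 0.5), 0)
  expect_identical(mask_union(on$mask, mask_intersect(off$mask, nel))$values,
                   off$mask$values)
  # CEL always covered once the NEL is disjoint from it
  expect_true(all(tc$pre_masks$cel$values <= off$mask$values))
  # empty NEL: the exclusion is a no-op
  tc2 <- tc
  tc2$pre_masks$nel$values[] <- 0
  expect_identical(eortc_ctv(tc2, exclude_edema = TRUE)$mask$values,
                   eortc_ctv(tc2, exclude_edema = FALSE)$mask$values)
  # both seeds empty -> error
  tc3 <- tc
  tc3$pre_masks$cel$values[] <- 0
  tc3$pre_masks$cavity$values[] <- 0
  expect_error(eortc_ctv(tc3), "both empty")
})

test_that("margin nesting: the 15 mm CTV is inside the 20 mm CTV", {
  tc <- toy_case()
  seedm <- mask_union(tc$pre_masks$cel, tc$pre_masks$cavity)
  inner <- isotropic_expand(seedm, 15, clip = tc$pre_masks$brain)
  outer <- isotropic_expand(seedm, 20, clip = tc$pre_masks$brain)
  expect_true(all(inner$values <= outer$values))
})

test_that("DL CTV keeps anchored components and fills holes", {
  tc <- toy_case()
  shape <- dim(tc$pre_masks$brain$values)
  sp <- tc$pre_masks$brain$spacing
  # blob over the lesion + a distant island
  prob <- vol_grid(array(0, shape), sp)
  prob$values[7:12, 7:11, 7:10] <- 0.9
  prob$values[14:15, 3:4, 12:13] <- 0.9
  res <- dl_ctv(prob, tc, threshold = 0.5, anchor = TRUE)
  lab <- label_mask_components(res$mask, 26)
  expect_equal(max(lab$values), 1) # distant island removed
  expect_equal(sum(res$mask$values > 0.5 & prob$values < 0.5), 0)
  res_off <- dl_ctv(prob, tc, threshold = 0.5, anchor = FALSE)
  expect_equal(max(label_mask_components(res_off$mask, 26)$values), 1)

  # single blob over the lesion is returned as-is
  prob1 <- vol_grid(array(0, shape), sp)
  prob1$values[7:12, 7:11, 7:10] <- 0.9
  res1 <- dl_ctv(prob1, tc)
  want <- mask_intersect(as_mask(vol_grid(prob1$values >= 0.5, sp)),
                         tc$pre_masks$brain)
  expect_identical(res1$mask$values, want$values)

  # threshold 0 keeps the whole brain
  resb <- dl_ctv(vol_grid(array(0.4, shape), sp), tc, threshold = 0)
  expect_identical(resb$mask$values, tc$pre_masks$brain$values)

  # visible pre-RT disease is always covered, even when the prediction
  # misses it; opting out reverts to the raw prediction
  prob_off <- vol_grid(array(0, shape), sp)
  prob_off$values[10:12, 9:11, 8:10] <- 0.9 # partial lesion coverage only
  res_inc <- dl_ctv(prob_off, tc, include_pre_lesion = TRUE)
  pre_lesion <- mask_union(tc$pre_masks$t2l, tc$pre_masks$cel)
  expect_true(all(pre_lesion$values <= res_inc$mask$values))
  res_exc <- dl_ctv(prob_off, tc, include_pre_lesion = FALSE)
  expect_gt(sum(pre_lesion$values > 0.5 & res_exc$mask$values <= 0.5), 0)

  expect_error(dl_ctv(vol_grid(array(0, shape), sp), tc), "empty")
  expect_error(dl_ctv(vol_grid(array(2, shape), sp), tc), "\\[0, 1\\]")
})

test_that("critical-structure removal subtracts exactly and errors when empty", {
  tc <- toy_case()
  ctv <- rtog_ctv(tc)
  none <- vol_grid(array(0, dim(ctv$mask$values)), ctv$mask$spacing)
  expect_identical(remove_critical_structures(ctv, none)$mask$values,
                   ctv$mask$values)
  part <- box_mask(dim(ctv$mask$values), ctv$mask$spacing,
                   c(2, 2, 2), c(5, 5, 5))
  before <- n_voxels(ctv$mask)
  overlap <- n_voxels(mask_intersect(ctv$mask, part))
  after <- remove_critical_structures(ctv, part)
  expect_equal(n_voxels(after$mask), before - overlap)
  expect_error(remove_critical_structures(ctv, all_mask(dim(ctv$mask$values),
                                                        ctv$mask$spacing)),
               "emptied")
})

test_that("cohort evaluation is lossless and ranks geometric CTVs sanely", {
  coh <- quick_cohort(n = 4, seed = 46, channels = c("nt1c", "nflair"))
  ev <- evaluate_cohort(coh$cases, c("RTOG", "EORTC", "PRERT_ONLY"))
  expect_s3_class(ev, "cohort_eval")
  # lossless: per-case rows regenerate the summary exactly
  re <- ev$per_case |>
    dplyr::group_by(definition, metric) |>
    dplyr::summarise(mean = mean(value, na.rm = TRUE), .groups = "drop")
  expect_equal(
    dplyr::arrange(re, definition, metric)$mean,
    dplyr::arrange(ev$summary, definition, metric)$mean,
    tolerance = 1e-12
  )
  # superset CTV never has lower sensitivity, per case
  wide <- tidyr::pivot_wider(
    dplyr::filter(ev$per_case, metric == "sensitivity"),
    id_cols = "case_id", names_from = "definition", values_from = "value"
  )
  expect_true(all(wide$RTOG >= wide$PRERT_ONLY))
  # sensitivity is monotone under dilation of any CTV
  cs <- coh$cases[[1]]
  tg <- make_target(cs)
  small <- eortc_ctv(cs)$mask
  big <- isotropic_expand(small, 6, clip = cs$pre_masks$brain)
  s_small <- evaluate_pair(small, tg, cs$pre_masks$brain)$sensitivity
  s_big <- evaluate_pair(big, tg, cs$pre_masks$brain)$sensitivity
  expect_gte(s_big, s_small)
  # tidiers
  expect_identical(tidy(ev), ev$per_case)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("definition comparison: degeneracy, symmetry, planted dominance", {
  per_case <- tidyr::expand_grid(case_id = sprintf("c%02d", 1:10),
                                 definition = c("A", "B"),
                                 metric = "specificity")
  set.seed(47)
  base <- runif(10, 0.7, 0.9)
  per_case$value <- ifelse(per_case$definition == "A",
                           rep(base, each = 2), rep(base, each = 2))
  r0 <- compare_definitions(per_case, "A", "B", "specificity")
  expect_equal(r0$status, "degenerate_all_ties")

  per_case$value[per_case$definition == "A"] <-
    per_case$value[per_case$definition == "A"] + runif(10, 0.02, 0.08)
  r1 <- compare_definitions(per_case, "A", "B", "specificity")
  r2 <- compare_definitions(per_case, "B", "A", "specificity")
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$mean_diff, -r2$mean_diff, tolerance = 1e-12)

  r3 <- compare_definitions(per_case[per_case$case_id %in%
                                       sprintf("c%02d", 1:3), ],
                            "A", "B", "specificity")
  expect_equal(r3$status, "insufficient_cases")
})
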