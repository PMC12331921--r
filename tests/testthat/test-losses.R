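test_that("confusion counts match a hand-placed fixture and the soft limit", {
  shape <- c(4, 4, 4)
  sp <- c(3, 3, 3)
  truth <- vol_grid(array(0, shape), sp)
  truth$values[1:4] <- 1                       # 4 truth voxels
  pred <- vol_grid(array(0, shape), sp)
  pred$values[c(1, 2, 3, 5, 6)] <- 1           # 3 TP, 2 FP, 1 FN
  ev <- all_mask(shape, sp)
  cc <- confusion_counts(pred, truth, ev)
  expect_equal(cc$tp, 3)
  expect_equal(cc$fp, 2)
  expect_equal(cc$fn, 1)
  expect_equal(cc$tn, 64 - 6)

  cc_soft <- confusion_counts(pred, truth, ev, soft = TRUE)
  expect_equal(unclass(cc_soft), unclass(cc))  # p in {0,1}: soft == hard

  expect_identical(confusion_counts(truth, truth, ev)$fp, 0)
  expect_identical(confusion_counts(truth, truth, ev)$fn, 0)

  bad <- pred; bad$values[1] <- 1.3
  expect_error(confusion_counts(bad, truth, ev, soft = TRUE), "\\[0, 1\\]")
})

test_that("Tversky at (0.5, 0.5) is exactly Dice on random mask pairs", {
  set.seed(10)
  for (i in 1:60) {
    a <- random_mask(c(6, 6, 6), p = runif(1, 0.05, 0.6))
    b <- random_mask(c(6, 6, 6), p = runif(1, 0.05, 0.6))
    cc <- confusion_counts(a, b, all_mask(c(6, 6, 6), c(3, 3, 3)))
    tv <- tversky_index(cc, 0.5, 0.5, smooth = 0)
    dc <- dice_coefficient(cc, smooth = 0)
    expect_equal(tv, dc, tolerance = 1e-12)
  }
})

test_that("Tversky fixture value and empty-overlap limit", {
  cc <- structure(list(tp = 8, fp = 4, fn = 2, tn = 0),
                  class = "confusion_counts")
  # 8 / (8 + 0.02*4 + 0.98*2) = 8 / 10.04
  expect_equal(tversky_index(cc, 0.02, 0.98, smooth = 0), 8 / 10.04,
               tolerance = 1e-12)
  cc0 <- structure(list(tp = 0, fp = 3, fn = 2, tn = 0),
                   class = "confusion_counts")
  expect_lt(tversky_index(cc0, 0.5, 0.5, smooth = 1e-9), 1e-6)
})

test_that("size-adaptive weights follow beta = 1/(f+1) exactly", {
  p <- size_adaptive_params(2, 100)
  expect_equal(round(p$beta, 2), 0.98)
  expect_equal(round(p$alpha, 2), 0.02)

  p1 <- size_adaptive_params(50, 50)   # f = 1
  expect_equal(p1$beta, 0.5)
  expect_equal(p1$alpha, 0.5)

  p2 <- size_adaptive_params(2000, 50000) # f = 0.04
  expect_equal(p2$beta, 1 / 1.04, tolerance = 1e-12)

  # the two printed forms are algebraically identical, and beta decreases in f
  fs <- c(0, 10^seq(-4, 1, length.out = 40))
  betas <- vapply(fs, function(f) {
    pp <- size_adaptive_params(f * 1e6, 1e6)
    expect_equal(pp$beta, pp$beta_ratio_form, tolerance = 1e-12)
    expect_equal(pp$alpha + pp$beta, 1, tolerance = 1e-12)
    pp$beta
  }, numeric(1))
  expect_true(all(diff(betas) < 0))
  expect_error(size_adaptive_params(5, 0), "positive")
})

test_that("PCC: perfect and disjoint limits, harsher on small-f misses", {
  shape <- c(8, 8, 8)
  sp <- c(3, 3, 3)
  brain <- all_mask(shape, sp)
  t <- vol_grid(array(0, shape), sp); t$values[1:10] <- 1
  expect_equal(pcc_score(t, t, brain), 1, tolerance = 1e-4)
  disj <- vol_grid(array(0, shape), sp); disj$values[21:30] <- 1
  expect_lt(pcc_score(disj, t, brain, smooth = 1e-9), 1e-6)
  expect_error(pcc_score(t, vol_grid(array(0, shape), sp), brain,
                         lesion_reference = vol_grid(array(0, shape), sp)),
               "empty")

  # identical confusion counts, different lesion fractions: with FN > FP the
  # smaller-f case (larger beta) scores lower
  cc <- structure(list(tp = 20, fp = 5, fn = 20, tn = 0),
                  class = "confusion_counts")
  p_small <- size_adaptive_params(100, 10000)   # f = 0.01
  p_large <- size_adaptive_params(1000, 10000)  # f = 0.10
  expect_lt(tversky_index(cc, p_small$alpha, p_small$beta),
            tversky_index(cc, p_large$alpha, p_large$beta))

  # compositional consistency: pcc == tversky o confusion_counts
  set.seed(11)
  pred <- random_mask(shape, p = 0.2)
  pars <- size_adaptive_params(n_voxels(t), n_voxels(brain))
  expect_equal(pcc_score(pred, t, brain),
               tversky_index(confusion_counts(pred, t, brain),
                             pars$alpha, pars$beta))
})

test_that("compound loss is linear in the BCE weight and matches hand BCE", {
  shape <- c(4, 4, 4)
  sp <- c(3, 3, 3)
  brain <- all_mask(shape, sp)
  set.seed(12)
  p <- vol_grid(array(runif(64, 0.05, 0.95), shape), sp)
  t <- random_mask(shape, p = 0.3)
  expect_equal(compound_loss(t, t, brain, bce_weight = 0), 0, tolerance = 1e-4)

  l0 <- compound_loss(p, t, brain, bce_weight = 0)
  l05 <- compound_loss(p, t, brain, bce_weight = 0.5)
  l1 <- compound_loss(p, t, brain, bce_weight = 1)
  bce_hand <- mean(-(t$values * log(p$values) +
                       (1 - t$values) * log(1 - p$values)))
  expect_equal(bce_mean(p, t, brain), bce_hand, tolerance = 1e-10)
  expect_equal(l1 - l05, 0.5 * bce_hand, tolerance = 1e-10)
  expect_equal(l05 - l0, 0.5 * bce_hand, tolerance = 1e-10)
})

test_that("soft-loss gradient agrees with finite differences", {
  set.seed(13)
  n <- 40
  p <- runif(n, 0.05, 0.95)
  t <- rbinom(n, 1, 0.3)
  for (w in list(c(0.5, 0.5, 0), c(0.02, 0.98, 0), c(0.1, 0.9, 0.5))) {
    g <- gliomctv:::tversky_bce_grad(p, t, w[1], w[2], w[3])
    lossf <- function(pp) {
      tp <- sum(pp * t); fp <- sum(pp * (1 - t)); fn <- sum((1 - pp) * t)
      l <- 1 - (tp + 1e-6) / (tp + w[1] * fp + w[2] * fn + 1e-6)
      if (w[3] > 0) {
        pc <- pmin(pmax(pp, 1e-7), 1 - 1e-7)
        l <- l + w[3] * mean(-(t * log(pc) + (1 - t) * log(1 - pc)))
      }
      l
    }
    for (i in c(1, 7, 25)) {
      eps <- 1e-6
      pp <- p; pp[i] <- p[i] + eps
      pm <- p; pm[i] <- p[i] - eps
      expect_equal(g[i], (lossf(pp) - lossf(pm)) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("hd95: identity, two-point case, symmetry, brute-force oracle", {
  shape <- c(12, 12, 12)
  sp <- c(3, 3, 3)
  a <- vol_grid(array(0, shape), sp); a$values[3, 3, 3] <- 1
  b <- vol_grid(array(0, shape), sp); b$values[7, 3, 3] <- 1 # 4 voxels = 12 mm
  expect_equal(hd95(a, a), 0)
  expect_equal(hd95(a, b), 12)
  expect_equal(hd95(a, b), hd95(b, a))
  expect_error(hd95(a, vol_grid(array(0, shape), sp)), "empty")

  set.seed(14)
  for (i in 1:8) {
    ra <- random_mask(shape, spacing = c(3, 3, 3), p = 0.08)
    rb <- random_mask(shape, spacing = c(3, 3, 3), p = 0.08)
    expect_equal(hd95(ra, rb), bf_hd95(ra, rb), tolerance = 1e-9)
  }
})

test_that("evaluate_pair matches hand computation on a countable fixture", {
  shape <- c(16, 16, 16)
  sp <- c(3, 3, 3)
  brain <- box_mask(shape, sp, c(2, 2, 2), c(15, 15, 15)) # 14^3 = 2744
  target <- box_mask(shape, sp, c(5, 5, 5), c(8, 8, 8))   # 4^3 = 64
  ctv <- box_mask(shape, sp, c(5, 5, 5), c(9, 8, 8))      # 5x4x4 = 80, TP 64
  r <- evaluate_pair(ctv$mask %||% ctv, target, brain)
  tp <- 64; fp <- 16; fn <- 0; tn <- 2744 - 80
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, tn / (tn + fp), tolerance = 1e-12)
  expect_equal(r$dice, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-4)
  expect_equal(r$tversky_002_098, tp / (tp + 0.02 * fp), tolerance = 1e-4)
  pars <- size_adaptive_params(64, 2744)
  expect_equal(r$pcc, tp / (tp + pars$alpha * fp), tolerance = 1e-4)
  expect_equal(r$hd95_mm, bf_hd95(ctv, target), tolerance = 1e-9)

  # degenerate over-treatment: CTV = brain
  r2 <- evaluate_pair(brain, target, brain)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)
  # identity
  r3 <- evaluate_pair(target, target, brain)
  expect_equal(r3$hd95_mm, 0)
  expect_equal(r3$pcc, 1, tolerance = 1e-4)
})

test_that("p-value banding matches the reporting convention", {
  expect_equal(p_band(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "<0.05", "<0.01", "<0.001", "<0.0001"))
})
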