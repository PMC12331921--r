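# hand-buildable geometry fixtures and brute-force oracles

ball_mask <- function(shape, spacing, centre_vox, radius_mm) {
  co <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                    z = seq_len(shape[3]))
  d <- sqrt(((co$x - centre_vox[1]) * spacing[1])^2 +
              ((co$y - centre_vox[2]) * spacing[2])^2 +
              ((co$z - centre_vox[3]) * spacing[3])^2)
  vol_grid(array(as.numeric(d <= radius_mm), shape), spacing)
}

box_mask <- function(shape, spacing, lo, hi) {
  a <- array(0, shape)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  vol_grid(a, spacing)
}

all_mask <- function(shape, spacing) {
  vol_grid(array(1, shape), spacing)
}

# brute-force margin expansion: all-pairs voxel-centre distances
bf_expand <- function(m, margin_mm, clip = NULL) {
  d <- dim(m$values)
  set_idx <- which(m$values > 0.5, arr.ind = TRUE)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  sp <- m$spacing
  keep <- vapply(seq_len(nrow(all_idx)), function(i) {
    dd <- sqrt(colSums((t(set_idx) * sp - all_idx[i, ] * sp)^2))
    min(dd) <= margin_mm + 1e-9
  }, logical(1))
  out <- vol_grid(array(as.numeric(keep), d), sp)
  if (!is.null(clip)) out <- mask_intersect(out, clip)
  out
}

# brute-force pooled 95th-percentile surface distance
bf_hd95 <- function(a, b, percentile = 95) {
  sa <- which(surface_voxels(a)$values > 0.5, arr.ind = TRUE)
  sb <- which(surface_voxels(b)$values > 0.5, arr.ind = TRUE)
  sp <- a$spacing
  pa <- t(t(sa) * sp)
  pb <- t(t(sb) * sp)
  dmat <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  unname(stats::quantile(c(d_ab, d_ba), percentile / 100))
}

# brute-force pairwise AUC (ties worth 1/2)
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# random small mask on a grid, guaranteed nonempty
random_mask <- function(shape, spacing = c(3, 3, 3), p = 0.15) {
  repeat {
    a <- array(as.numeric(stats::runif(prod(shape)) < p), shape)
    if (sum(a) > 0) return(vol_grid(a, spacing))
  }
}

# a fully hand-specified toy case on a 16^3 grid at 3 mm
toy_case <- function(channel_values = NULL) {
  shape <- c(16, 16, 16)
  sp <- c(3, 3, 3)
  brain <- box_mask(shape, sp, c(2, 2, 2), c(15, 15, 15))
  cavity <- box_mask(shape, sp, c(6, 6, 6), c(7, 7, 7))
  vent <- box_mask(shape, sp, c(12, 12, 12), c(13, 13, 13))
  cel <- box_mask(shape, sp, c(8, 8, 8), c(9, 9, 9))      # 8 voxels
  t2l <- box_mask(shape, sp, c(8, 8, 8), c(11, 10, 9))    # 4x3x2 = 24
  t2l <- mask_union(t2l, cel)
  pre <- derive_masks(cel, t2l, cavity, vent, brain)
  # progression: CEL grows into pre-NEL and NAV; T2L grows further
  cel_p <- box_mask(shape, sp, c(8, 8, 8), c(10, 10, 9))
  t2l_p <- box_mask(shape, sp, c(8, 8, 8), c(12, 11, 10))
  t2l_p <- mask_union(t2l_p, cel_p)
  prog <- derive_masks(cel_p, t2l_p, cavity, vent, brain)
  chans <- channel_values %||% list(
    cni = vol_grid(array(stats::rnorm(prod(shape), 0.5, 0.1), shape), sp),
    nflair = vol_grid(array(stats::rnorm(prod(shape), 0.5, 0.1), shape), sp)
  )
  structure(
    list(case_id = "toy_001", cohort = "SOC", time_to_progression = 5,
         channels = chans, pre_masks = pre, prog_masks = prog,
         mrsi_coverage = all_mask(shape, sp)),
    class = "case_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small quick cohort for pipeline tests
quick_cohort <- function(n = 6, seed = 11, grid = 32,
                         channels = c("nt1c", "nflair", "cni", "ccri")) {
  spec <- cohort_spec(
    n_cases = n, grid_shape = rep(grid, 3), seed = seed, channels = channels,
    lesion_volume_meanlog = log(26.4 / 3) # lesion scaled with the smaller brain
  )
  generate_cohort(spec)
}
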