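test_that("network output has the right shape, range and determinism", {
  cfg <- net_config(input_channels = c("a", "b"), base_features = 4,
                    stages = 3, add_coverage_channel = FALSE, seed = 1)
  m <- build_unet(cfg, n_channels = 2)
  set.seed(1)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  out1 <- gliomctv:::unet_forward(m, x)$prob
  out2 <- gliomctv:::unet_forward(m, x)$prob
  expect_equal(dim(out1), c(16, 16, 16))
  expect_true(all(out1 > 0 & out1 < 1))
  expect_identical(out1, out2)

  # parameter count strictly increases with base features
  m8 <- build_unet(net_config(base_features = 8, stages = 3,
                              add_coverage_channel = FALSE), n_channels = 2)
  expect_gt(n_parameters(m8), n_parameters(m))

  # non-divisible shapes are padded and cropped back
  x12 <- array(rnorm(12 * 14 * 12 * 2), c(12, 14, 12, 2))
  out12 <- gliomctv:::unet_forward(m, x12)$prob
  expect_equal(dim(out12), c(12, 14, 12))
})

test_that("cached and light forward passes agree", {
  cfg <- net_config(base_features = 4, stages = 2,
                    add_coverage_channel = FALSE, seed = 2)
  m <- build_unet(cfg, n_channels = 3)
  set.seed(2)
  x <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  expect_equal(gliomctv:::unet_forward(m, x, cache = TRUE)$prob,
               gliomctv:::unet_forward(m, x, cache = FALSE)$prob,
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- net_config(base_features = 4, stages = 2,
                    add_coverage_channel = FALSE, seed = 3)
  m <- build_unet(cfg, n_channels = 2)
  set.seed(3)
  x <- array(rnorm(8^3 * 2, sd = 0.5), c(8, 8, 8, 2))
  t <- array(as.numeric(runif(8^3) < 0.2), c(8, 8, 8))
  brain <- array(1, c(8, 8, 8))
  w <- list(alpha = 0.1, beta = 0.9, bce = 0.5)
  lossfun <- function(model) {
    fw <- gliomctv:::unet_forward(model, x, cache = TRUE)
    gliomctv:::case_loss_grad(fw$prob, t, brain, w)$loss
  }
  fw <- gliomctv:::unet_forward(m, x, cache = TRUE)
  lg <- gliomctv:::case_loss_grad(fw$prob, t, brain, w)
  gr <- gliomctv:::unet_backward(m, fw$cache, lg$grad)
  eps <- 1e-5
  for (nm in c("e1c1", "e2c2", "d1c1", "final")) {
    ii <- c(1, length(m$params[[nm]]$W) %/% 2 + 1)
    for (i in ii) {
      mp <- m; mp$params[[nm]]$W[i] <- m$params[[nm]]$W[i] + eps
      mm <- m; mm$params[[nm]]$W[i] <- m$params[[nm]]$W[i] - eps
      fd <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
      expect_equal(gr[[nm]]$W[i], fd, tolerance = 5e-3)
    }
    mpb <- m; mpb$params[[nm]]$b[1] <- m$params[[nm]]$b[1] + eps
    mmb <- m; mmb$params[[nm]]$b[1] <- m$params[[nm]]$b[1] - eps
    fdb <- (lossfun(mpb) - lossfun(mmb)) / (2 * eps)
    expect_equal(gr[[nm]]$b[1], fdb, tolerance = 5e-3)
  }
})

test_that("augmentation co-transforms geometry and is seed-reproducible", {
  set.seed(4)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  t <- array(as.numeric(runif(8^3) < 0.3), c(8, 8, 8))
  brain <- array(1, c(8, 8, 8))
  id_opts <- list(p_flip = 0, p_rot = 0, noise_sd = 0, p_shuffle = 0,
                  p_drop = 0)
  a0 <- augment_sample(x, t, brain, id_opts)
  expect_identical(a0$x, x)
  expect_identical(a0$t, t)

  # geometric transforms preserve the channel/target overlap statistic
  geo <- list(p_flip = 1, p_rot = 1, noise_sd = 0, p_shuffle = 0, p_drop = 0)
  before <- sum(x[, , , 1] * t)
  set.seed(9)
  a1 <- augment_sample(x, t, brain, geo)
  expect_equal(sum(a1$x[, , , 1] * a1$t), before, tolerance = 1e-9)
  expect_equal(sum(a1$t), sum(t))

  set.seed(9)
  a2 <- augment_sample(x, t, brain, geo)
  expect_identical(a1$x, a2$x)
})

test_that("case splits are stratified, disjoint, exhaustive, seeded", {
  mkc <- function(i, g) structure(list(case_id = sprintf("c%03d", i),
                                       cohort = g),
                                  class = "case_record")
  cases <- c(lapply(1:50, mkc, g = "SOC"), lapply(51:77, mkc, g = "ATT"),
             lapply(78:100, mkc, g = "ENZA"))
  s1 <- split_cases(cases, seed = 5)
  s2 <- split_cases(cases, seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(s1$train) + length(s1$val) + length(s1$test), 100)
  expect_true(abs(length(s1$train) - 66) <= 2)
  expect_true(abs(length(s1$val) - 16) <= 2)
  expect_true(abs(length(s1$test) - 18) <= 2)
  expect_equal(length(intersect(s1$train, s1$test)), 0)
  expect_equal(length(intersect(s1$train, s1$val)), 0)
  expect_error(split_cases(cases[1:4]), "at least 6")
})

test_that("composite target is the union of lesions at both timepoints", {
  tc <- toy_case()
  tg <- make_target(tc)
  manual <- mask_intersect(
    mask_union(mask_union(tc$pre_masks$cel, tc$pre_masks$nel),
               mask_union(tc$prog_masks$cel, tc$prog_masks$nel)),
    tc$pre_masks$brain
  )
  expect_identical(tg$values, manual$values)
  # superset of the pre-RT lesion
  pre <- mask_union(tc$pre_masks$cel, tc$pre_masks$nel)
  expect_true(all(pre$values <= tg$values))
  # no progression: target = pre-RT lesion
  tc0 <- tc
  tc0$prog_masks <- tc0$pre_masks
  expect_identical(make_target(tc0)$values, pre$values)
})

test_that("a tiny U-Net learns a one-case segmentation end to end", {
  coh <- quick_cohort(n = 1, seed = 44, channels = c("nt1c", "nflair"))
  cs <- coh$cases[[1]]
  cfg <- net_config(input_channels = c("nt1c", "nflair"), base_features = 4,
                    stages = 2, epochs = 30, learning_rate = 3e-3,
                    loss = "pcc_bce", bce_weight = 0.5, seed = 1,
                    add_coverage_channel = FALSE,
                    augment = list(p_flip = 0, p_rot = 0, noise_sd = 0,
                                   p_shuffle = 0, p_drop = 0))
  run <- train_unet(list(cs), cfg,
                    splits = list(train = cs$case_id, val = character(),
                                  test = character()))
  expect_s3_class(run, "training_run")
  expect_true(all(diff(run$history$epoch) == 1))
  pr <- predict_case(run, cs)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_true(all(pr$values[cs$pre_masks$brain$values <= 0.5] == 0))
  # the loss must actually decrease on its training case
  expect_lt(tail(run$history$train_loss, 1), run$history$train_loss[1] * 0.8)
  expect_error(predict_case(run, toy_case()), "missing input channel")
})

test_that("training is reproducible under a fixed seed", {
  coh <- quick_cohort(n = 1, seed = 45, channels = c("nt1c", "nflair"))
  cs <- coh$cases[[1]]
  cfg <- net_config(input_channels = c("nt1c", "nflair"), base_features = 4,
                    stages = 2, epochs = 3, learning_rate = 1e-3,
                    loss = "dice", seed = 7, add_coverage_channel = FALSE)
  sp <- list(train = cs$case_id, val = character(), test = character())
  r1 <- train_unet(list(cs), cfg, splits = sp)
  r2 <- train_unet(list(cs), cfg, splits = sp)
  expect_equal(r1$history$train_loss, r2$history$train_loss, tolerance = 1e-12)
})

test_that("the reference profile records the published optimum", {
  cfg <- net_config_paper()
  expect_equal(cfg$base_features, 48)
  expect_equal(cfg$learning_rate, 5e-5)
  expect_equal(cfg$batch_size, 1)
  expect_equal(cfg$stages, 4)
})

test_that("hyperparameter search ranks trials and is seed-stable", {
  coh <- quick_cohort(n = 6, seed = 48, grid = 16,
                      channels = c("nt1c", "nflair"))
  base_cfg <- net_config(input_channels = c("nt1c", "nflair"),
                         base_features = 4, stages = 2,
                         add_coverage_channel = FALSE,
                         augment = list(p_flip = 0, p_rot = 0, noise_sd = 0,
                                        p_shuffle = 0, p_drop = 0))
  grid <- list(base_features = 4, learning_rate = c(1e-3, 3e-3),
               batch_size = 1)
  r1 <- hyperparameter_search(coh$cases, grid, n_random = 2, epochs = 2,
                              seed = 3, base_cfg = base_cfg)
  r2 <- hyperparameter_search(coh$cases, grid, n_random = 2, epochs = 2,
                              seed = 3, base_cfg = base_cfg)
  expect_equal(nrow(r1), 4)
  expect_equal(r1$learning_rate, r2$learning_rate, tolerance = 1e-12)
  expect_equal(r1$val_tversky_002_098, r2$val_tversky_002_098,
               tolerance = 1e-12)
  # ranked: the top trial dominates every other trial
  expect_true(all(r1$val_tversky_002_098[1] >= r1$val_tversky_002_098))
  expect_true(all(diff(r1$val_tversky_002_098) <= 1e-12))

  # single-point space returns that configuration as the best
  r3 <- hyperparameter_search(coh$cases,
                              list(base_features = 4, learning_rate = 1e-3,
                                   batch_size = 1),
                              n_random = 0, epochs = 2, seed = 3,
                              base_cfg = base_cfg)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$learning_rate, 1e-3)
  expect_error(hyperparameter_search(coh$cases,
                                     list(base_features = integer(),
                                          learning_rate = numeric(),
                                          batch_size = integer()),
                                     seed = 3, base_cfg = base_cfg),
               "empty")
})
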