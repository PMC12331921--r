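#' Composite progression target for the segmentation task
#'
#' The mask the network learns to predict from pre-RT images alone: the
#' union of CEL and NEL at both timepoints (equivalently, pre-RT T2L
#' union progression T2L), clipped to the brain. It contains both the
#' current lesion and every voxel that will be lesion at progression.
#'
#' @param case a `case_record` with both timepoints' masks.
#' @return A binary `vol_grid`.
#' @export
make_target <- function(case) {
  stopifnot(inherits(case, "case_record"))
  if (is.null(case$prog_masks)) stop("case has no progression masks")
  les <- mask_union(
    mask_union(case$pre_masks$cel, case$pre_masks$nel),
    mask_union(case$prog_masks$cel, case$prog_masks$nel)
  )
  mask_intersect(les, case$pre_masks$brain)
}

#' Stratified train/validation/test split of cases
#'
#' Approximate 67/16/18 proportions (renormalized), preserved within
#' each treatment cohort by largest-remainder allocation of shuffled
#' cases. Deterministic under `seed`; splits are disjoint and exhaustive.
#'
#' @param cases list of `case_record`s.
#' @param fractions train/val/test proportions (renormalized to 1).
#' @param seed integer seed.
#' @return List of case-id character vectors: `train`, `val`, `test`.
#' @export
split_cases <- function(cases, fractions = c(0.67, 0.16, 0.18), seed = 1) {
  n <- length(cases)
  if (n < 6) stop("need at least 6 cases to populate train/val/test")
  fr <- fractions / sum(fractions)
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  coh <- vapply(cases, function(cs) cs$cohort, character(1))
  set.seed(as.integer(seed))
  out <- list(train = character(), val = character(), test = character())
  for (g in unique(coh)) {
    gi <- which(coh == g)
    gi <- gi[sample.int(length(gi))]
    m <- length(gi)
    base <- floor(fr * m)
    rem <- fr * m - base
    extra <- order(rem, decreasing = TRUE)[seq_len(m - sum(base))]
    cnt <- base
    cnt[extra] <- cnt[extra] + 1
    sp <- rep(1:3, cnt)
    out$train <- c(out$train, ids[gi[sp == 1]])
    out$val <- c(out$val, ids[gi[sp == 2]])
    out$test <- c(out$test, ids[gi[sp == 3]])
  }
  # guarantee all three splits are populated
  for (part in c("val", "test")) {
    if (length(out[[part]]) == 0) {
      mv <- out$train[length(out$train)]
      out$train <- setdiff(out$train, mv)
      out[[part]] <- mv
    }
  }
  if (length(out$train) == 0) stop("too few cases to populate all splits")
  stopifnot(length(intersect(out$train, out$val)) == 0,
            length(intersect(out$train, out$test)) == 0,
            length(intersect(out$val, out$test)) == 0,
            setequal(c(out$train, out$val, out$test), ids))
  out
}

# input stack for a case: normalized channels (+ coverage channel)
case_input_stack <- function(case, cfg) {
  missing_ch <- setdiff(cfg$input_channels, names(case$channels))
  if (length(missing_ch) > 0) {
    stop("case ", case$case_id, " is missing input channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  brain <- case$pre_masks$brain
  mats <- lapply(cfg$input_channels, function(ch) {
    minmax_normalize(case$channels[[ch]], brain)$values
  })
  if (cfg$add_coverage_channel) {
    mats <- c(mats, list(case$mrsi_coverage$values))
  }
  arr <- array(0, c(dim(brain$values), length(mats)))
  for (i in seq_along(mats)) arr[, , , i] <- mats[[i]]
  arr
}

#' Seeded geometric and intensity augmentation of a training sample
#'
#' Axis flips and axis-aligned 90-degree rotations are applied
#' identically to channels, target and brain mask; Gaussian noise,
#' channel shuffling and channel dropping touch the channels only.
#' Rotations are restricted to axis pairs of equal length so masks stay
#' on the grid without interpolation. Draws come from the current RNG
#' stream, so a fixed seed upstream makes the batch reproducible.
#'
#' @param x 4D input array (x, y, z, channel).
#' @param t 3D target array.
#' @param brain 3D brain array.
#' @param opts augmentation options list (see [net_config()]).
#' @return List `x`, `t`, `brain`.
#' @export
augment_sample <- function(x, t, brain, opts) {
  d <- dim(x)[1:3]
  flip4 <- function(a, ax) {
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- rev(idx[[ax]])
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (ax in 1:3) {
    if (stats::runif(1) < opts$p_flip) {
      x <- flip4(x, ax)
      t <- array(flip4(array(t, c(dim(t), 1)), ax), dim(t))
      brain <- array(flip4(array(brain, c(dim(brain), 1)), ax), dim(brain))
    }
  }
  if (stats::runif(1) < opts$p_rot) {
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    pairs <- pairs[vapply(pairs, function(p) d[p[1]] == d[p[2]], logical(1))]
    if (length(pairs) > 0) {
      pr <- pairs[[sample.int(length(pairs), 1)]]
      rot <- function(a) {
        perm <- seq_along(dim(a))
        perm[pr] <- rev(perm[pr])
        flip4(aperm(a, perm), pr[1])
      }
      x <- rot(x)
      t <- array(rot(array(t, c(dim(t), 1))), dim(t))
      brain <- array(rot(array(brain, c(dim(brain), 1))), dim(brain))
    }
  }
  if (opts$noise_sd > 0) {
    x <- x + array(stats::rnorm(length(x), sd = opts$noise_sd), dim(x))
  }
  nc <- dim(x)[4]
  if (nc > 1 && stats::runif(1) < opts$p_shuffle) {
    x <- x[, , , sample.int(nc), drop = FALSE]
  }
  if (nc > 1 && stats::runif(1) < opts$p_drop) {
    x[, , , sample.int(nc, 1)] <- 0
  }
  list(x = x, t = t, brain = brain)
}

# per-case loss weights under the configured loss
loss_weights <- function(cfg, target, brain) {
  switch(cfg$loss,
    dice = list(alpha = 0.5, beta = 0.5, bce = 0),
    tversky = list(alpha = cfg$alpha, beta = cfg$beta, bce = 0),
    pcc = {
      pars <- size_adaptive_params(sum(target > 0.5), sum(brain > 0.5))
      list(alpha = pars$alpha, beta = pars$beta, bce = 0)
    },
    pcc_bce = {
      pars <- size_adaptive_params(sum(target > 0.5), sum(brain > 0.5))
      list(alpha = pars$alpha, beta = pars$beta, bce = cfg$bce_weight)
    }
  )
}

# loss value and gradient array for one case
case_loss_grad <- function(prob, target, brain, w, smooth = 1e-6) {
  sel <- brain > 0.5
  p <- prob[sel]
  t <- as.numeric(target[sel] > 0.5)
  tp <- sum(p * t); fp <- sum(p * (1 - t)); fn <- sum((1 - p) * t)
  tv <- (tp + smooth) / (tp + w$alpha * fp + w$beta * fn + smooth)
  loss <- 1 - tv
  if (w$bce > 0) {
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    loss <- loss + w$bce * mean(-(t * log(pc) + (1 - t) * log(1 - pc)))
  }
  g <- tversky_bce_grad(p, t, w$alpha, w$beta, w$bce, smooth)
  grad <- array(0, dim(prob))
  grad[sel] <- g
  list(loss = loss, grad = grad)
}

# hard validation metrics on (possibly cropped) prepared arrays
val_metrics_arrays <- function(prob, target, brain, smooth = 1e-6) {
  sel <- brain > 0.5
  p <- prob[sel] > 0.5
  t <- target[sel] > 0.5
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  pars <- size_adaptive_params(max(sum(t), 1), sum(sel))
  c(pcc = (tp + smooth) / (tp + pars$alpha * fp + pars$beta * fn + smooth),
    tversky_002_098 = (tp + smooth) / (tp + 0.02 * fp + 0.98 * fn + smooth))
}

#' Train the 3D U-Net on a cohort
#'
#' Per-case min-max normalized channel stacks in, composite progression
#' target out; optimizes the configured loss with Adam (adaptive-moment
#' optimizer), evaluates validation PCC and Tversky(0.02, 0.98) each
#' epoch, and keeps the weights of the best epoch under the configured
#' selection metric. Asserts that no case id appears in more than one
#' split before touching any data.
#'
#' @param cases list of `case_record`s.
#' @param cfg a [net_config()].
#' @param splits a [split_cases()] result; computed from `cfg$seed` when
#'   `NULL`.
#' @param verbose print per-epoch progress?
#' @return A `training_run`: `model` (best weights), `history` tibble,
#'   `best_epoch`, `cfg`, `splits`.
#' @export
train_unet <- function(cases, cfg, splits = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "net_config"))
  if (is.null(splits)) splits <- split_cases(cases, seed = cfg$seed)
  stopifnot(length(intersect(splits$train, splits$val)) == 0,
            length(intersect(splits$train, splits$test)) == 0)
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  tr_cases <- cases[match(splits$train, ids)]
  va_cases <- cases[match(splits$val, ids)]
  model <- build_unet(cfg)
  # precompute inputs/targets once; augmentation perturbs copies
  prep <- function(cs) {
    x <- case_input_stack(cs, cfg)
    t <- array(as.numeric(make_target(cs)$values),
               dim(cs$pre_masks$brain$values))
    brain <- cs$pre_masks$brain$values
    if (isTRUE(cfg$crop_to_band)) {
      band <- band_mask(cs$pre_masks, 40)
      idx <- which(band$values > 0.5, arr.ind = TRUE)
      d <- dim(brain)
      lo <- pmax(apply(idx, 2, min) - 2L, 1L)
      hi <- pmin(apply(idx, 2, max) + 2L, d)
      x <- x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
      t <- t[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      brain <- brain[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] *
        band$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    }
    list(x = x, t = t, brain = brain, case = cs)
  }
  tr <- lapply(tr_cases, prep)
  va <- lapply(va_cases, prep)
  opt <- adam_init(model$params)
  set.seed(cfg$seed + 1L)
  hist <- list()
  best <- list(metric = -Inf, epoch = NA_integer_, params = model$params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(tr))
    ep_loss <- 0
    acc <- NULL
    n_acc <- 0
    for (ii in seq_along(ord)) {
      smp <- tr[[ord[ii]]]
      aug <- augment_sample(smp$x, smp$t, smp$brain, cfg$augment)
      w <- loss_weights(cfg, aug$t, aug$brain)
      fw <- unet_forward(model, aug$x, cache = TRUE)
      lg <- case_loss_grad(fw$prob, aug$t, aug$brain, w)
      if (!is.finite(lg$loss)) stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + lg$loss
      gr <- unet_backward(model, fw$cache, lg$grad)
      acc <- if (is.null(acc)) gr else
        mapply(function(a, g) list(W = a$W + g$W, b = a$b + g$b),
               acc, gr, SIMPLIFY = FALSE)
      n_acc <- n_acc + 1
      if (n_acc == cfg$batch_size || ii == length(ord)) {
        if (n_acc > 1) {
          acc <- lapply(acc, function(a) list(W = a$W / n_acc, b = a$b / n_acc))
        }
        st <- adam_step(model$params, acc, opt, cfg$learning_rate)
        model$params <- st$params
        opt <- st$state
        acc <- NULL
        n_acc <- 0
      }
    }
    vm <- c(pcc = NA_real_, tversky_002_098 = NA_real_)
    if (length(va) > 0) {
      vms <- vapply(va, function(smp) {
        pr <- unet_forward(model, smp$x)$prob
        val_metrics_arrays(pr, smp$t, smp$brain)
      }, numeric(2))
      vm <- rowMeans(vms)
    }
    sel_metric <- if (length(va) > 0) vm[[cfg$selection]] else -ep_loss / length(tr)
    if (sel_metric > best$metric) {
      best <- list(metric = sel_metric, epoch = ep, params = model$params)
    }
    train_pcc <- NA_real_
    if (!is.null(cfg$stop_train_pcc)) {
      train_pcc <- mean(vapply(tr, function(smp) {
        pr <- unet_forward(model, smp$x)$prob
        val_metrics_arrays(pr, smp$t, smp$brain)[["pcc"]]
      }, numeric(1)))
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / length(tr),
      train_pcc = train_pcc,
      val_pcc = vm[["pcc"]], val_tversky_002_098 = vm[["tversky_002_098"]]
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val PCC %.3f  val Tv %.3f",
                      ep, ep_loss / length(tr), vm[["pcc"]],
                      vm[["tversky_002_098"]]))
    }
    if (!is.null(cfg$stop_train_pcc) && isTRUE(train_pcc >= cfg$stop_train_pcc)) {
      if (length(va) == 0) best <- list(metric = train_pcc, epoch = ep,
                                       params = model$params)
      break
    }
  }
  model$params <- best$params
  structure(
    list(model = model, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, best_metric = best$metric,
         cfg = cfg, splits = splits),
    class = "training_run"
  )
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf(
    "<training_run> %d epochs (best %d: %s = %.3f), %d/%d/%d train/val/test cases\n",
    nrow(x$history), x$best_epoch, x$cfg$selection, x$best_metric,
    length(x$splits$train), length(x$splits$val), length(x$splits$test)
  ))
  invisible(x)
}

#' Predict a progression probability field for one case
#'
#' @param object a `training_run` or `unet_model`.
#' @param case a `case_record` carrying the model's input channels.
#' @return A `vol_grid` of probabilities in `[0, 1]`, zero outside the
#'   brain.
#' @export
predict_case <- function(object, case) {
  model <- if (inherits(object, "training_run")) object$model else object
  stopifnot(inherits(model, "unet_model"))
  x <- case_input_stack(case, model$cfg)
  pr <- unet_forward(model, x)$prob
  out <- new_like(case$pre_masks$brain, pr)
  out$values[case$pre_masks$brain$values <= 0.5] <- 0
  out
}

#' Two-phase hyperparameter search
#'
#' Coarse grid first, then `n_random` random draws around the best grid
#' point (log-uniform learning rate within a factor of 3, base features
#' jittered among neighbours). Trials are ranked by best validation
#' Tversky(0.02, 0.98); all trials are returned with full provenance.
#'
#' @param cases list of `case_record`s.
#' @param grid named list with vectors `base_features`, `learning_rate`,
#'   `batch_size`.
#' @param n_random random-phase trials (the reference pipeline used 30;
#'   desk scale defaults to 5).
#' @param epochs epochs per trial.
#' @param seed integer seed.
#' @param base_cfg template [net_config()] supplying everything the
#'   search does not vary.
#' @return Tibble of trials, ranked, with a `config` list-column.
#' @export
hyperparameter_search <- function(cases,
                                  grid = list(base_features = c(4, 8),
                                              learning_rate = c(1e-3, 3e-4),
                                              batch_size = 1),
                                  n_random = 5, epochs = 5, seed = 1,
                                  base_cfg = net_config()) {
  combos <- expand.grid(base_features = grid$base_features,
                        learning_rate = grid$learning_rate,
                        batch_size = grid$batch_size)
  if (nrow(combos) == 0) stop("empty search space")
  splits <- split_cases(cases, seed = seed)
  run_trial <- function(bf, lr, bs, phase, trial) {
    cfg <- base_cfg
    cfg$base_features <- as.integer(bf)
    cfg$learning_rate <- lr
    cfg$batch_size <- as.integer(bs)
    cfg$epochs <- epochs
    cfg$seed <- as.integer(seed + trial)
    run <- train_unet(cases, cfg, splits = splits)
    tibble::tibble(
      phase = phase, trial = trial, base_features = as.integer(bf),
      learning_rate = lr, batch_size = as.integer(bs),
      val_tversky_002_098 = run$best_metric, best_epoch = run$best_epoch,
      config = list(cfg)
    )
  }
  res <- purrr::pmap_dfr(
    list(combos$base_features, combos$learning_rate, combos$batch_size,
         seq_len(nrow(combos))),
    function(bf, lr, bs, i) run_trial(bf, lr, bs, "grid", i)
  )
  best <- res[which.max(res$val_tversky_002_098), ]
  set.seed(as.integer(seed))
  if (n_random > 0) {
    for (r in seq_len(n_random)) {
      lr <- exp(stats::runif(1, log(best$learning_rate / 3),
                             log(best$learning_rate * 3)))
      bf_pool <- unique(pmax(4, best$base_features + c(-4, 0, 4)))
      bf <- bf_pool[sample.int(length(bf_pool), 1)]
      res <- dplyr::bind_rows(res, run_trial(bf, lr, best$batch_size,
                                             "random", nrow(combos) + r))
    }
  }
  dplyr::arrange(res, dplyr::desc(.data$val_tversky_002_098))
}
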