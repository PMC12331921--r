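#' Network configuration for the 3D U-Net
#'
#' @param input_channels channel names fed to the network; the defaults
#'   are the six maps with the strongest progression signal.
#' @param base_features feature maps at the first stage; doubled per stage.
#' @param stages encoder depth (>= 2); 4 reproduces the reference
#'   architecture, smaller values give cheaper desk-scale models.
#' @param learning_rate Adam step size.
#' @param batch_size cases per gradient step (gradient accumulation).
#' @param loss one of `"dice"`, `"tversky"`, `"pcc"`, `"pcc_bce"`.
#' @param alpha,beta fixed Tversky weights (only for `loss = "tversky"`).
#' @param bce_weight lambda of the compound PCC+BCE loss.
#' @param epochs training epochs.
#' @param selection validation metric maximized for checkpointing:
#'   `"tversky_002_098"` (default) or `"pcc"`.
#' @param add_coverage_channel concatenate the MRSI coverage mask as an
#'   extra input channel when metabolic channels are used (`NULL` =
#'   auto).
#' @param stop_train_pcc optional early-stopping target: training stops
#'   once the mean hard PCC over the (unaugmented) training cases
#'   reaches this value.
#' @param crop_to_band restrict training samples to the bounding box of
#'   the 4 cm analysis band around the pre-RT lesion. No progression
#'   occurs outside the band, so voxels beyond it carry no training
#'   signal; the fully convolutional network still predicts whole
#'   volumes at inference.
#' @param augment list of augmentation probabilities/strengths:
#'   `p_flip`, `p_rot`, `noise_sd`, `p_shuffle`, `p_drop`.
#' @param seed integer seed (weights, shuffling, augmentation).
#' @export
net_config <- function(input_channels = c("nt1c", "nflair", "nadc", "nfa",
                                          "cni", "ccri"),
                       base_features = 8, stages = 4,
                       learning_rate = 1e-3, batch_size = 1,
                       loss = c("pcc", "dice", "tversky", "pcc_bce"),
                       alpha = 0.5, beta = 0.5, bce_weight = 0.5,
                       epochs = 60,
                       selection = c("tversky_002_098", "pcc"),
                       add_coverage_channel = NULL,
                       stop_train_pcc = NULL,
                       crop_to_band = TRUE,
                       augment = list(p_flip = 0.5, p_rot = 0.5,
                                      noise_sd = 0.02, p_shuffle = 0.1,
                                      p_drop = 0.1),
                       seed = 1) {
  loss <- match.arg(loss)
  selection <- match.arg(selection)
  stopifnot(stages >= 2, base_features >= 4, learning_rate > 0, batch_size >= 1)
  if (is.null(add_coverage_channel)) {
    add_coverage_channel <- any(input_channels %in% metabolic_channels())
  }
  structure(
    list(input_channels = input_channels, base_features = base_features,
         stages = stages, learning_rate = learning_rate,
         batch_size = batch_size, loss = loss, alpha = alpha, beta = beta,
         bce_weight = bce_weight, epochs = epochs, selection = selection,
         add_coverage_channel = add_coverage_channel,
         stop_train_pcc = stop_train_pcc, crop_to_band = crop_to_band,
         augment = augment,
         seed = as.integer(seed)),
    class = "net_config"
  )
}

#' The reference training profile
#'
#' The printed optimum of the original hyperparameter search: learning
#' rate 5e-5, 48 base features, mini-batch 1, four stages. Far heavier
#' than the desk-scale defaults; provided as a named profile.
#' @param ... overrides passed to [net_config()].
#' @export
net_config_paper <- function(...) {
  net_config(base_features = 48, stages = 4, learning_rate = 5e-5,
             batch_size = 1, ...)
}

# layer descriptors: channel arithmetic for an input with n_in channels
unet_arch <- function(cfg, n_in) {
  s <- cfg$stages
  fk <- cfg$base_features * 2^(0:(s - 1))
  layers <- list()
  cin <- n_in
  for (i in 1:s) {
    layers[[paste0("e", i, "c1")]] <- list(k = 3L, cin = cin, cout = fk[i])
    layers[[paste0("e", i, "c2")]] <- list(k = 3L, cin = fk[i], cout = fk[i])
    cin <- fk[i]
  }
  for (j in (s - 1):1) {
    layers[[paste0("d", j, "c1")]] <- list(k = 3L, cin = fk[j + 1] + fk[j], cout = fk[j])
    layers[[paste0("d", j, "c2")]] <- list(k = 3L, cin = fk[j], cout = fk[j])
  }
  layers[["final"]] <- list(k = 1L, cin = fk[1], cout = 1L)
  layers
}

#' Build a randomly initialized 3D U-Net
#'
#' Encoder of `stages` levels with two 3x3x3 convolution + ReLU blocks
#' per level and 2x max-pooling between levels, feature counts doubling
#' from `base_features`; symmetric decoder with nearest-neighbour
#' upsampling and concatenation skips; final 1x1x1 projection with a
#' logistic output. He-initialized from `cfg$seed`.
#'
#' @param cfg a [net_config()].
#' @param n_channels number of input channels (including the coverage
#'   channel when enabled).
#' @return A `unet_model`.
#' @export
build_unet <- function(cfg, n_channels = length(cfg$input_channels) +
                         as.integer(cfg$add_coverage_channel)) {
  arch <- unet_arch(cfg, n_channels)
  set.seed(cfg$seed)
  params <- lapply(arch, function(l) {
    fan_in <- l$k^3 * l$cin
    list(
      W = array(stats::rnorm(l$k^3 * l$cin * l$cout, sd = sqrt(2 / fan_in)),
                c(l$k, l$k, l$k, l$cin, l$cout)),
      b = rep(0, l$cout)
    )
  })
  structure(list(cfg = cfg, arch = arch, params = params,
                 n_channels = n_channels),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<unet_model> %d stages, base %d, %d input channels, %s parameters\n",
              x$cfg$stages, x$cfg$base_features, x$n_channels,
              format(np, big.mark = ",")))
  invisible(x)
}

#' @rdname build_unet
#' @param model a `unet_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

conv_f <- function(x, p) conv3d_fwd_cpp(x, p$W, p$b, dim(x), dim(p$W))
conv_b <- function(x, p, dy) conv3d_bwd_cpp(x, p$W, dy, dim(x), dim(p$W))

pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  target <- ceiling(d[1:3] / mult) * mult
  if (all(target == d[1:3])) {
    return(list(x = x, off = c(0L, 0L, 0L), orig = d[1:3]))
  }
  off <- as.integer(floor((target - d[1:3]) / 2))
  out <- array(0, c(target, d[4]))
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3]), ] <-
    x
  list(x = out, off = off, orig = d[1:3])
}

crop_from_pad <- function(x, off, orig) {
  x[off[1] + seq_len(orig[1]), off[2] + seq_len(orig[2]),
    off[3] + seq_len(orig[3]), , drop = FALSE]
}

# forward pass; with cache = TRUE keeps everything backward needs
unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$cfg
  s <- cfg$stages
  pad <- pad_to_multiple(x, 2^(s - 1))
  if (!cache) return(unet_forward_light(model, pad))
  cur <- pad$x
  cc <- list(pad = pad, enc = vector("list", s), dec = vector("list", s - 1))
  for (i in 1:s) {
    p1 <- model$params[[paste0("e", i, "c1")]]
    p2 <- model$params[[paste0("e", i, "c2")]]
    x1 <- cur
    z1 <- conv_f(x1, p1)
    a1 <- pmax(z1, 0)
    z2 <- conv_f(a1, p2)
    a2 <- pmax(z2, 0)
    cc$enc[[i]] <- list(x1 = x1, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
    if (i < s) {
      pl <- maxpool2_fwd_cpp(a2, dim(a2))
      cc$enc[[i]]$pool_argmax <- pl$argmax
      cur <- pl$y
    } else {
      cur <- a2
    }
  }
  skips <- lapply(cc$enc, `[[`, "a2")
  for (j in (s - 1):1) {
    up <- upsample2_fwd_cpp(cur, dim(cur))
    sk <- skips[[j]]
    cat_in <- array(0, c(dim(up)[1:3], dim(up)[4] + dim(sk)[4]))
    cat_in[, , , seq_len(dim(up)[4])] <- up
    cat_in[, , , dim(up)[4] + seq_len(dim(sk)[4])] <- sk
    p1 <- model$params[[paste0("d", j, "c1")]]
    p2 <- model$params[[paste0("d", j, "c2")]]
    z1 <- conv_f(cat_in, p1)
    a1 <- pmax(z1, 0)
    z2 <- conv_f(a1, p2)
    a2 <- pmax(z2, 0)
    cc$dec[[j]] <- list(low_dim = dim(cur), n_up = dim(up)[4],
                        x1 = cat_in, z1 = z1, a1 = a1, z2 = z2)
    cur <- a2
  }
  pf <- model$params[["final"]]
  zf <- conv_f(cur, pf)
  prob_pad <- 1 / (1 + exp(-zf))
  cc$final_x <- cur
  cc$prob_pad <- prob_pad
  prob <- crop_from_pad(prob_pad, pad$off, pad$orig)
  list(prob = array(prob, pad$orig), cache = cc)
}

unet_forward_light <- function(model, pad) {
  # inference path: identical math to the cached path, minimal storage
  cfg <- model$cfg
  s <- cfg$stages
  cur <- pad$x
  skips <- vector("list", s)
  for (i in 1:s) {
    a <- pmax(conv_f(cur, model$params[[paste0("e", i, "c1")]]), 0)
    a <- pmax(conv_f(a, model$params[[paste0("e", i, "c2")]]), 0)
    skips[[i]] <- a
    cur <- if (i < s) maxpool2_fwd_cpp(a, dim(a))$y else a
  }
  for (j in (s - 1):1) {
    up <- upsample2_fwd_cpp(cur, dim(cur))
    sk <- skips[[j]]
    cat_in <- array(0, c(dim(up)[1:3], dim(up)[4] + dim(sk)[4]))
    cat_in[, , , seq_len(dim(up)[4])] <- up
    cat_in[, , , dim(up)[4] + seq_len(dim(sk)[4])] <- sk
    a <- pmax(conv_f(cat_in, model$params[[paste0("d", j, "c1")]]), 0)
    cur <- pmax(conv_f(a, model$params[[paste0("d", j, "c2")]]), 0)
  }
  zf <- conv_f(cur, model$params[["final"]])
  prob_pad <- 1 / (1 + exp(-zf))
  prob <- crop_from_pad(prob_pad, pad$off, pad$orig)
  list(prob = array(prob, pad$orig), cache = NULL)
}

# backward pass: dprob is the gradient w.r.t. the (cropped) probability
# field; returns a grads list parallel to model$params
unet_backward <- function(model, cache, dprob) {
  s <- model$cfg$stages
  pad <- cache$pad
  dpp <- array(0, dim(cache$prob_pad))
  dpp[pad$off[1] + seq_len(pad$orig[1]), pad$off[2] + seq_len(pad$orig[2]),
      pad$off[3] + seq_len(pad$orig[3]), 1] <- dprob
  dzf <- dpp * cache$prob_pad * (1 - cache$prob_pad)
  grads <- list()
  bf <- conv_b(cache$final_x, model$params[["final"]], dzf)
  grads[["final"]] <- list(W = bf$dw, b = bf$db)
  cur <- bf$dx
  dskip <- vector("list", s)
  for (j in 1:(s - 1)) {
    dc <- cache$dec[[j]]
    dz2 <- cur * (dc$z2 > 0)
    b2 <- conv_b(dc$a1, model$params[[paste0("d", j, "c2")]], dz2)
    grads[[paste0("d", j, "c2")]] <- list(W = b2$dw, b = b2$db)
    dz1 <- b2$dx * (dc$z1 > 0)
    b1 <- conv_b(dc$x1, model$params[[paste0("d", j, "c1")]], dz1)
    grads[[paste0("d", j, "c1")]] <- list(W = b1$dw, b = b1$db)
    dcat <- b1$dx
    dup <- dcat[, , , seq_len(dc$n_up), drop = FALSE]
    dskip[[j]] <- dcat[, , , dc$n_up + seq_len(dim(dcat)[4] - dc$n_up),
                       drop = FALSE]
    cur <- upsample2_bwd_cpp(dup, dim(dup))
  }
  dpool_in <- NULL
  for (i in s:1) {
    ec <- cache$enc[[i]]
    g <- if (i == s) cur else dskip[[i]] +
      maxpool2_bwd_cpp(dpool_in, ec$pool_argmax, dim(ec$a2))
    dz2 <- g * (ec$z2 > 0)
    b2 <- conv_b(ec$a1, model$params[[paste0("e", i, "c2")]], dz2)
    grads[[paste0("e", i, "c2")]] <- list(W = b2$dw, b = b2$db)
    dz1 <- b2$dx * (ec$z1 > 0)
    b1 <- conv_b(ec$x1, model$params[[paste0("e", i, "c1")]], dz1)
    grads[[paste0("e", i, "c1")]] <- list(W = b1$dw, b = b1$db)
    dpool_in <- b1$dx
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) list(W = array(0, dim(p$W)), b = rep(0, length(p$b)))),
    v = lapply(params, function(p) list(W = array(0, dim(p$W)), b = rep(0, length(p$b)))),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g^2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (state$m[[nm]][[fld]] / bc1) /
          (sqrt(state$v[[nm]][[fld]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
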