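#' Network configuration for the 2D-to-3D reconstruction model
#'
#' Hyperparameters of the biplanar-projection to volumetric-CT network: two
#' convolutional encoders (one per projection) with residual blocks, a dense
#' fusion stage mapping the concatenated projection features onto a coarse 3D
#' grid, and a transposed-convolution decoder that upscales the coarse grid
#' to the reference CT shape. Defaults are desk-scale; every value is
#' exposed so larger studies can drop in their own settings.
#'
#' @param base_channels channel width of the first encoder stage (widths grow
#'   to 2x this value deeper in the encoder; the decoder starts from half of
#'   it).
#' @param n_residual_blocks number of residual blocks (each
#'   `x + conv(relu(conv(x)))`) at the encoder's coarsest 2D stage.
#' @param kernel_size odd convolution kernel edge length (voxels/pixels).
#' @param learning_rate Adam learning rate.
#' @param gradient_loss_weight weight of the edge (gradient) loss term; 0
#'   disables it.
#' @param epochs training epochs.
#' @param batch_size samples per optimizer step.
#' @param seed single integer seed; weight initialization and batch order
#'   derive from it (plus the fold index during cross-validation).
#' @param intensity_window `(low, high)` HU window used to normalize volumes
#'   to `[-1, 1]` and to de-normalize network output back to HU.
#' @param input_size square side (pixels) projections are resampled to
#'   before entering the encoders; must be `8 * 2^m`.
#' @param fusion_dim width of the dense bottleneck between the flattened
#'   projection features and the coarse 3D grid.
#' @param output_shape reference CT grid shape (voxels); each axis must be
#'   divisible by 8 (the decoder upscales 2x three times).
#' @return an object of class `network_config`.
#' @export
network_config <- function(base_channels = 16L, n_residual_blocks = 4L,
                           kernel_size = 3L, learning_rate = 1e-3,
                           gradient_loss_weight = 1.0, epochs = 50L,
                           batch_size = 1L, seed = 1L,
                           intensity_window = c(-1000, 600),
                           input_size = 128L, fusion_dim = 256L,
                           output_shape = c(64L, 64L, 48L)) {
  cfg <- list(base_channels = as.integer(base_channels),
              n_residual_blocks = as.integer(n_residual_blocks),
              kernel_size = as.integer(kernel_size),
              learning_rate = learning_rate,
              gradient_loss_weight = gradient_loss_weight,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              seed = as.integer(seed),
              intensity_window = as.numeric(intensity_window),
              input_size = as.integer(input_size),
              fusion_dim = as.integer(fusion_dim),
              output_shape = as.integer(output_shape))
  if (cfg$n_residual_blocks < 1L) stop("`n_residual_blocks` must be >= 1")
  if (cfg$kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  if (cfg$gradient_loss_weight < 0) stop("`gradient_loss_weight` must be >= 0")
  if (cfg$intensity_window[2] <= cfg$intensity_window[1])
    stop("`intensity_window` must be increasing")
  p <- cfg$input_size
  if (p < 16L || log2(p / 8) %% 1 != 0)
    stop("`input_size` must be 8 * 2^m with m >= 1")
  if (length(cfg$output_shape) != 3L || any(cfg$output_shape %% 8L != 0L))
    stop("`output_shape` axes must be divisible by 8")
  class(cfg) <- "network_config"
  cfg
}

#' HU normalization over an intensity window
#'
#' Affine map of HU onto `[-1, 1]` over `window` (and back); the round trip
#' is exact.
#'
#' @param hu,z numeric arrays.
#' @param window `(low, high)` HU window.
#' @return array of the same shape.
#' @export
normalize_hu <- function(hu, window) {
  2 * (hu - window[1]) / (window[2] - window[1]) - 1
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(z, window) {
  (z + 1) / 2 * (window[2] - window[1]) + window[1]
}

encoder_plan <- function(cfg) {
  p <- cfg$input_size
  n_down <- as.integer(log2(p / 8))
  couts <- cfg$base_channels * pmin(2^(seq_len(n_down) - 1L), 2L)
  list(n_down = n_down, couts = as.integer(couts),
       c_enc = as.integer(couts[n_down]))
}

decoder_channels <- function(cfg) {
  c0 <- cfg$base_channels
  as.integer(c(max(c0 %/% 2L, 2L), max(c0 %/% 4L, 2L),
               max(c0 %/% 8L, 2L), 1L))
}

#' Build the reconstruction model
#'
#' Instantiates the network with seeded He/linear weight initialization. The
#' forward map takes a resampled, normalized projection pair (an
#' `input_size x input_size x 2` array) to a normalized volume of
#' `output_shape`.
#'
#' @param config a [network_config()].
#' @return an object of class `inversenet` holding the parameter list and
#'   architecture plan.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel_size
  ep <- encoder_plan(config)
  dc <- decoder_channels(config)
  coarse <- config$output_shape %/% 8L
  params <- list()
  with_seed(config$seed, {
    for (e in 1:2) {
      cin <- 1L
      for (i in seq_len(ep$n_down)) {
        cout <- ep$couts[i]
        params[[sprintf("enc%d_down%d_W", e, i)]] <-
          he_init(c(k, k, cin, cout), k * k * cin)
        params[[sprintf("enc%d_down%d_b", e, i)]] <- numeric(cout)
        cin <- cout
      }
      for (j in seq_len(config$n_residual_blocks)) {
        for (h in 1:2) {
          params[[sprintf("enc%d_res%d_W%d", e, j, h)]] <-
            he_init(c(k, k, ep$c_enc, ep$c_enc), k * k * ep$c_enc)
          params[[sprintf("enc%d_res%d_b%d", e, j, h)]] <- numeric(ep$c_enc)
        }
      }
      params[[sprintf("enc%d_pool_W", e)]] <-
        he_init(c(k, k, ep$c_enc, ep$c_enc), k * k * ep$c_enc)
      params[[sprintf("enc%d_pool_b", e)]] <- numeric(ep$c_enc)
    }
    feat <- 2L * 4L * 4L * ep$c_enc
    gsize <- prod(coarse) * dc[1]
    params$fus1_W <- he_init(c(feat, config$fusion_dim), feat)
    params$fus1_b <- numeric(config$fusion_dim)
    params$fus2_W <- he_init(c(config$fusion_dim, gsize), config$fusion_dim)
    params$fus2_b <- numeric(gsize)
    for (i in 1:3) {
      init <- if (i < 3) he_init else lin_init
      params[[sprintf("dec%d_W", i)]] <-
        init(c(k, k, k, dc[i], dc[i + 1]), k^3 * dc[i])
      params[[sprintf("dec%d_b", i)]] <- numeric(dc[i + 1])
    }
    # air-prior output bias: start the prediction at the background value so
    # optimization spends its steps on anatomy rather than on empty space
    params$dec3_b[] <- max(-1, min(1, normalize_hu(-1000,
                                                   config$intensity_window)))
  })
  structure(list(config = config, plan = ep, dec_channels = dc,
                 coarse = coarse, params = params),
            class = "inversenet")
}

#' Number of trainable parameters
#'
#' @param model an [build_model()] result.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "inversenet"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.inversenet <- function(x, ...) {
  cat(sprintf(
    "<inversenet> %d -> %s, %d residual blocks, %s parameters\n",
    x$config$input_size,
    paste(x$config$output_shape, collapse = "x"),
    x$config$n_residual_blocks,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

net_forward <- function(model, input, want_cache = TRUE) {
  p <- model$params
  cfg <- model$config
  cache <- if (want_cache) list() else NULL
  feats <- vector("list", 2L)
  for (e in 1:2) {
    t <- array(input[, , e], c(dim(input)[1:2], 1L))
    for (i in seq_len(model$plan$n_down)) {
      cv <- conv2d_f(t, p[[sprintf("enc%d_down%d_W", e, i)]],
                     p[[sprintf("enc%d_down%d_b", e, i)]], stride = 2L)
      rl <- relu_f(cv$out)
      t <- rl$out
      if (want_cache) cache[[sprintf("e%dd%d", e, i)]] <-
          list(conv = cv, mask = rl$mask)
    }
    for (j in seq_len(cfg$n_residual_blocks)) {
      c1 <- conv2d_f(t, p[[sprintf("enc%d_res%d_W1", e, j)]],
                     p[[sprintf("enc%d_res%d_b1", e, j)]])
      r1 <- relu_f(c1$out)
      c2 <- conv2d_f(r1$out, p[[sprintf("enc%d_res%d_W2", e, j)]],
                     p[[sprintf("enc%d_res%d_b2", e, j)]])
      tnew <- t + c2$out
      if (want_cache) cache[[sprintf("e%dr%d", e, j)]] <-
          list(c1 = c1, m1 = r1$mask, c2 = c2)
      t <- tnew
    }
    cv <- conv2d_f(t, p[[sprintf("enc%d_pool_W", e)]],
                   p[[sprintf("enc%d_pool_b", e)]], stride = 2L)
    rl <- relu_f(cv$out)
    if (want_cache) cache[[sprintf("e%dpool", e)]] <-
        list(conv = cv, mask = rl$mask)
    feats[[e]] <- rl$out
  }
  f0 <- c(as.numeric(feats[[1]]), as.numeric(feats[[2]]))
  d1 <- dense_f(f0, p$fus1_W, p$fus1_b)
  r1 <- relu_f(d1$out)
  d2 <- dense_f(r1$out, p$fus2_W, p$fus2_b)
  r2 <- relu_f(d2$out)
  g <- array(r2$out, c(model$coarse, model$dec_channels[1]))
  if (want_cache) cache$fusion <-
      list(d1 = d1, m1 = r1$mask, d2 = d2, m2 = r2$mask,
           feat_dim = dim(feats[[1]]))
  for (i in 1:3) {
    z <- zstuff3_f(g)
    cv <- conv3d_f(z, p[[sprintf("dec%d_W", i)]], p[[sprintf("dec%d_b", i)]])
    if (i < 3) {
      rl <- relu_f(cv$out)
      if (want_cache) cache[[sprintf("dec%d", i)]] <-
          list(conv = cv, mask = rl$mask, z_in = dim(g))
      g <- rl$out
    } else {
      if (want_cache) cache[[sprintf("dec%d", i)]] <-
          list(conv = cv, z_in = dim(g))
      g <- cv$out
    }
  }
  out <- array(g, cfg$output_shape)
  list(out = out, cache = cache)
}

net_backward <- function(model, cache, dout) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  g <- array(dout, c(cfg$output_shape, 1L))
  for (i in 3:1) {
    cc <- cache[[sprintf("dec%d", i)]]
    if (i < 3) g <- relu_b(g, cc$mask)
    bk <- conv3d_b(g, p[[sprintf("dec%d_W", i)]], cc$conv)
    grads[[sprintf("dec%d_W", i)]] <- bk$dW
    grads[[sprintf("dec%d_b", i)]] <- bk$db
    g <- zstuff3_b(bk$dx, cc$z_in)
  }
  fu <- cache$fusion
  dg <- relu_b(as.numeric(g), fu$m2)
  bk2 <- dense_b(dg, p$fus2_W, fu$d2)
  grads$fus2_W <- bk2$dW; grads$fus2_b <- bk2$db
  dr <- relu_b(bk2$dx, fu$m1)
  bk1 <- dense_b(dr, p$fus1_W, fu$d1)
  grads$fus1_W <- bk1$dW; grads$fus1_b <- bk1$db
  nfeat <- prod(fu$feat_dim)
  dfeats <- list(array(bk1$dx[seq_len(nfeat)], fu$feat_dim),
                 array(bk1$dx[nfeat + seq_len(nfeat)], fu$feat_dim))
  for (e in 1:2) {
    cc <- cache[[sprintf("e%dpool", e)]]
    g <- relu_b(dfeats[[e]], cc$mask)
    bk <- conv2d_b(g, p[[sprintf("enc%d_pool_W", e)]], cc$conv)
    grads[[sprintf("enc%d_pool_W", e)]] <- bk$dW
    grads[[sprintf("enc%d_pool_b", e)]] <- bk$db
    g <- bk$dx
    for (j in rev(seq_len(cfg$n_residual_blocks))) {
      cc <- cache[[sprintf("e%dr%d", e, j)]]
      bk2c <- conv2d_b(g, p[[sprintf("enc%d_res%d_W2", e, j)]], cc$c2)
      grads[[sprintf("enc%d_res%d_W2", e, j)]] <- bk2c$dW
      grads[[sprintf("enc%d_res%d_b2", e, j)]] <- bk2c$db
      dh <- relu_b(bk2c$dx, cc$m1)
      bk1c <- conv2d_b(dh, p[[sprintf("enc%d_res%d_W1", e, j)]], cc$c1)
      grads[[sprintf("enc%d_res%d_W1", e, j)]] <- bk1c$dW
      grads[[sprintf("enc%d_res%d_b1", e, j)]] <- bk1c$db
      g <- g + bk1c$dx  # skip connection
    }
    for (i in rev(seq_len(model$plan$n_down))) {
      cc <- cache[[sprintf("e%dd%d", e, i)]]
      g <- relu_b(g, cc$mask)
      bk <- conv2d_b(g, p[[sprintf("enc%d_down%d_W", e, i)]], cc$conv)
      grads[[sprintf("enc%d_down%d_W", e, i)]] <- bk$dW
      grads[[sprintf("enc%d_down%d_b", e, i)]] <- bk$db
      g <- bk$dx
    }
    # input gradient discarded (projections are data, not parameters)
  }
  grads
}

#' Composite reconstruction loss
#'
#' Mean absolute error plus a weighted gradient (edge) term:
#' `mean(|pred - ref|) + w * mean_a(mean(|D_a pred - D_a ref|))` where `D_a`
#' is the forward finite difference along axis `a` and the outer mean runs
#' over the axes of length at least 2.
#'
#' @param pred,ref numeric arrays of identical shape.
#' @param w gradient-loss weight (>= 0).
#' @return non-negative scalar loss.
#' @export
composite_loss <- function(pred, ref, w = 1.0) {
  composite_loss_grad(pred, ref, w, want_grad = FALSE)$loss
}

composite_loss_grad <- function(pred, ref, w, want_grad = TRUE) {
  if (inherits(pred, "ct_volume")) pred <- pred$data
  if (inherits(ref, "ct_volume")) ref <- ref$data
  pred <- as.array(pred); ref <- as.array(ref)
  if (!identical(dim(pred), dim(ref))) stop("`pred` and `ref` shapes differ")
  if (length(dim(pred)) != 3L) stop("`pred` and `ref` must be 3D volumes")
  res <- .loss_grad(pred, ref, dim(pred), w, want_grad)
  list(loss = res$loss, grad = if (want_grad) res$grad else NULL)
}

#' Preprocess a projection pair for the network
#'
#' Bilinearly resamples each projection to the square network input grid and
#' scales it to `[0, 1]` by its own maximum.
#'
#' @param pair a [acquire_pair()] result.
#' @param config a [network_config()].
#' @return `input_size x input_size x 2` array.
#' @export
preprocess_pair <- function(pair, config) {
  stopifnot(inherits(pair, "projection_pair"))
  one <- function(m) {
    r <- resample_bilinear(m, config$input_size, config$input_size)
    mx <- max(r)
    if (mx > 0) r / mx else r
  }
  out <- array(0, c(config$input_size, config$input_size, 2L))
  out[, , 1] <- one(pair$proj_a)
  out[, , 2] <- one(pair$proj_b)
  out
}

#' Plan a leave-phase-out cross-validation campaign
#'
#' Enumerates every training run of a leave-phase-out protocol: one model
#' variant per (subject, held-out phase), trained on the remaining phases.
#'
#' @param n_subjects number of subjects.
#' @param n_phases respiratory phases per subject.
#' @return data frame with one row per planned training run: `subject`,
#'   `held_out_phase` (0-based) and the comma-separated `training_phases`.
#' @export
plan_leave_phase_out <- function(n_subjects, n_phases = 10L) {
  if (n_subjects < 1L || n_phases < 2L)
    stop("need >= 1 subject and >= 2 phases")
  grid <- expand.grid(held_out_phase = seq_len(n_phases) - 1L,
                      subject = seq_len(n_subjects))
  grid <- grid[, c("subject", "held_out_phase")]
  grid$training_phases <- vapply(grid$held_out_phase, function(h)
    paste(setdiff(seq_len(n_phases) - 1L, h), collapse = ","), character(1))
  grid
}

#' Leave-phase-out patient-specific training
#'
#' Trains one model variant per respiratory phase, each on the projection
#' pairs and reference volumes of all other phases, so every phase is
#' reconstructed by a model that never saw it. Training (weight
#' initialization, batch order, Adam) is fully determined by the config seed
#' and the fold index.
#'
#' @param data a [ct4d()] of reference phase volumes.
#' @param pairs list of [acquire_pair()] results, one per phase, all from the
#'   same source-angle pair.
#' @param config a [network_config()]; `output_shape` must match the data
#'   grid.
#' @param verbose print per-fold progress.
#' @return list of `trained_variant` objects (model, `held_out_phase`
#'   0-based, `angle_pair`, per-epoch `training_log`, `training_phases`).
#' @export
train_leave_phase_out <- function(data, pairs, config = network_config(),
                                  verbose = FALSE) {
  stopifnot(inherits(data, "ct4d"), inherits(config, "network_config"))
  np <- data$n_phases
  if (np < 2L) stop("leave-phase-out needs at least 2 phases")
  if (length(pairs) != np) stop("need exactly one projection pair per phase")
  ap <- pairs[[1]]$angle_pair
  for (pr in pairs) {
    if (!inherits(pr, "projection_pair")) stop("`pairs` must hold projection_pair")
    if (!isTRUE(all.equal(pr$angle_pair, ap)))
      stop("all projection pairs must share one source-angle pair")
  }
  if (!identical(dim(data$phases[[1]]$data), as.integer(config$output_shape)))
    stop("`config$output_shape` must equal the reference grid shape")

  inputs <- lapply(pairs, preprocess_pair, config = config)
  targets <- lapply(data$phases, function(v)
    normalize_hu(v$data, config$intensity_window))

  variants <- vector("list", np)
  for (fold in seq_len(np)) {
    train_idx <- setdiff(seq_len(np), fold)
    fold_seed <- (config$seed + 7919L * fold) %% .Machine$integer.max
    cfg_fold <- config
    cfg_fold$seed <- fold_seed
    model <- build_model(cfg_fold)
    state <- adam_init(model$params)
    log_loss <- numeric(config$epochs)
    batches_seen <- integer(0)
    with_seed(fold_seed + 1L, {
      for (ep in seq_len(config$epochs)) {
        ord <- train_idx[sample.int(length(train_idx))]
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        ep_loss <- 0
        for (bt in batches) {
          gacc <- NULL
          bl <- 0
          for (s in bt) {
            fw <- net_forward(model, inputs[[s]])
            lg <- composite_loss_grad(fw$out, targets[[s]],
                                      config$gradient_loss_weight)
            bl <- bl + lg$loss
            gs <- net_backward(model, fw$cache, lg$grad)
            if (is.null(gacc)) gacc <- gs else grads_add_inplace(gacc, gs)
          }
          grads_scale_inplace(gacc, 1 / length(bt))
          state <- adam_step(model$params, gacc, state, config$learning_rate)
          ep_loss <- ep_loss + bl
          batches_seen <- c(batches_seen, bt)
        }
        log_loss[ep] <- ep_loss / length(train_idx)
      }
    })
    if (fold %in% batches_seen)
      stop("fold hygiene violation: held-out phase appeared in training")
    variants[[fold]] <- structure(
      list(model = model, held_out_phase = fold - 1L, angle_pair = ap,
           training_log = data.frame(epoch = seq_len(config$epochs),
                                     loss = log_loss),
           training_phases = train_idx - 1L,
           ref_spacing = data$spacing,
           ref_origin = data$phases[[1]]$origin),
      class = "trained_variant")
    if (verbose)
      message(sprintf("fold %d/%d: loss %.4f -> %.4f", fold, np,
                      log_loss[1], log_loss[config$epochs]))
  }
  variants
}

#' @export
print.trained_variant <- function(x, ...) {
  cat(sprintf(
    "<trained_variant> held-out phase %d, angles %s, final loss %.4f\n",
    x$held_out_phase, angle_pair_label(x$angle_pair),
    x$training_log$loss[nrow(x$training_log)]))
  invisible(x)
}

#' Reconstruct a volume from an orthogonal projection pair
#'
#' Runs the trained model on a (preprocessed) projection pair and
#' de-normalizes the output to HU on the reference grid. Inference is
#' deterministic: repeated calls on the same inputs are bit-identical.
#'
#' @param variant a `trained_variant` from [train_leave_phase_out()].
#' @param pair a [acquire_pair()] result.
#' @param allow_pair_mismatch proceed (with a warning) when the pair's source
#'   angles differ from the variant's training angles.
#' @return a [ct_volume()] in HU.
#' @export
infer <- function(variant, pair, allow_pair_mismatch = FALSE) {
  stopifnot(inherits(variant, "trained_variant"),
            inherits(pair, "projection_pair"))
  if (!isTRUE(all.equal(pair$angle_pair, variant$angle_pair))) {
    msg <- sprintf("projection pair %s does not match the variant's %s",
                   angle_pair_label(pair$angle_pair),
                   angle_pair_label(variant$angle_pair))
    if (allow_pair_mismatch) warning(msg) else stop(msg)
  }
  cfg <- variant$model$config
  input <- preprocess_pair(pair, cfg)
  fw <- net_forward(variant$model, input, want_cache = FALSE)
  ct_volume(denormalize_hu(fw$out, cfg$intensity_window),
            spacing = variant$ref_spacing, origin = variant$ref_origin)
}

#' Save / load a trained variant
#'
#' The weights go to an RDS checkpoint and a human-readable JSON manifest
#' (config, held-out phase, angle pair, final loss) is written alongside;
#' the training curve goes to CSV.
#'
#' @param variant a `trained_variant`.
#' @param path checkpoint path (`.rds`); the manifest is `<path>.json` and
#'   the training curve `<path>_log.csv`.
#' @return `save_variant` returns `path` invisibly; `load_variant` the
#'   variant.
#' @export
save_variant <- function(variant, path) {
  stopifnot(inherits(variant, "trained_variant"))
  saveRDS(variant, path)
  manifest <- list(held_out_phase = variant$held_out_phase,
                   angle_pair = variant$angle_pair,
                   training_phases = variant$training_phases,
                   final_loss = variant$training_log$loss[nrow(variant$training_log)],
                   config = unclass(variant$model$config))
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(variant$training_log, paste0(path, "_log.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_variant
#' @export
load_variant <- function(path) readRDS(path)
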