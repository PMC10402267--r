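# Shared desk-scale fixtures. Everything is generated in code; no files.

# coarse phantom for fast structural tests (full 256 x 256 x 192 mm field)
tiny_phantom_config <- function(...) {
  defaults <- list(grid_shape = c(16L, 16L, 16L),
                   spacing = c(16, 16, 12),
                   noise_sd = 0)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# small panel that covers the default phantom field of view
small_geometry <- function(n = 64L, pitch = 6) {
  projection_geometry(0, panel_rows = n, panel_cols = n, pixel_pitch = pitch)
}

# minimal trainable network for contract tests
tiny_network_config <- function(...) {
  defaults <- list(base_channels = 2L, n_residual_blocks = 1L,
                   input_size = 16L, fusion_dim = 8L,
                   output_shape = c(16L, 16L, 16L),
                   epochs = 2L, batch_size = 2L, seed = 11L)
  do.call(network_config, utils::modifyList(defaults, list(...)))
}

# uniform-HU volume centered on the world origin
uniform_volume <- function(hu, shape = c(8L, 8L, 8L), spacing = c(4, 4, 4)) {
  ct_volume(array(hu, shape), spacing)
}

# naive windowed SSIM, averaged over full-window centers (independent oracle)
brute_force_ssim <- function(x, y, params, mask = NULL) {
  r <- (params$window_size - 1L) / 2L
  w1 <- flashigrt:::ssim_window_weights(params)
  w3 <- outer(outer(w1, w1), w1)
  L <- params$dynamic_range
  if (is.null(L)) L <- diff(range(if (is.null(mask)) y else y[mask]))
  if (L <= 0) L <- 1
  c1 <- (params$k1 * L)^2; c2 <- (params$k2 * L)^2
  d <- dim(x)
  vals <- c(); keep <- c()
  for (i in (r + 1):(d[1] - r)) for (j in (r + 1):(d[2] - r))
    for (k in (r + 1):(d[3] - r)) {
      if (!is.null(mask) && !mask[i, j, k]) next
      wx <- x[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      wy <- y[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      mx <- sum(w3 * wx); my <- sum(w3 * wy)
      vx <- sum(w3 * wx^2) - mx^2; vy <- sum(w3 * wy^2) - my^2
      cxy <- sum(w3 * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                        ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  mean(vals)
}
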