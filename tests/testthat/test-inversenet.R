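test_that("network config validates its structural constraints", {
  expect_error(network_config(n_residual_blocks = 0), "n_residual_blocks")
  expect_error(network_config(kernel_size = 4), "odd")
  expect_error(network_config(input_size = 20), "input_size")
  expect_error(network_config(output_shape = c(60, 64, 48)), "divisible by 8")
  expect_error(network_config(intensity_window = c(600, -1000)), "increasing")
  expect_error(network_config(gradient_loss_weight = -1), "gradient_loss_weight")
})

test_that("HU normalization round-trips exactly over the window", {
  w <- c(-1000, 600)
  hu <- seq(-1000, 600, by = 7.3)
  expect_equal(denormalize_hu(normalize_hu(hu, w), w), hu, tolerance = 1e-9)
  expect_equal(normalize_hu(-1000, w), -1)
  expect_equal(normalize_hu(600, w), 1)
  expect_lt(max(abs(denormalize_hu(normalize_hu(hu, w), w) - hu)), 0.5)
})

test_that("forward pass maps any projection pair to a finite reference-shaped volume", {
  cfg <- tiny_network_config()
  m <- build_model(cfg)
  zed <- array(0, c(cfg$input_size, cfg$input_size, 2))
  out <- flashigrt:::net_forward(m, zed, want_cache = FALSE)$out
  expect_identical(dim(out), cfg$output_shape)
  expect_true(all(is.finite(out)))
})

test_that("a residual block with zero weights is the identity map", {
  k <- 3L; ch <- 4L
  W0 <- array(0, c(k, k, ch, ch)); b0 <- numeric(ch)
  x <- array(rnorm(8 * 8 * ch), c(8, 8, ch))
  c1 <- flashigrt:::conv2d_f(x, W0, b0)
  r1 <- flashigrt:::relu_f(c1$out)
  c2 <- flashigrt:::conv2d_f(r1$out, W0, b0)
  expect_equal(x + c2$out, x)
})

test_that("parameter count grows strictly with residual depth", {
  counts <- vapply(1:3, function(n)
    n_parameters(build_model(tiny_network_config(n_residual_blocks = n))),
    numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("composite loss combines MAE and forward-difference edge terms", {
  ref <- array(rnorm(4^3), c(4, 4, 4))
  expect_equal(composite_loss(ref, ref, 1), 0)
  # constant shifts have zero gradient term
  expect_equal(composite_loss(ref + 3, ref, 1), 3, tolerance = 1e-12)
  expect_equal(composite_loss(ref - 0.5, ref, 5), 0.5, tolerance = 1e-12)
  # hand-computed 2x1x1 toy: MAE 1 plus edge difference 2
  expect_equal(composite_loss(array(c(0, 2), c(2, 1, 1)),
                              array(0, c(2, 1, 1)), 1), 3)
  # weight scales only the edge term
  p <- array(c(0, 2), c(2, 1, 1)); r <- array(0, c(2, 1, 1))
  expect_equal(composite_loss(p, r, 0.5), 1 + 0.5 * 2)
  expect_error(composite_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 1))),
               "shapes differ")
})

test_that("backpropagation matches central finite differences", {
  cfg <- network_config(base_channels = 2L, n_residual_blocks = 1L,
                        input_size = 16L, fusion_dim = 4L,
                        output_shape = c(8L, 8L, 8L), seed = 3L)
  m <- build_model(cfg)
  set.seed(1)
  inp <- array(runif(16 * 16 * 2), c(16, 16, 2))
  ref <- array(runif(8^3, -1, 1), c(8, 8, 8))
  fw <- flashigrt:::net_forward(m, inp)
  lg <- flashigrt:::composite_loss_grad(fw$out, ref, 1)
  gr <- flashigrt:::net_backward(m, fw$cache, lg$grad)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (ii in sample(length(p), min(2, length(p)))) {
      m2 <- m; m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      l2 <- composite_loss(flashigrt:::net_forward(m2, inp, FALSE)$out, ref, 1)
      m3 <- m; m3$params[[nm]][ii] <- m3$params[[nm]][ii] - eps
      l3 <- composite_loss(flashigrt:::net_forward(m3, inp, FALSE)$out, ref, 1)
      num <- (l2 - l3) / (2 * eps)
      # tolerance reflects the kinks of the L1 objective
      expect_lt(abs(num - gr[[nm]][ii]) / max(1e-8, abs(num), abs(gr[[nm]][ii])),
                5e-3)
    }
  }
})

test_that("leave-phase-out planning enumerates subjects times phases", {
  plan <- plan_leave_phase_out(30, 10)
  expect_equal(nrow(plan), 300)
  expect_equal(unname(table(plan$subject)), rep(10L, 30L),
               ignore_attr = TRUE)
  # held-out phase never appears in its own training list
  for (i in seq_len(nrow(plan))) {
    tr <- as.integer(strsplit(plan$training_phases[i], ",")[[1]])
    expect_length(tr, 9L)
    expect_false(plan$held_out_phase[i] %in% tr)
  }
  expect_error(plan_leave_phase_out(0, 10), "subject")
})

test_that("leave-phase-out training yields one hygienic variant per phase", {
  cfg4 <- tiny_phantom_config()
  ph <- make_thorax_phantom(cfg4)
  geom <- small_geometry(16, 24)
  pairs <- lapply(ph$phases, acquire_pair, angle_pair = c(135, 225),
                  geom_template = geom)
  ncfg <- tiny_network_config(epochs = 2L)
  vars <- train_leave_phase_out(ph, pairs, ncfg)
  expect_length(vars, 10L)
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    expect_identical(v$held_out_phase, k - 1L)
    expect_false(v$held_out_phase %in% v$training_phases)
    expect_length(v$training_phases, 9L)
    expect_equal(nrow(v$training_log), ncfg$epochs)
  }
})

test_that("two-phase input trains two variants on one phase each", {
  cfg4 <- tiny_phantom_config(n_phases = 2L)
  ph <- make_thorax_phantom(cfg4)
  geom <- small_geometry(16, 24)
  pairs <- lapply(ph$phases, acquire_pair, angle_pair = c(135, 225),
                  geom_template = geom)
  vars <- train_leave_phase_out(ph, pairs, tiny_network_config(epochs = 1L))
  expect_length(vars, 2L)
  expect_identical(vars[[1]]$training_phases, 1L)
  expect_identical(vars[[2]]$training_phases, 0L)
})

test_that("inference is deterministic and guards the angle pair", {
  cfg4 <- tiny_phantom_config(n_phases = 2L)
  ph <- make_thorax_phantom(cfg4)
  geom <- small_geometry(16, 24)
  pairs <- lapply(ph$phases, acquire_pair, angle_pair = c(135, 225),
                  geom_template = geom)
  vars <- train_leave_phase_out(ph, pairs, tiny_network_config(epochs = 1L))
  a <- infer(vars[[1]], pairs[[1]])
  b <- infer(vars[[1]], pairs[[1]])
  expect_identical(a$data, b$data)
  expect_identical(dim(a$data), dim(ph$phases[[1]]$data))
  other <- acquire_pair(ph$phases[[1]], c(180, 270), geom)
  expect_error(infer(vars[[1]], other), "does not match")
  expect_warning(infer(vars[[1]], other, allow_pair_mismatch = TRUE),
                 "does not match")
})

test_that("training is reproducible from the config seed", {
  cfg4 <- tiny_phantom_config(n_phases = 2L)
  ph <- make_thorax_phantom(cfg4)
  geom <- small_geometry(16, 24)
  pairs <- lapply(ph$phases, acquire_pair, angle_pair = c(135, 225),
                  geom_template = geom)
  ncfg <- tiny_network_config(epochs = 2L)
  v1 <- train_leave_phase_out(ph, pairs, ncfg)
  v2 <- train_leave_phase_out(ph, pairs, ncfg)
  expect_identical(v1[[1]]$model$params, v2[[1]]$model$params)
  expect_identical(v1[[1]]$training_log, v2[[1]]$training_log)
})

test_that("variants round-trip through checkpoints with manifests", {
  cfg4 <- tiny_phantom_config(n_phases = 2L)
  ph <- make_thorax_phantom(cfg4)
  geom <- small_geometry(16, 24)
  pairs <- lapply(ph$phases, acquire_pair, angle_pair = c(135, 225),
                  geom_template = geom)
  v <- train_leave_phase_out(ph, pairs, tiny_network_config(epochs = 1L))[[1]]
  path <- tempfile(fileext = ".rds")
  save_variant(v, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, "_log.csv")))
  back <- load_variant(path)
  expect_identical(back$model$params, v$model$params)
  man <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(man$held_out_phase, 0L)
})

test_that("projection preprocessing lands on the network grid in [0, 1]", {
  pairlike <- structure(list(proj_a = matrix(runif(32 * 48, 0, 200), 32),
                             proj_b = matrix(0, 32, 48),
                             angle_pair = c(135, 225)),
                        class = "projection_pair")
  cfg <- tiny_network_config()
  x <- preprocess_pair(pairlike, cfg)
  expect_identical(dim(x), c(16L, 16L, 2L))
  expect_gte(min(x), 0)
  expect_lte(max(x), 1)
  expect_equal(max(x[, , 1]), 1)   # scaled by its own maximum
  expect_equal(max(x[, , 2]), 0)   # empty projection stays zero
})
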