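test_that("ME and MAE follow their defining sums", {
  dl <- array(c(0, 10, -10), c(3, 1, 1))
  ref <- array(0, c(3, 1, 1))
  expect_equal(mean_error(dl, ref), 0)
  expect_equal(mean_absolute_error(dl, ref), 20 / 3)
  expect_equal(mean_error(ref, ref), 0)
  expect_equal(mean_error(ref + 10, ref), 10)
  # symmetry of MAE, antisymmetry of ME
  expect_equal(mean_absolute_error(dl, ref), mean_absolute_error(ref, dl))
  expect_equal(mean_error(dl, ref), -mean_error(ref, dl))
})

test_that("MAE dominates |ME| on random volume pairs", {
  for (s in 1:100) {
    set.seed(s)
    dl <- array(rnorm(4^3, 0, 50), c(4, 4, 4))
    ref <- array(rnorm(4^3, 0, 50), c(4, 4, 4))
    expect_gte(mean_absolute_error(dl, ref), abs(mean_error(dl, ref)))
  }
})

test_that("PSNR matches the constant-offset closed form", {
  ref <- array(runif(6^3, 0, 200), c(6, 6, 6))
  ref[1] <- 200  # pin the reference peak
  for (c_off in c(0.5, 2, 8)) {
    expect_equal(psnr(ref + c_off, ref), 10 * log10(200^2 / c_off^2),
                 tolerance = 1e-12)
  }
  expect_equal(psnr(ref + 2, ref), 40, tolerance = 1e-12)
  # strictly decreasing in the offset magnitude
  offs <- c(1, 2, 4, 8, 16)
  vals <- vapply(offs, function(o) psnr(ref + o, ref), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("identical volumes give the infinite-PSNR sentinel", {
  ref <- array(runif(5^3, -500, 500), c(5, 5, 5))
  expect_identical(psnr(ref, ref), Inf)
})

test_that("masked voxelwise metrics equal explicit loops on small toys", {
  set.seed(31)
  dl <- array(rnorm(8^3, 0, 100), c(8, 8, 8))
  ref <- array(rnorm(8^3, 0, 100), c(8, 8, 8))
  mask <- array(runif(8^3) < 0.4, c(8, 8, 8))
  me_loop <- 0; mae_loop <- 0; mse_loop <- 0; n <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) if (mask[i, j, k]) {
    d <- dl[i, j, k] - ref[i, j, k]
    me_loop <- me_loop + d; mae_loop <- mae_loop + abs(d)
    mse_loop <- mse_loop + d^2; n <- n + 1
  }
  expect_equal(mean_error(dl, ref, mask), me_loop / n, tolerance = 1e-12)
  expect_equal(mean_absolute_error(dl, ref, mask), mae_loop / n,
               tolerance = 1e-12)
  expect_equal(psnr(dl, ref, mask),
               10 * log10(max(ref[mask])^2 / (mse_loop / n)),
               tolerance = 1e-12)
})

test_that("SSIM is exactly 1 for identical volumes and matches brute force", {
  set.seed(5)
  x <- array(runif(8^3), c(8, 8, 8))
  y <- x + array(rnorm(8^3, 0, 0.1), c(8, 8, 8))
  prm <- ssim_params(window_size = 3L, sigma = 1.0)
  expect_equal(ssim(x, x, params = prm), 1)
  expect_equal(ssim(x, y, params = prm), brute_force_ssim(x, y, prm),
               tolerance = 1e-8)
  prm_u <- ssim_params(window_size = 3L, window = "uniform")
  expect_equal(ssim(x, y, params = prm_u), brute_force_ssim(x, y, prm_u),
               tolerance = 1e-8)
  # masked path agrees with the brute-force masked average
  mask <- array(FALSE, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- TRUE
  expect_equal(ssim(x, y, mask, params = prm),
               brute_force_ssim(x, y, prm, mask), tolerance = 1e-8)
})

test_that("affine distortion lowers SSIM below 1", {
  set.seed(8)
  x <- array(runif(10^3), c(10, 10, 10))
  prm <- ssim_params(window_size = 5L)
  expect_lt(ssim(1.5 * x + 0.2, x, params = prm), 1)
})

test_that("full-volume mask reproduces the unmasked SSIM", {
  set.seed(9)
  x <- array(runif(9^3), c(9, 9, 9))
  y <- array(runif(9^3), c(9, 9, 9))
  prm <- ssim_params(window_size = 3L, dynamic_range = 1)
  expect_equal(ssim(x, y, mask = array(TRUE, c(9, 9, 9)), params = prm),
               ssim(x, y, params = prm), tolerance = 1e-12)
  expect_error(ssim(x[1:2, 1:2, 1:2, drop = FALSE] -> xx, xx, params = prm),
               "smaller than the SSIM window")
})

test_that("voxelwise metrics are permutation-invariant; SSIM need not be", {
  set.seed(12)
  dl <- array(rnorm(6^3), c(6, 6, 6))
  ref <- array(rnorm(6^3), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.5, c(6, 6, 6))
  perm <- sample(6^3)
  pdl <- array(dl[perm], c(6, 6, 6))
  pref <- array(ref[perm], c(6, 6, 6))
  pmask <- array(mask[perm], c(6, 6, 6))
  expect_equal(mean_error(pdl, pref, pmask), mean_error(dl, ref, mask))
  expect_equal(mean_absolute_error(pdl, pref, pmask),
               mean_absolute_error(dl, ref, mask))
  expect_equal(psnr(pdl, pref, pmask), psnr(dl, ref, mask))
})

test_that("CT-number histograms conserve in-range voxels", {
  v <- uniform_volume(0, c(4, 4, 4))
  h <- ct_histogram(v, bins = 10, range = c(-500, 500))
  expect_s3_class(h, "ct_histogram")
  expect_equal(sum(h$counts), 64)
  expect_equal(h$counts[6], 64L)  # bin containing 0 HU
  # out-of-range voxels are dropped
  h2 <- ct_histogram(c(-2000, 0, 2000), bins = 4, range = c(-1000, 1000))
  expect_equal(sum(h2$counts), 1L)
  expect_error(ct_histogram(v, range = c(10, -10)), "increasing")
  expect_error(ct_histogram(v, bins = 0), "bins")
})

test_that("phantom histogram recovers per-material voxel counts", {
  cfg <- phantom_config(noise_sd = 0)
  ph <- make_thorax_phantom(cfg)
  vol <- ph$phases[[1]]
  h <- ct_histogram(vol, bins = 400, range = c(-1000, 1000))
  find_count <- function(hu) h$counts[findInterval(hu, h$breaks,
                                                   rightmost.closed = TRUE)]
  expect_equal(find_count(cfg$lung_hu), sum(vol$data == cfg$lung_hu))
  expect_equal(find_count(cfg$spine_hu), sum(vol$data == cfg$spine_hu))
})

test_that("percent ME restates HU offsets as attenuation percentages", {
  expect_equal(percent_me(0), 0)
  expect_equal(percent_me(-3.3), -0.33)
  expect_equal(percent_me(-15.5), -1.55)
  expect_error(percent_me(Inf), "finite")
})
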