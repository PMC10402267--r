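test_that("HLUT validation pins water and enforces monotonicity", {
  t <- hlut(c(-1000, 0, 1000, 3000), c(0.001, 1, 1.55, 2.4))
  expect_s3_class(t, "hlut")
  expect_error(hlut(c(0, -10), c(1, 2)), "strictly increasing")
  expect_error(hlut(c(-100, 0, 100), c(1.2, 1, 1.5)), "non-decreasing")
  expect_error(hlut(c(-100, 100), c(0.9, 1.1)), "water breakpoint")
  expect_error(hlut(numeric(0), numeric(0)), "empty")
})

test_that("RSP interpolation is exact at breakpoints and linear between", {
  t <- read_hlut()  # packaged default table
  expect_equal(hu_to_rsp(0, t), 1)
  expect_equal(hu_to_rsp(t$hu, t), t$rsp)
  expect_equal(hu_to_rsp(500, t), 1.275)
  # clamped outside the table
  expect_equal(hu_to_rsp(-5000, t), t$rsp[1])
  expect_equal(hu_to_rsp(9000, t), t$rsp[length(t$rsp)])
})

test_that("HLUT round-trips through CSV", {
  t <- hlut(c(-1000, -200, 0, 2000), c(0.001, 0.8, 1, 1.9))
  path <- tempfile(fileext = ".csv")
  write_hlut(t, path)
  expect_equal(unclass(read_hlut(path)), unclass(t))
})

test_that("WET in uniform slabs equals the analytic RSP-weighted depth", {
  t <- read_hlut()
  # water: voxel centered 58 mm behind the anterior boundary
  vol <- ct_volume(array(0, c(8, 30, 8)), c(4, 4, 4))
  roi <- array(FALSE, c(8, 30, 8)); roi[4, 15, 4] <- TRUE
  expect_equal(wet_map(vol, t, roi)$values, 14.5 * 4, tolerance = 1e-9)
  # air: scaled by its tiny stopping power
  vol_air <- ct_volume(array(-1000, c(8, 30, 8)), c(4, 4, 4))
  expect_equal(wet_map(vol_air, t, roi)$values, 0.001 * 14.5 * 4,
               tolerance = 1e-9)
  # layered slabs: sum of RSP * thickness, exactly
  arr <- array(0, c(4, 12, 4))
  arr[, 1:4, ] <- -1000; arr[, 5:8, ] <- 0; arr[, 9:12, ] <- 1000
  vol3 <- ct_volume(arr, c(5, 5, 5))
  roi3 <- array(FALSE, c(4, 12, 4)); roi3[2, 10, 2] <- TRUE
  expected <- 0.001 * 20 + 1 * 20 + 1.55 * 5 + 1.55 * 2.5
  expect_equal(wet_map(vol3, t, roi3)$values, expected, tolerance = 1e-6)
})

test_that("doubling a material's RSP doubles WET through it", {
  base <- hlut(c(-1000, 0, 1000), c(0.001, 1, 1.2))
  doubled <- hlut(c(-1000, 0, 1000), c(0.001, 1, 2.4))
  arr <- array(1000, c(4, 10, 4))
  vol <- ct_volume(arr, c(4, 4, 4))
  roi <- array(FALSE, dim(arr)); roi[2, 8, 2] <- TRUE
  w1 <- wet_map(vol, base, roi)$values
  w2 <- wet_map(vol, doubled, roi)$values
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
})

test_that("WET is non-decreasing with depth along each beam column", {
  set.seed(21)
  arr <- array(runif(6 * 20 * 4, -1000, 2000), c(6, 20, 4))
  vol <- ct_volume(arr, c(4, 3, 4))
  roi <- array(TRUE, dim(arr))
  wm <- wet_map(vol, read_hlut(), roi)
  w <- array(0, dim(arr)); w[roi] <- wm$values
  for (i in 1:6) for (k in 1:4)
    expect_true(all(diff(w[i, , k]) >= -1e-12))
})

test_that("exact traversal matches fine fixed-step integration", {
  t <- read_hlut()
  for (s in 1:20) {
    set.seed(100 + s)
    d <- c(4L, sample(8:16, 1), 3L)
    sp <- c(4, runif(1, 2, 5), 4)
    arr <- array(runif(prod(d), -1000, 2000), d)
    vol <- ct_volume(arr, sp)
    roi <- array(FALSE, d)
    j_roi <- sample(3:d[2], 1)
    roi[2, j_roi, 2] <- TRUE
    wm <- wet_map(vol, t, roi)
    # midpoint-rule numerical oracle at step = beam-axis spacing / 20
    h <- sp[2] / 20
    depth <- (j_roi - 0.5) * sp[2]
    nseg <- round(depth / h)
    pts <- (seq_len(nseg) - 0.5) * h
    rsp_at <- hu_to_rsp(arr[2, pmin(floor(pts / sp[2]) + 1, d[2]), 2], t)
    oracle <- sum(rsp_at * h)
    expect_lt(abs(wm$values - oracle) / oracle, 0.005)
  }
})

test_that("Gaussian histogram fit recovers known moments", {
  set.seed(17)
  v <- rnorm(10000, 50, 2)
  f <- fit_gaussian(v)
  expect_identical(f$flag, "ok")
  expect_lt(abs(f$mean - 50), 0.1)
  expect_lt(abs(f$sd - 2), 0.1)
  # fit and raw moments agree for unimodal data
  expect_lt(abs(f$mean - mean(v)) / mean(v), 0.02)
  expect_lt(abs(f$sd - sd(v)) / sd(v), 0.02)
})

test_that("degenerate WET distributions are flagged", {
  f <- fit_gaussian(rep(30, 10))
  expect_identical(f$flag, "degenerate")
  expect_equal(f$mean, 30)
  expect_equal(f$sd, 0)
  expect_error(fit_gaussian(c(1, 2)), "at least 3")
})

test_that("delta and epsilon WET follow their defining ratios", {
  vol <- ct_volume(array(0, c(4, 16, 4)), c(4, 4, 4))
  roi <- array(FALSE, c(4, 16, 4)); roi[2, 13, 2] <- TRUE; roi[3, 13, 3] <- TRUE
  t <- read_hlut()
  ref <- wet_map(vol, t, roi)
  dl <- ref
  expect_equal(delta_wet(dl, ref), 0)
  expect_equal(epsilon_wet(dl, ref), 0)
  dl2 <- ref; dl2$values <- ref$values + 2
  expect_equal(delta_wet(dl2, ref), 2)
  dl3 <- ref; dl3$values <- ref$values + c(1, -3)
  expect_equal(delta_wet(dl3, ref), -1)
  # epsilon: -1 mm over a 50 mm mean is -2%
  ref50 <- ref; ref50$values <- c(50, 50)
  dl50 <- ref50; dl50$values <- c(49, 49)
  expect_equal(epsilon_wet(dl50, ref50), -2)
  dl105 <- ref; dl105$values <- 1.05 * ref$values
  expect_equal(epsilon_wet(dl105, ref), 5, tolerance = 1e-9)
  # uniform HU inflation raises WET (monotone HLUT)
  vol_hot <- ct_volume(array(100, c(4, 16, 4)), c(4, 4, 4))
  dl_hot <- wet_map(vol_hot, t, roi)
  expect_gt(delta_wet(dl_hot, ref), 0)
  bad <- ref; bad$roi <- !ref$roi
  expect_error(delta_wet(bad, ref), "different ROIs")
})

test_that("WET maps export to NIfTI on the source grid", {
  vol <- ct_volume(array(0, c(6, 10, 6)), c(4, 4, 4))
  roi <- array(FALSE, c(6, 10, 6)); roi[3, 7, 3] <- TRUE
  wm <- wet_map(vol, read_hlut(), roi)
  path <- tempfile(fileext = ".nii.gz")
  write_wet_nifti(wm, path)
  back <- read_nifti_volume(path)
  expect_equal(back$data[3, 7, 3], wm$values, tolerance = 1e-6)
  expect_equal(sum(back$data != 0), 1)
})
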