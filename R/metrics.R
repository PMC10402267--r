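#' Evaluation region for paired volumes
#'
#' Pairs a generated volume with its reference (and an optional mask
#' restricting evaluation, e.g. the target contour) and validates shapes.
#'
#' @param dl generated volume ([ct_volume()] or 3D array), in HU.
#' @param ref reference volume of the same shape, in HU.
#' @param mask optional logical array selecting the evaluated voxels; `NULL`
#'   evaluates the whole volume.
#' @return an object of class `eval_region` with elements `dl`, `ref`,
#'   `mask`, `n`.
#' @export
eval_region <- function(dl, ref, mask = NULL) {
  dl <- if (inherits(dl, "ct_volume")) dl$data else unclass(dl)
  ref <- if (inherits(ref, "ct_volume")) ref$data else unclass(ref)
  if (!identical(dim(dl), dim(ref))) stop("`dl` and `ref` shapes differ")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(mask))
    if (!identical(dim(mask), dim(dl))) stop("`mask` shape differs")
    if (!any(mask)) stop("`mask` selects no voxels")
  }
  n <- if (is.null(mask)) length(dl) else sum(mask)
  structure(list(dl = dl, ref = ref, mask = mask, n = n),
            class = "eval_region")
}

as_region <- function(dl, ref = NULL, mask = NULL) {
  if (inherits(dl, "eval_region")) dl else eval_region(dl, ref, mask)
}

region_values <- function(region) {
  if (is.null(region$mask))
    list(dl = as.numeric(region$dl), ref = as.numeric(region$ref))
  else
    list(dl = region$dl[region$mask], ref = region$ref[region$mask])
}

#' Voxelwise image-quality metrics
#'
#' Mean error (ME), mean absolute error (MAE) and peak signal-to-noise ratio
#' (PSNR) between a generated and a reference CT volume, over the whole
#' volume or a mask:
#' \deqn{ME = \frac{1}{N}\sum_i (x_{i,DL} - x_{i,ref})}
#' \deqn{MAE = \frac{1}{N}\sum_i |x_{i,DL} - x_{i,ref}|}
#' \deqn{PSNR = 10\log_{10}\!\left[\frac{\max^2(x_{ref})}{\frac{1}{N}\sum_i
#'   (x_{i,DL} - x_{i,ref})^2}\right]}
#' The PSNR peak is the maximum of the reference over the evaluated region
#' (set `peak` to use a fixed scanner peak instead). Identical inputs give an
#' infinite PSNR, returned as `Inf` rather than an error.
#'
#' @param dl generated volume, reference volume and optional mask as in
#'   [eval_region()]; alternatively pass an `eval_region` as `dl`.
#' @param ref,mask see [eval_region()].
#' @return ME and MAE in HU; PSNR in dB.
#' @export
mean_error <- function(dl, ref = NULL, mask = NULL) {
  v <- region_values(as_region(dl, ref, mask))
  mean(v$dl - v$ref)
}

#' @rdname mean_error
#' @export
mean_absolute_error <- function(dl, ref = NULL, mask = NULL) {
  v <- region_values(as_region(dl, ref, mask))
  mean(abs(v$dl - v$ref))
}

#' @rdname mean_error
#' @param peak optional fixed PSNR peak value (HU); default uses
#'   `max(ref)` over the evaluated region.
#' @export
psnr <- function(dl, ref = NULL, mask = NULL, peak = NULL) {
  v <- region_values(as_region(dl, ref, mask))
  mse <- mean((v$dl - v$ref)^2)
  if (mse == 0) return(Inf)
  if (is.null(peak)) peak <- max(v$ref)
  10 * log10(peak^2 / mse)
}

#' Express a mean error in HU as a percent attenuation error
#'
#' Via the identity HU = 1000 (mu - 1), a CT-number offset of `me` HU is a
#' relative-attenuation offset of `me / 1000`, i.e. `me / 1000 * 100` percent.
#'
#' @param me mean error in HU.
#' @return percent error in relative linear attenuation.
#' @export
percent_me <- function(me) {
  if (any(!is.finite(me))) stop("`me` must be finite")
  me / 1000 * 100
}

#' SSIM parameters
#'
#' @param window_size odd window edge length in voxels.
#' @param window `"gaussian"` or `"uniform"`.
#' @param sigma Gaussian window SD in voxels.
#' @param k1,k2 stabilization constants.
#' @param dynamic_range value range L of the data; `NULL` uses
#'   `max(ref) - min(ref)` over the evaluated region.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(window_size = 11L, window = c("gaussian", "uniform"),
                        sigma = 1.5, k1 = 0.01, k2 = 0.03,
                        dynamic_range = NULL) {
  window <- match.arg(window)
  window_size <- as.integer(window_size)
  if (window_size %% 2L != 1L || window_size < 1L)
    stop("`window_size` must be odd and positive")
  if (k1 <= 0 || k2 <= 0) stop("`k1` and `k2` must be positive")
  structure(list(window_size = window_size, window = window, sigma = sigma,
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

ssim_window_weights <- function(params) {
  r <- (params$window_size - 1L) / 2L
  if (params$window == "uniform") {
    w <- rep(1, params$window_size)
  } else {
    w <- exp(-((-r):r)^2 / (2 * params$sigma^2))
  }
  w / sum(w)
}

# separable "same" filtering of a 3D array with zero padding; values at
# centers where the full window fits are exact windowed sums
sepfilter3 <- function(arr, w) {
  r <- (length(w) - 1L) / 2L
  band <- function(n) {
    M <- matrix(0, n, n)
    for (o in (-r):r) {
      i <- seq_len(n); j <- i + o
      keep <- j >= 1 & j <= n
      M[cbind(i[keep], j[keep])] <- w[o + r + 1]
    }
    M
  }
  d <- dim(arr)
  x <- array(band(d[1]) %*% matrix(arr, d[1]), d)
  x <- aperm(array(band(d[2]) %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(band(d[3]) %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
              d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Structural similarity between two volumes
#'
#' Local-window 3D SSIM averaged over the evaluated voxels. With a mask, the
#' volumes are first cropped to the mask's bounding box dilated by the window
#' radius (windowed statistics need spatial context) and the SSIM map is
#' averaged over mask voxels whose window fits inside the volume; without a
#' mask it is averaged over all such interior voxels.
#'
#' @inheritParams mean_error
#' @param params an [ssim_params()].
#' @return SSIM score in `[-1, 1]`; identical volumes give exactly 1.
#' @export
ssim <- function(dl, ref = NULL, mask = NULL, params = ssim_params()) {
  region <- as_region(dl, ref, mask)
  x <- region$dl; y <- region$ref; m <- region$mask
  r <- (params$window_size - 1L) / 2L
  d <- dim(x)
  if (!is.null(m)) {
    idx <- which(m, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - r, 1)
    hi <- pmin(apply(idx, 2, max) + r, d)
    # a bbox clipped at the volume edge may fall below the window size:
    # grow it toward the interior so windowed statistics stay computable
    for (a in 1:3) {
      short <- params$window_size - (hi[a] - lo[a] + 1L)
      if (short > 0) {
        hi[a] <- min(hi[a] + short, d[a])
        lo[a] <- max(hi[a] - params$window_size + 1L, 1L)
      }
    }
    x <- x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    y <- y[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    m <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    d <- dim(x)
  }
  if (any(d < params$window_size))
    stop("evaluated region is smaller than the SSIM window")
  L <- params$dynamic_range
  if (is.null(L)) {
    rv <- region_values(region)$ref
    L <- diff(range(rv))
  }
  if (L <= 0) L <- 1  # constant reference: fall back to unit range
  c1 <- (params$k1 * L)^2
  c2 <- (params$k2 * L)^2
  w <- ssim_window_weights(params)
  mx <- sepfilter3(x, w);  my <- sepfilter3(y, w)
  sxx <- sepfilter3(x * x, w) - mx^2
  syy <- sepfilter3(y * y, w) - my^2
  sxy <- sepfilter3(x * y, w) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  valid <- array(FALSE, d)
  valid[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)] <- TRUE
  sel <- if (is.null(m)) valid else (valid & m)
  if (!any(sel)) stop("no evaluated voxel has a full SSIM window")
  mean(smap[sel])
}

#' CT-number histogram
#'
#' Bin counts of voxel CT numbers over a stated HU range; voxels outside the
#' range are excluded, so the counts sum to the number of in-range voxels.
#'
#' @param volume a [ct_volume()] or numeric array/vector of HU values.
#' @param bins number of equal-width bins.
#' @param range length-2 HU range (low, high).
#' @return an object of class `ct_histogram` with `breaks`, `mids`, `counts`.
#' @export
ct_histogram <- function(volume, bins = 100L, range = c(-1000, 1000)) {
  v <- if (inherits(volume, "ct_volume")) as.numeric(volume$data)
       else as.numeric(volume)
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be >= 1")
  if (range[2] <= range[1]) stop("`range` must be increasing")
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  sel <- v >= range[1] & v <= range[2]
  counts <- tabulate(findInterval(v[sel], breaks, rightmost.closed = TRUE),
                     nbins = bins)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                 counts = counts),
            class = "ct_histogram")
}

#' @export
as.data.frame.ct_histogram <- function(x, ...) {
  data.frame(mid = x$mids, count = x$counts)
}

#' @export
print.ct_histogram <- function(x, ...) {
  cat(sprintf("<ct_histogram> %d bins over [%g, %g] HU, %d voxels\n",
              length(x$counts), min(x$breaks), max(x$breaks), sum(x$counts)))
  invisible(x)
}

#' All image metrics for one volume pair
#'
#' Convenience wrapper mirroring the clinical reporting convention: ME and
#' MAE over the whole volume, PSNR and SSIM over the target contour.
#'
#' @param dl,ref volumes as in [eval_region()].
#' @param target_mask logical array marking the target contour.
#' @param ssim_params an [ssim_params()].
#' @return named list with `me_hu`, `mae_hu`, `psnr_db`, `ssim`.
#' @export
evaluate_volumes <- function(dl, ref, target_mask,
                             ssim_params = flashigrt::ssim_params()) {
  list(me_hu = mean_error(dl, ref),
       mae_hu = mean_absolute_error(dl, ref),
       psnr_db = psnr(dl, ref, target_mask),
       ssim = ssim(dl, ref, target_mask, ssim_params))
}
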