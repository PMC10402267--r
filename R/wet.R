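#' Hounsfield-unit to relative-stopping-power lookup table
#'
#' A monotone piecewise-linear calibration (HLUT) mapping CT numbers to
#' proton stopping power relative to water. Breakpoint HU must be strictly
#' increasing, RSP non-decreasing, and the table must pin water at
#' (0 HU, RSP 1).
#'
#' @param hu numeric vector of breakpoint CT numbers (HU).
#' @param rsp numeric vector of breakpoint RSP values.
#' @return an object of class `hlut`.
#' @export
hlut <- function(hu, rsp) {
  hu <- as.numeric(hu); rsp <- as.numeric(rsp)
  if (!length(hu)) stop("HLUT is empty")
  if (length(hu) != length(rsp)) stop("`hu` and `rsp` lengths differ")
  if (any(diff(hu) <= 0)) stop("HLUT HU breakpoints must be strictly increasing")
  if (any(diff(rsp) < 0)) stop("HLUT RSP must be non-decreasing")
  w <- which(hu == 0)
  if (!length(w) || rsp[w] != 1)
    stop("HLUT must contain the water breakpoint (0 HU, RSP 1)")
  structure(list(hu = hu, rsp = rsp), class = "hlut")
}

#' Read / write an HLUT as two-column CSV
#'
#' The CSV has columns `hu` and `rsp`. The packaged default table
#' (`system.file("extdata", "hlut_default.csv", package = "flashigrt")`) is a
#' generic 4-breakpoint calibration; replace it with an
#' institution-commissioned table for any real-beam work.
#'
#' @param path CSV path; `read_hlut()` defaults to the packaged table.
#' @param table an [hlut()] (for writing).
#' @return `read_hlut` returns an [hlut()]; `write_hlut` returns `path`
#'   invisibly.
#' @export
read_hlut <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hlut_default.csv", package = "flashigrt")
  df <- read.csv(path)
  if (!all(c("hu", "rsp") %in% names(df)))
    stop("HLUT CSV must have columns `hu` and `rsp`")
  hlut(df$hu, df$rsp)
}

#' @rdname read_hlut
#' @export
write_hlut <- function(table, path) {
  stopifnot(inherits(table, "hlut"))
  write.csv(data.frame(hu = table$hu, rsp = table$rsp), path, row.names = FALSE)
  invisible(path)
}

#' Convert CT numbers to relative stopping power
#'
#' Linear interpolation between HLUT breakpoints, clamped to the end values
#' outside the table range.
#'
#' @param hu CT number(s) in HU.
#' @param table an [hlut()]; default is the packaged calibration.
#' @return RSP value(s), dimensionless.
#' @export
hu_to_rsp <- function(hu, table = read_hlut()) {
  stopifnot(inherits(table, "hlut"))
  if (length(table$hu) == 1L) return(rep(table$rsp, length(hu)))
  approx(table$hu, table$rsp, xout = as.numeric(hu), rule = 2)$y
}

#' Ray-traced water-equivalent thickness over an ROI
#'
#' For each ROI voxel, integrates RSP along the parallel anteroposterior ray
#' (anterior to posterior, +y) from the volume's anterior boundary to the
#' voxel center: full upstream voxels contribute `RSP * spacing_y` and the
#' voxel itself a half-voxel path, which is exact for the piecewise-constant
#' CT grid. WET is therefore non-decreasing with depth along each ray.
#'
#' @param volume a [ct_volume()] in HU.
#' @param table an [hlut()].
#' @param roi logical array of ROI voxels (matching the volume grid).
#' @param beam beam direction; only `"anteroposterior"` is part of the
#'   evaluation surface.
#' @param fit_bins histogram bins forwarded to [fit_gaussian()] for the
#'   summary fit.
#' @return an object of class `wet_map`: per-ROI-voxel WET values (mm,
#'   ordered as `which(roi)`), the mask, voxel count `n`, `beam_axis`, and
#'   `gaussian_fit` = (mean, sd) in mm with its `fit_flag`.
#' @export
wet_map <- function(volume, table = read_hlut(), roi,
                    beam = "anteroposterior", fit_bins = 50L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(table, "hlut"))
  beam <- match.arg(beam)
  d <- dim(volume$data)
  if (!identical(dim(roi), d)) stop("`roi` must match the volume grid")
  if (!any(roi)) stop("`roi` selects no voxels")
  rsp <- array(hu_to_rsp(volume$data, table), d)
  dy <- volume$spacing[2]
  # cumulative WET at voxel centers along +y: columns are the y axis
  perm <- aperm(rsp, c(2, 1, 3))                  # (y, x, z)
  m <- matrix(perm, d[2])
  cum <- apply(m, 2, cumsum) * dy                 # WET at posterior face
  wet_center <- cum - m * dy / 2                  # back off half a voxel
  wet_arr <- aperm(array(wet_center, d[c(2, 1, 3)]), c(2, 1, 3))
  vals <- wet_arr[roi]
  fit <- if (length(vals) >= 3L) fit_gaussian(vals, bins = fit_bins)
         else list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
                   flag = "too_few_voxels")
  structure(list(values = vals, roi = roi, n = sum(roi),
                 beam_axis = "+y (anteroposterior)",
                 gaussian_fit = c(mean = fit$mean, sd = fit$sd),
                 fit_flag = fit$flag,
                 spacing = volume$spacing),
            class = "wet_map")
}

#' @export
print.wet_map <- function(x, ...) {
  cat(sprintf("<wet_map> %d ROI voxels, beam %s\n", x$n, x$beam_axis))
  cat(sprintf("  WET range [%.2f, %.2f] mm; Gaussian fit mean %.2f mm, sd %.2f mm%s\n",
              min(x$values), max(x$values),
              x$gaussian_fit["mean"], x$gaussian_fit["sd"],
              if (x$fit_flag != "ok") paste0(" [", x$fit_flag, "]") else ""))
  invisible(x)
}

#' Export a WET map as NIfTI
#'
#' Writes the WET values on the ROI voxels (0 elsewhere) on the source grid.
#'
#' @param wet a [wet_map()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_wet_nifti <- function(wet, path) {
  arr <- array(0, dim(wet$roi))
  arr[wet$roi] <- wet$values
  write_nifti_volume(ct_volume(arr, wet$spacing), path)
}

#' Gaussian fit of a WET histogram
#'
#' Least-squares fit of an amplitude/mean/SD Gaussian to the binned histogram
#' of WET values, initialized at the sample moments; fitting the histogram
#' rather than taking raw moments suppresses the influence of image noise.
#' If the nonlinear fit fails to converge the sample mean/SD are returned
#' with `flag = "moment_fallback"`; all-equal input returns `(value, 0)` with
#' `flag = "degenerate"`.
#'
#' @param wet a [wet_map()] or numeric vector of WET values (mm).
#' @param bins histogram bin count.
#' @return list with `mean` (mm), `sd` (mm) and `flag` (`"ok"`,
#'   `"moment_fallback"` or `"degenerate"`).
#' @export
fit_gaussian <- function(wet, bins = 50L) {
  v <- if (inherits(wet, "wet_map")) wet$values else as.numeric(wet)
  if (length(v) < 3L) stop("need at least 3 WET values to fit")
  if (diff(range(v)) == 0)
    return(list(mean = v[1], sd = 0, flag = "degenerate"))
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = bins + 1L),
                      plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  m0 <- mean(v); s0 <- sd(v)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                      start = list(a = max(df$y), m = m0, s = s0),
                      lower = c(0, min(v), 1e-9),
                      upper = c(Inf, max(v), diff(range(v))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = m0, sd = s0, flag = "moment_fallback"))
  co <- coef(fit)
  list(mean = unname(co["m"]), sd = unname(co["s"]), flag = "ok")
}

#' WET agreement between generated and reference anatomy
#'
#' `delta_wet()` is the mean signed per-voxel WET difference over the shared
#' ROI, \deqn{\Delta WET = \frac{1}{N}\sum_i (WET_{i,DL} - WET_{i,ref})}
#' in mm; `epsilon_wet()` expresses it relative to the mean reference WET,
#' \deqn{\epsilon_{WET} = \frac{\Delta WET}{\frac{1}{N}\sum_i WET_{i,ref}}
#'   \times 100\%.}
#'
#' @param dl,ref [wet_map()] objects computed over the identical ROI.
#' @return `delta_wet` in mm; `epsilon_wet` in percent.
#' @export
delta_wet <- function(dl, ref) {
  stopifnot(inherits(dl, "wet_map"), inherits(ref, "wet_map"))
  if (!identical(dl$roi, ref$roi)) stop("WET maps use different ROIs")
  mean(dl$values - ref$values)
}

#' @rdname delta_wet
#' @export
epsilon_wet <- function(dl, ref) {
  d <- delta_wet(dl, ref)
  mref <- mean(ref$values)
  if (mref <= 0) stop("mean reference WET must be positive")
  d / mref * 100
}
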