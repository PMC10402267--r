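#' kV projection geometry
#'
#' Cone-beam geometry for one synthetic kV projection. The source angle is
#' measured in the axial plane about the superior-inferior axis: 0 degrees
#' places the source anterior of the patient and angles increase toward
#' patient-left (so 90 degrees is a left-lateral source). The detector panel
#' is perpendicular to the source-isocenter line, on the far side of the
#' isocenter; panel rows run along the superior-inferior axis, columns along
#' the in-plane transverse axis.
#'
#' @param source_angle source position angle in degrees.
#' @param source_axis_distance source-to-isocenter distance in mm.
#' @param source_detector_distance source-to-panel distance in mm.
#' @param panel_rows,panel_cols detector channels; the defaults mirror a
#'   clinical on-board panel (768 x 1024 at 0.39 mm pitch) and scale down
#'   freely for desk-size studies.
#' @param pixel_pitch detector channel spacing in mm.
#' @return an object of class `projection_geometry`.
#' @export
projection_geometry <- function(source_angle,
                                source_axis_distance = 1000,
                                source_detector_distance = 1500,
                                panel_rows = 768L, panel_cols = 1024L,
                                pixel_pitch = 0.39) {
  if (!(source_detector_distance > source_axis_distance &&
        source_axis_distance > 0))
    stop("require source_detector_distance > source_axis_distance > 0")
  if (panel_rows < 1L || panel_cols < 1L || pixel_pitch <= 0)
    stop("panel must have positive rows, cols and pitch")
  structure(list(source_angle = as.numeric(source_angle),
                 source_axis_distance = source_axis_distance,
                 source_detector_distance = source_detector_distance,
                 panel_rows = as.integer(panel_rows),
                 panel_cols = as.integer(panel_cols),
                 pixel_pitch = as.numeric(pixel_pitch)),
            class = "projection_geometry")
}

#' Convert CT number to relative linear attenuation
#'
#' Uses the CT-number identity HU = 1000 (mu - 1), with mu the linear
#' attenuation coefficient relative to water, clamped below at 0 (vacuum).
#'
#' @param hu CT number(s) in HU.
#' @return relative attenuation, dimensionless; 0 HU maps to 1 (water),
#'   -1000 HU to 0 (air).
#' @export
hu_to_mu <- function(hu) {
  if (any(!is.finite(hu))) stop("`hu` must be finite")
  pmax(hu / 1000 + 1, 0)
}

# unit vector from isocenter toward the source at `angle` degrees
source_direction <- function(angle) {
  th <- angle * pi / 180
  c(sin(th), -cos(th), 0)
}

#' Ray-traced kV projection of a CT volume
#'
#' Computes, for every detector pixel, the line integral of relative
#' attenuation (mm of water-equivalent attenuation path) along the ray from
#' the point source to the pixel center, by exact Siddon voxel traversal.
#' Rays that miss the volume contribute 0. The projection is returned in the
#' log (line-integral) domain; see [line_integral_to_intensity()] for a
#' detector-intensity view.
#'
#' @param volume a [ct_volume()].
#' @param geom a [projection_geometry()].
#' @param isocenter world position (mm) the gantry rotates about; defaults to
#'   the volume center.
#' @return numeric `panel_rows x panel_cols` matrix of line integrals (mm),
#'   with the geometry attached as attribute `"geometry"`.
#' @export
project <- function(volume, geom, isocenter = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(geom, "projection_geometry"))
  d <- dim(volume$data)
  if (is.null(isocenter)) isocenter <- volume$origin + d * volume$spacing / 2
  dirv <- source_direction(geom$source_angle)
  src <- isocenter + geom$source_axis_distance * dirv
  det <- isocenter - (geom$source_detector_distance -
                        geom$source_axis_distance) * dirv
  bmin <- volume$origin
  bmax <- volume$origin + d * volume$spacing
  if (all(src > bmin & src < bmax))
    stop("x-ray source lies inside the volume; increase source_axis_distance")
  th <- geom$source_angle * pi / 180
  u_axis <- c(cos(th), sin(th), 0)
  v_axis <- c(0, 0, 1)
  mu <- hu_to_mu(volume$data)
  out <- .siddon_project(as.numeric(mu), as.integer(d),
                         as.numeric(volume$spacing), as.numeric(bmin),
                         as.numeric(src), as.numeric(det),
                         u_axis, v_axis,
                         geom$panel_rows, geom$panel_cols, geom$pixel_pitch)
  attr(out, "geometry") <- geom
  out
}

#' The four clinical source-angle pairs
#'
#' Orthogonal kV source-angle pairs (degrees) used for biplanar acquisition:
#' 112/202, 135/225, 157/247 and 180/270.
#'
#' @return a list of length-2 numeric vectors.
#' @export
standard_angle_pairs <- function() {
  list(c(112, 202), c(135, 225), c(157, 247), c(180, 270))
}

angle_pair_label <- function(pair) sprintf("%g/%g", pair[1], pair[2])

#' Acquire an orthogonal projection pair
#'
#' Projects the volume from two source angles 90 degrees apart with identical
#' panel settings.
#'
#' @param volume a [ct_volume()].
#' @param angle_pair numeric length-2 source angles in degrees; must differ by
#'   90 degrees modulo 360 unless `allow_non_orthogonal = TRUE`.
#' @param geom_template a [projection_geometry()] providing distances and
#'   panel settings (its `source_angle` is ignored).
#' @param allow_non_orthogonal set `TRUE` to permit non-orthogonal pairs.
#' @param isocenter optional world isocenter (mm); defaults to volume center.
#' @return an object of class `projection_pair` with elements `proj_a`,
#'   `proj_b`, `geom_a`, `geom_b`, `angle_pair`.
#' @export
acquire_pair <- function(volume, angle_pair, geom_template,
                         allow_non_orthogonal = FALSE, isocenter = NULL) {
  if (length(angle_pair) != 2L) stop("`angle_pair` must be two angles")
  dd <- abs(angle_pair[2] - angle_pair[1]) %% 360
  sep <- min(dd, 360 - dd)
  if (abs(sep - 90) > 1e-9 && !allow_non_orthogonal)
    stop(sprintf("source angles %s are not orthogonal (separation %.3f deg)",
                 angle_pair_label(angle_pair), sep))
  ga <- geom_template; ga$source_angle <- as.numeric(angle_pair[1])
  gb <- geom_template; gb$source_angle <- as.numeric(angle_pair[2])
  structure(list(proj_a = project(volume, ga, isocenter),
                 proj_b = project(volume, gb, isocenter),
                 geom_a = ga, geom_b = gb,
                 angle_pair = as.numeric(angle_pair)),
            class = "projection_pair")
}

#' @export
print.projection_pair <- function(x, ...) {
  cat(sprintf("<projection_pair> angles %s deg, panel %d x %d @ %.3g mm\n",
              angle_pair_label(x$angle_pair),
              x$geom_a$panel_rows, x$geom_a$panel_cols, x$geom_a$pixel_pitch))
  invisible(x)
}

#' Convert a line-integral projection to detector intensities
#'
#' Applies the monoenergetic Beer-Lambert relation
#' `I = I0 * exp(-integral / mu_water_mm)` for visualization/export; the
#' line-integral (log) domain remains the computational representation.
#'
#' @param proj line-integral matrix from [project()] (mm of water-equivalent
#'   path).
#' @param I0 unattenuated intensity.
#' @param mu_water_mm linear attenuation of water per mm (default 0.02/mm,
#'   a typical kV-beam effective value).
#' @return intensity matrix.
#' @export
line_integral_to_intensity <- function(proj, I0 = 1, mu_water_mm = 0.02) {
  I0 * exp(-proj * mu_water_mm)
}

#' Write a projection as 16-bit TIFF with a JSON sidecar
#'
#' The projection is linearly scaled to the 16-bit range; the scale and
#' offset needed to recover the line integrals, plus the acquisition
#' geometry, are recorded in `<path>.json`.
#'
#' @param proj projection matrix from [project()].
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
write_projection_tiff <- function(proj, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF projections")
  rng <- range(proj)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((proj - rng[1]) / scale, path, bits.per.sample = 16L)
  geom <- attr(proj, "geometry")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            geometry = unclass(geom)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

# bilinear resampling of a projection matrix onto an out_rows x out_cols grid
# (pixel-center aligned field of view), as dense interpolation GEMMs
resample_bilinear <- function(mat, out_rows, out_cols) {
  interp_matrix <- function(n_out, n_in) {
    if (n_out == n_in) return(diag(n_in))
    # map output pixel centers onto input pixel-center coordinates
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    w <- pos - lo
    M <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      l <- lo[i] + 1
      M[i, l] <- 1 - w[i]
      M[i, min(l + 1, n_in)] <- M[i, min(l + 1, n_in)] + w[i]
    }
    M
  }
  R <- interp_matrix(out_rows, nrow(mat))
  C <- interp_matrix(out_cols, ncol(mat))
  R %*% mat %*% t(C)
}
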