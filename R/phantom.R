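#' Configuration for the 4D breathing-thorax phantom
#'
#' Defines a digital thorax emulating a respiratory-gated (4D) CT study: an
#' elliptic soft-tissue body, two lung ellipsoids, a spine cylinder, a heart
#' surrogate and a spherical lung tumor that translates along the
#' superior-inferior axis over the breathing cycle. The phantom stands in for
#' a clinical 4D CT cohort so that projection synthesis, network training and
#' WET evaluation are all testable from code alone.
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z).
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param body_hu,lung_hu,tumor_hu,spine_hu,heart_hu material CT numbers (HU).
#' @param tumor_center numeric length-3, tumor center in world mm at phase 0
#'   (full inhale).
#' @param tumor_radius tumor radius in mm.
#' @param motion_amplitude peak-to-peak superior-inferior tumor excursion (mm).
#' @param n_phases number of respiratory phases (default 10).
#' @param noise_sd additive Gaussian noise SD in HU (0 disables noise).
#' @param seed integer seed controlling the noise field.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 48L),
                           spacing = c(4, 4, 4),
                           body_hu = 40, lung_hu = -750, tumor_hu = 40,
                           spine_hu = 700, heart_hu = 50,
                           tumor_center = c(-55, -8, -10),
                           tumor_radius = 15,
                           motion_amplitude = 10,
                           n_phases = 10L,
                           noise_sd = 15,
                           seed = 42L) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              body_hu = body_hu, lung_hu = lung_hu, tumor_hu = tumor_hu,
              spine_hu = spine_hu, heart_hu = heart_hu,
              tumor_center = as.numeric(tumor_center),
              tumor_radius = as.numeric(tumor_radius),
              motion_amplitude = as.numeric(motion_amplitude),
              n_phases = as.integer(n_phases),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  hu <- c(cfg$body_hu, cfg$lung_hu, cfg$tumor_hu, cfg$spine_hu, cfg$heart_hu)
  if (any(hu < -1000 | hu > 3000)) stop("material HU must lie in [-1000, 3000]")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    stop("`grid_shape` must be 3 values >= 8")
  if (cfg$n_phases < 1L) stop("`n_phases` must be >= 1")
  if (cfg$tumor_radius <= 0) stop("`tumor_radius` must be positive")
  if (cfg$motion_amplitude < 0) stop("`motion_amplitude` must be >= 0")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

#' Read a phantom configuration from YAML
#'
#' Any field of [phantom_config()] may appear in the file; missing fields take
#' the defaults.
#'
#' @param path path to a YAML file.
#' @return a [phantom_config()].
#' @export
phantom_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown phantom config fields: ", paste(unknown, collapse = ", "))
  do.call(phantom_config, vals)
}

#' Superior-inferior displacement of a respiratory phase
#'
#' A sinusoidal surrogate for the breathing trajectory: phase 0 is the full
#' inhale reference and the displacement of phase k (0-based) is
#' `amplitude * (1 - cos(2 * pi * k / n_phases)) / 2`, peaking at full exhale
#' mid-cycle.
#'
#' @param phase_index 0-based phase index (vectorized).
#' @param amplitude peak-to-peak amplitude in mm.
#' @param n_phases number of phases in the cycle (default 10).
#' @return displacement in mm, in `[0, amplitude]`.
#' @export
phase_displacement <- function(phase_index, amplitude, n_phases = 10L) {
  if (any(phase_index < 0 | phase_index >= n_phases))
    stop("`phase_index` must lie in [0, n_phases - 1]")
  amplitude * (1 - cos(2 * pi * phase_index / n_phases)) / 2
}

# evaluate a function under a temporary RNG state derived from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# world-coordinate meshes for a centered grid (voxel-center convention)
grid_axes <- function(shape, spacing) {
  origin <- -shape * spacing / 2
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * spacing[a])
}

ellipsoid_mask <- function(ax, center, semi) {
  dx2 <- ((ax[[1]] - center[1]) / semi[1])^2
  dy2 <- ((ax[[2]] - center[2]) / semi[2])^2
  dz2 <- ((ax[[3]] - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

cylinder_mask_z <- function(ax, center_xy, radius) {
  dx2 <- (ax[[1]] - center_xy[1])^2
  dy2 <- (ax[[2]] - center_xy[2])^2
  in_xy <- outer(dx2, dy2, `+`) <= radius^2
  array(rep(in_xy, length(ax[[3]])), c(length(ax[[1]]), length(ax[[2]]),
                                       length(ax[[3]])))
}

#' Generate a 4D breathing-thorax phantom
#'
#' Builds one CT volume per respiratory phase on a common grid. Anatomy is
#' painted in order (body, lungs, heart, spine, tumor) over a -1000 HU air
#' background; the tumor center and the diaphragm (the lungs' inferior
#' boundary) translate superiorly by [phase_displacement()] at each phase.
#' Optional additive Gaussian HU noise is drawn from the configured seed, so
#' regeneration with an identical configuration is bit-identical.
#'
#' Organ positions and sizes scale with the grid extent only through the fixed
#' world-space layout below; the default 64 x 64 x 48 grid at 4 mm covers a
#' 256 x 256 x 192 mm field of view.
#'
#' @param config a [phantom_config()].
#' @return a [ct4d()] whose `roi_target` masks mark the tumor at each phase.
#' @export
make_thorax_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$grid_shape
  ax <- grid_axes(shape, config$spacing)

  body <- ellipsoid_mask(ax, c(0, 0, 0), c(110, 85, 1e9))  # elliptic cylinder
  lung_semi <- c(40, 58, 70)
  lung_centers <- list(right = c(-55, -8, 5), left = c(55, -8, 5))
  lung_floor <- lung_centers$right[3] - lung_semi[3]  # diaphragm at inhale
  heart <- ellipsoid_mask(ax, c(12, -20, -25), c(32, 28, 32))
  spine <- cylinder_mask_z(ax, c(0, 62), 14) & body

  zc <- ax[[3]]
  phases <- vector("list", config$n_phases)
  rois <- vector("list", config$n_phases)
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed,
              lapply(seq_len(config$n_phases), function(k)
                array(rnorm(prod(shape), 0, config$noise_sd), shape)))
  } else NULL

  for (k in seq_len(config$n_phases)) {
    disp <- phase_displacement(k - 1L, config$motion_amplitude, config$n_phases)
    above_dia <- outer(array(TRUE, shape[1:2]), zc >= lung_floor + disp, `&`)
    lungs <- (ellipsoid_mask(ax, lung_centers$right, lung_semi) |
              ellipsoid_mask(ax, lung_centers$left, lung_semi)) & above_dia
    tc <- config$tumor_center + c(0, 0, disp)
    tumor <- ellipsoid_mask(ax, tc, rep(config$tumor_radius, 3))
    if (!any(tumor))
      stop("tumor contains no voxels; increase `tumor_radius` or refine the grid")
    if (any(tumor & !lungs))
      stop(sprintf("tumor exits the lung at phase %d; adjust `tumor_center`,
`tumor_radius` or `motion_amplitude`", k - 1L))

    vol <- array(-1000, shape)
    vol[body] <- config$body_hu
    vol[lungs] <- config$lung_hu
    vol[heart & body] <- config$heart_hu
    vol[spine] <- config$spine_hu
    vol[tumor] <- config$tumor_hu
    if (!is.null(noise)) {
      vol <- vol + noise[[k]]
      vol[vol < -1000] <- -1000
      vol[vol > 3000] <- 3000
    }
    phases[[k]] <- ct_volume(vol, config$spacing)
    rois[[k]] <- tumor
  }
  ct4d(phases, rois)
}

#' Centroid of a binary mask in world coordinates
#'
#' @param mask logical 3D array.
#' @param vol the [ct_volume()] providing the grid geometry.
#' @return numeric length-3 world position (mm) of the mask centroid.
#' @export
mask_centroid <- function(mask, vol) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask is empty")
  vapply(1:3, function(a)
    mean(vol$origin[a] + (idx[, a] - 0.5) * vol$spacing[a]), numeric(1))
}
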