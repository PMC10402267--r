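#' Configuration of a full framework run
#'
#' Bundles the phantom, acquisition, network and WET settings for one
#' end-to-end study: phantom generation, orthogonal projection synthesis at
#' each source-angle pair, leave-phase-out training, held-out-phase
#' reconstruction, and image-quality plus WET evaluation.
#'
#' @param phantom a [phantom_config()].
#' @param angle_pairs list of length-2 source-angle vectors (degrees);
#'   default the four clinical pairs of [standard_angle_pairs()].
#' @param network a [network_config()]; its `output_shape` must match the
#'   phantom grid.
#' @param geom_template a [projection_geometry()] giving distances and panel
#'   settings; the default desk-scale panel (128 x 128 at 3.5 mm pitch)
#'   covers the default phantom's field of view.
#' @param hlut_path path to an HLUT CSV; `NULL` uses the packaged table.
#' @param ssim an [ssim_params()] used for the target-contour SSIM.
#' @param seed global seed; re-seeds the phantom (`seed`) and the network
#'   (`seed + 1`) so one integer reproduces the whole run.
#' @param identity_reconstruction debug switch: skip training and use the
#'   reference volume as its own reconstruction (end-to-end null case).
#' @param output_dir optional directory for report files; `NULL` skips
#'   writing.
#' @param write_volumes also write reconstructed volumes as NIfTI.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       angle_pairs = standard_angle_pairs(),
                       network = network_config(),
                       geom_template = projection_geometry(
                         0, panel_rows = 128L, panel_cols = 128L,
                         pixel_pitch = 3.5),
                       hlut_path = NULL,
                       ssim = ssim_params(),
                       seed = 1L,
                       identity_reconstruction = FALSE,
                       output_dir = NULL,
                       write_volumes = FALSE) {
  if (!length(angle_pairs)) stop("need at least one angle pair")
  if (!is.null(hlut_path) && !file.exists(hlut_path))
    stop("`hlut_path` does not exist: ", hlut_path)
  if (!is.null(seed)) {
    phantom$seed <- as.integer(seed)
    network$seed <- as.integer(seed) + 1L
  }
  if (!identical(as.integer(network$output_shape),
                 as.integer(phantom$grid_shape)))
    stop("`network$output_shape` must equal the phantom grid shape")
  structure(list(phantom = phantom, angle_pairs = angle_pairs,
                 network = network, geom_template = geom_template,
                 hlut_path = hlut_path, ssim = ssim, seed = seed,
                 identity_reconstruction = identity_reconstruction,
                 output_dir = output_dir, write_volumes = write_volumes),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `phantom`, `network` and `geometry` hold the fields of
#' [phantom_config()], [network_config()] and [projection_geometry()];
#' `angle_pairs` is a list of 2-element angle lists; remaining keys map to
#' [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(vals$phantom)) args$phantom <- do.call(phantom_config, vals$phantom)
  if (!is.null(vals$network)) args$network <- do.call(network_config, vals$network)
  if (!is.null(vals$geometry))
    args$geom_template <- do.call(projection_geometry, vals$geometry)
  if (!is.null(vals$angle_pairs))
    args$angle_pairs <- lapply(vals$angle_pairs, as.numeric)
  for (nm in c("hlut_path", "seed", "identity_reconstruction",
               "output_dir", "write_volumes"))
    if (!is.null(vals[[nm]])) args[[nm]] <- vals[[nm]]
  do.call(run_config, args)
}

report_metrics <- c("me_hu", "mae_hu", "psnr_db", "ssim",
                    "delta_wet_mm", "epsilon_wet_pct")

evaluate_phase <- function(dl, ref, roi, table, ssim = ssim_params()) {
  img <- evaluate_volumes(dl, ref, roi, ssim_params = ssim)
  wd <- wet_map(dl, table, roi)
  wr <- wet_map(ref, table, roi)
  c(img, list(delta_wet_mm = delta_wet(wd, wr),
              epsilon_wet_pct = epsilon_wet(wd, wr)))
}

aggregate_rows <- function(rows) {
  do.call(rbind, lapply(split(rows, rows$angle_pair), function(g) {
    out <- data.frame(angle_pair = g$angle_pair[1])
    for (m in report_metrics) {
      out[[paste0(m, "_mean")]] <- mean(g[[m]])
      out[[paste0(m, "_sd")]] <- sd(g[[m]])
    }
    out
  }))
}

#' Run the full image-guidance framework on a phantom
#'
#' Executes every stage for each configured source-angle pair: generates the
#' 4D phantom, synthesizes orthogonal projection pairs per phase, trains the
#' leave-phase-out variants, reconstructs each held-out phase, and evaluates
#' ME/MAE over the whole volume, PSNR/SSIM over the target contour, and
#' WET agreement over the target ROI for an anteroposterior beam. A stage
#' failure for one angle pair is logged and marked in the report rather than
#' aborting the run.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress.
#' @return an object of class `eval_report`: per-(phase, angle-pair) `rows`,
#'   per-pair `aggregates` (mean and sample SD over phases), the training
#'   `manifest`, `failures`, and the config.
#' @export
run_framework <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating %d-phase phantom", config$phantom$n_phases)
  data <- make_thorax_phantom(config$phantom)
  table <- if (is.null(config$hlut_path)) read_hlut()
           else read_hlut(config$hlut_path)
  np <- data$n_phases
  rows <- list(); manifest <- list(); failures <- character(0)

  for (ap in config$angle_pairs) {
    lab <- angle_pair_label(ap)
    res <- tryCatch({
      if (config$identity_reconstruction) {
        # null case: the reference stands in for its own reconstruction, so
        # projection synthesis and training are skipped (validate the pair)
        dd <- abs(ap[2] - ap[1]) %% 360
        if (abs(min(dd, 360 - dd) - 90) > 1e-9)
          stop(sprintf("source angles %s are not orthogonal",
                       angle_pair_label(ap)))
        recon <- data$phases
        man <- NULL
      } else {
        say("angle pair %s: projecting %d phases", lab, np)
        pairs <- lapply(data$phases, acquire_pair, angle_pair = ap,
                        geom_template = config$geom_template)
        say("angle pair %s: leave-phase-out training (%d folds)", lab, np)
        variants <- train_leave_phase_out(data, pairs, config$network)
        recon <- lapply(seq_len(np), function(k)
          infer(variants[[k]], pairs[[k]]))
        man <- data.frame(
          angle_pair = lab,
          held_out_phase = vapply(variants, `[[`, integer(1), "held_out_phase"),
          training_phases = vapply(variants, function(v)
            paste(v$training_phases, collapse = ","), character(1)),
          final_loss = vapply(variants, function(v)
            v$training_log$loss[nrow(v$training_log)], numeric(1)))
      }
      say("angle pair %s: evaluating", lab)
      prs <- lapply(seq_len(np), function(k) {
        met <- evaluate_phase(recon[[k]], data$phases[[k]],
                              data$roi_target[[k]], table, config$ssim)
        cbind(data.frame(angle_pair = lab, phase = k - 1L),
              as.data.frame(met))
      })
      list(rows = do.call(rbind, prs), manifest = man, recon = recon)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", lab, conditionMessage(res)))
      fail <- data.frame(angle_pair = lab, phase = seq_len(np) - 1L)
      for (m in report_metrics) fail[[m]] <- NA_real_
      rows[[lab]] <- fail
    } else {
      rows[[lab]] <- res$rows
      if (!is.null(res$manifest)) manifest[[lab]] <- res$manifest
      if (!is.null(config$output_dir) && config$write_volumes) {
        vd <- file.path(config$output_dir, gsub("/", "_", lab))
        dir.create(vd, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_len(np))
          write_nifti_volume(res$recon[[k]],
                             file.path(vd, sprintf("recon_%02d.nii.gz", k - 1L)))
      }
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  ok <- !is.na(rows$me_hu)
  report <- structure(
    list(rows = rows,
         aggregates = if (any(ok)) aggregate_rows(rows[ok, ]) else NULL,
         manifest = if (length(manifest)) do.call(rbind, manifest) else NULL,
         failures = failures,
         config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "eval_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d rows (%d angle pairs x %d phases)\n",
              nrow(x$rows), length(unique(x$rows$angle_pair)),
              length(unique(x$rows$phase))))
  if (!is.null(x$aggregates)) {
    for (i in seq_len(nrow(x$aggregates))) {
      a <- x$aggregates[i, ]
      cat(sprintf("  %s: MAE %.1f +/- %.1f HU, SSIM %.3f, eWET %.2f%%\n",
                  a$angle_pair, a$mae_hu_mean, a$mae_hu_sd,
                  a$ssim_mean, a$epsilon_wet_pct_mean))
    }
  }
  if (length(x$failures))
    cat("  failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.csv` (per-phase rows), `report.json` (rows, aggregates,
#' failures), `summary.csv` (per-pair aggregates), `manifest.csv` (trained
#' variants) and a YAML snapshot of the configuration.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$rows, file.path(dir, "report.csv"), row.names = FALSE)
  if (!is.null(report$aggregates))
    write.csv(report$aggregates, file.path(dir, "summary.csv"),
              row.names = FALSE)
  if (!is.null(report$manifest))
    write.csv(report$manifest, file.path(dir, "manifest.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(rows = report$rows, aggregates = report$aggregates,
         failures = report$failures),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  cfg <- report$config
  snapshot <- list(phantom = unclass(cfg$phantom),
                   network = unclass(cfg$network),
                   geometry = unclass(cfg$geom_template),
                   angle_pairs = cfg$angle_pairs,
                   seed = cfg$seed,
                   identity_reconstruction = cfg$identity_reconstruction)
  yaml::write_yaml(snapshot, file.path(dir, "config_snapshot.yaml"))
  invisible(dir)
}

#' Cohort summary across subjects
#'
#' Averages per-subject evaluation reports into a table shaped like a
#' patient-averaged results table: one row per (angle pair, metric) with the
#' mean and sample SD across subjects of the subjects' phase-averaged
#' values. With a single report the means equal that report's aggregates and
#' the SD is `NA`.
#'
#' @param reports list of `eval_report` objects (one per subject/phantom).
#' @return data frame with `angle_pair`, `metric`, `mean`, `sd`,
#'   `n_subjects`.
#' @export
summarize_reports <- function(reports) {
  if (!length(reports)) stop("`reports` must be non-empty")
  per <- lapply(reports, function(r) {
    stopifnot(inherits(r, "eval_report"))
    a <- r$aggregates
    if (is.null(a)) stop("report has no successful rows to summarize")
    a
  })
  pairs <- unique(unlist(lapply(per, function(a) a$angle_pair)))
  out <- list()
  for (ap in pairs) {
    for (m in report_metrics) {
      vals <- vapply(per, function(a) {
        row <- a[a$angle_pair == ap, ]
        if (nrow(row)) row[[paste0(m, "_mean")]] else NA_real_
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      out[[length(out) + 1L]] <- data.frame(
        angle_pair = ap, metric = m, mean = mean(vals),
        sd = if (length(vals) > 1L) sd(vals) else NA_real_,
        n_subjects = length(vals))
    }
  }
  do.call(rbind, out)
}
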