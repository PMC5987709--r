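# Umbrella pipeline: executes the requested analysis stages from a single
# JSON config, writes per-stage TSV/JSON outputs, and records every
# parameter (including implicitly applied defaults) in a run report so all
# numbers are traceable.

default_of <- function(cfg, key, default, log_env) {
  if (!is.null(cfg[[key]])) return(cfg[[key]])
  log_env$defaults[[length(log_env$defaults) + 1L]] <-
    list(key = key, value = default)
  default
}

require_path <- function(path, stage) {
  if (is.null(path)) stop_bad("stage '%s': required input path missing", stage)
  if (!file.exists(path)) {
    stop_bad("stage '%s': input file not found: %s", stage, path)
  }
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_bad("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the analysis pipeline from a config
#'
#' The config is a JSON file (or an equivalent R list) with optional
#' top-level `seed` and `out_dir` and a `stages` object holding one entry
#' per requested stage: `tracks`, `shape`, `halo`, `proteomics`,
#' `distance`, `adhesion`, `transwell`, `nta`, `pore_coverage`. Stages are
#' executed in that fixed order; a failing stage aborts with an error
#' naming the stage, retaining outputs of completed stages. Inputs are
#' never modified; every output is a new file under `out_dir`. The
#' returned report (also written to `out_dir/report.json`) records the
#' parameters of each stage, including defaults that were applied
#' implicitly, so paper-gap defaults are auditable.
#'
#' @param config path to a JSON config file, or a list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the report, invisibly (a nested list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bad("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop_bad("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop_bad("config has no stages")
  report <- list(seed = seed, stages = list())
  log_env <- new.env()

  add <- function(name, params, results) {
    report$stages[[name]] <<- list(parameters = params,
                                   defaults_applied = log_env$defaults,
                                   results = results)
  }

  if (!is.null(stages$tracks)) {
    cfg <- stages$tracks
    log_env$defaults <- list()
    run_stage("tracks", {
      tr <- read_tracks_csv(require_path(cfg$path, "tracks"))
      gd <- default_of(cfg, "gradient", c(1, 0), log_env)
      grad <- gradient_frame(gd[1], gd[2])
      min_disp <- default_of(cfg, "min_displacement", 24.1, log_env)
      kept <- filter_by_displacement(tr, min_disp)
      mets <- track_metrics(kept, grad)
      data.table::fwrite(mets, file.path(out_dir, "track_metrics.tsv"),
                         sep = "\t")
      n_bins <- default_of(cfg, "n_bins", 8, log_env)
      rose <- angle_histogram(kept, grad, n_bins)
      data.table::fwrite(rose, file.path(out_dir, "angle_histogram.tsv"),
                         sep = "\t")
      add("tracks",
          list(gradient = gd, min_displacement = min_disp, n_bins = n_bins),
          list(n_tracks_in = length(unique(tr$track_id)),
               n_tracks_kept = length(unique(kept$track_id)),
               mean_chemotactic_index =
                 mean(mets$chemotactic_index, na.rm = TRUE),
               mean_speed = mean(mets$speed, na.rm = TRUE)))
    })
  }

  if (!is.null(stages$shape)) {
    cfg <- stages$shape
    log_env$defaults <- list()
    run_stage("shape", {
      ct <- read_contours_csv(require_path(cfg$path, "shape"))
      res <- circularity_series(ct)
      data.table::fwrite(res$per_contour,
                         file.path(out_dir, "circularity.tsv"), sep = "\t")
      add("shape", list(),
          list(n_contours = nrow(res$per_contour),
               mean_circularity = mean(res$per_contour$circularity)))
    })
  }

  if (!is.null(stages$halo)) {
    cfg <- stages$halo
    log_env$defaults <- list()
    run_stage("halo", {
      prof <- read_profile_csv(require_path(cfg$path, "halo"))
      marker <- default_of(cfg, "marker", "CD9", log_env)
      vessel <- default_of(cfg, "vessel", "podoplanin", log_env)
      smode <- default_of(cfg, "sigma_mode", "band", log_env)
      sw <- default_of(cfg, "smoothing_window", 3, log_env)
      pf <- default_of(cfg, "prominence_fraction", 0.1, log_env)
      hm <- diameter_ratio(prof, marker, vessel, smoothing_window = sw,
                           prominence_fraction = pf, sigma_mode = smode)
      add("halo",
          list(marker = marker, vessel = vessel, sigma_mode = smode,
               smoothing_window = sw, prominence_fraction = pf),
          list(sigma = as.list(hm$sigma_per_channel), ratio = hm$ratio,
               status = hm$status))
    })
  }

  if (!is.null(stages$proteomics)) {
    cfg <- stages$proteomics
    log_env$defaults <- list()
    run_stage("proteomics", {
      tab <- read_peptide_tsv(require_path(cfg$peptides, "proteomics"))
      meta <- read_sample_meta_json(require_path(cfg$meta, "proteomics"))
      alpha <- default_of(cfg, "alpha", 0.05, log_env)
      norm <- normalize_channels(tab, meta)
      ab <- top3(norm)
      quant <- ratios_and_significance(ab, norm, meta,
                                       treated = cfg$treated,
                                       reference = cfg$reference,
                                       alpha = alpha)
      data.table::fwrite(quant, file.path(out_dir, "protein_quant.tsv"),
                         sep = "\t")
      dens <- ratio_density(quant)
      data.table::fwrite(dens$histogram,
                         file.path(out_dir, "ratio_density.tsv"), sep = "\t")
      hmv <- heatmap_matrix(ab, meta, reference = cfg$reference)
      data.table::fwrite(
        data.table::data.table(protein_id = rownames(hmv), hmv),
        file.path(out_dir, "heatmap_matrix.tsv"), sep = "\t")
      enr_res <- NULL
      if (!is.null(cfg$clusters)) {
        cl <- read_gmt(require_path(cfg$clusters, "proteomics"))
        enr <- cluster_enrichment(ab, cl, meta)
        data.table::fwrite(enr, file.path(out_dir, "cluster_enrichment.tsv"),
                           sep = "\t")
        enr_res <- list(n_clusters = length(cl))
      }
      add("proteomics", list(alpha = alpha),
          list(n_proteins = nrow(quant),
               n_significant = sum(quant$significant, na.rm = TRUE),
               overall_fold_change = dens$overall_fold_change,
               clusters = enr_res))
    })
  }

  if (!is.null(stages$distance)) {
    cfg <- stages$distance
    log_env$defaults <- list()
    run_stage("distance", {
      if (is.null(cfg$xlim) || is.null(cfg$ylim)) {
        stop_bad("field extents xlim/ylim are required")
      }
      vm <- read_vessels_csv(require_path(cfg$vessels, "distance"),
                             as.numeric(cfg$xlim), as.numeric(cfg$ylim))
      pts <- read_points_csv(require_path(cfg$points, "distance"))
      n_mc <- default_of(cfg, "n_mc", 10000, log_env)
      res <- normalized_mean_distance(pts, vm, n_mc = n_mc, seed = seed)
      d <- min_distance_to_vessels(pts, vm)
      data.table::fwrite(data.table::data.table(x_um = pts[, 1],
                                                y_um = pts[, 2],
                                                min_distance_um = d),
                         file.path(out_dir, "point_distances.tsv"),
                         sep = "\t")
      add("distance", list(n_mc = n_mc, seed = seed), res)
    })
  }

  if (!is.null(stages$adhesion)) {
    cfg <- stages$adhesion
    log_env$defaults <- list()
    run_stage("adhesion", {
      ev <- read_events_csv(require_path(cfg$path, "adhesion"))
      md <- default_of(cfg, "min_duration_s", 3, log_env)
      fi <- default_of(cfg, "frame_interval_s", 1, log_env)
      n <- adherent_tracks(ev, md, fi)
      add("adhesion", list(min_duration_s = md, frame_interval_s = fi),
          list(n_adherent = n, n_cells = length(unique(ev$cell_id))))
    })
  }

  if (!is.null(stages$transwell)) {
    cfg <- stages$transwell
    log_env$defaults <- list()
    run_stage("transwell", {
      curve <- read_standard_curve_csv(require_path(cfg$curve, "transwell"))
      rd <- read_delim_checked(require_path(cfg$readings, "transwell"),
                               c("time_min", "replicate", "fluorescence"))
      res <- calibrate_transwell(curve, rd)
      data.table::fwrite(res$kinetics,
                         file.path(out_dir, "transwell_kinetics.tsv"),
                         sep = "\t")
      add("transwell", list(),
          list(slope = res$slope, intercept = res$intercept,
               final_mean_count =
                 res$kinetics$mean_count[nrow(res$kinetics)]))
    })
  }

  if (!is.null(stages$nta)) {
    cfg <- stages$nta
    log_env$defaults <- list()
    run_stage("nta", {
      reps <- lapply(cfg$paths, function(p) {
        read_histogram_csv(require_path(p, "nta"))
      })
      res <- nta_average(reps)
      data.table::fwrite(res$histogram,
                         file.path(out_dir, "nta_average.tsv"), sep = "\t")
      add("nta", list(n_replicates = length(reps)), res$summary)
    })
  }

  if (!is.null(stages$pore_coverage)) {
    cfg <- stages$pore_coverage
    log_env$defaults <- list()
    run_stage("pore_coverage", {
      d <- default_of(cfg, "diameter_um", 3, log_env)
      rho <- default_of(cfg, "density_per_cm2", 8e5, log_env)
      add("pore_coverage", list(diameter_um = d, density_per_cm2 = rho),
          list(coverage_percent = pore_coverage(d, rho)))
    })
  }

  if (!length(report$stages)) stop_bad("config requested no known stages")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
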