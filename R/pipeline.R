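#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages in dependency order with a single seed, writing
#' every artifact (CSV/JSON/TIFF) plus a JSON manifest recording the seed,
#' parameter echoes and MD5 checksums of all outputs, so any artifact is
#' regenerable from manifest + seed.
#'
#' Stages: `simulate_spt` (movie + ground truth), `track` (detection +
#' linking), `dynamics` (D1-4, mobility), `stoichiometry` (MSI, monomer
#' calibration, size classes), `simulate_rics` + `rics`,
#' `simulate_tracks` + `chemotaxis`, `simulate_lipids` + `lipidstats`.
#' Each analysis stage reads the files its simulation stage wrote, so the
#' pipeline also exercises the CSV/TIFF round trip.
#'
#' @param config a list (or path to a JSON file) with optional elements
#'   `stages` (character vector, default all), `seed` (default 1),
#'   `outdir` (default `tempdir()`), and per-stage parameter blocks
#'   (`spt`, `track`, `dynamics`, `stoichiometry`, `rics`, `chemotaxis`,
#'   `lipids`) overriding the generator/analysis defaults.
#' @return The manifest (list), invisibly written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  all_stages <- c("simulate_spt", "track", "dynamics", "stoichiometry",
                  "simulate_rics", "rics", "simulate_tracks", "chemotaxis",
                  "simulate_lipids", "lipidstats")
  stages <- config$stages %||% all_stages
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% file.path(tempdir(), "nanodyn_run")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop("stage '", stage, "': missing upstream output ", f)
    pth(f)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("nanodyn")),
                   seed = seed, stages = stages, params = list(),
                   outputs = list())

  if ("simulate_spt" %in% stages) {
    args <- config$spt %||% list()
    args$seed <- args$seed %||% seed
    cfg <- do.call(spt_sim_config, args)
    sim <- simulate_spt_movie(cfg)
    scale <- write_stack_tiff(sim$stack, pth("spt_movie.tif"))
    write.csv(sim$truth, pth("spt_truth.csv"), row.names = FALSE)
    # matched monomer-control acquisition for the intensity calibration;
    # field sized so the calibration sees enough particles
    mono_args <- unclass(cfg)
    mono_args$oligomer_probs <- 1
    mono_args$seed <- cfg$seed + 1000L
    mono_args$field_px <- max(cfg$field_px,
                              ceiling(sqrt(120 / cfg$density) /
                                      cfg$pixel_size))
    mono_cfg <- do.call(spt_sim_config, mono_args)
    mono_scale <- write_stack_tiff(simulate_spt_movie(mono_cfg)$stack,
                                   pth("monomer_movie.tif"))
    jsonlite::write_json(c(unclass(cfg), tiff_scale = scale,
                           monomer_tiff_scale = mono_scale),
                         pth("spt_config.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$params$simulate_spt <- unclass(cfg)
  }
  if ("track" %in% stages) {
    cfgj <- jsonlite::read_json(need("spt_config.json", "track"),
                                simplifyVector = TRUE)
    args <- config$track %||% list()
    track_one <- function(tif, scale, out) {
      stack <- read_stack_tiff(pth(tif), pixel_size = cfgj$pixel_size,
                               frame_interval = cfgj$frame_interval,
                               scale = scale)
      trajs <- track_movie(stack,
                           psf_sigma = args$psf_sigma %||%
                             (cfgj$psf_sigma / cfgj$pixel_size),
                           snr_threshold = args$snr_threshold %||% 5,
                           max_disp = args$max_disp %||% 4,
                           max_gap = args$max_gap %||% 2,
                           min_length = args$min_length %||% 20)
      write_trajectories_csv(trajs, pth(out))
    }
    need("spt_movie.tif", "track")
    track_one("spt_movie.tif", cfgj$tiff_scale, "trajectories.csv")
    if (file.exists(pth("monomer_movie.tif")))
      track_one("monomer_movie.tif", cfgj$monomer_tiff_scale,
                "monomer_trajectories.csv")
    manifest$params$track <- args
  }
  if ("dynamics" %in% stages) {
    trajs <- read_trajectories_csv(need("trajectories.csv", "dynamics"))
    args <- config$dynamics %||% list()
    set.seed(seed + 1)
    dyn <- analyze_dynamics(trajs, threshold = args$threshold)
    write.csv(as.data.frame(dyn), pth("dynamics.csv"), row.names = FALSE)
    summ <- population_summary(dyn, label = args$label %||% "sample")
    jsonlite::write_json(summ[c("label", "n", "pct_mobile", "pct_immobile",
                                "median_d14_mobile")],
                         pth("dynamics_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$params$dynamics <- args
  }
  if ("stoichiometry" %in% stages) {
    trajs <- read_trajectories_csv(need("trajectories.csv", "stoichiometry"))
    args <- config$stoichiometry %||% list()
    ref_mode <- args$monomer_ref %||% "control"
    msi_ref <- if (identical(ref_mode, "self")) {
      select_monomer_msi(trajs, first_n = args$first_n %||% 20)
    } else {
      mono <- read_trajectories_csv(need("monomer_trajectories.csv",
                                         "stoichiometry"))
      ids <- unique(mono$traj_id)
      vapply(ids, function(id)
        trajectory_msi(mono[mono$traj_id == id, ],
                       args$first_n %||% 20), 0)
    }
    cal <- fit_monomer_reference(msi_ref)
    sto <- analyze_stoichiometry(trajs, cal, first_n = args$first_n %||% 20)
    write.csv(as.data.frame(sto), pth("stoichiometry.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(cal), pth("monomer_calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$params$stoichiometry <- args
  }
  if ("simulate_rics" %in% stages) {
    args <- config$rics_sim %||% list()
    args$seed <- args$seed %||% seed
    cfg <- do.call(rics_sim_config, args)
    stk <- simulate_rics_series(cfg)
    write_stack_tiff(stk, pth("rics_series.tif"))
    jsonlite::write_json(unclass(cfg), pth("rics_config.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$params$simulate_rics <- unclass(cfg)
  }
  if ("rics" %in% stages) {
    cfgj <- jsonlite::read_json(need("rics_config.json", "rics"),
                                simplifyVector = TRUE)
    stk <- read_stack_tiff(need("rics_series.tif", "rics"),
                           pixel_size = cfgj$pixel_size)
    args <- config$rics %||% list()
    params <- raster_params(pixel_size = cfgj$pixel_size,
                            dwell_time = cfgj$dwell_time,
                            line_time = cfgj$line_time,
                            w0 = args$w0 %||% cfgj$w0,
                            roi_size = args$roi_size %||% 64,
                            window = args$window %||% 10)
    set.seed(seed + 2)
    res <- rics_analyze(stk, params, n_rois = args$n_rois %||% 4)
    jsonlite::write_json(list(d_mean = res$d_mean,
                              d_values = res$d_values,
                              n_converged = res$n_converged,
                              params = unclass(params)),
                         pth("rics_fit.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$params$rics <- unclass(params)
  }
  if ("simulate_tracks" %in% stages) {
    args <- config$chemotaxis_sim %||% list()
    args$seed <- args$seed %||% seed
    cfg <- do.call(chemotaxis_sim_config, args)
    write_tracks_csv(simulate_chemotaxis_tracks(cfg), pth("cell_tracks.csv"))
    manifest$params$simulate_tracks <- unclass(cfg)
  }
  if ("chemotaxis" %in% stages) {
    tracks <- read_tracks_csv(need("cell_tracks.csv", "chemotaxis"))
    metrics <- track_metrics(tracks)
    write.csv(as.data.frame(metrics), pth("chemotaxis_metrics.csv"),
              row.names = FALSE)
    sp <- spider_plot_data(tracks)
    write.csv(sp$endpoints, pth("spider_endpoints.csv"), row.names = FALSE)
    manifest$params$chemotaxis <- list()
  }
  if ("simulate_lipids" %in% stages) {
    args <- config$lipid_sim %||% list()
    args$seed <- args$seed %||% seed
    cfg <- do.call(lipid_sim_config, args)
    write_lipid_csv(simulate_lipid_table(cfg), pth("lipid_table.csv"))
    manifest$params$simulate_lipids <-
      unclass(cfg)[setdiff(names(cfg), "fold_changes")]
  }
  if ("lipidstats" %in% stages) {
    tab <- read_lipid_csv(need("lipid_table.csv", "lipidstats"))
    args <- config$lipids %||% list()
    res <- lipid_stats_pipeline(tab, alpha = args$alpha %||% 0.05,
                                cv_threshold = args$cv_threshold %||% 10)
    write.csv(as.data.frame(res), pth("lipid_results.csv"),
              row.names = FALSE)
    manifest$params$lipidstats <- args
  }

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demonstration: recover generator settings end to end
#'
#' Simulates a resting-state and a ligand-stimulated-like condition
#' (higher nanocluster fraction, slower diffusion), runs tracking,
#' dynamics and stoichiometry on both, and returns the per-condition
#' mobile percentage, median D1-4 and size-class fractions side by side
#' with the generator truth.
#'
#' @param seed integer seed.
#' @param field_px,n_frames movie geometry (kept modest by default so the
#'   demo runs in seconds).
#' @return A data frame with one row per condition.
#' @export
nanodyn_demo <- function(seed = 1L, field_px = 96, n_frames = 40) {
  conditions <- list(
    control = list(oligomer_probs = c(0.40, 0.25, 0.20, 0.15),
                   d_mobile = 0.017, mobile_frac = 0.82),
    stimulated = list(oligomer_probs = c(0.22, 0.18, 0.30, 0.30),
                      d_mobile = 0.007, mobile_frac = 0.70))
  # matched monomer-control acquisition for the intensity calibration
  mono_cfg <- spt_sim_config(field_px = field_px, n_frames = n_frames,
                             density = 0.3, oligomer_probs = 1,
                             seed = seed + 1000L)
  mono <- track_movie(simulate_spt_movie(mono_cfg)$stack,
                      psf_sigma = mono_cfg$psf_sigma / mono_cfg$pixel_size,
                      min_length = 20)
  mono_msi <- vapply(unique(mono$traj_id), function(id)
    trajectory_msi(mono[mono$traj_id == id, ]), 0)
  cal <- fit_monomer_reference(mono_msi)
  rows <- lapply(names(conditions), function(cn) {
    p <- conditions[[cn]]
    cfg <- spt_sim_config(field_px = field_px, n_frames = n_frames,
                          density = 0.3, oligomer_probs = p$oligomer_probs,
                          d_mobile = p$d_mobile, mobile_frac = p$mobile_frac,
                          seed = seed + match(cn, names(conditions)))
    sim <- simulate_spt_movie(cfg)
    trajs <- track_movie(sim$stack, psf_sigma = cfg$psf_sigma / cfg$pixel_size,
                         min_length = 20)
    set.seed(seed + 10)
    dyn <- analyze_dynamics(trajs)
    summ <- population_summary(dyn, cn)
    sto <- analyze_stoichiometry(trajs, cal)
    truth_ge3 <- sum(p$oligomer_probs[-(1:2)])
    data.frame(condition = cn, n_traj = summ$n,
               pct_mobile = summ$pct_mobile,
               true_pct_mobile = 100 * p$mobile_frac,
               median_d14 = summ$median_d14_mobile,
               true_d = p$d_mobile,
               frac_ge3 = mean(sto$size_class == ">=3"),
               true_frac_ge3 = truth_ge3,
               monomer_mean = cal$mean)
  })
  do.call(rbind, rows)
}
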