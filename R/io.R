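#' Default pipeline configuration
#'
#' A plain, fully serializable list of every pipeline parameter: paths,
#' calibration constants, protocol choice, preprocessing, GLM and
#' simulation options. Every run record embeds the resolved configuration
#' together with the master seed, since the calibrated estimates depend on
#' the assumed physiological parameters.
#'
#' @param out_dir Root output directory.
#' @param ... Named overrides of any default entry.
#' @return A named list.
#' @export
default_config <- function(out_dir = tempfile("laminarbold_"), ...) {
  cfg <- list(
    out_dir = out_dir,
    n_subjects = 8L,
    alt_subjects = integer(0),
    grid = c(40L, 40L, 22L),
    levels = c("+5", "+10"),
    alt_levels = c("+3", "+8"),
    sequences = c("GE", "SE"),
    params = calib_params(),
    tsnr = 50,
    drift_amp = 0.01,
    transition_tau = 15,
    gas_noise_sd = 0.5,
    jitter_sd = 0.05,
    fwhm_mm = 2.35,
    cutoff_hz = 0.003,
    alpha = 0.05,
    co2_plateau_frac = 0.5,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

## --- writers -------------------------------------------------------------

write_tsv <- function(df, path, sidecar = NULL) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_vol <- function(arr, path, voxel_mm = c(1, 1, 1), tr = NULL) {
  pixdim <- if (is.null(tr)) voxel_mm else c(voxel_mm, tr)
  img <- RNifti::asNifti(arr, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

protocol_to_list <- function(protocol) {
  list(blocks = protocol$blocks, tr = protocol$tr,
       baseline_petco2 = protocol$baseline_petco2,
       baseline_peto2 = protocol$baseline_peto2,
       levels = protocol$levels, hyperoxia = protocol$hyperoxia,
       total_s = protocol$total_s, n_volumes = protocol$n_volumes)
}

protocol_from_list <- function(doc) {
  structure(list(blocks = as.data.frame(doc$blocks), tr = doc$tr,
                 baseline_petco2 = doc$baseline_petco2,
                 baseline_peto2 = doc$baseline_peto2,
                 levels = as.character(doc$levels %||% character(0)),
                 hyperoxia = isTRUE(doc$hyperoxia),
                 total_s = doc$total_s,
                 n_volumes = as.integer(doc$n_volumes)),
            class = "gas_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated input bundle to disk
#'
#' Generates the complete input bundle for every subject and sequence of a
#' configuration and writes it in standard formats: 4D NIfTI-1 functional
#' series, NIfTI-1 label volumes (depth layers, ROI, vein flag), TSV gas /
#' respiration / pulse / motion traces with JSON sidecars carrying sampling
#' rate and units, a protocol JSON, and a ground-truth record (JSON index
#' plus NIfTI maps) for recovery scoring. Deterministic under a fixed seed.
#'
#' @param config A [default_config()] list.
#' @return Invisibly, the output directory. A `run.json` record with the
#'   resolved configuration and seed is written at the root.
#' @export
run_simulate <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- make_slab(config$grid)
  lab_dir <- file.path(config$out_dir, "labels")
  dir.create(lab_dir, showWarnings = FALSE)
  write_vol(labels$depth, file.path(lab_dir, "depth.nii.gz"))
  write_vol(labels$roi, file.path(lab_dir, "roi.nii.gz"))
  write_vol(labels$vein + 0L, file.path(lab_dir, "vein.nii.gz"))

  for (s in seq_len(config$n_subjects)) {
    levels <- if (s %in% config$alt_subjects) config$alt_levels
              else config$levels
    for (sq in config$sequences) {
      bundle <- simulate_session(
        labels, sq, levels, config$params, config$tsnr, config$drift_amp,
        config$transition_tau, config$gas_noise_sd, config$jitter_sd,
        seed = derive_seed(config$seed, s, sq == "SE"))
      sdir <- file.path(config$out_dir, sprintf("sub-%02d", s), sq)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(protocol_to_list(bundle$protocol),
                           file.path(sdir, "protocol.json"),
                           auto_unbox = TRUE, digits = NA)
      write_vol(bundle$series$data, file.path(sdir, "bold.nii.gz"),
                tr = bundle$protocol$tr)
      write_tsv(bundle$traces, file.path(sdir, "gas.tsv"),
                sidecar = list(sampling = "per volume",
                               units = list(time_s = "s", petco2 = "mmHg",
                                            peto2 = "mmHg")))
      fs <- attr(bundle$physio, "fs")
      write_tsv(bundle$physio$respiration, file.path(sdir, "respiration.tsv"),
                sidecar = list(sampling_frequency_hz = fs, units = "a.u."))
      write_tsv(bundle$physio$pulse, file.path(sdir, "pulse.tsv"),
                sidecar = list(sampling_frequency_hz = fs, units = "a.u."))
      write_tsv(bundle$motion, file.path(sdir, "motion.tsv"),
                sidecar = list(units = "mm (trans), deg (rot)"))
      tdir <- file.path(sdir, "truth")
      dir.create(tdir, showWarnings = FALSE)
      write_vol(bundle$truth$m_true, file.path(tdir, "m_true.nii.gz"))
      write_vol(bundle$truth$cvr_true, file.path(tdir, "cvr_true.nii.gz"))
      for (lev in names(bundle$truth$cbv_ratio_true))
        write_vol(bundle$truth$cbv_ratio_true[[lev]],
                  file.path(tdir, sprintf("cbv_ratio_%s.nii.gz", lev)))
      jsonlite::write_json(
        list(sequence = sq, s0 = bundle$truth$s0, seed = bundle$seed,
             levels = levels,
             bin_summary = truth_bin_summary(bundle$truth, labels)),
        file.path(tdir, "truth.json"), auto_unbox = TRUE, digits = NA)
      rm(bundle)
    }
  }
  jsonlite::write_json(config_record(config),
                       file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

config_record <- function(config) {
  rec <- config
  rec$params <- unclass(config$params)
  rec
}

read_session_bundle <- function(sdir, labels) {
  proto <- protocol_from_list(jsonlite::fromJSON(file.path(sdir, "protocol.json")))
  traces <- utils::read.delim(file.path(sdir, "gas.tsv"))
  attr(traces, "protocol") <- proto
  class(traces) <- c("gas_traces", "data.frame")
  dat <- RNifti::readNifti(file.path(sdir, "bold.nii.gz"))
  series <- structure(list(data = array(as.numeric(dat), dim(dat)),
                           tr = proto$tr, voxel_mm = c(1, 1, 1)),
                      class = "functional_series")
  physio <- list(
    respiration = utils::read.delim(file.path(sdir, "respiration.tsv")),
    pulse = utils::read.delim(file.path(sdir, "pulse.tsv")))
  attr(physio, "fs") <-
    jsonlite::fromJSON(file.path(sdir, "respiration.json"))$sampling_frequency_hz
  motion <- utils::read.delim(file.path(sdir, "motion.tsv"))
  list(protocol = proto, traces = traces, series = series, motion = motion,
       physio = physio, labels = labels,
       sequence = basename(sdir))
}

read_labels <- function(out_dir) {
  lab_dir <- file.path(out_dir, "labels")
  depth <- RNifti::readNifti(file.path(lab_dir, "depth.nii.gz"))
  roi <- RNifti::readNifti(file.path(lab_dir, "roi.nii.gz"))
  vein <- RNifti::readNifti(file.path(lab_dir, "vein.nii.gz"))
  structure(list(depth = array(as.integer(depth), dim(depth)),
                 roi = array(as.integer(roi), dim(roi)),
                 vein = array(as.integer(vein) > 0L, dim(vein)),
                 roi_names = c("V1", "V2", "V3"),
                 n_layers = max(depth), depth_axis = 3L,
                 voxel_mm = c(1, 1, 1)),
            class = "label_volume")
}

#' Fit the pipeline to an input bundle on disk
#'
#' Reads every session written by [run_simulate()], checks the bundle is
#' complete before any computation, runs [fit_session()], and writes per
#' session: the selection mask and the CVR / M / CBV-change maps as
#' NIfTI-1, the selected-voxel table as TSV, and a QC JSON. Group depth
#' profiles and GE/SE ratios are written as TSV at the root.
#'
#' @param config The [default_config()] list used for simulation (the run
#'   record in the bundle is authoritative for paths).
#' @return Invisibly, the output directory (`<out_dir>/derived`).
#' @export
run_fit <- function(config = default_config()) {
  out <- config$out_dir
  sdirs <- list.dirs(out, recursive = FALSE)
  sdirs <- sort(grep("sub-", sdirs, value = TRUE))
  missing <- character(0)
  need <- c("protocol.json", "bold.nii.gz", "gas.tsv", "respiration.tsv",
            "pulse.tsv", "motion.tsv")
  sessions <- list()
  for (sd in sdirs)
    for (sq in list.dirs(sd, recursive = FALSE)) {
      sessions[[length(sessions) + 1L]] <- sq
      missing <- c(missing, file.path(sq, need)[!file.exists(file.path(sq, need))])
    }
  if (!file.exists(file.path(out, "labels", "depth.nii.gz")))
    missing <- c(missing, file.path(out, "labels", "depth.nii.gz"))
  if (length(missing))
    stop("incomplete input bundle; missing:\n  ",
         paste(missing, collapse = "\n  "))
  if (!length(sessions)) stop("no sessions found under ", out)

  labels <- read_labels(out)
  der <- file.path(out, "derived")
  dir.create(der, showWarnings = FALSE)
  all_vox <- list()
  for (sq in sessions) {
    bundle <- read_session_bundle(sq, labels)
    fit <- fit_session(bundle, config$params, config$fwhm_mm,
                       config$cutoff_hz, config$alpha,
                       config$co2_plateau_frac)
    rel <- sub(paste0("^", out, "/?"), "", sq)
    fdir <- file.path(der, rel)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    write_vol(fit$selected + 0L, file.path(fdir, "selected.nii.gz"))
    maps <- session_maps(fit, labels)
    for (nm in names(maps))
      write_vol(maps[[nm]], file.path(fdir, paste0(nm, ".nii.gz")))
    write_tsv(fit$voxels, file.path(fdir, "voxels.tsv"))
    jsonlite::write_json(fit$qc, file.path(fdir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    v <- fit$voxels
    v$subject <- as.integer(sub("^sub-", "", basename(dirname(sq))))
    v$sequence <- basename(sq)
    all_vox[[length(all_vox) + 1L]] <- v
    rm(bundle, fit)
  }
  voxels <- merge_voxel_frames(all_vox)
  metrics <- c("m_pct", "cvr", grep("^dcbv_", names(voxels), value = TRUE))
  for (sq in unique(voxels$sequence))
    write_tsv(depth_profiles(voxels[voxels$sequence == sq, ], metrics),
              file.path(der, paste0("profiles_", sq, ".tsv")))
  if (all(c("GE", "SE") %in% voxels$sequence))
    write_tsv(sequence_ratio(
      depth_profiles(voxels[voxels$sequence == "GE", ], metrics),
      depth_profiles(voxels[voxels$sequence == "SE", ], metrics)),
      file.path(der, "ratios_GE_over_SE.tsv"))
  invisible(der)
}

## Scatter selected-voxel metrics back into full-grid maps (NA elsewhere).
session_maps <- function(fit, labels) {
  shape <- dim(labels$depth)
  out <- list()
  for (nm in c("m_pct", "cvr",
               grep("^(dbold|dcbv)_", names(fit$voxels), value = TRUE))) {
    arr <- array(NA_real_, shape)
    arr[fit$voxels$voxel] <- fit$voxels[[nm]]
    out[[nm]] <- arr
  }
  names(out) <- sub("\\+", "", names(out)) # file-system safe
  out
}

#' Score fitted maps against the stored ground truth
#'
#' Reads the fitted per-session voxel tables and the ground-truth records
#' written by [run_simulate()] / [run_fit()] and writes a JSON recovery
#' report with per-session and per-bin relative errors plus pass/fail
#' against the configured tolerances.
#'
#' @param config The configuration used for the run.
#' @param tol_bin Tolerance on per-bin group relative error.
#' @return The report, invisibly; written to
#'   `<out_dir>/derived/recovery.json`.
#' @export
run_recover <- function(config = default_config(), tol_bin = 0.10) {
  out <- config$out_dir
  der <- file.path(out, "derived")
  labels <- read_labels(out)
  bin <- bin_layers(labels$depth)
  sess <- list()
  for (sd in sort(grep("sub-", list.dirs(out, recursive = FALSE),
                       value = TRUE)))
    for (sq in list.dirs(sd, recursive = FALSE)) {
      vox_path <- file.path(der, sub(paste0("^", out, "/?"), "", sq),
                            "voxels.tsv")
      truth_path <- file.path(sq, "truth")
      if (!file.exists(vox_path))
        stop("missing fit output ", vox_path, "; run run_fit() first")
      vox <- utils::read.delim(vox_path, check.names = FALSE)
      truth_m <- RNifti::readNifti(file.path(truth_path, "m_true.nii.gz"))
      truth_cvr <- RNifti::readNifti(file.path(truth_path, "cvr_true.nii.gz"))
      if (!all(dim(truth_m) == dim(labels$depth)))
        stop("ground-truth grid does not match label grid")
      per_bin <- lapply(1:3, function(b) {
        sel <- vox$bin == b
        idx <- vox$voxel[sel]
        list(bin = b,
             m_rel = mean(vox$m_pct[sel], na.rm = TRUE) /
                     (mean(truth_m[idx]) * 100) - 1,
             cvr_rel = mean(vox$cvr[sel], na.rm = TRUE) /
                       mean(truth_cvr[idx]) - 1)
      })
      sess[[paste(basename(sd), basename(sq), sep = "_")]] <- per_bin
    }
  errs <- unlist(sess)
  errs <- errs[!grepl("\\.bin$", names(errs))]
  report <- list(tolerance = tol_bin,
                 max_abs_rel_error = max(abs(errs)),
                 pass = max(abs(errs)) <= tol_bin,
                 sessions = sess)
  jsonlite::write_json(report, file.path(der, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' One-command demonstration run
#'
#' Chains simulate, fit and recover on a reduced grid with the default
#' physiological parameters; all randomness flows from one master seed.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_subjects,grid Reduced problem size for a quick run.
#' @return The recovery report, invisibly.
#' @export
run_demo <- function(out_dir = tempfile("laminarbold_demo_"), seed = 1L,
                     n_subjects = 2L, grid = c(14L, 14L, 22L)) {
  cfg <- default_config(out_dir, n_subjects = n_subjects, grid = grid,
                        seed = seed)
  message("simulating ", n_subjects, " subjects under ", out_dir)
  run_simulate(cfg)
  message("fitting")
  run_fit(cfg)
  message("scoring recovery")
  rep <- run_recover(cfg)
  message(sprintf("max |relative error| per bin: %.3f (tolerance %.2f) -> %s",
                  rep$max_abs_rel_error, rep$tolerance,
                  if (rep$pass) "PASS" else "FAIL"))
  invisible(rep)
}
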