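## Derive a stream of sub-seeds from one master seed, keeping everything in
## 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed) %% 2147483647
  for (p in parts) s <- (s * 1009 + as.double(p) * 131 + 17) %% 2147483647
  as.integer(s)
}

#' Simulate one complete laminar gas-challenge session
#'
#' Chains the generator stages: protocol, gas traces, ground truth, forward
#' BOLD simulation, and nuisance (motion, respiration, pulse) traces, all
#' driven from one seed.
#'
#' @param labels A [make_slab()] label volume.
#' @param sequence `"GE"` or `"SE"`.
#' @param levels Hypercapnia levels for this session.
#' @param params A [calib_params()] object.
#' @param tsnr Temporal SNR of the series (`Inf` = noiseless).
#' @param drift_amp Drift amplitude, fraction of baseline signal.
#' @param transition_tau Gas settling time constant, s.
#' @param gas_noise_sd Breath-to-breath PetCO2 noise, mmHg.
#' @param jitter_sd Voxel-level log-normal jitter of the ground truth.
#' @param seed Master seed for the session.
#' @return A session bundle: list with `protocol`, `traces`, `truth`,
#'   `series`, `motion`, `physio`, `labels`, `sequence`, `seed`.
#' @export
simulate_session <- function(labels, sequence = "GE",
                             levels = c("+5", "+10"),
                             params = calib_params(),
                             tsnr = 50, drift_amp = 0.01,
                             transition_tau = 15, gas_noise_sd = 0.5,
                             jitter_sd = 0.05, seed = 1L) {
  protocol <- make_protocol(levels = levels)
  traces <- make_gas_traces(protocol, transition_tau, gas_noise_sd,
                            seed = derive_seed(seed, 1))
  truth <- make_ground_truth(labels, sequence, params, jitter_sd,
                             seed = derive_seed(seed, 2))
  series <- simulate_bold(truth, traces, protocol, params, tsnr, drift_amp,
                          seed = derive_seed(seed, 3))
  motion <- make_motion_params(protocol$n_volumes,
                               seed = derive_seed(seed, 4))
  physio <- make_physio_traces(protocol, seed = derive_seed(seed, 5))
  list(protocol = protocol, traces = traces, truth = truth, series = series,
       motion = motion, physio = physio, labels = labels,
       sequence = sequence, seed = seed)
}

#' Fit the calibrated-BOLD pipeline to one session
#'
#' Runs the full estimation chain on a session bundle: depth/ROI-restricted
#' smoothing, discrete-cosine high-pass filtering, percent-signal-change
#' rescaling, the binary-regressor GLM with nuisance regressors,
#' Holm-Bonferroni voxel selection on the omnibus gas test, and the three
#' headline maps (CVR, M, per-condition CBV change) on the selected voxels.
#'
#' @param bundle A [simulate_session()] bundle (or an equivalent list built
#'   from files on disk).
#' @param params A [calib_params()] object.
#' @param fwhm_mm Smoothing kernel FWHM, mm (0 disables smoothing).
#' @param cutoff_hz High-pass cutoff, Hz.
#' @param alpha Familywise error level for voxel selection.
#' @param co2_plateau_frac Fraction of each hypercapnic block used for the
#'   measured plateau PetCO2 (see [gas_block_summary()]).
#' @return A `session_fit`: list with `voxels` (data.frame of selected
#'   voxels: depth, bin, roi, %BOLD per condition, `m_pct`, `cvr`, per
#'   condition `dcbv_*`), `glm`, `selected` (logical array), `gas`, `qc`.
#' @export
fit_session <- function(bundle, params = calib_params(), fwhm_mm = 2.35,
                        cutoff_hz = 0.003, alpha = 0.05,
                        co2_plateau_frac = 0.5) {
  protocol <- bundle$protocol
  labels <- bundle$labels
  if (!protocol$hyperoxia)
    stop("the session has no hyperoxia block: the M-value calibration ",
         "(and hence the CBV inversion) requires one")

  ser <- masked_gaussian_smooth(bundle$series, labels, fwhm_mm)
  ser <- dct_highpass(ser, cutoff_hz)
  ser <- percent_signal_change(ser)

  vt <- volume_times(protocol)
  fs <- attr(bundle$physio, "fs")
  nuis <- cbind(as.matrix(bundle$motion),
                rvt = rvt(bundle$physio$respiration, fs, vt),
                bpm = bpm(bundle$physio$pulse, fs, vt))
  design <- build_design(protocol, nuis)
  # apply the same high-pass projection to the regressors (Frisch-Waugh:
  # identical to adding the DCT basis to the model), so filtering the data
  # does not bias the condition betas
  flt <- colnames(design) != "intercept"
  design[, flt] <- dct_highpass(design[, flt, drop = FALSE], cutoff_hz,
                                protocol$tr)
  fit <- fit_glm(ser, design)

  bin <- bin_layers(labels$depth)
  inmask <- !is.na(bin) & labels$roi > 0L
  selected <- array(FALSE, dim(labels$depth))
  selected[inmask] <- holm_select(fit$p_gas[which(inmask)], alpha)

  gas <- gas_block_summary(bundle$traces, protocol, co2_plateau_frac)
  hc <- condition_labels(protocol, "hc")
  ho <- condition_labels(protocol, "ho")
  # percent signal change is taken against the whole-series mean; rescaling
  # by the intercept (the baseline level in PSC units) converts the plateau
  # betas to percent of the condition baseline, which is what the
  # calibration model is written in
  to_base <- 100 / (100 + fit$beta[, "intercept"])
  beta_ho <- fit$beta[, ho] * to_base
  betas_hc <- fit$beta[, hc, drop = FALSE] * to_base
  # effective deoxyhemoglobin contrast of the hyperoxia challenge: the
  # response tracks the measured PetO2 trace, so the binary beta represents
  # the component of the trace-shaped response the (filtered) regressor
  # captures; running the trace-derived shape through the same GLM yields
  # exactly that component per unit M, for any settling dynamics. For an
  # ideal step trace this reduces to 1 - [dHb]v/[dHb]v0 at the block mean.
  h <- 1 - dhb_ratio_trace(gas$baseline_peto2, bundle$traces$peto2, params)
  cvec <- fit_glm(matrix(h, ncol = 1), design)$beta[1, ]
  g <- cvec[[ho]]
  if (!is.finite(g) || g <= 0)
    stop("uninformative hyperoxia challenge: no deoxyhemoglobin contrast ",
         "in the measured PetO2 trace")
  m_pct <- m_value(beta_ho / 100, 1 - g, params) * 100
  # the same trace-shaped component leaks into the other condition betas
  # with known coefficients (per unit M); remove that leakage exactly
  betas_hc <- betas_hc - outer(beta_ho / g, cvec[hc])
  m_pct[!is.na(m_pct) & m_pct <= 0] <- NA_real_ # implausible: excluded
  cvr <- cvr_fit(gas$dpetco2[hc], betas_hc)
  dcbv <- compute_cbv_map(betas_hc, m_pct, params)

  idx <- which(selected)
  vox <- data.frame(voxel = idx, depth = labels$depth[idx], bin = bin[idx],
                    roi = labels$roi[idx], vein = labels$vein[idx],
                    m_pct = m_pct[idx], cvr = cvr[idx],
                    check.names = FALSE)
  vox[[paste0("dbold_", ho)]] <- beta_ho[idx]
  for (lab in hc) {
    vox[[paste0("dbold_", lab)]] <- betas_hc[idx, lab]
    vox[[paste0("dcbv_", lab)]] <- dcbv[idx, lab]
  }
  qc <- list(n_inmask = sum(inmask), n_selected = length(idx),
             n_psc_invalid = attr(ser, "invalid_voxels"),
             n_m_implausible = sum(is.na(m_pct[idx])),
             n_cbv_flagged = sum(is.na(dcbv[idx, , drop = FALSE]) &
                                   !is.na(betas_hc[idx, , drop = FALSE])))
  structure(list(voxels = vox, glm = fit, selected = selected, gas = gas,
                 qc = qc, design = design,
                 sequence = bundle$sequence),
            class = "session_fit")
}

#' Per-voxel parameter recovery of one fitted session
#'
#' Compares the recovered maps of a fitted session with the generating
#' ground truth, voxel by voxel, over the selected voxels.
#'
#' @param fit A [fit_session()] result.
#' @param truth The [make_ground_truth()] object that generated the session.
#' @return List with per-metric vectors of relative errors and their
#'   maxima (`max_rel_error`, named by metric).
#' @export
recover_voxels <- function(fit, truth) {
  stopifnot(inherits(fit, "session_fit"), inherits(truth, "ground_truth"))
  vox <- fit$voxels
  idx <- vox$voxel
  rel <- list(m = abs(vox$m_pct / (truth$m_true[idx] * 100) - 1),
              cvr = abs(vox$cvr / truth$cvr_true[idx] - 1))
  for (nm in names(vox)[startsWith(names(vox), "dcbv_")]) {
    lev <- hc_level(sub("^dcbv_", "", nm))
    truth_pct <- (truth$cbv_ratio_true[[lev]][idx] - 1) * 100
    rel[[paste0("dcbv", lev)]] <- abs(vox[[nm]] / truth_pct - 1)
  }
  list(rel_error = rel,
       max_rel_error = vapply(rel, max, numeric(1), na.rm = TRUE))
}

#' Multi-subject parameter-recovery study
#'
#' Simulates and fits a group of synthetic subjects for both GE-like and
#' SE-like contrasts, aggregates the selected-voxel maps into depth
#' profiles, forms GE/SE ratios, and scores group-level recovery against
#' the generating ground truth. A subset of subjects can be assigned the
#' alternative +3/+8 mmHg session, mirroring an unbalanced design in which
#' not every participant performs every level.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param grid Slab dimensions passed to [make_slab()].
#' @param tsnr Temporal SNR (`Inf` = noiseless).
#' @param alt_subjects Indices of subjects given the +3/+8 session.
#' @param params A [calib_params()] object.
#' @param seed Master seed.
#' @param ... Further arguments passed to [simulate_session()] and
#'   [fit_session()] (`drift_amp`, `transition_tau`, `gas_noise_sd`,
#'   `jitter_sd`, `fwhm_mm`, `cutoff_hz`, `alpha`, `co2_plateau_frac`).
#' @return A `recovery_study`: list with `voxels` (pooled data.frame),
#'   `profiles` (per-sequence depth profiles), `ratios` (GE/SE), `truth`
#'   (group ground-truth bin means), `recovery` (per sequence/metric/bin
#'   recovered vs truth and relative error), `qc`.
#' @export
recovery_study <- function(n_subjects = 8, grid = c(40, 40, 22), tsnr = 50,
                           alt_subjects = integer(0),
                           params = calib_params(), seed = 1L, ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% c("drift_amp", "transition_tau",
                                      "gas_noise_sd", "jitter_sd")]
  fit_args <- dots[names(dots) %in% c("fwhm_mm", "cutoff_hz", "alpha",
                                      "co2_plateau_frac")]
  labels <- make_slab(grid)
  all_vox <- list()
  truth_bins <- list()
  qc <- list()
  for (s in seq_len(n_subjects)) {
    levels <- if (s %in% alt_subjects) c("+3", "+8") else c("+5", "+10")
    for (sq in c("GE", "SE")) {
      bundle <- do.call(simulate_session,
                        c(list(labels = labels, sequence = sq,
                               levels = levels, params = params, tsnr = tsnr,
                               seed = derive_seed(seed, s, sq == "SE")),
                          sim_args))
      fit <- do.call(fit_session, c(list(bundle = bundle, params = params),
                                    fit_args))
      v <- fit$voxels
      if (nrow(v)) {
        v$subject <- s
        v$sequence <- sq
        all_vox[[length(all_vox) + 1L]] <- v
      }
      tb <- truth_bin_summary(bundle$truth, labels)
      tb$subject <- s
      truth_bins[[length(truth_bins) + 1L]] <- tb
      qc[[paste0("s", s, "_", sq)]] <- fit$qc
      rm(bundle, fit)
    }
  }
  voxels <- merge_voxel_frames(all_vox)
  tb <- do.call(rbind, truth_bins)

  metrics <- c("m_pct", "cvr",
               grep("^dcbv_", names(voxels), value = TRUE))
  profiles <- lapply(c(GE = "GE", SE = "SE"), function(sq)
    depth_profiles(voxels[voxels$sequence == sq, ], metrics))
  ratios <- sequence_ratio(profiles$GE, profiles$SE)

  truth_group <- truth_group_summary(tb)
  recovery <- score_recovery(profiles, truth_group)
  structure(list(voxels = voxels, profiles = profiles, ratios = ratios,
                 truth = truth_group, recovery = recovery, qc = qc,
                 n_subjects = n_subjects, tsnr = tsnr, seed = seed),
            class = "recovery_study")
}

## rbind voxel data.frames whose condition columns may differ (unbalanced
## sessions): missing columns become NA.
merge_voxel_frames <- function(frames) {
  cols <- unique(unlist(lapply(frames, names)))
  do.call(rbind, lapply(frames, function(f) {
    for (nm in setdiff(cols, names(f))) f[[nm]] <- NA
    f[, cols]
  }))
}

## Across-subject mean of the per-subject ground-truth bin summaries,
## reshaped to align with depth_profiles output.
truth_group_summary <- function(tb) {
  num <- setdiff(names(tb), c("bin", "bin_name", "n", "sequence", "subject"))
  out <- list()
  for (sq in unique(tb$sequence)) {
    for (b in unique(tb$bin)) {
      sub <- tb[tb$sequence == sq & tb$bin == b, ]
      for (met in num) {
        val <- mean(sub[[met]])
        prof_met <- if (met == "m_pct") "m_pct"
                    else if (met == "cvr") "cvr"
                    else sub("^dcbv\\+", "dcbv_hc+", met)
        out[[length(out) + 1L]] <- data.frame(
          sequence = sq, metric = prof_met, bin = b, truth = val)
      }
    }
  }
  do.call(rbind, out)
}

## Join recovered profiles with group truth and compute relative errors.
score_recovery <- function(profiles, truth_group) {
  rec <- do.call(rbind, lapply(names(profiles), function(sq) {
    p <- profiles[[sq]]
    p$sequence <- sq
    p
  }))
  mrg <- merge(rec, truth_group, by = c("sequence", "metric", "bin"))
  mrg$rel_error <- abs(mrg$mean / mrg$truth - 1)
  mrg[order(mrg$sequence, mrg$metric, mrg$bin),
      c("sequence", "metric", "bin", "bin_name", "mean", "sem",
        "n_subjects", "truth", "rel_error")]
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Recovery study: %d subjects, tSNR = %g, %d selected voxels\n",
              x$n_subjects, x$tsnr, nrow(x$voxels)))
  print(x$recovery, row.names = FALSE)
  invisible(x)
}
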