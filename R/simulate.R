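#' Simulate a laminar BOLD session from ground truth
#'
#' Forward-generates a 4D functional series. Each voxel's signal is
#' `s(t) = s0 * (1 + f_hc(t) + f_ho(t)) + drift(t) + noise(t)`:
#'
#' * `f_hc` is a square plateau during each hypercapnic block, equal to the
#'   Davis forward model evaluated at that block's ground-truth volume ratio
#'   and metabolic scaling (the vasodilatory response is modeled at block
#'   level, which is what binary-regressor fitting estimates);
#' * `f_ho` tracks the PetO2 trace sample by sample,
#'   `m_true * (1 - [dHb]v/[dHb]v0 (t))`, so the hyperoxic response carries
#'   the trace's settling dynamics and noise;
#' * `drift` is a half-cycle cosine of amplitude `drift_amp * s0` (a slow
#'   scanner drift, well below the high-pass cutoff);
#' * `noise` is white Gaussian with standard deviation `s0 / tsnr`
#'   (`tsnr = Inf` gives a noiseless series).
#'
#' @param truth A [make_ground_truth()] object.
#' @param traces A [make_gas_traces()] data.frame.
#' @param protocol The matching protocol.
#' @param params A [calib_params()] object.
#' @param tsnr Temporal signal-to-noise ratio (> 0; `Inf` for noiseless).
#' @param drift_amp Drift amplitude as a fraction of `s0`.
#' @param seed Integer seed for the noise draws.
#' @return A `functional_series`: list with 4D `data` (x, y, z, t), `tr`,
#'   `voxel_mm`.
#' @export
simulate_bold <- function(truth, traces, protocol, params = truth$params,
                          tsnr = 50, drift_amp = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "gas_protocol"))
  if (!(tsnr > 0)) stop("tsnr must be > 0")
  nt <- protocol$n_volumes
  if (nrow(traces) != nt)
    stop("gas traces and protocol disagree on sample count")
  shape <- dim(truth$m_true)
  nv <- prod(shape)
  in_ctx <- !is.na(truth$m_true)

  # voxel x time response matrix, built from outer products per block
  resp <- matrix(0, nrow = sum(in_ctx), ncol = nt)
  blk <- volume_blocks(protocol)
  for (lab in condition_labels(protocol, "hc")) {
    lev <- hc_level(lab)
    v <- truth$cbv_ratio_true[[lev]][in_ctx]
    b <- forward_bold_hypercapnia(v, cmro2_ratio_for(params, lev),
                                  truth$m_true[in_ctx], params)
    resp[, blk == lab] <- resp[, blk == lab] + b
  }
  if (protocol$hyperoxia) {
    base_o2 <- mean(traces$peto2[blk == "baseline"])
    r <- dhb_ratio_trace(base_o2, traces$peto2, params)
    resp <- resp + truth$m_true[in_ctx] %o% (1 - r)
  }

  t_s <- volume_times(protocol)
  drift <- drift_amp * truth$s0 * cos(pi * t_s / protocol$total_s)

  dat <- matrix(truth$s0, nrow = nv, ncol = nt)
  dat[in_ctx, ] <- truth$s0 * (1 + resp)
  dat <- sweep(dat, 2, drift, "+")
  if (is.finite(tsnr))
    dat <- dat + with_seed(seed, matrix(stats::rnorm(nv * nt, 0, truth$s0 / tsnr),
                                        nv, nt))
  structure(list(data = array(dat, c(shape, nt)), tr = protocol$tr,
                 voxel_mm = c(1, 1, 1)),
            class = "functional_series")
}

#' @export
print.functional_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Functional series %s, %d volumes, TR = %g s\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr))
  invisible(x)
}

#' Synthetic respiration and pulse traces
#'
#' Quasi-periodic respiratory-belt and pulse-unit traces consistent with
#' RVT / BPM extraction: a breathing oscillation around 16 breaths/min with
#' slowly varying amplitude and rate, and a cardiac oscillation around
#' 66 beats/min with slowly varying rate.
#'
#' @param protocol A [make_protocol()] object (sets the duration).
#' @param fs Sampling frequency, Hz.
#' @param seed Integer seed.
#' @return List of two data.frames `respiration` and `pulse` (columns
#'   `time_s`, `value`) with attribute `fs`.
#' @export
make_physio_traces <- function(protocol, fs = 50, seed = 1L) {
  stopifnot(inherits(protocol, "gas_protocol"), fs > 1)
  t <- seq(0, protocol$total_s, by = 1 / fs)
  n <- length(t)
  draws <- with_seed(seed, stats::rnorm(6))
  slow <- function(k, f) sin(2 * pi * f * t + draws[k])

  resp_rate <- (16 + 1.5 * slow(1, 0.004)) / 60     # breaths per second
  resp_amp <- 1 + 0.15 * slow(2, 0.006)
  resp <- resp_amp * sin(2 * pi * cumsum(resp_rate) / fs + draws[3])

  card_rate <- (66 + 3 * slow(4, 0.005)) / 60       # beats per second
  pulse <- sin(2 * pi * cumsum(card_rate) / fs + draws[5])

  out <- list(respiration = data.frame(time_s = t, value = resp),
              pulse = data.frame(time_s = t, value = pulse))
  attr(out, "fs") <- fs
  out
}

#' Synthetic rigid-body motion parameters
#'
#' Six slowly wandering motion time courses (3 translations in mm, 3
#' rotations in degrees) modeled as small-amplitude AR(1) random walks, used
#' as nuisance regressors.
#'
#' @param n_volumes Number of volumes.
#' @param scale Innovation standard deviation (mm or degrees per volume).
#' @param seed Integer seed.
#' @return data.frame with columns `trans_x..z`, `rot_x..z`.
#' @export
make_motion_params <- function(n_volumes, scale = 0.01, seed = 1L) {
  stopifnot(n_volumes > 1)
  eps <- with_seed(seed, matrix(stats::rnorm(n_volumes * 6, 0, scale),
                                n_volumes, 6))
  mot <- apply(eps, 2, function(e) stats::filter(e, 0.98, "recursive"))
  mot <- as.data.frame(mot)
  names(mot) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  mot
}
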