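#' Synthesize end-tidal gas traces for a protocol
#'
#' Per-volume PetCO2 and PetO2 time courses: the protocol's piecewise-constant
#' targets, smoothed by a first-order exponential approach with time constant
#' `transition_tau` (the sequential gas delivery system reaches its targets
#' over a few breaths), plus additive Gaussian breath-to-breath noise. The
#' O2 trace gets 10x the CO2 noise standard deviation, matching the much
#' larger excursion and breath-to-breath variability of end-tidal O2.
#'
#' @param protocol A [make_protocol()] object.
#' @param transition_tau Exponential settling time constant, s (>= 0;
#'   0 gives exact step functions).
#' @param noise_sd Breath-to-breath noise standard deviation on PetCO2, mmHg
#'   (>= 0). PetO2 noise is `10 * noise_sd`.
#' @param seed Integer seed for the noise draws.
#' @return A `gas_traces` data.frame with columns `time_s`, `petco2`,
#'   `peto2` (one row per volume), carrying the protocol as an attribute.
#' @export
make_gas_traces <- function(protocol, transition_tau = 15, noise_sd = 0.5,
                            seed = 1L) {
  stopifnot(inherits(protocol, "gas_protocol"))
  if (transition_tau < 0) stop("transition_tau must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  t <- volume_times(protocol)
  blk <- volume_blocks(protocol)
  b <- protocol$blocks
  tco2 <- protocol$baseline_petco2 + b$dpetco2[match(blk, b$label)]
  to2 <- protocol$baseline_peto2 + b$dpeto2[match(blk, b$label)]

  settle <- function(target, tau, dt) {
    if (tau == 0) return(target)
    a <- 1 - exp(-dt / tau)
    y <- numeric(length(target))
    y[1] <- target[1] # steady state at the initial target
    for (k in 2:length(target)) y[k] <- y[k - 1] + a * (target[k] - y[k - 1])
    y
  }

  co2 <- settle(tco2, transition_tau, protocol$tr)
  o2 <- settle(to2, transition_tau, protocol$tr)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * length(co2), 0, noise_sd))
    co2 <- co2 + noise[seq_along(co2)]
    o2 <- o2 + 10 * noise[length(co2) + seq_along(o2)]
  }
  out <- data.frame(time_s = t, petco2 = co2, peto2 = o2)
  attr(out, "protocol") <- protocol
  class(out) <- c("gas_traces", "data.frame")
  out
}

## Evaluate `expr` under a private RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards so generator calls compose predictably.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Measured block-plateau gas values
#'
#' Summarizes a gas trace into the quantities the model stages consume: the
#' baseline-block means of PetCO2 and PetO2, the plateau PetCO2 of each
#' hypercapnic block (measured over the settled part of the block), and the
#' full-block mean PetO2 of the hyperoxic block.
#'
#' The hypercapnic plateau uses the last `co2_plateau_frac` of each block
#' because the binary-regressor BOLD estimate represents the settled plateau
#' response; averaging the exponential approach into the estimate would
#' understate the stimulus. The hyperoxic value keeps the full-block mean:
#' the hyperoxic BOLD response tracks the O2 trace itself, and the venous
#' deoxyhemoglobin ratio is nearly affine in PetO2 above arterial saturation,
#' so the full-block mean is the unbiased pairing there.
#'
#' @param traces A [make_gas_traces()] data.frame.
#' @param protocol The matching protocol (defaults to the one attached to
#'   `traces`).
#' @param co2_plateau_frac Fraction (from the end) of each hypercapnic block
#'   used for the plateau mean, in (0, 1].
#' @return List with `baseline_petco2`, `baseline_peto2`, `dpetco2` (named
#'   by hypercapnic block label), `peto2_ho` and `dpeto2` for the hyperoxic
#'   block (NA when absent).
#' @export
gas_block_summary <- function(traces, protocol = attr(traces, "protocol"),
                              co2_plateau_frac = 0.5) {
  stopifnot(inherits(protocol, "gas_protocol"),
            co2_plateau_frac > 0, co2_plateau_frac <= 1)
  blk <- volume_blocks(protocol)
  t <- traces$time_s
  b <- protocol$blocks
  base <- blk == "baseline"
  base_co2 <- mean(traces$petco2[base])
  base_o2 <- mean(traces$peto2[base])

  hc <- b[b$condition == "hc", , drop = FALSE]
  dpetco2 <- vapply(seq_len(nrow(hc)), function(i) {
    t0 <- hc$onset_s[i] + (1 - co2_plateau_frac) * hc$duration_s[i]
    sel <- blk == hc$label[i] & t >= t0
    mean(traces$petco2[sel]) - base_co2
  }, numeric(1))
  names(dpetco2) <- hc$label

  ho <- b[b$condition == "ho", , drop = FALSE]
  peto2_ho <- if (nrow(ho)) mean(traces$peto2[blk == ho$label[1]]) else NA_real_

  list(baseline_petco2 = base_co2, baseline_peto2 = base_o2,
       dpetco2 = dpetco2, peto2_ho = peto2_ho,
       dpeto2 = peto2_ho - base_o2)
}
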