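#' Gas-challenge breathing protocol
#'
#' Build the block design of the breathing task: a long normocapnic
#' baseline, one 120 s hypercapnic block per requested end-tidal CO2 step
#' (consecutive steps are connected, with no return to baseline in
#' between), and a terminal 120 s hyperoxic block (+350 mmHg end-tidal O2).
#' A gas-transition buffer at baseline targets precedes the hypercapnic
#' group and the hyperoxic block; the CO2 washout after the hypercapnic
#' group happens there, before the hyperoxic block, and the hyperoxic block
#' ends the scan. The default session (levels +5
#' and +10) lasts 697 s, which at TR = 0.85 s is exactly 820 volumes; the
#' alternative session swaps in the +3 and +8 mmHg steps.
#'
#' @param levels Character vector of hypercapnia level labels, a subset of
#'   `c("+3", "+5", "+8", "+10")`, in presentation order.
#' @param hyperoxia Include the +350 mmHg end-tidal O2 block (default TRUE).
#' @param baseline_s Leading baseline duration, s.
#' @param block_s Gas-block duration, s.
#' @param transition_s Gas-transition duration before the hypercapnic group
#'   and before the hyperoxic block, s. The default pads the default
#'   two-level session to the 697 s scan.
#' @param tr Repetition time, s.
#' @param baseline_petco2,baseline_peto2 Baseline end-tidal tensions, mmHg.
#' @param dpeto2 Hyperoxic end-tidal O2 step, mmHg.
#' @return A `gas_protocol`: list with `blocks` (data.frame: label,
#'   condition, onset_s, duration_s, dpetco2, dpeto2), `tr`,
#'   `baseline_petco2`, `baseline_peto2`, `total_s`, `n_volumes`.
#' @export
#' @examples
#' p <- make_protocol()
#' p$total_s     # 697
#' p$n_volumes   # 820
make_protocol <- function(levels = c("+5", "+10"),
                          hyperoxia = TRUE,
                          baseline_s = 200,
                          block_s = 120,
                          transition_s = 68.5,
                          tr = 0.85,
                          baseline_petco2 = 40,
                          baseline_peto2 = 100,
                          dpeto2 = 350) {
  known <- c("+3", "+5", "+8", "+10")
  levels <- as.character(levels)
  if (length(levels) && !all(levels %in% known))
    stop("unknown hypercapnia level label(s): ",
         paste(setdiff(levels, known), collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  stopifnot(tr > 0, baseline_s >= 0, block_s > 0, transition_s >= 0)

  lab <- "baseline"; cond <- "baseline"; dur <- baseline_s
  dpetco2 <- 0; dpo2 <- 0
  if (length(levels)) {
    lab <- c(lab, "transition-hc", paste0("hc", levels))
    cond <- c(cond, "transition", rep("hc", length(levels)))
    dur <- c(dur, transition_s, rep(block_s, length(levels)))
    dpetco2 <- c(dpetco2, 0, as.numeric(levels))
    dpo2 <- c(dpo2, rep(0, length(levels) + 1L))
  }
  if (hyperoxia) {
    lab <- c(lab, "transition-ho", paste0("ho+", dpeto2))
    cond <- c(cond, "transition", "ho")
    dur <- c(dur, transition_s, block_s)
    dpetco2 <- c(dpetco2, 0, 0)
    dpo2 <- c(dpo2, 0, dpeto2)
  }

  blocks <- data.frame(label = lab, condition = cond,
                       onset_s = cumsum(c(0, dur[-length(dur)])),
                       duration_s = dur, dpetco2 = dpetco2, dpeto2 = dpo2,
                       stringsAsFactors = FALSE)
  total_s <- sum(dur)
  structure(list(blocks = blocks, tr = tr,
                 baseline_petco2 = baseline_petco2,
                 baseline_peto2 = baseline_peto2,
                 levels = levels, hyperoxia = hyperoxia,
                 total_s = total_s,
                 n_volumes = as.integer(round(total_s / tr))),
            class = "gas_protocol")
}

#' @export
print.gas_protocol <- function(x, ...) {
  cat(sprintf("Gas protocol: %g s, %d volumes at TR = %g s\n",
              x$total_s, x$n_volumes, x$tr))
  cat(sprintf("  baseline PetCO2 = %g mmHg, PetO2 = %g mmHg\n",
              x$baseline_petco2, x$baseline_peto2))
  print(x$blocks)
  invisible(x)
}

#' Volume acquisition times of a protocol
#'
#' Mid-volume times `(k - 1/2) * TR`, used both to sample gas traces per
#' volume and to assign volumes to blocks.
#'
#' @param protocol A `gas_protocol`.
#' @return Numeric vector of length `n_volumes`, s.
#' @export
volume_times <- function(protocol) {
  stopifnot(inherits(protocol, "gas_protocol"))
  (seq_len(protocol$n_volumes) - 0.5) * protocol$tr
}

#' Per-volume block membership
#'
#' @param protocol A `gas_protocol`.
#' @return Character vector of block labels, one per volume (a volume belongs
#'   to the block containing its mid-volume time).
#' @export
volume_blocks <- function(protocol) {
  stopifnot(inherits(protocol, "gas_protocol"))
  tmid <- volume_times(protocol)
  b <- protocol$blocks
  idx <- findInterval(tmid, c(b$onset_s, protocol$total_s),
                      rightmost.closed = TRUE)
  b$label[pmin(pmax(idx, 1L), nrow(b))]
}

#' Gas-condition block labels of a protocol
#'
#' @param protocol A `gas_protocol`.
#' @param conditions Which condition classes to return.
#' @return Character vector of block labels (e.g. `"hc+5"`, `"ho+350"`).
#' @export
condition_labels <- function(protocol, conditions = c("hc", "ho")) {
  stopifnot(inherits(protocol, "gas_protocol"))
  b <- protocol$blocks
  b$label[b$condition %in% conditions]
}

## Hypercapnia level ("+5") from a block label ("hc+5").
hc_level <- function(label) sub("^hc", "", label)
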