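## Depth anchors for the ground-truth generator. Values are the group depth
## profiles reported for 7 T human visual cortex: the M-value rises from 9%
## (deepest included layer) to 21% (most superficial) for GE-like contrast
## and to 16% for SE-like; CVR rises 0.39 -> 0.64 %BOLD/mmHg (GE) and
## 0.18 -> 0.25 (SE); the +10 mmHg blood-volume response is depth-constant
## at 12.5% (GE) and 8.5% (SE).
truth_anchors <- function(sequence = c("GE", "SE")) {
  sequence <- match.arg(sequence)
  if (sequence == "GE")
    list(m_pct = c(9, 21), cvr = c(0.39, 0.64), dcbv10_pct = 12.5)
  else
    list(m_pct = c(9, 16), cvr = c(0.18, 0.25), dcbv10_pct = 8.5)
}

#' Per-voxel ground truth for the synthetic slab
#'
#' Assigns every in-cortex voxel an M-value, a cerebrovascular reactivity
#' (CVR) and per-condition venous blood-volume ratios, interpolated linearly
#' across the included depth layers (2 to `n_layers - 1`) between
#' sequence-specific deep and superficial anchors, with optional
#' multiplicative log-normal voxel jitter.
#'
#' The per-condition blood-volume ratios are constructed so that the model
#' is exactly self-consistent with both the CVR and the blood-volume
#' anchors: the +10 mmHg condition gets the anchored volume change, the
#' hypercapnic BOLD plateaus are placed on a straight line in measured
#' end-tidal CO2 step with slope equal to the voxel's CVR through the +10
#' point, and each remaining condition's volume ratio is obtained by exact
#' Davis-model inversion of its plateau. A noiseless pipeline run therefore
#' recovers M, CVR and every per-condition volume change to machine
#' precision.
#'
#' @param labels A [make_slab()] label volume.
#' @param sequence `"GE"` (all-venous contrast) or `"SE"` (micro-vascular).
#' @param params A [calib_params()] object.
#' @param jitter_sd Standard deviation of the log-normal voxel jitter applied
#'   independently to M, CVR and the +10 volume change (0 disables it).
#' @param s0 Baseline signal level (arbitrary scanner units).
#' @param seed Integer seed for the jitter draws.
#' @return A `ground_truth`: arrays `m_true` (fraction), `cvr_true`
#'   (%BOLD/mmHg), `dcbv10_true` (%), and `cbv_ratio_true` (named list of
#'   arrays, one per hypercapnia level), plus `s0`, `sequence`, `params`.
#'   Out-of-cortex voxels are NA.
#' @export
make_ground_truth <- function(labels, sequence = c("GE", "SE"),
                              params = calib_params(), jitter_sd = 0.05,
                              s0 = 1000, seed = 1L) {
  stopifnot(inherits(labels, "label_volume"), jitter_sd >= 0, s0 > 0)
  sequence <- match.arg(sequence)
  anc <- truth_anchors(sequence)
  depth <- labels$depth
  nl <- labels$n_layers
  incl <- depth >= 2L & depth <= nl - 1L # layers adjacent to WM/CSF excluded
  in_ctx <- depth > 0L

  # linear depth interpolation over included layers; the excluded boundary
  # layers take the nearest anchor value (they never enter depth profiles)
  frac <- (pmin(pmax(depth, 2L), nl - 1L) - 2) / (nl - 3)
  shape <- dim(depth)
  m <- array(NA_real_, shape)
  cvr <- array(NA_real_, shape)
  d10 <- array(NA_real_, shape)
  m[in_ctx] <- (anc$m_pct[1] + diff(anc$m_pct) * frac[in_ctx]) / 100
  cvr[in_ctx] <- anc$cvr[1] + diff(anc$cvr) * frac[in_ctx]
  d10[in_ctx] <- anc$dcbv10_pct

  if (jitter_sd > 0) {
    n <- sum(in_ctx)
    jit <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3))
    m[in_ctx] <- m[in_ctx] * exp(jit[, 1])
    cvr[in_ctx] <- cvr[in_ctx] * exp(jit[, 2])
    d10[in_ctx] <- d10[in_ctx] * exp(jit[, 3])
  }

  # anchored-line construction of per-condition volume ratios
  levels_all <- names(params$cmro2_ratio)
  steps <- as.numeric(levels_all)
  q10 <- cmro2_ratio_for(params, "+10")
  v10 <- 1 + d10 / 100
  b10 <- forward_bold_hypercapnia(v10[in_ctx], q10, m[in_ctx], params)
  cbv <- stats::setNames(vector("list", length(levels_all)), levels_all)
  for (i in seq_along(levels_all)) {
    arr <- array(NA_real_, shape)
    if (levels_all[i] == "+10") {
      arr[in_ctx] <- v10[in_ctx]
    } else {
      b <- b10 - cvr[in_ctx] / 100 * (10 - steps[i])
      arr[in_ctx] <- invert_cbv(b, m[in_ctx],
                                cmro2_ratio_for(params, levels_all[i]), params)
    }
    cbv[[i]] <- arr
  }

  structure(list(m_true = m, cvr_true = cvr, dcbv10_true = d10,
                 cbv_ratio_true = cbv, s0 = s0, sequence = sequence,
                 included = incl, params = params),
            class = "ground_truth")
}

#' Ground-truth depth-bin summary
#'
#' Mean ground-truth M, CVR and per-condition volume change within each of
#' the three depth bins, for comparison with recovered group profiles.
#'
#' @param truth A [make_ground_truth()] object.
#' @param labels The matching label volume.
#' @return data.frame with one row per depth bin.
#' @export
truth_bin_summary <- function(truth, labels) {
  stopifnot(inherits(truth, "ground_truth"), inherits(labels, "label_volume"))
  bin <- bin_layers(labels$depth)
  out <- do.call(rbind, lapply(1:3, function(b) {
    sel <- !is.na(bin) & bin == b
    row <- data.frame(bin = b, bin_name = c("deep", "middle", "superficial")[b],
                      n = sum(sel),
                      m_pct = mean(truth$m_true[sel]) * 100,
                      cvr = mean(truth$cvr_true[sel]))
    for (lev in names(truth$cbv_ratio_true))
      row[[paste0("dcbv", lev)]] <- mean(truth$cbv_ratio_true[[lev]][sel] - 1) * 100
    row
  }))
  out$sequence <- truth$sequence
  out
}
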