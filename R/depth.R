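#' Collapse 20 depth layers into 3 depth bins
#'
#' The two boundary layers (1, adjacent to white matter; 20, adjacent to
#' CSF) are excluded; the remaining 18 layers are downsampled by a factor of
#' 6 into deep (2-7), middle (8-13) and superficial (14-19) bins.
#'
#' @param depth_index Integer layer indices in 0-20 (0 = outside cortex).
#'   Vectorized (arrays keep their shape).
#' @return Integer bins 1-3 (`NA` for excluded/outside voxels), with
#'   attribute `bin_names`.
#' @export
#' @examples
#' bin_layers(c(1, 2, 7, 8, 13, 14, 19, 20))
bin_layers <- function(depth_index) {
  if (any(depth_index < 0 | depth_index > 20, na.rm = TRUE))
    stop("depth index out of range 0-20")
  bin <- ifelse(depth_index >= 2 & depth_index <= 19,
                (depth_index - 2) %/% 6 + 1, NA_integer_)
  if (is.array(depth_index)) dim(bin) <- dim(depth_index)
  attr(bin, "bin_names") <- c("deep", "middle", "superficial")
  bin
}

#' Cerebrovascular reactivity: %BOLD per mmHg CO2
#'
#' Least-squares slope (with intercept) of the per-condition hypercapnic
#' %BOLD estimates against the measured end-tidal CO2 increases. Rows with
#' fewer than two available conditions get `NA` (undefined, not zero),
#' which handles sessions missing the +3/+8 levels.
#'
#' @param dpetco2 Measured end-tidal CO2 increases, mmHg (one per
#'   condition).
#' @param dbold_hc Voxel-by-condition matrix of %BOLD estimates (or a
#'   vector for a single voxel). NA marks a missing condition.
#' @return Numeric CVR per voxel, %BOLD/mmHg.
#' @export
#' @examples
#' cvr_fit(c(0, 5, 10), c(0, 2, 4)) # 0.4
cvr_fit <- function(dpetco2, dbold_hc) {
  if (is.vector(dbold_hc)) dbold_hc <- matrix(dbold_hc, nrow = 1)
  stopifnot(ncol(dbold_hc) == length(dpetco2))
  ok <- !is.na(dbold_hc)
  nok <- rowSums(ok)
  x <- matrix(dpetco2, nrow(dbold_hc), length(dpetco2), byrow = TRUE)
  x[!ok] <- NA
  xbar <- rowMeans(x, na.rm = TRUE)
  ybar <- rowMeans(dbold_hc, na.rm = TRUE)
  xc <- x - xbar
  yc <- dbold_hc - ybar
  slope <- rowSums(xc * yc, na.rm = TRUE) / rowSums(xc^2, na.rm = TRUE)
  slope[nok < 2] <- NA_real_
  slope
}

#' Voxelwise M-value map from the hyperoxic response
#'
#' Applies the hyperoxia calibration to per-voxel %BOLD estimates for the
#' hyperoxic condition, using the venous deoxyhemoglobin ratio implied by
#' the measured baseline and hyperoxic-block end-tidal O2.
#'
#' @param dbold_ho_pct Per-voxel hyperoxic %BOLD estimates.
#' @param po2_baseline Baseline-block mean end-tidal O2, mmHg.
#' @param po2_ho Hyperoxic-block mean end-tidal O2, mmHg.
#' @param params A [calib_params()] object.
#' @return Per-voxel M in percent.
#' @export
compute_m_map <- function(dbold_ho_pct, po2_baseline, po2_ho,
                          params = calib_params()) {
  r <- hyperoxia_dhb_ratio(po2_baseline, po2_ho, params)
  if (r >= 1)
    stop("uninformative hyperoxia challenge: deoxyhemoglobin ratio >= 1")
  m_value(dbold_ho_pct / 100, r, params) * 100
}

#' Voxelwise blood-volume change maps
#'
#' Inverts the Davis model per hypercapnic condition to the venous CBV
#' change in percent. Voxels that violate model preconditions (non-positive
#' M, or %BOLD at or above M: model saturation) get `NA` and are counted in
#' the `n_flagged` attribute.
#'
#' @param dbold_hc_pct Voxel-by-condition matrix of hypercapnic %BOLD
#'   estimates; columns named by condition label (e.g. `"hc+10"`).
#' @param m_pct Per-voxel M in percent.
#' @param params A [calib_params()] object.
#' @return Voxel-by-condition matrix of CBV changes in percent, with
#'   attribute `n_flagged`.
#' @export
compute_cbv_map <- function(dbold_hc_pct, m_pct, params = calib_params()) {
  if (is.vector(dbold_hc_pct)) dbold_hc_pct <- as.matrix(dbold_hc_pct)
  out <- dbold_hc_pct * NA_real_
  flagged <- 0L
  for (j in seq_len(ncol(dbold_hc_pct))) {
    lev <- hc_level(colnames(dbold_hc_pct)[j])
    q <- cmro2_ratio_for(params, lev)
    d <- dbold_hc_pct[, j] / 100
    m <- m_pct / 100
    ok <- !is.na(d) & !is.na(m) & m > 0 & d < m
    flagged <- flagged + sum(!ok & !is.na(d))
    out[ok, j] <- (invert_cbv(d[ok], m[ok], q, params) - 1) * 100
  }
  attr(out, "n_flagged") <- flagged
  out
}

#' Depth profiles across subjects
#'
#' Two-stage aggregation matching group laminar profiles: voxel values are
#' first averaged within (subject, depth bin), then bin means and standard
#' errors are taken across subjects.
#'
#' @param maps data.frame of selected voxels with at least columns
#'   `subject`, `bin`, and the metric columns named in `metrics`.
#' @param metrics Character vector of metric column names.
#' @return data.frame with columns `metric`, `bin`, `bin_name`, `mean`,
#'   `sem` (0 for a single subject), `n_subjects`.
#' @export
depth_profiles <- function(maps, metrics) {
  stopifnot(all(c("subject", "bin") %in% names(maps)),
            all(metrics %in% names(maps)))
  bins <- sort(unique(maps$bin[!is.na(maps$bin)]))
  out <- list()
  for (met in metrics) {
    for (b in bins) {
      sub <- maps[!is.na(maps$bin) & maps$bin == b & !is.na(maps[[met]]), ]
      if (!nrow(sub)) next
      per_subj <- tapply(sub[[met]], sub$subject, mean)
      ns <- length(per_subj)
      out[[length(out) + 1L]] <- data.frame(
        metric = met, bin = b,
        bin_name = c("deep", "middle", "superficial")[b],
        mean = mean(per_subj),
        sem = if (ns > 1) stats::sd(per_subj) / sqrt(ns) else 0,
        n_subjects = ns)
    }
  }
  do.call(rbind, out)
}

#' GE/SE ratio of depth profiles
#'
#' Elementwise ratio of two depth profiles (e.g. gradient-echo over
#' spin-echo) per metric and bin, with the standard error propagated to
#' first order: `se(r) = r * sqrt((se_a/a)^2 + (se_b/b)^2)`.
#'
#' @param profile_num,profile_den Outputs of [depth_profiles()] with
#'   matching metric/bin rows.
#' @return data.frame with `metric`, `bin`, `bin_name`, `ratio`, `sem`.
#' @export
sequence_ratio <- function(profile_num, profile_den) {
  key <- c("metric", "bin")
  mrg <- merge(profile_num, profile_den, by = key,
               suffixes = c("_num", "_den"))
  if (!nrow(mrg)) stop("profiles share no (metric, bin) rows")
  if (any(mrg$mean_den == 0)) stop("zero denominator in profile ratio")
  r <- mrg$mean_num / mrg$mean_den
  sem <- abs(r) * sqrt((mrg$sem_num / mrg$mean_num)^2 +
                       (mrg$sem_den / mrg$mean_den)^2)
  data.frame(metric = mrg$metric, bin = mrg$bin,
             bin_name = mrg$bin_name_num, ratio = r, sem = sem)
}
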