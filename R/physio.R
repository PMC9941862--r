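#' Hemoglobin oxygen saturation (Severinghaus)
#'
#' Empirical human oxyhemoglobin dissociation curve,
#' `S = 1 / (23400 / (PO2^3 + 150 PO2) + 1)`, with PO2 in mmHg.
#' Strictly increasing and bounded in (0, 1).
#'
#' @param po2 Partial pressure of O2, mmHg (> 0). Vectorized.
#' @return Saturation fraction in (0, 1).
#' @export
#' @examples
#' severinghaus_saturation(100) # ~0.977
severinghaus_saturation <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 <= 0))
    stop("po2 must be finite and > 0")
  1 / (23400 / (po2^3 + 150 * po2) + 1)
}

#' Arterial oxygen content
#'
#' Hemoglobin-bound plus dissolved oxygen:
#' `CaO2 = phi * Hb * SaO2(PO2) + eps * PO2` (mL O2/dL).
#'
#' @param po2 Partial pressure of O2, mmHg (> 0). Vectorized.
#' @param params A [calib_params()] object.
#' @return Arterial O2 content, mL O2/dL.
#' @export
arterial_o2_content <- function(po2, params = calib_params()) {
  stopifnot(inherits(params, "calib_params"))
  params$phi * params$hb * severinghaus_saturation(po2) + params$eps * po2
}

## Venous dHb fraction chain shared by the ratio operations. Assumes CBF and
## CMRO2 unchanged by hyperoxia, so the arterio-venous O2 content difference
## stays at its baseline value OEF0 * CaO2(baseline). Venous dissolved O2 is
## neglected when converting content to saturation; SvO2 is capped at 1.
venous_state <- function(po2, cao2_baseline, params) {
  cao2 <- arterial_o2_content(po2, params)
  cvo2 <- cao2 - params$oef0 * cao2_baseline
  svo2 <- pmin(cvo2 / (params$phi * params$hb), 1)
  list(cao2 = cao2, cvo2 = cvo2, svo2 = svo2, dhb_fraction = 1 - svo2)
}

#' Venous deoxyhemoglobin ratio under hyperoxia
#'
#' Fractional change in venous deoxyhemoglobin, `[dHb]v / [dHb]v0`, when the
#' arterial O2 tension rises from `po2_baseline` to `po2_hyper` with CBF and
#' CMRO2 assumed unchanged (mild hyperoxia). The arterio-venous O2 content
#' difference is held constant at `OEF0 * CaO2(baseline)`; venous saturation
#' follows from the venous content (dissolved venous O2 neglected, saturation
#' capped at 1) and the ratio is `(1 - SvO2_hyper) / (1 - SvO2_baseline)`.
#'
#' @param po2_baseline Baseline arterial (end-tidal) O2 tension, mmHg.
#' @param po2_hyper Hyperoxic arterial O2 tension, mmHg; vectorized, each
#'   `>= po2_baseline`.
#' @param params A [calib_params()] object.
#' @return Dimensionless ratio in (0, 1].
#' @export
#' @examples
#' hyperoxia_dhb_ratio(100, 450) # ~0.75 with defaults
hyperoxia_dhb_ratio <- function(po2_baseline, po2_hyper,
                                params = calib_params()) {
  stopifnot(inherits(params, "calib_params"), length(po2_baseline) == 1L)
  if (po2_baseline <= 0 || any(po2_hyper <= 0))
    stop("oxygen tensions must be > 0")
  if (any(po2_hyper < po2_baseline))
    stop("po2_hyper must be >= po2_baseline")
  dhb_ratio_trace(po2_baseline, po2_hyper, params)
}

## Unchecked vectorized version used to drive simulation from a measured
## (noisy) PetO2 trace, where samples may dip below the baseline mean.
dhb_ratio_trace <- function(po2_baseline, po2_trace, params) {
  cao2_b <- arterial_o2_content(po2_baseline, params)
  base <- venous_state(po2_baseline, cao2_b, params)
  if (base$dhb_fraction <= 0)
    stop("degenerate baseline state: venous blood fully saturated ",
         "(no baseline deoxyhemoglobin)")
  st <- venous_state(po2_trace, cao2_b, params)
  st$dhb_fraction / base$dhb_fraction
}

#' M-value from the hyperoxic BOLD response
#'
#' The calibration scaling factor M (theoretical maximum fractional BOLD
#' change at complete deoxyhemoglobin washout), estimated from the
#' hyperoxia-induced fractional BOLD change and the venous deoxyhemoglobin
#' ratio: `M = dBOLD / (1 - r^beta)`.
#'
#' @param dbold_ho Fractional BOLD change during hyperoxia (not percent).
#'   Vectorized.
#' @param dhb_ratio `[dHb]v / [dHb]v0` during hyperoxia, in (0, 1).
#' @param params A [calib_params()] object.
#' @return Fractional M. Vectorized over `dbold_ho`.
#' @export
m_value <- function(dbold_ho, dhb_ratio, params = calib_params()) {
  stopifnot(inherits(params, "calib_params"))
  if (any(!is.finite(dbold_ho))) stop("dbold_ho must be finite")
  if (any(dhb_ratio <= 0 | dhb_ratio >= 1))
    stop("dhb_ratio must lie in (0, 1); a ratio of 1 means the hyperoxia ",
         "challenge carried no deoxyhemoglobin contrast")
  dbold_ho / (1 - dhb_ratio^params$beta)
}

#' Grubb flow-volume coupling
#'
#' Venous blood-volume ratio implied by a flow ratio via the power law
#' `CBV/CBV0 = (CBF/CBF0)^alpha`.
#'
#' @param cbf_ratio CBF/CBF0, > 0. Vectorized.
#' @param params A [calib_params()] object.
#' @return CBV/CBV0.
#' @export
grubb_cbv_ratio <- function(cbf_ratio, params = calib_params()) {
  stopifnot(inherits(params, "calib_params"))
  if (any(!is.finite(cbf_ratio)) || any(cbf_ratio <= 0))
    stop("cbf_ratio must be finite and > 0")
  cbf_ratio^params$alpha
}

#' Davis forward model for the hypercapnic BOLD response
#'
#' Fractional BOLD change produced by a venous blood-volume change and a
#' metabolic change, with flow eliminated through Grubb coupling:
#' `dBOLD = M * (1 - v^(1 - beta/alpha) * q^beta)` where `v = CBV/CBV0` and
#' `q = CMRO2/CMRO2|0`.
#'
#' @param cbv_ratio CBV/CBV0, > 0. Vectorized.
#' @param cmro2_ratio CMRO2/CMRO2|0, in (0, 1].
#' @param m Fractional M-value (>= 0).
#' @param params A [calib_params()] object.
#' @return Fractional BOLD change.
#' @export
#' @examples
#' forward_bold_hypercapnia(1.1, 0.95, 0.14) # ~0.0492
forward_bold_hypercapnia <- function(cbv_ratio, cmro2_ratio, m,
                                     params = calib_params()) {
  stopifnot(inherits(params, "calib_params"))
  if (any(cbv_ratio <= 0)) stop("cbv_ratio must be > 0")
  if (any(cmro2_ratio <= 0 | cmro2_ratio > 1))
    stop("cmro2_ratio must lie in (0, 1]")
  if (any(m < 0)) stop("m must be >= 0")
  expo <- 1 - params$beta / params$alpha
  m * (1 - cbv_ratio^expo * cmro2_ratio^params$beta)
}

#' Invert the Davis model for the venous blood-volume ratio
#'
#' Exact algebraic inverse of [forward_bold_hypercapnia()]:
#' `v = ((1 - dBOLD/M) / q^beta)^(1 / (1 - beta/alpha))`.
#' The volume change is conventionally reported as `(v - 1) * 100` percent.
#'
#' @param dbold_hc Fractional BOLD change during hypercapnia; must be `< m`
#'   (otherwise the model is saturated). Vectorized.
#' @param m Fractional M-value, > 0.
#' @param cmro2_ratio CMRO2/CMRO2|0, in (0, 1].
#' @param params A [calib_params()] object.
#' @return CBV/CBV0.
#' @export
invert_cbv <- function(dbold_hc, m, cmro2_ratio, params = calib_params()) {
  stopifnot(inherits(params, "calib_params"))
  if (any(m <= 0)) stop("m must be > 0")
  if (any(cmro2_ratio <= 0 | cmro2_ratio > 1))
    stop("cmro2_ratio must lie in (0, 1]")
  if (any(dbold_hc >= m))
    stop("model saturated: dbold_hc must be < m")
  expo <- 1 - params$beta / params$alpha
  ((1 - dbold_hc / m) / cmro2_ratio^params$beta)^(1 / expo)
}
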