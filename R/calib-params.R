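#' Calibrated-BOLD model parameters
#'
#' Bundles every physiological and physical constant of the calibrated-BOLD
#' model: the Grubb flow-volume coupling exponent, the deoxyhemoglobin
#' relaxation exponent, the assumed baseline oxygen extraction fraction,
#' hemoglobin oxygen-carrying constants, and the per-condition metabolic
#' scaling applied during hypercapnia.
#'
#' Defaults reflect 7 T venous-weighted BOLD: `alpha = 0.2` (venous
#' flow-volume coupling), `beta = 1` (linear deoxyhemoglobin effect on
#' transverse relaxation at high field), `oef0 = 0.30`, `hb = 15` g/dL,
#' `phi = 1.34` mL O2/g Hb, `eps = 0.0031` mL O2/dL/mmHg, and
#' CMRO2/CMRO2|0 of 0.97, 0.95, 0.92, 0.90 for the +3, +5, +8 and +10 mmHg
#' end-tidal CO2 steps (a small metabolic depression that scales with the
#' inspired CO2 level).
#'
#' @param alpha Flow-volume coupling exponent (dimensionless, in (0, 1)).
#' @param beta Deoxyhemoglobin relaxation exponent (dimensionless, > 0).
#' @param oef0 Baseline oxygen extraction fraction (dimensionless, in (0, 1)).
#' @param hb Hemoglobin concentration, g/dL.
#' @param phi O2-carrying capacity of hemoglobin, mL O2/g Hb.
#' @param eps O2 solubility in plasma, mL O2/dL/mmHg.
#' @param cmro2_ratio Named numeric vector mapping hypercapnia level labels
#'   to CMRO2/CMRO2|0, each in (0, 1].
#' @return An object of class `calib_params`.
#' @export
#' @examples
#' p <- calib_params()
#' p$cmro2_ratio[["+10"]]
calib_params <- function(alpha = 0.2,
                         beta = 1.0,
                         oef0 = 0.30,
                         hb = 15.0,
                         phi = 1.34,
                         eps = 0.0031,
                         cmro2_ratio = c("+3" = 0.97, "+5" = 0.95,
                                         "+8" = 0.92, "+10" = 0.90)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(oef0), length(oef0) == 1L)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(beta > 0)) stop("beta must be > 0")
  if (!(oef0 > 0 && oef0 < 1)) stop("oef0 must lie in (0, 1)")
  if (!(hb > 0)) stop("hb must be > 0")
  if (!(phi > 0)) stop("phi must be > 0")
  if (eps < 0) stop("eps must be >= 0")
  if (is.null(names(cmro2_ratio)) || any(!nzchar(names(cmro2_ratio))))
    stop("cmro2_ratio must be a named vector of hypercapnia level labels")
  if (any(cmro2_ratio <= 0 | cmro2_ratio > 1))
    stop("all CMRO2 ratios must lie in (0, 1]")
  structure(list(alpha = alpha, beta = beta, oef0 = oef0, hb = hb,
                 phi = phi, eps = eps, cmro2_ratio = cmro2_ratio),
            class = "calib_params")
}

#' Look up the CMRO2 scaling for a hypercapnia level
#'
#' Per-condition lookup (no interpolation across end-tidal CO2): each
#' breathing condition carries its own fixed metabolic scaling.
#'
#' @param params A `calib_params` object.
#' @param level Hypercapnia level label, e.g. `"+10"`.
#' @return CMRO2/CMRO2|0 for that condition.
#' @export
cmro2_ratio_for <- function(params, level) {
  stopifnot(inherits(params, "calib_params"))
  level <- as.character(level)
  out <- params$cmro2_ratio[level]
  if (any(is.na(out)))
    stop("no CMRO2 ratio configured for level(s): ",
         paste(level[is.na(out)], collapse = ", "))
  unname(out)
}

#' @export
print.calib_params <- function(x, ...) {
  cat("Calibrated-BOLD parameters\n")
  cat(sprintf("  alpha = %g, beta = %g, OEF0 = %g\n", x$alpha, x$beta, x$oef0))
  cat(sprintf("  [Hb] = %g g/dL, phi = %g mL O2/g, eps = %g mL O2/dL/mmHg\n",
              x$hb, x$phi, x$eps))
  cat("  CMRO2/CMRO2|0:",
      paste(sprintf("%s -> %g", names(x$cmro2_ratio), x$cmro2_ratio),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore calibration parameters as flat JSON
#'
#' @param params A `calib_params` object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `params_to_json`: the path (invisibly) or a JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "calib_params"))
  doc <- unclass(params)
  doc$cmro2_ratio <- as.list(doc$cmro2_ratio) # keep level labels in JSON
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @param json A JSON string or file path produced by [params_to_json()].
#' @return `params_from_json`: a `calib_params` object.
#' @export
params_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  calib_params(alpha = doc$alpha, beta = doc$beta, oef0 = doc$oef0,
               hb = doc$hb, phi = doc$phi, eps = doc$eps,
               cmro2_ratio = unlist(doc$cmro2_ratio))
}
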