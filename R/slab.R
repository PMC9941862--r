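#' Synthetic cortical slab label volume
#'
#' A rectangular cortical slab carrying the labels the depth analysis needs:
#' a 20-level equivolumetric depth index along `depth_axis` (flanked by one
#' out-of-cortex slice on each side, emulating white matter and CSF
#' adjacency), three visual-area ROI stripes (V1/V2/V3) along the first
#' in-plane axis, and a deterministic pial-vein flag concentrated on the
#' superficial face of the slab.
#'
#' @param shape Integer grid dimensions; the extent along `depth_axis` must
#'   be at least `n_layers + 2`.
#' @param depth_axis Axis (1-3) along which cortical depth runs.
#' @param n_layers Number of depth layers (default 20).
#' @return A `label_volume`: list of arrays `depth` (integer 0 = outside
#'   cortex, 1 = deepest ... `n_layers` = most superficial), `roi` (integer
#'   0 = none, 1..3 = V1/V2/V3) and `vein` (logical), plus `voxel_mm`.
#' @export
#' @examples
#' lab <- make_slab(c(12, 12, 22))
#' range(lab$depth) # 0..20
make_slab <- function(shape = c(40, 40, 22), depth_axis = 3, n_layers = 20L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, depth_axis %in% 1:3, n_layers >= 3)
  if (shape[depth_axis] < n_layers + 2L)
    stop("shape too small: need at least ", n_layers + 2L,
         " voxels along the depth axis")

  idx <- array(slice.index(array(0L, shape), depth_axis), dim = shape)
  # center the cortical band; one (or more) out-of-cortex slice on each side
  lo <- (shape[depth_axis] - n_layers) %/% 2L
  depth <- idx - lo
  depth[depth < 1L | depth > n_layers] <- 0L

  stripe_axis <- setdiff(1:3, depth_axis)[1]
  pos <- array(slice.index(array(0L, shape), stripe_axis), dim = shape)
  roi <- 1L + ((pos - 1L) * 3L) %/% shape[stripe_axis]
  roi[depth == 0L] <- 0L

  other <- setdiff(1:3, depth_axis)[2]
  pos2 <- array(slice.index(array(0L, shape), other), dim = shape)
  vein <- depth >= n_layers - 1L & ((pos + pos2) %% 9L == 0L)

  structure(list(depth = depth, roi = roi, vein = vein,
                 roi_names = c("V1", "V2", "V3"),
                 n_layers = as.integer(n_layers),
                 depth_axis = as.integer(depth_axis),
                 voxel_mm = c(1, 1, 1)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume %s: %d cortical layers along axis %d, %d in-cortex voxels\n",
              paste(dim(x$depth), collapse = "x"), x$n_layers, x$depth_axis,
              sum(x$depth > 0)))
  invisible(x)
}
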