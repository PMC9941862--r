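#' Build the gas-challenge design matrix
#'
#' One intercept column, one binary column per gas condition (1 exactly
#' during that block's volumes, 0 otherwise; binary regressors fit the
#' average plateau and are insensitive to residual transients), and the
#' mean-centered nuisance columns (6 motion parameters, RVT, BPM).
#'
#' @param protocol A [make_protocol()] object.
#' @param nuisance data.frame or matrix of per-volume nuisance regressors
#'   (8 columns; same number of rows as protocol volumes).
#' @return Numeric design matrix with named columns and attribute
#'   `condition_cols` giving the gas-condition column names.
#' @export
build_design <- function(protocol, nuisance) {
  stopifnot(inherits(protocol, "gas_protocol"))
  nuisance <- as.matrix(nuisance)
  n <- protocol$n_volumes
  if (nrow(nuisance) != n)
    stop("nuisance length (", nrow(nuisance),
         ") does not match protocol sample count (", n, ")")
  blk <- volume_blocks(protocol)
  conds <- condition_labels(protocol)
  cols <- vapply(conds, function(lab) as.numeric(blk == lab), numeric(n))
  if (length(conds) > 1 && any(rowSums(cols) > 1))
    stop("overlapping condition blocks")
  nuis <- scale(nuisance, center = TRUE, scale = FALSE)
  x <- cbind(intercept = 1, cols, nuis)
  colnames(x) <- c("intercept", conds, colnames(nuisance))
  attr(x, "condition_cols") <- conds
  x
}

#' Per-voxel ordinary least squares over a design matrix
#'
#' Fits every voxel time series by OLS, returning coefficients (the
#' condition betas are the %BOLD plateau estimates when the data are in
#' percent signal change), standard errors, t-statistics and two-sided
#' p-values from the t distribution with the residual degrees of freedom,
#' plus an omnibus F test over the gas-condition columns (used for voxel
#' selection). A voxel fitted exactly (zero residual variance, as in
#' noiseless simulation) gets p = 0 for nonzero effects.
#'
#' @param y Time-by-voxel matrix (e.g. percent signal change), or a
#'   `functional_series` (reshaped internally; voxel order is the array's
#'   column-major order).
#' @param design Design matrix from [build_design()].
#' @return A `glm_result`: list of voxel-by-coefficient matrices `beta`,
#'   `se`, `t`, `p`; vectors `f_gas`, `p_gas`; `df_residual`,
#'   `condition_cols`.
#' @export
fit_glm <- function(y, design) {
  if (inherits(y, "functional_series")) {
    d <- dim(y$data)
    y <- t(matrix(y$data, nrow = prod(d[1:3]), ncol = d[4]))
  }
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(nrow(design) == n)
  p <- ncol(design)
  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ok <- !colAnyNA(y)
  beta <- matrix(NA_real_, ncol(y), p, dimnames = list(NULL, colnames(design)))
  rss <- rep(NA_real_, ncol(y))
  cf <- qr.coef(qx, y[, ok, drop = FALSE])
  res <- y[, ok, drop = FALSE] - design %*% cf
  beta[ok, ] <- t(cf)
  rss[ok] <- colSums(res^2)
  df <- n - p
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  sigma2 <- rss / df
  exact <- ok & sigma2 <= 1e-18 * pmax(colMeans(y^2), 1e-300)
  se <- sqrt(outer(sigma2, xtx_inv_diag))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tval[exact, ] <- sign(beta[exact, , drop = FALSE]) * Inf
  pval[exact, ] <- ifelse(beta[exact, , drop = FALSE] == 0, 1, 0)

  conds <- attr(design, "condition_cols")
  keep <- !(colnames(design) %in% conds)
  x0 <- design[, keep, drop = FALSE]
  q0 <- qr(x0)
  res0 <- qr.resid(q0, y[, ok, drop = FALSE])
  rss0 <- rep(NA_real_, ncol(y))
  rss0[ok] <- colSums(res0^2)
  qdf <- length(conds)
  f <- ((rss0 - rss) / qdf) / sigma2
  p_gas <- stats::pf(f, qdf, df, lower.tail = FALSE)
  f[exact] <- Inf
  p_gas[exact] <- 0
  dimnames(se) <- dimnames(tval) <- dimnames(pval) <- dimnames(beta)
  structure(list(beta = beta, se = se, t = tval, p = pval,
                 f_gas = f, p_gas = p_gas, df_residual = df,
                 condition_cols = conds),
            class = "glm_result")
}

colAnyNA <- function(m) colSums(is.na(m)) > 0

#' Holm-Bonferroni voxel selection
#'
#' Step-down familywise-error control over a family of per-voxel p-values
#' (by default the omnibus gas F test): sort ascending and reject while
#' `p_(i) <= alpha / (m - i + 1)`. Implemented through
#' `stats::p.adjust(method = "holm")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA entries are never
#'   selected).
#' @param alpha Familywise error level in (0, 1).
#' @return Logical inclusion mask, same length as `p`.
#' @export
holm_select <- function(p, alpha = 0.05) {
  if (!length(p) || all(is.na(p))) stop("empty p-value family")
  stopifnot(alpha > 0, alpha < 1)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  !is.na(adj) & adj <= alpha
}
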