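make_nuisance <- function(n, seed = 1) {
  mot <- make_motion_params(n, seed = seed)
  cbind(as.matrix(mot), rvt = sin(seq_len(n) / 40), bpm = 60 + cos(seq_len(n) / 55))
}

test_that("design matrix has binary, disjoint, correctly sized condition columns", {
  p <- make_protocol()
  nuis <- make_nuisance(p$n_volumes)
  x <- build_design(p, nuis)
  expect_equal(ncol(x), 1 + 3 + 8) # intercept + conditions + nuisance
  conds <- attr(x, "condition_cols")
  expect_equal(conds, c("hc+5", "hc+10", "ho+350"))
  for (cc in conds) expect_true(all(x[, cc] %in% 0:1))
  expect_equal(sum(x[, "hc+10"]), round(120 / 0.85), tolerance = 1)
  # disjoint blocks: pairwise dot products vanish
  expect_equal(crossprod(x[, conds])[lower.tri(diag(3))], rep(0, 3))
  # nuisance columns are mean-centered
  expect_equal(colMeans(x[, 5:12]), rep(0, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(build_design(p, nuis[-1, ]), "sample count")
})

test_that("OLS recovers exact coefficients from noiseless constructions", {
  p <- make_protocol()
  x <- build_design(p, make_nuisance(p$n_volumes))
  set.seed(51)
  betas <- matrix(rnorm(ncol(x) * 4), ncol(x), 4)
  y <- x %*% betas
  fit <- fit_glm(y, x)
  expect_equal(t(fit$beta), betas, tolerance = 1e-9, ignore_attr = TRUE)
  # exact fits are flagged significant for nonzero effects
  expect_true(all(fit$p_gas == 0))
})

test_that("OLS equals brute-force normal equations on a 5-voxel toy", {
  p <- make_protocol()
  x <- build_design(p, make_nuisance(p$n_volumes))
  set.seed(52)
  y <- x %*% matrix(rnorm(ncol(x) * 5), ncol(x), 5) +
    matrix(rnorm(p$n_volumes * 5), p$n_volumes, 5)
  fit <- fit_glm(y, x)
  xtx_inv <- solve(t(x) %*% x)
  bhat <- xtx_inv %*% t(x) %*% y
  expect_lt(max(abs(t(fit$beta) - bhat)), 1e-10)
  for (j in 1:5) {
    res <- y[, j] - x %*% bhat[, j]
    s2 <- sum(res^2) / (nrow(x) - ncol(x))
    se <- sqrt(s2 * diag(xtx_inv))
    expect_lt(max(abs(fit$se[j, ] - se)), 1e-10)
    expect_lt(max(abs(fit$t[j, ] - bhat[, j] / se)), 1e-8)
    expect_equal(fit$p[j, ], 2 * stats::pt(-abs(bhat[, j] / se),
                                           nrow(x) - ncol(x)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("voxel permutation permutes results identically", {
  p <- make_protocol()
  x <- build_design(p, make_nuisance(p$n_volumes))
  set.seed(53)
  y <- matrix(rnorm(p$n_volumes * 6), p$n_volumes, 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- fit_glm(y, x)
  b <- fit_glm(y[, perm], x)
  expect_equal(b$beta, a$beta[perm, ])
  expect_equal(b$p_gas, a$p_gas[perm])
})

test_that("rank deficiency is reported with the collinear column", {
  p <- make_protocol()
  nuis <- make_nuisance(p$n_volumes)
  nuis[, "bpm"] <- 2 * nuis[, "rvt"] # force collinearity
  x <- build_design(p, nuis)
  y <- matrix(rnorm(p$n_volumes * 2), p$n_volumes, 2)
  expect_error(fit_glm(y, x), "rank deficient.*bpm|bpm.*rank deficient")
})

test_that("Holm step-down matches a hand implementation", {
  hand_holm <- function(p, alpha) {
    m <- length(p)
    ord <- order(p)
    keep <- logical(m)
    for (i in seq_len(m)) {
      if (p[ord[i]] <= alpha / (m - i + 1)) keep[ord[i]] <- TRUE else break
    }
    keep
  }
  set.seed(54)
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    expect_identical(holm_select(p, 0.05), hand_holm(p, 0.05))
  }
  expect_identical(holm_select(c(0.001, 0.02, 0.04), 0.05), rep(TRUE, 3))
  expect_identical(holm_select(rep(1, 10), 0.05), rep(FALSE, 10))
  expect_error(holm_select(numeric(0)), "empty")
  expect_error(holm_select(c(0.5, 1.2)), "0, 1")
})

test_that("Holm rejections contain the Bonferroni rejections", {
  set.seed(55)
  for (rep in 1:50) {
    p <- stats::runif(30)^2
    holm <- holm_select(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(holm[bonf]))
  }
})

test_that("condition betas equal plateau-minus-baseline block means", {
  # noiseless series with square plateaus and no nuisance correlation
  p <- make_protocol()
  blk <- volume_blocks(p)
  plateau <- c("hc+5" = 1.5, "hc+10" = 3.2, "ho+350" = 2.1)
  y <- rep(0, p$n_volumes)
  for (lab in names(plateau)) y[blk == lab] <- plateau[[lab]]
  nuis <- matrix(rnorm(p$n_volumes * 8, sd = 1e-8), ncol = 8,
                 dimnames = list(NULL, paste0("n", 1:8)))
  x <- build_design(p, nuis)
  fit <- fit_glm(matrix(y), x)
  expect_equal(fit$beta[1, names(plateau)], plateau, tolerance = 1e-6)
})
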