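test_that("a single latent factor recovers rank-1 noiseless data", {
  set.seed(101)
  t1 <- rnorm(8); t1 <- t1 - mean(t1)
  p1 <- rnorm(20)
  X <- tcrossprod(t1, p1)
  y <- 2 * t1
  fit <- fit_pls1(X, y, ncomp = 1)
  expect_lt(max(abs(fit$fitted[, 1] - y)), 1e-8)
  expect_equal(sum(fit$weights[, 1]^2), 1)
})

test_that("full-factor PLS equals the least-squares fit (normal equations)", {
  set.seed(102)
  pr <- random_problem(6, 3, 102)
  fit <- fit_pls1(pr$Xc, pr$yc, ncomp = 3)
  # independent oracle: solve the normal equations directly
  beta <- solve(crossprod(pr$Xc), crossprod(pr$Xc, pr$yc))
  expect_lt(max(abs(fit$fitted[, 3] - drop(pr$Xc %*% beta))), 1e-8)
})

test_that("with orthonormal columns the first weight is exactly X'y", {
  set.seed(103)
  Q <- qr.Q(qr(matrix(rnorm(8 * 4), 8, 4)))
  y <- rnorm(8); y <- y - mean(y)
  fit <- fit_pls1(Q, y, ncomp = 1)
  w_direct <- drop(crossprod(Q, y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(drop(fit$weights[, 1]), w_direct, tolerance = 1e-12)
})

test_that("fit_pls1 rejects invalid requests and names the achievable rank", {
  pr <- random_problem(5, 10, 104)
  expect_error(fit_pls1(pr$Xc, pr$yc, ncomp = 5), "min\\(n-1, p\\)")
  expect_error(fit_pls1(pr$Xc, rep(0, 5), ncomp = 1), "zero variance")
  # rank-1 X cannot supply 3 factors
  t1 <- rnorm(6); t1 <- t1 - mean(t1)
  X1 <- tcrossprod(t1, rnorm(10))
  y <- 3 * t1
  expect_error(fit_pls1(X1, y, ncomp = 3), "only 1 factor achievable")
  expect_equal(fit_pls1(X1, y, ncomp = 3, strict = FALSE)$ncomp, 1)
})

test_that("training scores are mutually orthogonal and deflation is complete", {
  for (seed in 1:100) {
    pr <- random_problem(7, 5, 200 + seed)
    fit <- fit_pls1(pr$Xc, pr$yc, ncomp = 5, strict = FALSE)
    G <- crossprod(fit$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
  # residual X after rank(X) factors vanishes
  pr <- random_problem(6, 4, 301)
  fit <- fit_pls1(pr$Xc, pr$yc, ncomp = 4)
  Xres <- pr$Xc
  for (f in 1:4)
    Xres <- Xres - tcrossprod(fit$scores[, f], fit$x_loadings[, f])
  expect_lt(sqrt(sum(Xres^2)), 1e-8)
})

test_that("deflation-path and regression-vector predictions agree", {
  pr <- random_problem(9, 6, 401)
  fit <- fit_pls1(pr$Xc, pr$yc, ncomp = 4)
  new <- matrix(rnorm(3 * 6), 3, 6)
  for (f in 1:4)
    expect_equal(predict(fit, new, ncomp = f, method = "deflation"),
                 predict(fit, new, ncomp = f, method = "regvec"),
                 tolerance = 1e-10)
  # train-set replay equals stored fitted values
  expect_equal(predict(fit, pr$Xc), fit$fitted[, 4])
})

test_that("PLS predictions match the reference implementation", {
  skip_if_not_installed("mixOmics")
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(501)
  for (rep in 1:10) {
    n <- 8; p <- 5
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    fit <- fit_pls1(Xc, yc, ncomp = 4)
    ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
    pref <- predict(ref, X)$predict
    for (f in 1:4)
      expect_lt(max(abs(fit$fitted[, f] + mean(y) - pref[, 1, f])), 1e-6)
  }
})

test_that("AIC follows n ln(MSE) + 2(F+1) with the stated penalty structure", {
  expect_equal(pls_aic(10, n = 6, nf = 1), 6 * log(100) + 4)
  # strictly increasing in rmsecv at fixed F
  expect_true(all(diff(pls_aic(seq(1, 50, by = 0.5), n = 6, nf = 2)) > 0))
  # +2 per extra factor at fixed rmsecv
  expect_equal(pls_aic(7, 6, 3) - pls_aic(7, 6, 2), 2)
  expect_warning(a0 <- pls_aic(0, 6, 1), "degenerate")
  expect_identical(a0, -Inf)
  expect_error(pls_aic(-1, 6, 1), "nonnegative")
})

test_that("factor selection takes the first AIC minimum", {
  expect_equal(select_n_factors(c(10, 8, 8, 9)), 2)
  expect_equal(select_n_factors(c(10, 9, 8, 7)), 4)
  expect_equal(select_n_factors(5), 1)
  expect_error(select_n_factors(numeric(0)), "empty")
})

test_that("uninformative spectra give the closed-form LOO error of the mean", {
  # identical rows vanish after centering; every held-out prediction is the
  # training-fold mean, with errors (6 y_i - 2850) / 5
  base <- sin(seq(0, 6, length.out = 250)) + 2
  X <- matrix(rep(base, each = 6), 6, 250)
  y <- seq(350, 600, by = 50)
  cv <- loo_cv(X, y)
  expect_equal(unname(cv$rmsecv), rep(sqrt(10500), 4), tolerance = 1e-9)
  expect_equal(cv$chosen_factors, 1)  # AIC ties resolve to fewest factors
  # fold means (2850 - y_i)/5 are exactly anticorrelated with y, a known
  # artefact of the leave-one-out mean predictor: squared Pearson r2 is 1
  expect_equal(cv$r2, 1)
  expect_equal(unname(cor(cv$predicted, cv$observed)), -1)
})

test_that("a noiseless rank-1 relation cross-validates perfectly", {
  cfg <- noiseless_preset()
  cs <- simulate_calibration(cfg, seed = 1)
  cv <- loo_cv(cs$spectra, cs$temperatures, snv = FALSE, window = 1)
  expect_lt(cv$rmsecv[1], 1e-6)
  expect_gt(cv$r2, 1 - 1e-9)
})

test_that("LOO CV is invariant to sample order", {
  cfg <- taxon_preset("Quercus")
  cs <- simulate_calibration(cfg, seed = 5)
  cv <- loo_cv(cs$spectra$values, cs$temperatures)
  set.seed(55)
  ix <- sample(6)
  cv2 <- loo_cv(cs$spectra$values[ix, ], cs$temperatures[ix])
  expect_equal(cv2$rmsecv, cv$rmsecv, tolerance = 1e-10)
})

test_that("chosen-F RMSECV never exceeds the one-factor RMSECV when F > 1", {
  # two latent directions drive y, so one factor cannot suffice
  multi <- 0L
  for (seed in 1:20) {
    set.seed(600 + seed)
    n <- 10; p <- 30
    t1 <- rnorm(n); t2 <- rnorm(n)
    X <- tcrossprod(t1, rnorm(p)) + tcrossprod(t2, rnorm(p)) +
      matrix(rnorm(n * p, 0, 0.01), n, p)
    y <- 20 * t1 + 50 * t2 + rnorm(n, 0, 0.1) + 475
    cv <- loo_cv(X, y, window = 1, snv = FALSE)
    if (cv$chosen_factors > 1) {
      multi <- multi + 1L
      expect_lte(cv$rmsecv[cv$chosen_factors], cv$rmsecv[1] + 1e-9)
    }
  }
  expect_gt(multi, 10)  # the construction does force multi-factor models
})

test_that("VIP satisfies its normalisation identity and closed forms", {
  pr <- random_problem(8, 12, 701)
  fit <- fit_pls1(pr$Xc, pr$yc, ncomp = 3)
  v <- vip(fit)
  p <- 12
  expect_equal(sum(v$values^2), p, tolerance = 1e-6 * p)
  # single-factor closed form: sqrt(p) * |w_j| / ||w||
  fit1 <- fit_pls1(pr$Xc, pr$yc, ncomp = 1)
  v1 <- vip(fit1)
  expect_equal(v1$values, sqrt(p) * abs(drop(fit1$weights)), tolerance = 1e-10)
  # uniform weights give VIP = 1 everywhere
  fake <- fit1
  fake$weights <- matrix(1 / sqrt(p), p, 1)
  expect_equal(vip(fake)$values, rep(1, p), tolerance = 1e-12)
})

test_that("diagnostic band extraction handles flat, single and close peaks", {
  flat <- structure(list(values = rep(1.5, 50), wavenumbers = seq(900, 410, by = -10)),
                    class = "vip_profile")
  expect_length(diagnostic_bands(flat), 0)

  # single informative band: only the 1730 band varies with temperature
  g <- grid_spec()
  cfg <- generator_config(list(band_spec(1730, 12, 0.5, 4e-4),
                               band_spec(1040, 12, 0.6, 0)),
                          noise_sd = 0, scatter_sd = 0, grid = g)
  cs <- simulate_calibration(cfg, seed = 3)
  pp <- fit_preprocess(cs$spectra, cs$temperatures)
  fit <- fit_pls1(pp$Xp, pp$yp, 1, strict = FALSE)
  db <- diagnostic_bands(vip(fit, g$axis))
  step <- abs(diff(g$axis[1:2]))
  expect_lte(min(abs(db - 1730)), step)

  # two informative bands 30 apart merge under min_separation 50
  # (raw-intensity pipeline so the weights sit exactly on the bands)
  cfg2 <- generator_config(list(band_spec(1200, 12, 0.5, 4e-4),
                                band_spec(1230, 12, 0.5, 4e-4)),
                           noise_sd = 0, scatter_sd = 0, grid = g)
  cs2 <- simulate_calibration(cfg2, seed = 4)
  pp2 <- fit_preprocess(cs2$spectra, cs2$temperatures, snv = FALSE)
  fit2 <- fit_pls1(pp2$Xp, pp2$yp, 1, strict = FALSE)
  db2 <- diagnostic_bands(vip(fit2, g$axis), min_separation = 50)
  expect_length(db2, 1)
  expect_lt(abs(db2 - 1215), 30)  # the merged hill sits between the bands
})
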