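#' Fit a PLS1 regression by NIPALS deflation
#'
#' Iteratively extracts latent factors from a centered predictor matrix and
#' centered response. Per factor f: the weight vector is proportional to
#' \eqn{X^T y} (unit-normalised), the score is \eqn{t = X w}, the x-loading
#' \eqn{p = X^T t / t^T t}, the y-loading \eqn{q = y^T t / t^T t}; X and y
#' are then deflated by the extracted factor. Inputs are expected centered
#' (see [fit_preprocess]); the higher-level [charcoal_calibration] handles
#' centering and back-transformation.
#'
#' @param X Centered numeric matrix (n x p).
#' @param y Centered numeric response vector, length n.
#' @param ncomp Number of latent factors F, `1 <= F <= min(n-1, p)`.
#' @param strict If `TRUE` (default), requesting more factors than the data
#'   can supply is an error naming the achievable maximum; if `FALSE` the
#'   fit is truncated at the achievable rank (used inside cross-validation,
#'   where degenerate folds must not abort the loop).
#'
#' @return An object of class `"pls1_fit"`: list with `weights` (p x F, unit
#'   columns), `x_loadings` (p x F), `y_loadings` (length F), `scores`
#'   (n x F training scores), `ncomp` (factors actually extracted), `coef`
#'   (p x F matrix; column f is the regression vector of the f-factor
#'   model), and `fitted` (n x F centered fitted values per factor count).
#' @examples
#' X <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
#' y <- drop(X %*% rnorm(5)); y <- y - mean(y)
#' fit <- fit_pls1(X, y, ncomp = 3)
#' fit$ncomp
#' @export
fit_pls1 <- function(X, y, ncomp, strict = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("fit_pls1: length(y) must equal nrow(X)")
  if (n < 2) stop("fit_pls1: need at least 2 samples")
  if (stats::var(y) == 0) stop("fit_pls1: response has zero variance")
  ncomp <- as.integer(ncomp)
  max_f <- min(n - 1L, p)
  if (ncomp < 1) stop("fit_pls1: ncomp must be >= 1")
  if (ncomp > max_f)
    stop(sprintf("fit_pls1: ncomp = %d exceeds min(n-1, p) = %d", ncomp, max_f))

  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  Xd <- X; yd <- y
  tol <- 1e-12 * max(1, sum(X^2))
  reached <- 0L
  for (f in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol) break
    w <- w / wn
    tf <- drop(Xd %*% w)
    tt <- sum(tf^2)
    if (tt <= tol) break
    pf <- drop(crossprod(Xd, tf)) / tt
    qf <- sum(yd * tf) / tt
    W[, f] <- w; P[, f] <- pf; Q[f] <- qf; Tm[, f] <- tf
    Xd <- Xd - tcrossprod(tf, pf)
    yd <- yd - qf * tf
    reached <- f
  }
  if (reached < ncomp) {
    if (strict)
      stop(sprintf(
        "fit_pls1: rank deficiency, only %d factor%s achievable (requested %d)",
        reached, if (reached == 1) "" else "s", ncomp))
    if (reached == 0L) {
      # uninformative X: the model is the (centered) mean, i.e. all zeros
      W <- P <- matrix(0, p, 0); Q <- numeric(0); Tm <- matrix(0, n, 0)
    } else {
      W <- W[, seq_len(reached), drop = FALSE]
      P <- P[, seq_len(reached), drop = FALSE]
      Q <- Q[seq_len(reached)]
      Tm <- Tm[, seq_len(reached), drop = FALSE]
    }
    ncomp <- reached
  }
  fitted <- if (ncomp > 0) {
    tmp <- sweep(Tm, 2L, Q, `*`)
    tmp <- apply(tmp, 1L, cumsum)
    if (ncomp == 1) matrix(tmp, n, 1) else t(tmp)
  } else matrix(0, n, 0)
  # regression vector per factor count: B_F = W_F (P_F' W_F)^-1 q_F
  coefs <- matrix(0, p, ncomp)
  if (ncomp > 0) {
    for (f in seq_len(ncomp)) {
      Wf <- W[, seq_len(f), drop = FALSE]
      Pf <- P[, seq_len(f), drop = FALSE]
      coefs[, f] <- Wf %*% solve(crossprod(Pf, Wf), Q[seq_len(f)])
    }
  }
  structure(list(weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
                 ncomp = ncomp, coef = coefs, fitted = fitted),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d latent factor%s, %d predictors, %d samples\n",
              x$ncomp, if (x$ncomp == 1) "" else "s",
              nrow(x$weights), nrow(x$scores)))
  invisible(x)
}

#' Predict from a low-level PLS1 fit
#'
#' Computes latent scores for new (already preprocessed and centered) rows
#' by sequential deflation with the stored weights and x-loadings, then
#' accumulates the y-loading-weighted scores. Equivalent to multiplying by
#' the accumulated regression vector; both paths are available.
#'
#' @param object A `"pls1_fit"`.
#' @param newdata Centered numeric matrix with `nrow(object$weights)` columns.
#' @param ncomp Number of factors to use (default: all extracted).
#' @param method `"deflation"` (score accumulation) or `"regvec"`
#'   (regression-vector product); both give identical predictions.
#' @param ... Unused.
#' @return Numeric vector of centered predictions.
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = object$ncomp,
                             method = c("deflation", "regvec"), ...) {
  method <- match.arg(method)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$weights))
    stop("predict.pls1_fit: column count does not match the fitted model")
  ncomp <- min(as.integer(ncomp), object$ncomp)
  if (ncomp == 0 || object$ncomp == 0) return(rep(0, nrow(newdata)))
  if (method == "regvec")
    return(drop(newdata %*% object$coef[, ncomp]))
  Xd <- newdata
  yhat <- rep(0, nrow(newdata))
  for (f in seq_len(ncomp)) {
    tf <- drop(Xd %*% object$weights[, f])
    Xd <- Xd - tcrossprod(tf, object$x_loadings[, f])
    yhat <- yhat + object$y_loadings[f] * tf
  }
  yhat
}

# centered predictions at every factor count 1..object$ncomp: n x F matrix
.predict_all_factors <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  if (object$ncomp == 0) return(matrix(0, n, 0))
  out <- matrix(0, n, object$ncomp)
  Xd <- newdata
  acc <- rep(0, n)
  for (f in seq_len(object$ncomp)) {
    tf <- drop(Xd %*% object$weights[, f])
    Xd <- Xd - tcrossprod(tf, object$x_loadings[, f])
    acc <- acc + object$y_loadings[f] * tf
    out[, f] <- acc
  }
  out
}

#' AIC for cross-validated PLS factor selection
#'
#' `AIC = n * ln(RMSECV^2) + 2 * (F + 1)`, counting the intercept among the
#' parameters. A penalised fit measure used to choose the number of latent
#' factors without overfitting.
#'
#' @param rmsecv Cross-validated root mean squared error (degrees C), > 0.
#' @param n Number of calibration samples.
#' @param nf Number of latent factors F.
#' @return The AIC value; `-Inf` (with a warning) for a degenerate exact fit
#'   (`rmsecv = 0`).
#' @examples
#' pls_aic(10, n = 6, nf = 1)  # 6*log(100) + 4
#' @export
pls_aic <- function(rmsecv, n, nf) {
  if (any(rmsecv < 0)) stop("pls_aic: rmsecv must be nonnegative")
  out <- n * log(rmsecv^2) + 2 * (nf + 1)
  if (any(rmsecv == 0)) {
    warning("pls_aic: rmsecv = 0, degenerate -Inf AIC")
    out[rmsecv == 0] <- -Inf
  }
  out
}

#' Select the number of latent factors from an AIC sequence
#'
#' Returns the smallest factor count attaining the minimum AIC (ties broken
#' toward fewer factors, i.e. parsimony).
#'
#' @param aic Numeric vector, element f being the AIC of the f-factor model.
#' @return Integer factor count.
#' @examples
#' select_n_factors(c(10, 8, 8, 9))  # 2
#' @export
select_n_factors <- function(aic) {
  if (length(aic) == 0) stop("select_n_factors: empty AIC sequence")
  which.min(aic)
}

#' Leave-one-out cross-validation of the PLS1 calibration
#'
#' For every left-out sample the entire pipeline is re-estimated on the
#' remaining samples: preprocessing (including the column means) and the
#' PLS fit see only the training fold, so no test information leaks.
#' RMSECV and AIC are reported for every factor count up to `F_max`; the
#' factor count minimising AIC is chosen, and the squared Pearson
#' correlation of the cross-validated predicted-vs-observed pairs at that
#' choice is reported with its two-sided t-test p-value (n-2 df).
#'
#' @param X Raw calibration spectra: a spectral matrix or numeric matrix.
#' @param y Known charring temperatures (degrees C).
#' @param F_max Maximum factor count to evaluate (default `min(n-2, p)`).
#' @param window Median filter window passed to [fit_preprocess].
#' @param snv Apply SNV (default `TRUE`).
#'
#' @return Object of class `"pls_cv"`: list with `rmsecv` (length F_max),
#'   `aic`, `chosen_factors`, `predicted` and `observed` (paired degrees C at
#'   the chosen factor count), `predictions` (n x F_max matrix), `r2`,
#'   `p_value`, `n`.
#' @export
loo_cv <- function(X, y, F_max = NULL, window = 5, snv = TRUE) {
  V <- if (inherits(X, "spectral_matrix")) X$values else as.matrix(X)
  n <- nrow(V)
  if (n < 3) stop("loo_cv: need at least 3 samples for leave-one-out CV")
  if (length(y) != n) stop("loo_cv: length(y) must equal nrow(X)")
  if (is.null(F_max)) F_max <- min(n - 2L, ncol(V))
  F_max <- as.integer(F_max)
  if (F_max < 1 || F_max > n - 2L)
    stop("loo_cv: F_max must lie in [1, n-2]")

  # SNV and the median filter act per spectrum, so they are identical in
  # every fold; only the column centering and the PLS fit are re-estimated
  # on each training fold
  R <- .row_transform(V, window, snv)
  .loo_cv_core(R, y, F_max)
}

# LOO CV on a row-transformed (but not yet column-centered) matrix
.loo_cv_core <- function(R, y, F_max) {
  n <- nrow(R)
  csum <- colSums(R)
  pred <- matrix(NA_real_, n, F_max)
  for (i in seq_len(n)) {
    mu <- (csum - R[i, ]) / (n - 1)
    Xc <- sweep(R[-i, , drop = FALSE], 2L, mu)
    ym <- mean(y[-i])
    pred[i, ] <- ym + .nipals_loo(Xc, y[-i] - ym, R[i, ] - mu, F_max)
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  aic <- suppressWarnings(pls_aic(rmsecv, n = n, nf = seq_len(F_max)))
  chosen <- select_n_factors(aic)
  pv <- pred[, chosen]
  if (stats::sd(pv) == 0 || stats::sd(y) == 0) {
    r2 <- 0; p_value <- 1
  } else {
    ct <- stats::cor.test(pv, y, alternative = "two.sided")
    r2 <- unname(ct$estimate^2)
    p_value <- ct$p.value
  }
  structure(list(rmsecv = rmsecv, aic = aic, chosen_factors = chosen,
                 predicted = pv, observed = y, predictions = pred,
                 r2 = r2, p_value = p_value, n = n),
            class = "pls_cv")
}

# minimal NIPALS for one CV fold: centered training data in, centered
# held-out predictions at factor counts 1..F_max out (padded at the
# achievable rank; all zeros, i.e. the fold mean, for uninformative X)
.nipals_loo <- function(Xc, yc, xnew, F_max) {
  out <- numeric(F_max)
  tol <- 1e-12 * max(1, sum(Xc^2))
  acc <- 0
  reached <- 0L
  maxf <- min(F_max, nrow(Xc) - 1L, ncol(Xc))
  for (f in seq_len(maxf)) {
    w <- drop(crossprod(Xc, yc))
    wn2 <- sum(w^2)
    if (wn2 <= tol) break
    w <- w / sqrt(wn2)
    tf <- drop(Xc %*% w)
    tt <- sum(tf^2)
    if (tt <= tol) break
    pf <- drop(crossprod(Xc, tf)) / tt
    qf <- sum(yc * tf) / tt
    th <- sum(xnew * w)
    xnew <- xnew - th * pf
    acc <- acc + qf * th
    Xc <- Xc - tcrossprod(tf, pf)
    yc <- yc - qf * tf
    out[f] <- acc
    reached <- f
  }
  if (reached < F_max) out[(reached + 1L):F_max] <- if (reached > 0) acc else 0
  out
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out CV: %d samples, %d factor counts evaluated\n",
    x$n, length(x$rmsecv)))
  cat(sprintf("  chosen factors: %d (RMSECV %.2f degC, AIC %.2f)\n",
              x$chosen_factors, x$rmsecv[x$chosen_factors],
              x$aic[x$chosen_factors]))
  cat(sprintf("  cross-validated r2 = %.4f (p = %.3g)\n", x$r2, x$p_value))
  invisible(x)
}

#' Variable importance for projection (VIP)
#'
#' Per-wavenumber importance scores for a fitted PLS1 model:
#' \deqn{VIP_j = \sqrt{p \sum_f SS_f w_{jf}^2 / \sum_f SS_f}}
#' with \eqn{SS_f = q_f^2 t_f^T t_f} the response variance captured by
#' factor f. The squared VIPs always sum to p (the number of wavenumbers),
#' so values above 1 flag wavenumbers contributing more than average.
#'
#' @param x A `"pls1_fit"` or `"charcoal_calibration"`.
#' @param wavenumbers Optional wavenumber axis to attach (length p); the
#'   calibration method supplies its own grid axis.
#' @param ... Passed to methods.
#' @return Object of class `"vip_profile"`: list with `values`,
#'   `wavenumbers` (or NULL).
#' @export
vip <- function(x, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.pls1_fit <- function(x, wavenumbers = NULL, ...) {
  fit <- x
  if (fit$ncomp == 0) stop("vip: degenerate model with no factors")
  ss <- fit$y_loadings^2 * colSums(fit$scores^2)
  total <- sum(ss)
  if (total <= 0) stop("vip: degenerate model, zero explained sum of squares")
  p <- nrow(fit$weights)
  vals <- sqrt(p * drop(fit$weights^2 %*% ss) / total)
  structure(list(values = vals, wavenumbers = wavenumbers),
            class = "vip_profile")
}

#' @export
print.vip_profile <- function(x, ...) {
  cat(sprintf("VIP profile over %d wavenumbers; %d above 1.0\n",
              length(x$values), sum(x$values > 1)))
  invisible(x)
}

#' Diagnostic wavenumber bands from a VIP profile
#'
#' Reports the local maxima of the VIP trace that exceed `threshold`,
#' greedily thinned so that reported bands are at least `min_separation`
#' cm\eqn{^{-1}} apart (highest VIP first). A plateau (run of equal values
#' strictly above both flanking values) counts as one maximum. Because the
#' median-filtered pipeline produces flat-topped VIP peaks whose argmax
#' wanders under noise, each reported band position is refined to the
#' VIP-weighted centroid of the peak's own hill (the points reachable from
#' the maximum by non-increasing descent on both sides), which is stable to
#' within a fraction of a grid step. A perfectly flat trace has no local
#' maxima and yields an empty list.
#'
#' @param v A `"vip_profile"` with a wavenumber axis.
#' @param threshold VIP threshold (default 1, the mean-square level).
#' @param min_separation Minimum spacing between reported bands in
#'   cm\eqn{^{-1}} (default 25).
#' @return Numeric vector of band wavenumbers, in decreasing VIP order.
#' @export
diagnostic_bands <- function(v, threshold = 1, min_separation = 25) {
  stopifnot(inherits(v, "vip_profile"))
  if (is.null(v$wavenumbers))
    stop("diagnostic_bands: VIP profile has no wavenumber axis")
  vals <- v$values
  wn <- v$wavenumbers
  n <- length(vals)
  if (n < 3) return(numeric(0))
  # collapse plateaus: one candidate per run of equal values that is
  # strictly above both neighbours (interior runs only)
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > threshold &&
          r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
        cand <- c(cand, starts[j])   # run start; position refined below
    }
  }
  if (length(cand) == 0) return(numeric(0))
  refine <- function(i0) {
    # hill support: walk out while non-increasing
    hi <- i0
    while (hi < n && vals[hi + 1] <= vals[hi]) hi <- hi + 1L
    lo <- i0
    while (lo > 1 && vals[lo - 1] <= vals[lo]) lo <- lo - 1L
    seg <- lo:hi
    sum(vals[seg] * wn[seg]) / sum(vals[seg])
  }
  heights <- vals[cand]
  pos <- vapply(cand, refine, numeric(1))
  ord <- order(heights, decreasing = TRUE)
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(pos[i] - kept) >= min_separation)) kept <- c(kept, pos[i])
  }
  kept
}
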