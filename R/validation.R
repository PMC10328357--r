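# run expr under a local RNG state so package functions do not disturb the
# caller's random stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# all permutations of 1..n (n small), one per row
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[r, ] <- c(k, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Permutation (randomised response) validation of a PLS calibration
#'
#' Guards against spurious fits: the calibration temperatures are shuffled
#' and the *full* pipeline (preprocessing refit, leave-one-out CV, AIC
#' factor selection) is rerun on each shuffled response, building a null
#' distribution of apparent cross-validated r-squared. The p-value uses the
#' add-one permutation formula `(1 + #(null >= observed)) / (n_perm + 1)`,
#' so it can never be exactly zero.
#'
#' @param X Raw calibration spectra (spectral matrix or numeric matrix).
#' @param y Known charring temperatures (degrees C).
#' @param F_max Maximum factor count (default `min(n-2, p)`).
#' @param n_perm Number of random shuffles (default 199).
#' @param seed Integer seed; the same seed reproduces the same null
#'   sequence exactly.
#' @param window,snv Preprocessing options, as in [loo_cv].
#' @param exhaustive If `TRUE` and `n <= 7`, enumerate all `n!` permutations
#'   instead of sampling; the p-value is then the exact proportion of
#'   permutations (identity included) whose r-squared reaches the observed.
#'
#' @return Object of class `"permutation_result"`: list with `observed_r2`,
#'   `null_r2`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_null <- function(X, y, F_max = NULL, n_perm = 199, seed = NULL,
                             window = 5, snv = TRUE, exhaustive = FALSE) {
  V <- if (inherits(X, "spectral_matrix")) X$values else as.matrix(X)
  n <- nrow(V)
  if (n < 3) stop("permutation_null: need at least 3 samples")
  if (!exhaustive && n_perm < 1)
    stop("permutation_null: n_perm must be at least 1")
  if (is.null(F_max)) F_max <- min(n - 2L, ncol(V))
  # the response permutation leaves the spectra untouched, so the per-row
  # SNV + filtering transform is shared by every rerun of the pipeline
  R <- .row_transform(V, window, snv)
  cv_r2 <- function(yy) .loo_cv_core(R, yy, as.integer(F_max))$r2
  observed <- cv_r2(y)
  if (exhaustive) {
    if (n > 7) stop("permutation_null: exhaustive enumeration limited to n <= 7")
    pm <- .all_perms(n)
    null_r2 <- apply(pm, 1L, function(ix) cv_r2(y[ix]))
    p_value <- mean(null_r2 >= observed)
    n_perm <- nrow(pm)
  } else {
    null_r2 <- .with_seed(seed, vapply(seq_len(n_perm), function(b)
      cv_r2(sample(y)), numeric(1)))
    p_value <- (1 + sum(null_r2 >= observed)) / (n_perm + 1)
  }
  structure(list(observed_r2 = observed, null_r2 = null_r2,
                 p_value = p_value, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation validation: observed CV r2 = %.4f, %d permutations, p = %.4g\n",
    x$observed_r2, x$n_perm, x$p_value))
  invisible(x)
}

#' Accept or reject a calibration model from its permutation test
#'
#' @param perm A `"permutation_result"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `accepted` (logical) and `reason` (character recording
#'   the observed r-squared, p-value and alpha).
#' @export
accept_model <- function(perm, alpha = 0.05) {
  stopifnot(inherits(perm, "permutation_result"))
  accepted <- perm$p_value < alpha
  reason <- sprintf(
    "observed CV r2 = %.4f; permutation p = %.4g %s alpha = %g: model %s",
    perm$observed_r2, perm$p_value, if (accepted) "<" else ">=", alpha,
    if (accepted) "accepted" else "rejected as potentially spurious")
  list(accepted = accepted, reason = reason)
}
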