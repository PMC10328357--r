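#' Standard normal variate transform
#'
#' Per-spectrum centering and scaling to unit sample standard deviation
#' (n-1 denominator), the standard chemometric correction for multiplicative
#' scatter and additive baseline offsets.
#'
#' @param x Numeric intensity vector, length >= 2.
#' @return The transformed vector: mean 0, sample sd 1.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("snv: vector must have at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("snv: degenerate spectrum (zero variance)")
  (x - mean(x)) / s
}

#' Moving median filter with edge replication
#'
#' Element i of the output is the median of the `window` values centred at
#' i, the ends padded by replicating the first and last values (nearest
#' padding). `window = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer, at most `length(x)`.
#' @return Filtered vector, same length as `x`.
#' @examples
#' median_filter(c(0, 0, 10, 0, 0), 3)  # spike removed
#' @export
median_filter <- function(x, window) {
  window <- as.integer(window)
  if (length(window) != 1 || is.na(window) || window < 1 || window %% 2 == 0)
    stop("median_filter: 'window' must be a positive odd integer")
  n <- length(x)
  if (window > n) stop("median_filter: 'window' exceeds vector length")
  if (window == 1) return(x)
  h <- (window - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  # column j of 'emb' holds the j-th element of each window
  emb <- vapply(seq_len(window), function(j) padded[j:(j + n - 1L)],
                numeric(n))
  apply(emb, 1L, stats::median)
}

#' Fit the spectral preprocessing stack
#'
#' Applies, in order: standard normal variate per spectrum, a moving median
#' filter per spectrum, then mean centering of each wavenumber column using
#' the calibration matrix itself. The calibration temperatures are centered
#' by their mean. All constants needed to reproduce the transform on new
#' spectra are returned in the state.
#'
#' @param X A [stack_spectra] result, or a numeric matrix on `grid`.
#' @param y Known charring temperatures, one per row of `X` (degrees C).
#' @param window Median filter window (odd, default 5 grid points).
#' @param snv Apply the SNV step (default `TRUE`); exposed for ablation.
#' @param grid The analysis grid (taken from `X` when it is a
#'   spectral matrix).
#'
#' @return List with `Xp` (processed matrix), `yp` (centered temperatures)
#'   and `state`, an object of class `"preprocess_state"` holding
#'   `column_means`, `y_mean`, `filter_window`, `snv` and `grid`.
#' @export
fit_preprocess <- function(X, y, window = 5, snv = TRUE, grid = NULL) {
  if (inherits(X, "spectral_matrix")) {
    grid <- X$grid
    ids <- X$meta$sample_id
    X <- X$values
  } else {
    X <- as.matrix(X)
    ids <- rownames(X)
    if (is.null(grid)) grid <- grid_spec(n_points = ncol(X))
  }
  if (nrow(X) == 0) stop("fit_preprocess: empty calibration matrix")
  if (length(y) != nrow(X))
    stop("fit_preprocess: length(y) must equal nrow(X)")
  Xp <- .row_transform(X, window, snv, ids)
  column_means <- colMeans(Xp)
  Xp <- sweep(Xp, 2L, column_means)
  y_mean <- mean(y)
  state <- structure(
    list(column_means = column_means, y_mean = y_mean,
         filter_window = as.integer(window), snv = snv, grid = grid),
    class = "preprocess_state")
  list(Xp = Xp, yp = y - y_mean, state = state)
}

# per-row SNV + median filter, with sample-id error reporting
.row_transform <- function(X, window, snv_on, ids = NULL) {
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    row <- X[i, ]
    if (snv_on) {
      row <- tryCatch(snv(row), error = function(e) {
        id <- if (!is.null(ids) && !is.na(ids[i])) ids[i] else paste0("row ", i)
        stop("fit_preprocess: degenerate spectrum for sample ", id,
             call. = FALSE)
      })
    }
    out[i, ] <- median_filter(row, window)
  }
  out
}

#' Apply a fitted preprocessing state to new spectra
#'
#' SNV and median filtering are per-spectrum operations; the column
#' centering uses the *stored* calibration column means, never statistics of
#' the new data, so held-out predictions cannot leak test-set information.
#'
#' @param X New spectra: a spectral matrix, a list of spectra, or a numeric
#'   matrix on the state's grid.
#' @param state A `"preprocess_state"` from [fit_preprocess].
#' @return Processed numeric matrix.
#' @export
apply_preprocess <- function(X, state) {
  stopifnot(inherits(state, "preprocess_state"))
  V <- .as_values(X, state$grid)
  Xp <- .row_transform(V, state$filter_window, state$snv)
  sweep(Xp, 2L, state$column_means)
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat(sprintf(
    "Preprocessing state: %s median filter window %d, %d column means, y mean %.2f degC\n",
    if (x$snv) "SNV +" else "no SNV,", x$filter_window,
    length(x$column_means), x$y_mean))
  invisible(x)
}
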