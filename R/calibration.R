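#' Fit a taxon-specific charring-temperature calibration
#'
#' The central fitting function of the package. Given laboratory calibration
#' spectra of one wood taxon charred at known temperatures, it runs the full
#' chemometric pipeline: leave-one-out cross-validation over candidate
#' latent-factor counts, AIC factor selection, a final NIPALS PLS1 fit on
#' all samples at the chosen factor count, and permutation (randomised
#' response) validation. The returned object carries everything needed to
#' predict the charring temperature of archaeological spectra of the same
#' taxon.
#'
#' @param X Calibration spectra: a `"spectral_matrix"` from [stack_spectra],
#'   a `"calibration_set"` from [simulate_calibration], a list of spectra,
#'   or a numeric matrix on `grid`.
#' @param temperatures Known charring temperatures in degrees C (taken from
#'   the calibration set when `X` is one).
#' @param taxon Taxon label (e.g. `"Olea"`, `"Quercus"`, `"Pinus"`).
#' @param window Median filter window in grid points (odd, default 5).
#' @param snv Apply the standard normal variate step (default `TRUE`).
#' @param F_max Maximum latent factor count evaluated (default
#'   `min(n - 2, p)`).
#' @param n_perm Permutations for the validation step (default 199).
#' @param alpha Significance level for model acceptance (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @param grid Analysis grid when `X` is a bare matrix.
#'
#' @return An object of class `"charcoal_calibration"`: list with `taxon`,
#'   `grid`, `state` (preprocessing constants), `fit` (the `"pls1_fit"`),
#'   `n_factors`, `cv` (the `"pls_cv"`), `perm` (the
#'   `"permutation_result"`), `accepted`, `reason`, `temperatures`,
#'   `fitted_values` and `call`.
#' @seealso [predict.charcoal_calibration], [vip], [predict_group]
#' @examples
#' cal_set <- simulate_calibration(taxon_preset("Olea"), seed = 7)
#' cal <- charcoal_calibration(cal_set, n_perm = 99, seed = 7)
#' print(cal)
#' @export
charcoal_calibration <- function(X, temperatures = NULL, taxon = NULL,
                                 window = 5, snv = TRUE, F_max = NULL,
                                 n_perm = 199, alpha = 0.05, seed = NULL,
                                 grid = NULL) {
  cl <- match.call()
  if (inherits(X, "calibration_set")) {
    if (is.null(temperatures)) temperatures <- X$temperatures
    if (is.null(taxon)) taxon <- X$taxon
    X <- X$spectra
  }
  if (is.null(taxon)) taxon <- "custom"
  if (inherits(X, "spectral_matrix")) {
    grid <- X$grid
    if (is.null(temperatures) && "known_temperature" %in% names(X$meta))
      temperatures <- as.numeric(X$meta$known_temperature)
    V <- X$values
  } else if (is.list(X) && !is.matrix(X)) {
    sm <- stack_spectra(X, if (is.null(grid)) grid_spec() else grid)
    grid <- sm$grid
    V <- sm$values
  } else {
    V <- as.matrix(X)
    if (is.null(grid)) grid <- grid_spec(n_points = ncol(V))
  }
  if (is.null(temperatures))
    stop("charcoal_calibration: calibration temperatures are required")
  y <- as.numeric(temperatures)
  n <- nrow(V)
  if (n < 3 || length(unique(y)) < 3)
    stop("charcoal_calibration: need at least 3 samples with at least 3 distinct temperatures")
  if (length(y) != n)
    stop("charcoal_calibration: one temperature per calibration spectrum required")

  cv <- loo_cv(V, y, F_max = F_max, window = window, snv = snv)
  pp <- fit_preprocess(V, y, window = window, snv = snv, grid = grid)
  fit <- fit_pls1(pp$Xp, pp$yp, ncomp = cv$chosen_factors, strict = FALSE)
  perm <- permutation_null(V, y, F_max = F_max, n_perm = n_perm, seed = seed,
                           window = window, snv = snv)
  verdict <- accept_model(perm, alpha = alpha)
  fitted_values <- predict(fit, pp$Xp) + pp$state$y_mean

  structure(list(taxon = taxon, grid = grid, state = pp$state, fit = fit,
                 n_factors = fit$ncomp, cv = cv, perm = perm,
                 accepted = verdict$accepted, reason = verdict$reason,
                 alpha = alpha, temperatures = y,
                 fitted_values = fitted_values, call = cl),
            class = "charcoal_calibration")
}

#' @export
print.charcoal_calibration <- function(x, ...) {
  cat(sprintf("Charring-temperature calibration for taxon '%s'\n", x$taxon))
  cat(sprintf("  %d calibration spectra, %g-%g degC\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures)))
  cat(sprintf("  latent factors: %d (AIC-selected)\n", x$n_factors))
  cat(sprintf("  cross-validated r2 = %.4f (p = %.3g), RMSECV = %.2f degC\n",
              x$cv$r2, x$cv$p_value, x$cv$rmsecv[x$cv$chosen_factors]))
  cat(sprintf("  permutation validation: p = %.4g -> %s\n", x$perm$p_value,
              if (x$accepted) "ACCEPTED" else "REJECTED (spurious)"))
  invisible(x)
}

#' @export
summary.charcoal_calibration <- function(object, ...) {
  out <- list(
    taxon = object$taxon,
    n = length(object$temperatures),
    factor_table = data.frame(factors = seq_along(object$cv$rmsecv),
                              rmsecv = object$cv$rmsecv,
                              aic = object$cv$aic),
    chosen_factors = object$n_factors,
    r2 = object$cv$r2, p_value = object$cv$p_value,
    perm_p = object$perm$p_value, accepted = object$accepted,
    reason = object$reason,
    top_bands = diagnostic_bands(vip(object), min_separation = 25))
  class(out) <- "summary.charcoal_calibration"
  out
}

#' @export
print.summary.charcoal_calibration <- function(x, ...) {
  cat(sprintf("Calibration summary, taxon '%s' (%d samples)\n", x$taxon, x$n))
  cat("\nFactor selection (leave-one-out CV):\n")
  tab <- x$factor_table
  tab$rmsecv <- round(tab$rmsecv, 2)
  tab$aic <- round(tab$aic, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("\nChosen factors: %d\nCV r2 = %.4f (p = %.3g)\n",
              x$chosen_factors, x$r2, x$p_value))
  cat(x$reason, "\n")
  if (length(x$top_bands))
    cat("Diagnostic bands (VIP > 1): ",
        paste(round(x$top_bands), collapse = ", "), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
coef.charcoal_calibration <- function(object, ...) {
  if (object$n_factors == 0)
    return(stats::setNames(object$state$y_mean, "(Intercept)"))
  b <- object$fit$coef[, object$n_factors]
  intercept <- object$state$y_mean - sum(object$state$column_means * b)
  stats::setNames(c(intercept, b),
                  c("(Intercept)", format(round(object$grid$axis, 2))))
}

#' @export
fitted.charcoal_calibration <- function(object, ...) object$fitted_values

#' @export
residuals.charcoal_calibration <- function(object, ...)
  object$temperatures - object$fitted_values

#' Predict charring temperatures for new spectra
#'
#' Applies the stored preprocessing (SNV, median filter, calibration column
#' means) and the fitted PLS1 factors, then adds back the calibration mean
#' temperature. Predictions are *not* clipped to the calibration range;
#' a warning reports extrapolation beyond it.
#'
#' @param object A `"charcoal_calibration"`.
#' @param newdata New spectra: spectral matrix, list of spectra, or numeric
#'   matrix on the model grid.
#' @param force Predict even from a model whose permutation validation
#'   failed (default `FALSE`).
#' @param ... Unused.
#' @return Numeric vector of predicted temperatures in degrees C.
#' @export
predict.charcoal_calibration <- function(object, newdata, force = FALSE, ...) {
  if (!object$accepted && !force)
    stop("predict.charcoal_calibration: model flagged spurious by permutation ",
         "validation; use force = TRUE to override (", object$reason, ")")
  Xp <- apply_preprocess(newdata, object$state)
  pred <- predict(object$fit, Xp) + object$state$y_mean
  rng <- range(object$temperatures)
  if (any(pred < rng[1] | pred > rng[2]))
    warning(sprintf(
      "prediction%s outside the calibration range %g-%g degC (extrapolation)",
      if (sum(pred < rng[1] | pred > rng[2]) > 1) "s" else "", rng[1], rng[2]))
  pred
}

#' @rdname vip
#' @export
vip.charcoal_calibration <- function(x, ...)
  vip(x$fit, wavenumbers = x$grid$axis)

#' @export
plot.charcoal_calibration <- function(x, which = c("cv", "vip"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("cv" %in% which) {
    graphics::plot(x$cv$observed, x$cv$predicted,
                   xlab = "Observed temperature (degC)",
                   ylab = "LOO-CV predicted temperature (degC)",
                   main = sprintf("%s: CV r2 = %.3f", x$taxon, x$cv$r2), ...)
    graphics::abline(0, 1, lty = 2)
  }
  if ("vip" %in% which) {
    v <- vip(x)
    graphics::plot(v$wavenumbers, v$values, type = "l", xlim =
                   rev(range(v$wavenumbers)),
                   xlab = "Wavenumber (cm^-1)", ylab = "VIP",
                   main = "Variable importance")
    graphics::abline(h = 1, lty = 3)
  }
  invisible(x)
}

#' Predict and summarise a group of archaeological spectra
#'
#' Predicts each replicate spectrum of one taxon-by-context group (e.g. all
#' Pinus particles from one stratigraphic unit) and reports the unrounded
#' mean, minimum and maximum; rounding is left to report time.
#'
#' @param object An accepted `"charcoal_calibration"`.
#' @param spectra Replicate spectra of the group.
#' @param group Group label, e.g. `"Pinus/SU74"`.
#' @param force Passed to [predict.charcoal_calibration].
#' @return Object of class `"temperature_prediction"`: list with `group`,
#'   `taxon`, `per_spectrum`, `mean`, `min`, `max`, `n`.
#' @export
predict_group <- function(object, spectra, group = "group", force = FALSE) {
  stopifnot(inherits(object, "charcoal_calibration"))
  pred <- suppressWarnings(
    predict(object, spectra, force = force))
  if (length(pred) < 1) stop("predict_group: no spectra supplied")
  structure(list(group = group, taxon = object$taxon, per_spectrum = pred,
                 mean = mean(pred), min = min(pred), max = max(pred),
                 n = length(pred)),
            class = "temperature_prediction")
}

#' Construct a group temperature prediction from values
#'
#' Builds the same summary object as [predict_group] from already-predicted
#' (or published) per-spectrum temperatures, so group contrasts and reports
#' can be formed from tabulated values.
#'
#' @param per_spectrum Predicted temperatures, degrees C (nonempty).
#' @param group Group label.
#' @param taxon Taxon label.
#' @return A `"temperature_prediction"`.
#' @export
temperature_prediction <- function(per_spectrum, group = "group",
                                   taxon = "custom") {
  per_spectrum <- as.numeric(per_spectrum)
  if (length(per_spectrum) < 1)
    stop("temperature_prediction: per_spectrum must be nonempty")
  structure(list(group = group, taxon = taxon, per_spectrum = per_spectrum,
                 mean = mean(per_spectrum), min = min(per_spectrum),
                 max = max(per_spectrum), n = length(per_spectrum)),
            class = "temperature_prediction")
}

#' @export
print.temperature_prediction <- function(x, ...) {
  cat(sprintf("%s (taxon %s): n = %d, mean %.0f degC (range %.0f-%.0f)\n",
              x$group, x$taxon, x$n, round_half_away(x$mean),
              round_half_away(x$min), round_half_away(x$max)))
  invisible(x)
}

#' Temperature contrast between two groups of the same taxon
#'
#' Difference of group mean temperatures (a minus b), for example the same
#' taxon in two stratigraphic units.
#'
#' @param pred_a,pred_b `"temperature_prediction"` objects of one taxon.
#' @return List with `difference` (unrounded degC) and `rounded`.
#' @export
su_contrast <- function(pred_a, pred_b) {
  stopifnot(inherits(pred_a, "temperature_prediction"),
            inherits(pred_b, "temperature_prediction"))
  if (!identical(pred_a$taxon, pred_b$taxon))
    stop(sprintf("su_contrast: taxon mismatch ('%s' vs '%s')",
                 pred_a$taxon, pred_b$taxon))
  d <- pred_a$mean - pred_b$mean
  list(difference = d, rounded = round_half_away(d))
}

#' Round half away from zero
#'
#' Report-time rounding convention (0.5 always rounds away from zero,
#' unlike base [round]'s banker's rounding), matching printed one-decimal
#' percentages and integer temperatures in field reports.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @examples
#' round_half_away(8.45, 1)  # 8.5
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
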