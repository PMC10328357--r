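#' Gaussian band specification for the spectrum generator
#'
#' One mid-infrared absorption band: a Gaussian profile whose peak amplitude
#' changes linearly with charring temperature. The sign of `temp_slope`
#' encodes whether the band grows (aromatisation products) or decays
#' (thermally labile groups) as charring temperature rises.
#'
#' @param center Band centre, cm\eqn{^{-1}}, inside the analysis window.
#' @param width Gaussian sigma, cm\eqn{^{-1}} (> 0).
#' @param base_amplitude Peak absorbance at the 475 degC anchor.
#' @param temp_slope Absorbance change per degC (may be 0 or negative).
#' @return A list of class `"band_spec"`.
#' @export
band_spec <- function(center, width, base_amplitude, temp_slope = 0) {
  if (width <= 0) stop("band_spec: width must be positive")
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude, temp_slope = temp_slope),
            class = "band_spec")
}

#' Synthetic spectrum generator configuration
#'
#' Statistical model of a charred-wood MIR spectrum: a sum of Gaussian bands
#' with linearly temperature-dependent amplitudes on a sloping baseline,
#' scaled by a per-spectrum log-normal multiplicative scatter factor, plus
#' i.i.d. additive Gaussian noise. This is the minimal structure under which
#' the PLS linearity assumption holds exactly when noise is switched off.
#'
#' @param bands List of [band_spec] objects.
#' @param baseline_offset Constant baseline absorbance (default 0.1).
#' @param baseline_slope Baseline change across the window, low to high end
#'   (default 0.05).
#' @param scatter_sd Log-scale sd of the multiplicative scatter factor
#'   (default 0.05).
#' @param noise_sd Additive absorbance noise sd (default 0.005).
#' @param grid Analysis grid (default [grid_spec()]).
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(bands, baseline_offset = 0.1,
                             baseline_slope = 0.05, scatter_sd = 0.05,
                             noise_sd = 0.005, grid = grid_spec()) {
  stopifnot(all(vapply(bands, inherits, logical(1), "band_spec")))
  if (noise_sd < 0 || scatter_sd < 0)
    stop("generator_config: noise_sd and scatter_sd must be nonnegative")
  for (b in bands)
    if (b$center < grid$low || b$center > grid$high)
      stop(sprintf("generator_config: band at %g cm^-1 outside the window",
                   b$center))
  structure(list(bands = bands, baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, scatter_sd = scatter_sd,
                 noise_sd = noise_sd, grid = grid),
            class = "generator_config")
}

# fixture constants for the three reference taxa: temperature-sensitive
# diagnostic bands per taxon plus temperature-insensitive filler bands.
# Widths (12 cm^-1 sigma), amplitudes and slopes (+-4e-4 absorbance/degC)
# are the package's own invented values, not measured ones.
.preset_bands <- list(
  Olea = list(
    c(1730, 0.60, -4e-4), c(1580, 0.80, +4e-4), c(1410, 0.60, +4e-4),
    c(800, 0.35, -4e-4), c(740, 0.30, -4e-4)),
  Quercus = list(
    c(1580, 0.80, +4e-4), c(1410, 0.60, +4e-4), c(1370, 0.50, +4e-4),
    c(800, 0.35, -4e-4), c(740, 0.30, -4e-4), c(1730, 0.60, 0)),
  Pinus = list(
    c(1730, 0.60, -4e-4), c(1410, 0.60, +4e-4), c(1370, 0.50, +4e-4),
    c(1245, 0.50, -4e-4), c(1040, 0.90, -4e-4))
)
.filler_bands <- list(c(1570, 0.70, 0), c(1380, 0.45, 0), c(1270, 0.40, 0),
                      c(1040, 0.90, 0))

#' Generator preset for a reference taxon
#'
#' Returns a [generator_config] whose temperature-sensitive bands are the
#' diagnostic band sets of the three laboratory reference taxa (Olea:
#' 1730, 1580, 1410, 800, 740 cm\eqn{^{-1}}; Quercus: 1580, 1410, 1370,
#' 800, 740, with 1730 present but temperature-insensitive; Pinus: 1730,
#' 1410, 1370, 1245, 1040), plus insensitive filler bands at 1570, 1380,
#' 1270 and 1040 cm\eqn{^{-1}} for realism.
#'
#' @param taxon `"Olea"`, `"Quercus"` or `"Pinus"`.
#' @param ... Overrides passed on to [generator_config] (e.g. `noise_sd = 0`).
#' @return A `"generator_config"` with a `taxon` attribute.
#' @export
taxon_preset <- function(taxon = c("Olea", "Quercus", "Pinus"), ...) {
  taxon <- match.arg(taxon)
  spec <- .preset_bands[[taxon]]
  sens_centers <- vapply(spec, `[`, numeric(1), 1)
  # a filler within 20 cm^-1 of a preset band would be sub-resolution
  # (band sigma 12): physically the same band, so it is not duplicated
  fillers <- Filter(function(b) all(abs(b[1] - sens_centers) > 20),
                    .filler_bands)
  bands <- lapply(c(spec, fillers), function(b)
    band_spec(center = b[1], width = 12, base_amplitude = b[2],
              temp_slope = b[3]))
  cfg <- generator_config(bands, ...)
  cfg$taxon <- taxon
  cfg
}

# noiseless expected spectrum at temperature T on the config grid
.clean_spectrum <- function(temperature, cfg) {
  wn <- cfg$grid$axis
  base <- cfg$baseline_offset + cfg$baseline_slope *
    (wn - cfg$grid$low) / (cfg$grid$high - cfg$grid$low)
  for (b in cfg$bands) {
    amp <- b$base_amplitude + b$temp_slope * (temperature - 475)
    base <- base + amp * exp(-(wn - b$center)^2 / (2 * b$width^2))
  }
  base
}

#' Simulate one charred-wood spectrum
#'
#' `intensity = m * clean(T) + eps`, where `clean(T)` is the band-plus-
#' baseline model at temperature `T`, `m` is a per-spectrum log-normal
#' scatter factor (`meanlog = 0, sdlog = scatter_sd`) and `eps` is i.i.d.
#' Gaussian noise. Deterministic for a fixed seed. Negative intensities are
#' floored at zero with a warning.
#'
#' @param temperature Charring temperature in degrees C (0--1200).
#' @param cfg A [generator_config].
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return A [mir_spectrum] with `known_temperature` in its metadata.
#' @export
simulate_spectrum <- function(temperature, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (temperature < 0 || temperature > 1200)
    stop("simulate_spectrum: temperature outside the sane range 0-1200 degC")
  clean <- .clean_spectrum(temperature, cfg)
  vals <- .with_seed(seed, {
    m <- if (cfg$scatter_sd > 0) stats::rlnorm(1, 0, cfg$scatter_sd) else 1
    eps <- if (cfg$noise_sd > 0)
      stats::rnorm(length(clean), 0, cfg$noise_sd) else 0
    m * clean + eps
  })
  if (any(vals < 0)) {
    warning("simulate_spectrum: negative intensities floored at 0")
    vals[vals < 0] <- 0
  }
  mir_spectrum(cfg$grid$axis, vals,
               meta = list(known_temperature = temperature,
                           taxon = if (is.null(cfg$taxon)) "custom" else cfg$taxon,
                           source = "synthetic"))
}

#' Simulate a laboratory calibration set
#'
#' Reproduces the calibration design: one (or more) composite spectrum per
#' furnace step over the 350--600 degC range in 50 degC increments. Each
#' spectrum gets a distinct sub-seed derived from `seed`, so the whole set
#' is reproducible.
#'
#' @param cfg A [generator_config] (typically a [taxon_preset]).
#' @param temperatures Charring temperatures, degrees C (default
#'   `seq(350, 600, by = 50)`).
#' @param reps Replicate spectra per temperature (default 1).
#' @param seed Integer seed.
#' @return Object of class `"calibration_set"`: list with `spectra` (a
#'   `"spectral_matrix"`), `temperatures` (one per row) and `taxon`.
#' @export
simulate_calibration <- function(cfg, temperatures = seq(350, 600, by = 50),
                                 reps = 1, seed = NULL) {
  if (length(temperatures) == 0)
    stop("simulate_calibration: empty temperature list")
  temps <- rep(temperatures, each = reps)
  specs <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    sub <- if (is.null(seed)) NULL else (seed + i - 1L) %% .Machine$integer.max
    specs[[i]] <- simulate_spectrum(temps[i], cfg, seed = sub)
    specs[[i]]$meta$sample_id <- sprintf("cal_%03d_%dC", i, temps[i])
  }
  structure(list(spectra = stack_spectra(specs, cfg$grid),
                 temperatures = temps,
                 taxon = if (is.null(cfg$taxon)) "custom" else cfg$taxon),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("Synthetic calibration set (%s): %d spectra at %s degC\n",
              x$taxon, length(x$temperatures),
              paste(unique(x$temperatures), collapse = "/")))
  invisible(x)
}

#' Simulate archaeological replicate spectra at one true temperature
#'
#' Stand-in for archaeological charcoal spectra (which are never deposited
#' with known temperatures): `n` spectra at `true_T` under the same noise
#' model, the truth recorded in metadata for recovery scoring.
#'
#' @param cfg A [generator_config].
#' @param true_T True charring temperature, degrees C.
#' @param n Number of replicate spectra (>= 1).
#' @param seed Integer seed.
#' @return A `"spectral_matrix"` whose metadata carries `true_T`.
#' @export
simulate_archaeological <- function(cfg, true_T, n, seed = NULL) {
  if (n < 1) stop("simulate_archaeological: n must be at least 1")
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- if (is.null(seed)) NULL else (seed + 7919L * i) %% .Machine$integer.max
    specs[[i]] <- simulate_spectrum(true_T, cfg, seed = sub)
    specs[[i]]$meta$sample_id <- sprintf("arch_%03d", i)
    specs[[i]]$meta$true_T <- true_T
    specs[[i]]$meta$source <- "synthetic-archaeological"
  }
  stack_spectra(specs, cfg$grid)
}

#' Simulate a charcoal count table
#'
#' Seeded multinomial draws per stratigraphic unit, for exercising the
#' assemblage statistics on random fixtures.
#'
#' @param taxa_probs Taxon-by-SU matrix of probabilities; each column must
#'   sum to 1 (tolerance 1e-9). Rownames are taxa, colnames SUs.
#' @param totals Named vector of fragment totals per SU.
#' @param seed Integer seed.
#' @return A [taxon_count_table].
#' @export
simulate_count_table <- function(taxa_probs, totals, seed = NULL) {
  taxa_probs <- as.matrix(taxa_probs)
  sums <- colSums(taxa_probs)
  if (any(abs(sums - 1) > 1e-9))
    stop("simulate_count_table: per-SU probabilities must sum to 1")
  if (length(totals) != ncol(taxa_probs))
    stop("simulate_count_table: one total per SU required")
  counts <- .with_seed(seed, {
    out <- matrix(0L, nrow(taxa_probs), ncol(taxa_probs),
                  dimnames = dimnames(taxa_probs))
    for (j in seq_len(ncol(out)))
      out[, j] <- stats::rmultinom(1, totals[j], taxa_probs[, j])
    out
  })
  taxon_count_table(counts)
}
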