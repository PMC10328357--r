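#' Wavenumber grid specification
#'
#' Defines the common analysis axis onto which all spectra are resampled
#' before modelling. The default grid covers the fingerprint window
#' 1800--400 cm\eqn{^{-1}} at 250 uniformly spaced points in descending
#' wavenumber order (the spectroscopic display convention), giving a spacing
#' of about 5.6 cm\eqn{^{-1}}.
#'
#' @param high Upper wavenumber bound in cm\eqn{^{-1}} (default 1800).
#' @param low Lower wavenumber bound in cm\eqn{^{-1}} (default 400).
#' @param n_points Number of grid points (default 250).
#'
#' @return An object of class `"grid_spec"`: a list with elements `high`,
#'   `low`, `n_points` and `axis` (the descending wavenumber vector).
#' @examples
#' g <- grid_spec()
#' head(g$axis)
#' @export
grid_spec <- function(high = 1800, low = 400, n_points = 250) {
  stopifnot(is.numeric(high), is.numeric(low), is.numeric(n_points))
  if (!(high > low)) stop("grid_spec: 'high' must exceed 'low'")
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("grid_spec: 'n_points' must be at least 2")
  structure(
    list(high = high, low = low, n_points = n_points,
         axis = seq(high, low, length.out = n_points)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %g to %g cm^-1, %d points (spacing %.3f cm^-1)\n",
              x$high, x$low, x$n_points, (x$high - x$low) / (x$n_points - 1)))
  invisible(x)
}

#' Construct a single mid-infrared spectrum
#'
#' @param wavenumbers Strictly monotone numeric vector, cm\eqn{^{-1}}.
#' @param intensities Absorbance values, same length as `wavenumbers`.
#' @param meta Named list of free-form labels (sample id, taxon, source,
#'   known charring temperature, stratigraphic unit, ...).
#'
#' @return An object of class `"mir_spectrum"`.
#' @examples
#' s <- mir_spectrum(c(1800, 1100, 400), c(0.2, 0.5, 0.3),
#'                   meta = list(sample_id = "OLE-350"))
#' @export
mir_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("mir_spectrum: wavenumbers and intensities differ in length")
  if (length(wavenumbers) < 2)
    stop("mir_spectrum: a spectrum needs at least 2 points")
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0)))
    stop("mir_spectrum: wavenumbers must be strictly monotone (duplicates or reversals found)")
  if (!all(is.finite(intensities)))
    stop("mir_spectrum: intensities must all be finite")
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = as.list(meta)),
            class = "mir_spectrum")
}

#' @export
print.mir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("MIR spectrum: %d points, %g-%g cm^-1", length(x$wavenumbers),
              rng[2], rng[1]))
  if (!is.null(x$meta$sample_id)) cat(sprintf(" [%s]", x$meta$sample_id))
  cat("\n")
  invisible(x)
}

# Detect whether the first line of a delimited file is a header
# (any field that does not parse as a number).
.has_header <- function(path, sep) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(";", first, fixed = TRUE)) ";" else ","
}

#' Read spectra from CSV files
#'
#' Two dialects are supported. `"two-column"`: one spectrum per file,
#' wavenumber and intensity columns, optional header. `"wide"`: one sample
#' per row; the first column is the sample id and the remaining column
#' headers are wavenumbers. Comma or semicolon separators are auto-detected;
#' decimal points must be dots. With `dialect = "auto"` the wide form is
#' assumed when the file has more than two columns.
#'
#' @param path Path to a CSV file.
#' @param dialect `"auto"`, `"two-column"` or `"wide"`.
#' @param meta Optional data frame of per-sample metadata with a
#'   `sample_id` column, merged into each spectrum's `meta` by id.
#'
#' @return A single [mir_spectrum] (two-column dialect) or a list of them
#'   (wide dialect).
#' @export
read_spectra <- function(path, dialect = c("auto", "two-column", "wide"),
                         meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_spectra: file not found: ", path)
  sep <- .sniff_sep(path)
  header <- .has_header(path, sep)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           skip = if (header) 1L else 0L,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (dialect == "auto")
    dialect <- if (ncol(raw) > 2) "wide" else "two-column"

  parse_num <- function(x, what, rows, cols) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(x))
    if (length(bad))
      stop(sprintf("read_spectra: non-numeric %s at row %d, column %d ('%s')",
                   what, rows[bad[1]], cols[bad[1]], x[bad[1]]))
    if (anyNA(v))
      stop("read_spectra: missing ", what, " value")
    v
  }

  if (dialect == "two-column") {
    if (ncol(raw) < 2) stop("read_spectra: two-column dialect needs 2 columns")
    nr <- nrow(raw)
    wn <- parse_num(raw[[1]], "wavenumber", seq_len(nr) + header, rep(1L, nr))
    ab <- parse_num(raw[[2]], "intensity", seq_len(nr) + header, rep(2L, nr))
    if (anyDuplicated(wn)) stop("read_spectra: duplicate wavenumbers in ", path)
    m <- list(source_file = basename(path))
    return(mir_spectrum(wn, ab, meta = m))
  }

  # wide dialect: need the header row for the wavenumber axis
  if (!header)
    stop("read_spectra: wide dialect requires a header row of wavenumbers")
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  wn <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(wn))
    stop("read_spectra: wide dialect header has non-numeric wavenumber labels")
  if (anyDuplicated(wn)) stop("read_spectra: duplicate wavenumbers in header")
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    vals <- parse_num(unlist(raw[i, -1], use.names = FALSE), "intensity",
                      rep(i + 1L, ncol(raw) - 1L), seq_len(ncol(raw) - 1L) + 1L)
    m <- list(sample_id = raw[i, 1], source_file = basename(path))
    if (!is.null(meta) && "sample_id" %in% names(meta)) {
      row <- meta[meta$sample_id == raw[i, 1], , drop = FALSE]
      if (nrow(row) == 1) m <- utils::modifyList(m, as.list(row))
    }
    out[[i]] <- mir_spectrum(wn, vals, meta = m)
  }
  out
}

#' Resample a spectrum onto an analysis grid
#'
#' Linear interpolation onto the uniform descending grid. No extrapolation:
#' the grid must lie within the span of the source spectrum.
#'
#' @param s A [mir_spectrum].
#' @param grid A [grid_spec] (default: the standard 1800--400 cm\eqn{^{-1}},
#'   250-point grid).
#'
#' @return A [mir_spectrum] on `grid$axis`, metadata preserved.
#' @export
resample_to_grid <- function(s, grid = grid_spec()) {
  stopifnot(inherits(s, "mir_spectrum"), inherits(grid, "grid_spec"))
  span <- range(s$wavenumbers)
  if (grid$low < span[1] || grid$high > span[2])
    stop(sprintf(paste0("resample_to_grid: grid %g-%g cm^-1 extends beyond the ",
                        "source span %g-%g cm^-1 (no extrapolation)"),
                 grid$low, grid$high, span[1], span[2]))
  # already on the grid: return intensities untouched (bitwise identity)
  if (length(s$wavenumbers) == grid$n_points &&
      isTRUE(all.equal(s$wavenumbers, grid$axis, tolerance = 0)))
    return(s)
  ord <- order(s$wavenumbers)   # approx needs an ascending abscissa
  vals <- stats::approx(s$wavenumbers[ord], s$intensities[ord],
                        xout = grid$axis, method = "linear",
                        ties = "ordered")$y
  mir_spectrum(grid$axis, vals, meta = s$meta)
}

#' Stack spectra into a sample-by-wavenumber matrix
#'
#' Each spectrum is resampled onto the grid and becomes one row, in input
#' order. Per-spectrum metadata is collected into a data frame.
#'
#' @param spectra A list of [mir_spectrum] objects (a single spectrum is
#'   accepted).
#' @param grid A [grid_spec].
#'
#' @return An object of class `"spectral_matrix"`: list with `grid`,
#'   `values` (n x n_points matrix) and `meta` (data frame, one row per
#'   sample).
#' @export
stack_spectra <- function(spectra, grid = grid_spec()) {
  if (inherits(spectra, "mir_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) stop("stack_spectra: empty spectrum list")
  if (!all(vapply(spectra, inherits, logical(1), "mir_spectrum")))
    stop("stack_spectra: all elements must be mir_spectrum objects")
  rs <- lapply(spectra, resample_to_grid, grid = grid)
  values <- do.call(rbind, lapply(rs, `[[`, "intensities"))
  keys <- unique(unlist(lapply(rs, function(s) names(s$meta))))
  meta <- if (length(keys)) {
    as.data.frame(
      lapply(stats::setNames(keys, keys), function(k)
        vapply(rs, function(s) {
          v <- s$meta[[k]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = seq_along(rs))
  }
  structure(list(grid = grid, values = values, meta = meta),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("Spectral matrix: %d spectra x %d wavenumbers (%g-%g cm^-1)\n",
              nrow(x$values), ncol(x$values), x$grid$high, x$grid$low))
  invisible(x)
}

# internal: coerce matrix-like input (spectral_matrix, matrix, spectrum list)
# to a plain matrix on the expected grid
.as_values <- function(X, grid) {
  if (inherits(X, "spectral_matrix")) {
    if (X$grid$n_points != grid$n_points ||
        !isTRUE(all.equal(X$grid$axis, grid$axis)))
      stop("grid mismatch: input spectra are not on the model grid")
    return(X$values)
  }
  if (inherits(X, "mir_spectrum"))
    return(stack_spectra(list(X), grid)$values)
  if (is.list(X)) return(stack_spectra(X, grid)$values)
  X <- as.matrix(X)
  if (ncol(X) != grid$n_points)
    stop(sprintf("grid mismatch: matrix has %d columns, grid has %d points",
                 ncol(X), grid$n_points))
  X
}
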