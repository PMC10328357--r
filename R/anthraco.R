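#' Charcoal assemblage count table
#'
#' Container for anthracological quantification: fragment counts per taxon
#' and stratigraphic unit (SU), optional size-class counts and optional
#' anatomical-feature counts (e.g. vitrification).
#'
#' @param counts Nonnegative integer matrix, taxa in rows (rownames), SUs in
#'   columns (colnames). A tidy data frame with columns `taxon`, `su`,
#'   `count` is also accepted.
#' @param indeterminate Taxon labels excluded from the minimum-taxa count
#'   (e.g. `"Angiosperm"`).
#' @param size_classes Optional taxon-by-class count matrix; per-taxon
#'   totals must not exceed the taxon total.
#' @param feature_counts Optional data frame with columns `taxon`,
#'   `feature`, `count`; each count must not exceed the taxon total.
#'
#' @return Object of class `"taxon_count_table"`.
#' @export
taxon_count_table <- function(counts, indeterminate = character(),
                              size_classes = NULL, feature_counts = NULL) {
  if (is.data.frame(counts) &&
      all(c("taxon", "su", "count") %in% names(counts))) {
    counts <- stats::xtabs(count ~ taxon + su, data = counts)
    counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("taxon_count_table: counts need taxon rownames and SU colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("taxon_count_table: counts must be nonnegative integers")
  totals <- rowSums(counts)
  if (!is.null(size_classes)) {
    size_classes <- as.matrix(size_classes)
    bad <- rowSums(size_classes) > totals[rownames(size_classes)]
    if (any(bad, na.rm = TRUE))
      stop("taxon_count_table: size-class totals exceed taxon totals for ",
           paste(rownames(size_classes)[bad], collapse = ", "))
  }
  if (!is.null(feature_counts)) {
    stopifnot(all(c("taxon", "feature", "count") %in% names(feature_counts)))
    over <- feature_counts$count > totals[feature_counts$taxon]
    if (any(over, na.rm = TRUE))
      stop("taxon_count_table: feature counts exceed taxon totals")
  }
  structure(list(counts = counts, indeterminate = indeterminate,
                 size_classes = size_classes,
                 feature_counts = feature_counts),
            class = "taxon_count_table")
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat(sprintf("Charcoal count table: %d taxa x %d SUs, %d fragments\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Relative frequencies of taxa
#'
#' Per-SU percentage `100 * N_taxon(SU) / N_total(SU)` and the overall
#' percentage from summed counts. Values are returned unrounded; report
#' rounding is one decimal, half away from zero ([round_half_away]).
#'
#' @param x A [taxon_count_table].
#' @return List with `per_su` (taxon x SU percentage matrix) and `overall`
#'   (named vector).
#' @export
relative_frequencies <- function(x) {
  stopifnot(inherits(x, "taxon_count_table"))
  if (sum(x$counts) == 0) stop("relative_frequencies: all-zero count table")
  per_su <- sweep(x$counts, 2L, colSums(x$counts), `/`) * 100
  overall <- rowSums(x$counts) / sum(x$counts) * 100
  list(per_su = per_su, overall = overall)
}

#' Ubiquity-corrected relative frequencies (%U)
#'
#' For taxon A over n stratigraphic units,
#' `%U(A) = (%A(SU1) + ... + %A(SUn)) / n`, the plain mean of the per-SU
#' relative frequencies. Every SU in the table contributes, including those
#' where the taxon is absent (a 0 term), which is what distinguishes %U from
#' the abundance-weighted overall percentage. Unrounded per-SU percentages
#' are used.
#'
#' @param x A [taxon_count_table].
#' @return Named numeric vector of %U values (sums to 100 across taxa).
#' @export
ubiquity_correction <- function(x) {
  rf <- relative_frequencies(x)
  rowMeans(rf$per_su)
}

#' Combined share of the k most abundant taxa
#'
#' Top k taxa ranked by overall fragment count; their summed overall
#' percentage and summed %U.
#'
#' @param x A [taxon_count_table].
#' @param k Number of taxa to combine.
#' @return List with `taxa`, `percent`, `percent_u` (unrounded).
#' @export
main_taxa_share <- function(x, k) {
  stopifnot(inherits(x, "taxon_count_table"))
  if (k > nrow(x$counts)) stop("main_taxa_share: k exceeds the number of taxa")
  rf <- relative_frequencies(x)
  u <- ubiquity_correction(x)
  top <- names(sort(rowSums(x$counts), decreasing = TRUE))[seq_len(k)]
  list(taxa = top, percent = sum(rf$overall[top]), percent_u = sum(u[top]))
}

#' Minimum number of taxa in one stratigraphic unit
#'
#' Counts taxa with at least one fragment in the SU, excluding labels marked
#' indeterminate (fragments identifiable only above the taxon level, e.g.
#' "Angiosperm", do not add a taxon).
#'
#' @param x A [taxon_count_table].
#' @param su SU label.
#' @return Integer count.
#' @export
minimum_taxa_number <- function(x, su) {
  stopifnot(inherits(x, "taxon_count_table"))
  if (!su %in% colnames(x$counts))
    stop("minimum_taxa_number: unknown SU '", su, "'")
  keep <- setdiff(rownames(x$counts), x$indeterminate)
  sum(x$counts[keep, su] > 0)
}

#' Prevalence of an anatomical feature within a taxon
#'
#' Percentage of a taxon's fragments showing a recorded feature
#' (vitrification, radial cracks, ...): `100 * feature count / taxon total`.
#'
#' @param x A [taxon_count_table] with `feature_counts`.
#' @param taxon Taxon label.
#' @param feature Feature label.
#' @return Unrounded percentage.
#' @export
feature_prevalence <- function(x, taxon, feature) {
  stopifnot(inherits(x, "taxon_count_table"))
  fc <- x$feature_counts
  if (is.null(fc)) stop("feature_prevalence: no feature counts recorded")
  row <- fc[fc$taxon == taxon & fc$feature == feature, , drop = FALSE]
  if (nrow(row) != 1)
    stop(sprintf("feature_prevalence: no record of feature '%s' for taxon '%s'",
                 feature, taxon))
  total <- sum(x$counts[taxon, ])
  if (total == 0) stop("feature_prevalence: taxon has zero fragments")
  100 * row$count / total
}

#' Assemblage report table
#'
#' One row per taxon with fragment counts, per-SU and overall relative
#' frequencies, and %U, rounded to one decimal (half away from zero) the way
#' assemblage tables are printed.
#'
#' @param x A [taxon_count_table].
#' @return A data frame.
#' @export
assemblage_report <- function(x) {
  rf <- relative_frequencies(x)
  u <- ubiquity_correction(x)
  out <- data.frame(taxon = rownames(x$counts),
                    stringsAsFactors = FALSE)
  for (su in colnames(x$counts)) {
    out[[paste0("N_", su)]] <- x$counts[, su]
    out[[paste0("pct_", su)]] <- round_half_away(rf$per_su[, su], 1)
  }
  out$N_total <- rowSums(x$counts)
  out$pct_total <- round_half_away(rf$overall, 1)
  out$pct_U <- round_half_away(u, 1)
  rownames(out) <- NULL
  out
}

#' Pit 16 charcoal counts (published assemblage)
#'
#' The fragment counts of the Pit 16 charcoal assemblage (stratigraphic
#' units SU72 and SU74): 754 fragments over 8 taxon labels, with
#' "Angiosperm" marking fragments identifiable only to division level
#' (excluded from minimum-taxa counts). Recorded anatomical features:
#' vitrification in 85 Quercus fragments, radial cracks in 90 and tracheid
#' grooves in 27 Pinus fragments.
#'
#' @return A [taxon_count_table].
#' @examples
#' t <- pit16_counts()
#' round_half_away(ubiquity_correction(t), 1)
#' @export
pit16_counts <- function() {
  counts <- matrix(
    c(33, 215,   # Olea europaea
      66, 162,   # Quercus spp. (evergreen)
      99, 57,    # Pinus pinaster
      0, 10,     # Fraxinus cf. angustifolia
      8, 33,     # Cistus sp.
      2, 14,     # Fabaceae
      0, 7,      # Arbutus unedo
      0, 48),    # Angiosperm (indeterminate)
    ncol = 2, byrow = TRUE,
    dimnames = list(c("Olea europaea", "Quercus spp.", "Pinus pinaster",
                      "Fraxinus cf. angustifolia", "Cistus sp.", "Fabaceae",
                      "Arbutus unedo", "Angiosperm"),
                    c("SU72", "SU74")))
  features <- data.frame(
    taxon = c("Quercus spp.", "Pinus pinaster", "Pinus pinaster"),
    feature = c("vitrification", "radial cracks", "tracheid grooves"),
    count = c(85, 90, 27),
    stringsAsFactors = FALSE)
  taxon_count_table(counts, indeterminate = "Angiosperm",
                    feature_counts = features)
}
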