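#' One-way analysis of variance on grouped temperatures
#'
#' Classical fixed-effects decomposition of the total sum of squares into
#' between-group and within-group parts, with the F test from the F
#' distribution.
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per group;
#'   at least 2 groups with at least 2 values each.
#' @return List with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `ss_between`, `ss_within`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  tab <- stats::anova(stats::lm(values ~ labels))
  ssw <- tab[["Sum Sq"]][2]
  if (ssw <= 0)
    stop("one_way_anova: zero within-group variance (degenerate data)")
  list(f_statistic = tab[["F value"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1],
       ss_between = tab[["Sum Sq"]][1], ss_within = ssw)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("at least 2 groups are required")
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 values")
  invisible(TRUE)
}

#' Tukey-Kramer pairwise comparison with compact letter display
#'
#' All-pairs mean comparisons controlling the family-wise error rate via the
#' studentized range distribution, using the Tukey-Kramer standard error for
#' unequal group sizes. Groups are then labelled with a compact letter
#' display: two groups share a letter exactly when their adjusted p-value
#' exceeds `alpha`. Letters are assigned greedily starting from the group
#' with the largest mean.
#'
#' @param groups Named list of numeric vectors (unnamed lists are labelled
#'   `g1, g2, ...`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `"group_comparison"`: list with the
#'   [one_way_anova] fields, `pairs` (data frame: `group_a`, `group_b`,
#'   `diff` in degC, `p_adj`), `letters` (named character vector) and
#'   `alpha`.
#' @examples
#' g <- list(low = c(9, 10, 11), mid = c(49, 50, 51), high = c(89, 90, 91))
#' tukey_hsd(g)$letters
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  an <- one_way_anova(groups)
  k <- length(groups)
  ni <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  mse <- an$ss_within / an$df_within

  idx <- utils::combn(k, 2)
  diffs <- means[idx[1, ]] - means[idx[2, ]]
  se <- sqrt(mse / 2 * (1 / ni[idx[1, ]] + 1 / ni[idx[2, ]]))
  qstat <- abs(diffs) / se
  p_adj <- stats::ptukey(qstat, nmeans = k, df = an$df_within,
                         lower.tail = FALSE)
  pairs <- data.frame(group_a = names(groups)[idx[1, ]],
                      group_b = names(groups)[idx[2, ]],
                      diff = unname(diffs), p_adj = p_adj,
                      stringsAsFactors = FALSE)
  letters_out <- .compact_letters(names(groups), means, pairs, alpha)
  structure(c(an, list(pairs = pairs, letters = letters_out, alpha = alpha,
                       means = means)),
            class = "group_comparison")
}

# insert-and-absorb compact letter display: split letter groups on each
# significant pair, drop letter sets contained in others, label in order of
# decreasing group mean
.compact_letters <- function(labels, means, pairs, alpha) {
  k <- length(labels)
  sets <- list(seq_len(k))
  sig <- pairs[pairs$p_adj <= alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group_a[r], labels)
    j <- match(sig$group_b[r], labels)
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop duplicates and sets properly contained in another set
    new_sets <- unique(lapply(new_sets, sort))
    keep <- vapply(seq_along(new_sets), function(a)
      !any(vapply(seq_along(new_sets), function(b)
        b != a && !identical(new_sets[[a]], new_sets[[b]]) &&
          all(new_sets[[a]] %in% new_sets[[b]]),
        logical(1))), logical(1))
    sets <- new_sets[keep]
  }
  # order letters by the largest member mean, descending
  ord <- order(vapply(sets, function(s) max(means[s]), numeric(1)),
               decreasing = TRUE)
  sets <- sets[ord]
  out <- stats::setNames(rep("", k), labels)
  for (li in seq_along(sets)) {
    for (g in sets[[li]])
      out[g] <- paste0(out[g], letters[li])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  tab <- x$pairs
  tab$diff <- round(tab$diff, 2)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab, row.names = FALSE)
  cat("Letters (shared letter = no significant difference at alpha ",
      x$alpha, "):\n", sep = "")
  disp <- sprintf("  %s: mean %.1f %s", names(x$letters), x$means, x$letters)
  cat(disp, sep = "\n")
  invisible(x)
}
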