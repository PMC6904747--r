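#' Pixel-level confusion between automatic and manual colony masks
#'
#' Scores an automatically extracted colony mask against a manually drawn
#' reference. True positives are pixels correctly extracted as colony, true
#' negatives pixels correctly left as feeder; the three reported ratios are
#' undetected = FN/total, overdetected = FP/total and
#' accurate = (TP+TN)/total, which sum to 1 exactly (integer arithmetic
#' before division).
#'
#' @param predicted `colony_mask` or logical matrix (automatic extraction).
#' @param manual Logical matrix (manual reference), same shape.
#' @return An object of class `pixel_confusion`: `tp`, `fp`, `fn`, `tn`,
#'   `undetected_frac`, `overdetected_frac`, `accurate_frac`.
#' @export
pixel_confusion <- function(predicted, manual) {
  p <- if (inherits(predicted, "colony_mask")) predicted$pixels else predicted
  if (!identical(dim(p), dim(manual))) stop("mask shapes differ")
  tp <- sum(p & manual)
  fp <- sum(p & !manual)
  fn <- sum(!p & manual)
  tn <- sum(!p & !manual)
  total <- tp + fp + fn + tn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 undetected_frac = fn / total,
                 overdetected_frac = fp / total,
                 accurate_frac = (tp + tn) / total),
            class = "pixel_confusion")
}

#' @export
print.pixel_confusion <- function(x, ...) {
  cat(sprintf(
    "<pixel_confusion: TP %d FP %d FN %d TN %d | undetected %.3f overdetected %.3f accurate %.3f>\n",
    x$tp, x$fp, x$fn, x$tn, x$undetected_frac, x$overdetected_frac,
    x$accurate_frac))
  invisible(x)
}

#' Two-group comparison of per-colony mean speeds
#'
#' Unpaired two-tailed Mann-Whitney U test. The sampling unit is the
#' per-colony mean speed, never pixelwise values (pixel samples are for
#' violin plots only); groups of 5 colonies with complete separation
#' therefore bottom out at the exact two-tailed p = 2/choose(10,5) = 0.0079.
#' The exact permutation distribution is used for small samples (both groups
#' <= 10) without ties; larger samples or tied values fall back to the
#' normal approximation with midranks, and a tie note is recorded.
#'
#' @param a,b Numeric vectors of per-colony mean speeds, >= 3 values each.
#' @param labels Length-2 character vector of group names.
#' @return An object of class `group_comparison` with `test_name`,
#'   `statistic` (U), `p_value`, `n`, `exact`, and `note`.
#' @export
compare_two_groups <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  want_exact <- !has_ties && length(a) <= 10L && length(b) <= 10L
  note <- if (has_ties)
    "ties present: midranks with normal approximation (exact method assumes continuity)"
  else NA_character_
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = want_exact,
                       correct = TRUE))
  structure(list(test_name = "Mann-Whitney U (unpaired, two-tailed)",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n = c(length(a), length(b)),
                 groups = stats::setNames(list(a, b), labels),
                 exact = want_exact,
                 note = note),
            class = "group_comparison")
}

#' Multi-group comparison with Kruskal-Wallis and Dunn's post-hoc test
#'
#' Tie-corrected Kruskal-Wallis H over >= 3 groups of per-colony mean
#' speeds, followed by Dunn's pairwise z tests of every group against a
#' designated control, Bonferroni-adjusted over the number of comparisons
#' (the adjustment is named in the output). Degenerate all-constant input
#' (every value identical) returns H = 0, p = 1 under the tie-corrected
#' convention. With 2 groups, use [compare_two_groups()].
#'
#' @param groups Named list of >= 3 numeric vectors (>= 3 values each).
#' @param control Name of the control group (default: first element).
#' @return An object of class `group_comparison` with `statistic` (H),
#'   `p_value`, and `posthoc_table` (data frame: comparison, z, p_unadjusted,
#'   p_adjusted, adjustment).
#' @export
compare_multi_groups <- function(groups, control = names(groups)[1L]) {
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use compare_two_groups()")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (!control %in% names(groups)) stop("unknown control group '", control, "'")
  if (any(vapply(groups, length, 1L) < 3L))
    stop("each group needs at least 3 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (length(unique(x)) == 1L) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  # Dunn's z tests vs control on midranks with tie correction
  N <- length(x)
  rk <- rank(x)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  others <- setdiff(names(groups), control)
  z <- vapply(others, function(gr) {
    se <- sqrt(s2 * (1 / nn[[control]] + 1 / nn[[gr]]))
    if (se == 0) 0 else (mean_rank[[gr]] - mean_rank[[control]]) / se
  }, numeric(1L))
  p_un <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(1, p_un * length(others))
  posthoc <- data.frame(comparison = paste(control, "vs", others),
                        z = as.numeric(z),
                        p_unadjusted = as.numeric(p_un),
                        p_adjusted = as.numeric(p_adj),
                        adjustment = "bonferroni",
                        row.names = NULL)
  structure(list(test_name = "Kruskal-Wallis with Dunn's post-hoc vs control",
                 statistic = kw_stat,
                 p_value = kw_p,
                 n = vapply(groups, length, 1L),
                 groups = groups,
                 control = control,
                 posthoc_table = posthoc,
                 note = NA_character_),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$test_name, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g, n = %s\n", x$statistic, x$p_value,
              paste(x$n, collapse = ", ")))
  if (!is.null(x$posthoc_table)) {
    cat("  post-hoc (", x$posthoc_table$adjustment[1L], "):\n", sep = "")
    for (i in seq_len(nrow(x$posthoc_table)))
      cat(sprintf("    %s: z = %.3f, p_adj = %.4g\n",
                  x$posthoc_table$comparison[i], x$posthoc_table$z[i],
                  x$posthoc_table$p_adjusted[i]))
  }
  if (!is.na(x$note %||% NA_character_)) cat("  note:", x$note, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
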