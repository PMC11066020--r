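# Cohort-level statistics: pooled-percentile thresholds (the "top 1% OSI" /
# "lowest 1% shear" rules), ROC threshold-sensitivity analysis with AUC and
# Gini index, Kruskal-Wallis omnibus testing with Dunn pairwise follow-up,
# and Table-style group summaries.

#' Pooled percentile threshold across subjects
#'
#' Pools all per-face values across subjects (unweighted by face area) and
#' returns the upper or lower `pct` percentile by linear interpolation
#' between order statistics. An area-weighted variant is available but
#' non-default: the pooled rule operates on data points, not surface area.
#'
#' @param fields List of `wall_scalar_field`s (one per subject) or plain
#'   numeric vectors.
#' @param tail `"upper"` (value exceeded by pct% of the data) or `"lower"`.
#' @param pct Tail percentage (default 1).
#' @param area_weighted If `TRUE`, percentile of the area-weighted
#'   distribution.
#' @return The threshold value.
#' @export
pooled_percentile_threshold <- function(fields, tail = c("upper", "lower"),
                                        pct = 1, area_weighted = FALSE) {
  tail <- match.arg(tail)
  stopifnot(pct > 0, pct < 100)
  pull <- function(f) {
    if (inherits(f, "wall_scalar_field")) {
      ok <- f$valid & !is.na(f$values)
      list(v = f$values[ok], w = f$areas[ok])
    } else {
      list(v = as.numeric(f), w = rep(1, length(f)))
    }
  }
  parts <- lapply(fields, pull)
  v <- unlist(lapply(parts, `[[`, "v"), use.names = FALSE)
  if (!length(v)) stop("no pooled values", call. = FALSE)
  p <- if (tail == "upper") 1 - pct / 100 else pct / 100
  if (!area_weighted) return(unname(stats::quantile(v, p, type = 7)))
  w <- unlist(lapply(parts, `[[`, "w"), use.names = FALSE)
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  v[o][which.max(cw >= p)]
}

#' ROC curve, AUC and Gini index
#'
#' AUC by the Mann-Whitney identity (ties counted one half); the curve by
#' sweeping the unique score cutoffs (predict positive when score >=
#' cutoff). Gini = 2 AUC - 1 exactly.
#'
#' @param scores Numeric per-subject metric values (higher = more positive).
#' @param labels Logical or 0/1 event labels.
#' @return An object of class `roc_result`: data frame `curve` (threshold,
#'   fpr, tpr), `auc`, `gini`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present (degenerate labels)", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(c) sum(scores[labels] >= c) / n1, 0)
  fpr <- vapply(cuts, function(c) sum(scores[!labels] >= c) / n0, 0)
  structure(list(curve = data.frame(threshold = cuts, fpr = fpr, tpr = tpr),
                 auc = auc, gini = 2 * auc - 1),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f, Gini = %.4f (%d cutoffs)\n",
              x$auc, x$gini, nrow(x$curve)))
  invisible(x)
}

#' Trapezoidal AUC from a ROC curve
#'
#' Numerically identical to the Mann-Whitney AUC; kept as an internal
#' consistency check.
#' @param roc A `roc_result`.
#' @return AUC in 0..1.
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  with(roc$curve, sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

#' Threshold sensitivity sweep over low-velocity candidates
#'
#' Scores each subject by its time-averaged low-velocity volume percentage
#' at every candidate threshold and evaluates how well the score separates
#' event-positive subjects by ROC AUC. Returns the candidate with the
#' largest AUC (ties broken toward the smallest threshold).
#'
#' @param score_table Data frame or matrix: one row per subject, one column
#'   per candidate (as produced by the pipeline), of low-velocity volume
#'   percentages.
#' @param labels Event labels, one per subject.
#' @param candidates Candidate thresholds, cm/s, matching the columns
#'   (default the standard sweep 0.5, 1, 2, 3, 5, 7.5, 10).
#' @return A list of class `threshold_sweep`: `best_threshold`, `best_auc`,
#'   and `results` (per-candidate `roc_result`s, named by threshold).
#' @export
threshold_sweep <- function(score_table, labels,
                            candidates = c(0.5, 1, 2, 3, 5, 7.5, 10)) {
  score_table <- as.matrix(score_table)
  stopifnot(ncol(score_table) == length(candidates),
            nrow(score_table) == length(labels), length(candidates) >= 1L)
  ord <- order(candidates)  # result invariant to candidate ordering
  rocs <- lapply(ord, function(j) roc_curve(score_table[, j], labels))
  names(rocs) <- as.character(candidates[ord])
  aucs <- vapply(rocs, `[[`, 0, "auc")
  best <- which.max(aucs)  # first max = smallest threshold on ties
  structure(list(best_threshold = candidates[ord][best],
                 best_auc = unname(aucs[best]), results = rocs),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Threshold sweep (cm/s -> AUC):\n")
  for (nm in names(x$results))
    cat(sprintf("  %5s : %.4f%s\n", nm, x$results[[nm]]$auc,
                if (as.numeric(nm) == x$best_threshold) "  <- best" else ""))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn pairwise comparisons
#'
#' Omnibus H (tie-corrected) and p from the chi-square approximation via
#' [stats::kruskal.test()]; pairwise follow-up by Dunn's z statistics on the
#' pooled ranks, with optional Bonferroni adjustment.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param adjust `"none"` (default, matching reported per-pair values) or
#'   `"bonferroni"`.
#' @return An object of class `group_comparison`: `H`, `p_value`, data
#'   frames `groups` (n, mean, sd, median) and `pairwise` (group1, group2,
#'   z, p, significant at 0.05).
#' @export
kruskal_wallis_pairwise <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- vapply(groups, length, 1L)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  if (adjust == "bonferroni") p <- pmin(1, p * ncol(pairs))
  structure(list(
    H = unname(kw$statistic), p_value = kw$p.value, adjust = adjust,
    groups = data.frame(group = names(groups), n = as.integer(n),
                        mean = vapply(groups, mean, 0),
                        sd = vapply(groups, stats::sd, 0),
                        median = vapply(groups, stats::median, 0),
                        row.names = NULL),
    pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                          z = z, p = p, significant = p < 0.05)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, p = %.4g (pairwise: Dunn, %s)\n",
              x$H, x$p_value, x$adjust))
  print(x$groups, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Group summary table of cohort biomarkers
#'
#' For each metric column: per-group mean, SD and n, the Kruskal-Wallis
#' omnibus test and Dunn pairwise p-values; plus the count of subjects per
#' group whose stasis spans the full cardiac cycle (stasis = 100%).
#'
#' @param summaries Data frame with one row per subject: column `group`
#'   plus numeric metric columns.
#' @param metrics Character vector of metric column names (default: all
#'   numeric columns).
#' @param adjust Pairwise adjustment, passed to
#'   [kruskal_wallis_pairwise()].
#' @return A named list of `group_comparison` objects (single-group inputs
#'   yield the per-group data frame without tests), with attribute
#'   `"full_cycle_stasis"` counting stasis = 100 subjects per group when a
#'   `stasis_pct` column is present.
#' @export
group_summary_table <- function(summaries, metrics = NULL,
                                adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(summaries), "group" %in% names(summaries))
  if (is.null(metrics))
    metrics <- names(summaries)[vapply(summaries, is.numeric, TRUE) &
                                  names(summaries) != "group"]
  gl <- split(summaries, summaries$group)
  out <- lapply(metrics, function(m) {
    vals <- lapply(gl, `[[`, m)
    if (length(vals) < 2L || any(vapply(vals, length, 1L) < 2L)) {
      data.frame(group = names(vals), n = vapply(vals, length, 1L),
                 mean = vapply(vals, mean, 0),
                 sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0),
                 median = vapply(vals, stats::median, 0), row.names = NULL)
    } else {
      kruskal_wallis_pairwise(vals, adjust = adjust)
    }
  })
  names(out) <- metrics
  if ("stasis_pct" %in% names(summaries)) {
    attr(out, "full_cycle_stasis") <-
      vapply(gl, function(d) sum(d$stasis_pct >= 100 - 1e-9), 0L)
  }
  out
}
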