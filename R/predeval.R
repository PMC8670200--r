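# Classifier evaluation against experimental labels: confusion counts,
# ROC/AUC, Youden-optimal threshold and the resampled mean threshold.

#' Confusion counts for a set-valued prediction
#'
#' @param predicted [ref_set()] (or character vector) of genes called
#'   positive.
#' @param positives [ref_set()] of experimentally validated positives (the
#'   label set).
#' @param universe [ref_set()] of all genes under evaluation.
#' @return Tibble with one row: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, positives, universe) {
  p <- set_members(predicted)
  y <- set_members(positives)
  u <- set_members(universe)
  bad <- c(setdiff(p, u), setdiff(y, u))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "ids outside the universe: ", paste(utils::head(unique(bad), 5), collapse = ", ")
    ))
  }
  tp <- length(intersect(p, y))
  tibble::tibble(
    tp = tp,
    fp = length(p) - tp,
    fn = length(y) - tp,
    tn = length(u) - length(union(p, y))
  )
}

#' Performance metrics from confusion counts
#'
#' Sensitivity (= recall = tpr), specificity, precision and fpr. A metric
#' with a zero denominator is reported as `NA` rather than erroring.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `fn`, `tn`.
#' @return Tibble with columns `tpr`, `fpr`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, tibble::tibble(
    tpr = safe_div(tp, tp + fn),
    fpr = safe_div(fp, fp + tn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp)
  ))
}

# Internal vectorised ROC computation on a score vector and logical labels.
# Scores use -1 as missing flag; missing genes are negative at every real
# threshold and enter the curve only at the terminal predict-all point.
roc_points <- function(score, label) {
  finite <- score != -1
  thr <- sort(unique(score[finite]), decreasing = TRUE)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  pts <- vapply(thr, function(t) {
    pred <- finite & score >= t
    c(sum(pred & label), sum(pred & !label))
  }, numeric(2))
  tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    tpr = c(0, pts[1, ] / n_pos, 1),
    fpr = c(0, pts[2, ] / n_neg, 1)
  )
}

#' ROC curve and AUC for a gene-score classifier
#'
#' Candidate thresholds are the unique observed scores (with
#' greater-or-equal inclusion), bracketed by a sentinel above the maximum
#' (nothing predicted) and a terminal predict-everything point, so the curve
#' runs from (0,0) to (1,1). Genes carrying the `-1` missing flag are
#' negative at every real threshold. AUC is the trapezoidal area.
#'
#' @param scores Tibble with columns `gene`, `score` (gene-score table).
#'   Universe genes absent from the table are treated as missing (`-1`).
#' @param positives [ref_set()] of labelled positives.
#' @param universe [ref_set()] of genes to evaluate over.
#' @return Object of class `phospho_roc`: list with `points` tibble
#'   (`threshold`, `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, positives, universe) {
  u <- set_members(universe)
  if (length(u) == 0) rlang::abort("empty universe")
  y <- set_members(positives)
  bad <- setdiff(y, u)
  if (length(bad) > 0) {
    rlang::abort(paste0("positives outside the universe: ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  s <- stats::setNames(rep(-1, length(u)), u)
  in_u <- scores$gene %in% u
  s[scores$gene[in_u]] <- scores$score[in_u]
  label <- u %in% y
  if (all(label) || !any(label)) {
    rlang::abort("ROC needs at least one positive and one negative label")
  }
  pts <- roc_points(unname(s), label)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(
    list(points = pts, auc = auc, n_pos = sum(label), n_neg = sum(!label)),
    class = "phospho_roc"
  )
}

#' @export
print.phospho_roc <- function(x, ...) {
  cat(
    "<phospho_roc> AUC =", format(x$auc, digits = 4),
    sprintf("(%d positives, %d negatives, %d cutoffs)\n", x$n_pos, x$n_neg, nrow(x$points) - 2)
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname roc_curve
#' @param x A `phospho_roc` object.
#' @param ... Unused.
#' @export
tidy.phospho_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @export
glance.phospho_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
    optimal_threshold = optimal_threshold(x),
    youden_max = max(x$points$tpr - x$points$fpr)
  )
}

#' @rdname roc_curve
#' @param object A `phospho_roc` object.
#' @export
autoplot.phospho_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Youden-optimal classification threshold
#'
#' The finite candidate threshold maximising the Youden statistic
#' J = tpr - fpr; ties are broken toward the largest (strictest) threshold.
#'
#' @param roc A `phospho_roc` from [roc_curve()].
#' @return A single numeric threshold.
#' @export
optimal_threshold <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), ]
  if (nrow(pts) == 0) rlang::abort("ROC curve has no finite thresholds")
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  max(pts$threshold[best])
}

#' Resampled mean optimal threshold
#'
#' Repeatedly subsamples a fraction of the universe without replacement,
#' recomputes the Youden-optimal threshold on each subsample, and returns the
#' arithmetic mean. Subsamples missing either class are redrawn (the redraw
#' count is reported).
#'
#' @param scores Gene-score tibble (`gene`, `score`).
#' @param positives,universe As in [roc_curve()].
#' @param n_rep Number of resamples (default 5000).
#' @param frac Fraction of the universe per resample (default 0.30).
#' @param seed Integer seed; the procedure is fully reproducible given the
#'   seed.
#' @return List with `mean_threshold`, `per_rep_thresholds` (length
#'   `n_rep`), `n_redrawn` and a `summary` tibble (mean, sd, quartiles).
#' @export
resampled_threshold <- function(scores, positives, universe,
                                n_rep = 5000, frac = 0.30, seed = 1) {
  if (n_rep < 1) rlang::abort("n_rep must be >= 1")
  if (frac <= 0 || frac >= 1) rlang::abort("frac must lie in (0, 1)")
  u <- set_members(universe)
  y <- set_members(positives)
  s <- stats::setNames(rep(-1, length(u)), u)
  in_u <- scores$gene %in% u
  s[scores$gene[in_u]] <- scores$score[in_u]
  label <- u %in% y
  m <- max(1L, floor(frac * length(u)))

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  thr <- numeric(n_rep)
  redrawn <- 0L
  for (i in seq_len(n_rep)) {
    repeat {
      idx <- sample.int(length(u), m)
      if (any(label[idx]) && any(!label[idx])) break
      redrawn <- redrawn + 1L
    }
    pts <- roc_points(unname(s[idx]), label[idx])
    pts <- pts[is.finite(pts$threshold), ]
    j <- pts$tpr - pts$fpr
    thr[i] <- max(pts$threshold[j == max(j)])
  }
  list(
    mean_threshold = mean(thr),
    per_rep_thresholds = thr,
    n_redrawn = redrawn,
    summary = tibble::tibble(
      n_rep = n_rep, frac = frac, seed = seed,
      mean = mean(thr), sd = stats::sd(thr),
      q25 = unname(stats::quantile(thr, 0.25)),
      median = stats::median(thr),
      q75 = unname(stats::quantile(thr, 0.75))
    )
  )
}
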