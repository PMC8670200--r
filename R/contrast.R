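# Binary significance matrices across comparisons, pattern groups,
# sample-specific term calls and GenRatio.

#' Binary significance matrix across enrichment comparisons
#'
#' One row per GO term significant in at least one comparison; cell 1 iff
#' `fdr < alpha` in that comparison. Terms tested in some comparisons but
#' not others (e.g. removed by a node-size filter) score 0 in the missing
#' column, with a warning.
#'
#' @param tables Named list of `enrichment_table`s (see [run_comparison()]),
#'   all from the same namespace; names become the comparison columns, in
#'   order.
#' @param alpha Significance level on the FDR scale (default 0.01).
#' @return Tibble of class `sig_matrix`: column `term` plus one 0/1 integer
#'   column per comparison. Attributes `comparisons` and `namespace`.
#' @export
significance_matrix <- function(tables, alpha = 0.01) {
  if (length(tables) < 2) rlang::abort("need at least two comparisons")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    rlang::abort("'tables' must be a named list (names label the comparisons)")
  }
  ns <- unique(vapply(tables, function(t) t$namespace[1], character(1)))
  if (length(ns) > 1) {
    rlang::abort(paste0("tables mix namespaces: ", paste(ns, collapse = ", ")))
  }
  sig <- lapply(tables, function(t) t$term[t$fdr < alpha])
  rows <- sort(unique(unlist(sig)))
  tested <- lapply(tables, function(t) t$term)
  untested <- sum(vapply(tested, function(tt) length(setdiff(rows, tt)), integer(1)))
  if (untested > 0) {
    rlang::warn(paste0(
      untested, " term/comparison cell(s) untested in a comparison; scored 0"
    ))
  }
  out <- tibble::tibble(term = rows)
  for (nm in names(tables)) {
    out[[nm]] <- as.integer(rows %in% sig[[nm]])
  }
  attr(out, "comparisons") <- names(tables)
  attr(out, "namespace") <- ns
  class(out) <- c("sig_matrix", class(out))
  out
}

sig_comparisons <- function(matrix) {
  attr(matrix, "comparisons") %||% setdiff(names(matrix), "term")
}

pattern_strings <- function(matrix) {
  cols <- sig_comparisons(matrix)
  apply(as.matrix(matrix[cols]), 1, paste, collapse = "")
}

#' Group terms by their binary significance pattern
#'
#' Every observed non-zero pattern over the comparisons becomes a group.
#' Group labels (`G1`, `G2`, ... or `CG1`, ... via `prefix`) are assigned by
#' descending number of biological-process terms carrying the pattern, with
#' ties broken by the pattern read as a binary number, descending.
#'
#' @param matrices Named list of [significance_matrix()] objects, one per
#'   namespace, all over the same comparisons.
#' @param bp Name of the namespace whose counts order the groups (default
#'   `"biological_process"`; falls back to the first matrix if absent).
#' @param prefix Label prefix (default `"G"`; use `"CG"` for contrast
#'   groups).
#' @return List with `groups` (tibble: `label`, `pattern`, one count column
#'   per namespace) and `assignment` (tibble: `term`, `namespace`,
#'   `pattern`, `label`).
#' @export
group_patterns <- function(matrices, bp = "biological_process", prefix = "G") {
  if (inherits(matrices, "sig_matrix")) {
    matrices <- stats::setNames(list(matrices), attr(matrices, "namespace") %||% "ns")
  }
  comps <- lapply(matrices, sig_comparisons)
  if (length(unique(comps)) > 1) {
    rlang::abort("matrices use different comparison lists")
  }
  if (!(bp %in% names(matrices))) bp <- names(matrices)[[1]]

  assign <- dplyr::bind_rows(lapply(names(matrices), function(nsn) {
    m <- matrices[[nsn]]
    if (nrow(m) == 0) {
      return(NULL)
    }
    tibble::tibble(term = m$term, namespace = nsn, pattern = pattern_strings(m))
  }))
  if (is.null(assign) || nrow(assign) == 0) {
    return(list(
      groups = tibble::tibble(label = character(), pattern = character()),
      assignment = tibble::tibble(
        term = character(), namespace = character(),
        pattern = character(), label = character()
      )
    ))
  }
  pats <- unique(assign$pattern)
  bp_count <- vapply(pats, function(p) sum(assign$pattern == p & assign$namespace == bp), integer(1))
  binval <- vapply(pats, function(p) strtoi(p, base = 2L), integer(1))
  ord <- order(-bp_count, -binval)
  groups <- tibble::tibble(
    label = paste0(prefix, seq_along(pats)),
    pattern = pats[ord]
  )
  for (nsn in names(matrices)) {
    groups[[paste0("n_", nsn)]] <- vapply(
      groups$pattern,
      function(p) sum(assign$pattern == p & assign$namespace == nsn), integer(1),
      USE.NAMES = FALSE
    )
  }
  assign$label <- groups$label[match(assign$pattern, groups$pattern)]
  list(groups = groups, assignment = assign)
}

#' Terms specifically enriched in the sample
#'
#' A term is specific to the sample when it is significant in both the
#' sample-vs-genome and the sample-vs-phospho-reference comparisons,
#' irrespective of whether the reference itself is enriched against the
#' genome (in the three-column layout this is the union of the two contrast
#' groups with `1` in both sample columns).
#'
#' @param matrix A [significance_matrix()].
#' @param sample_vs_genome,sample_vs_ref Column names of the two sample
#'   comparisons.
#' @return Character vector of term ids.
#' @export
specific_terms <- function(matrix, sample_vs_genome, sample_vs_ref) {
  cols <- sig_comparisons(matrix)
  miss <- setdiff(c(sample_vs_genome, sample_vs_ref), cols)
  if (length(miss) > 0) {
    rlang::abort(paste0("unknown comparison column(s): ", paste(miss, collapse = ", ")))
  }
  matrix$term[matrix[[sample_vs_genome]] == 1 & matrix[[sample_vs_ref]] == 1]
}

#' GenRatio: fraction of a term's genes present in the sample
#'
#' For each term, the percentage of the genes annotated to the term (within
#' the feasible universe) that belong to the sample. The exact ratio is kept
#' alongside a one-decimal display value.
#'
#' @param terms Character vector of term ids present in the index.
#' @param sample [ref_set()] or character vector of sample genes.
#' @param index A [build_term_index()] object.
#' @return Tibble with columns `term`, `n_sample`, `n_term`, `ratio`
#'   (exact percentage) and `gen_ratio` (rounded to one decimal).
#' @export
gen_ratio <- function(terms, sample, index) {
  s <- set_members(sample)
  rows <- lapply(terms, function(t) {
    genes <- index$index[[t]]
    if (is.null(genes)) rlang::abort(paste0("term not in index: ", t))
    if (length(genes) == 0) rlang::abort(paste0("term has no annotated genes: ", t))
    k <- length(intersect(s, genes))
    tibble::tibble(
      term = t, n_sample = k, n_term = length(genes),
      ratio = 100 * k / length(genes)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$gen_ratio <- round(out$ratio, 1)
  out
}

#' Binary-heatmap view of a significance matrix
#'
#' @param object A [significance_matrix()].
#' @param groups Optional result of [group_patterns()] used to order rows by
#'   group.
#' @param ... Unused.
#' @return A ggplot: terms on the y axis, comparisons on the x axis, filled
#'   cells significant at the matrix's alpha.
#' @export
autoplot.sig_matrix <- function(object, groups = NULL, ...) {
  cols <- sig_comparisons(object)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), dplyr::all_of(cols),
    names_to = "comparison", values_to = "significant"
  )
  long$comparison <- factor(long$comparison, levels = cols)
  if (!is.null(groups)) {
    ord <- groups$assignment[order(groups$assignment$label), ]
    long$term <- factor(long$term, levels = rev(unique(ord$term)))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$term)) +
    ggplot2::geom_tile(
      ggplot2::aes(fill = factor(.data$significant)),
      colour = "grey80"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "white", `1` = "grey40"), guide = "none"
    ) +
    ggplot2::labs(x = NULL, y = NULL)
}
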