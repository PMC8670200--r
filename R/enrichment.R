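# Parent-child Fisher over-representation testing with BH-FDR control.

#' Build a term-to-gene index over a gene universe
#'
#' Restricts the universe to "feasible" genes (those with at least one
#' propagated annotation in the namespace), inverts the propagated
#' annotation map to term -> genes, and drops terms annotating fewer than
#' `min_node_size` feasible genes. The unfiltered map is retained internally
#' because the parent-child test conditions on parent gene pools even when a
#' parent itself falls below the size filter.
#'
#' @param annotations A `go_annotation` from [propagate_annotations()].
#' @param universe [ref_set()] (or character vector) of universe genes.
#' @param dag The [go_dag()] the annotations were propagated on.
#' @param namespace GO namespace to index (e.g. `"biological_process"`).
#' @param min_node_size Minimum feasible-gene count for a term to be tested
#'   (default 1).
#' @return Object of class `term_index`: list with `index` (term -> feasible
#'   genes, filtered), `full_index` (unfiltered), `universe` (feasible
#'   genes), `namespace`, `dag`, `n_dropped_terms`.
#' @export
build_term_index <- function(annotations, universe, dag, namespace,
                             min_node_size = 1L) {
  stopifnot(inherits(annotations, "go_annotation"), inherits(dag, "go_dag"))
  u <- set_members(universe)
  if (length(u) == 0) rlang::abort("empty universe")
  ns_terms <- dag$terms$id[dag$terms$namespace == namespace & !dag$terms$obsolete]
  if (length(ns_terms) == 0) {
    rlang::abort(paste0("no terms in namespace '", namespace, "'"))
  }
  prop <- annotations$propagated
  prop <- prop[names(prop) %in% u]
  prop <- lapply(prop, function(ts) ts[ts %in% ns_terms])
  prop <- prop[lengths(prop) > 0]
  feasible <- names(prop)
  if (length(feasible) == 0) {
    rlang::abort("no universe gene carries an annotation in this namespace")
  }
  pairs <- tibble::tibble(
    gene = rep(names(prop), lengths(prop)),
    term = unlist(prop, use.names = FALSE)
  )
  full <- split(pairs$gene, pairs$term)
  keep <- lengths(full) >= min_node_size
  structure(
    list(
      index = full[keep],
      full_index = full,
      universe = sort(feasible),
      namespace = namespace,
      dag = dag,
      min_node_size = as.integer(min_node_size),
      n_dropped_terms = sum(!keep)
    ),
    class = "term_index"
  )
}

#' @export
print.term_index <- function(x, ...) {
  cat(
    "<term_index> ", length(x$index), " testable terms over ",
    length(x$universe), " feasible genes (", x$namespace, ")\n",
    sep = ""
  )
  invisible(x)
}

# Upper-tail hypergeometric: P(X >= k) with N genes, K in the term,
# n drawn (the sample).
hyper_upper <- function(k, K, N, n) {
  if (K == 0 || n == 0) {
    return(1)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_sample <- function(sample, index) {
  s <- set_members(sample)
  bad <- setdiff(s, index$universe)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "sample ids outside the feasible universe: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  s
}

#' Classic Fisher over-representation p-value for one term
#'
#' One-sided upper-tail hypergeometric probability of drawing at least the
#' observed number of term genes when `|sample|` genes are drawn from the
#' feasible universe.
#'
#' @param sample [ref_set()] or character vector, contained in the feasible
#'   universe.
#' @param index A [build_term_index()] object.
#' @param term Term id.
#' @return A p-value in (0, 1].
#' @export
fisher_classic <- function(sample, index, term) {
  s <- check_sample(sample, index)
  genes <- index$index[[term]]
  if (is.null(genes)) rlang::abort(paste0("term not in index: ", term))
  hyper_upper(
    k = length(intersect(s, genes)),
    K = length(genes),
    N = length(index$universe),
    n = length(s)
  )
}

#' Parent-child over-representation p-value for one term
#'
#' The parent-child-union variant: the conditioning universe is the set of
#' genes annotated to the union of the term's parents, which removes the
#' enrichment a term inherits merely because its parent is enriched. With
#' the intersection variant the pool is the genes annotated to all parents.
#' A term whose parents' pool covers the feasible universe (in particular a
#' child of the namespace root) reduces to [fisher_classic()]; the root
#' itself returns 1 by convention.
#'
#' @inheritParams fisher_classic
#' @param variant `"union"` (default) or `"intersection"` parent pooling.
#' @return A p-value in (0, 1].
#' @export
parent_child_p <- function(sample, index, term, variant = c("union", "intersection")) {
  variant <- match.arg(variant)
  s <- check_sample(sample, index)
  genes <- index$index[[term]]
  if (is.null(genes)) rlang::abort(paste0("term not in index: ", term))
  par <- names(index$dag$parents[[term]])
  par <- par[par %in% index$dag$terms$id[index$dag$terms$namespace == index$namespace]]
  if (length(par) == 0) {
    return(1) # namespace root
  }
  pools <- lapply(par, function(p) index$full_index[[p]] %||% character())
  pool <- if (variant == "union") {
    unique(unlist(pools, use.names = FALSE))
  } else {
    Reduce(intersect, pools)
  }
  hyper_upper(
    k = length(intersect(s, genes)),
    K = length(intersect(genes, pool)),
    N = length(pool),
    n = length(intersect(s, pool))
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1), delegated to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run one enrichment comparison
#'
#' Tests every indexed term of one namespace for over-representation of the
#' sample against the universe with the parent-child Fisher test, adjusts
#' within the namespace by Benjamini-Hochberg, and flags significance at
#' `fdr < alpha`. Sample genes outside the feasible universe are dropped
#' with a warning (their count is recorded in the `"n_dropped_sample"`
#' attribute).
#'
#' @param sample [ref_set()] or character vector of sample genes.
#' @param index A [build_term_index()] object (pass either this or
#'   `universe` + `annotations` + `dag` + `namespace`).
#' @param universe,annotations,dag,namespace,min_node_size Used to build the
#'   index when `index` is not supplied.
#' @param alpha Significance level on the FDR scale (default 0.01).
#' @param method `"parentchild"` (default) or `"classic"` Fisher.
#' @param variant Parent pooling for the parent-child test.
#' @return Tibble of class `enrichment_table` with columns `term`,
#'   `namespace`, `n_universe`, `n_sample`, `p_value`, `fdr`, `significant`,
#'   ordered by `fdr` then term id. Attributes: `comparison` (optional
#'   label), `alpha`, `n_dropped_sample`.
#' @export
run_comparison <- function(sample, universe = NULL, annotations = NULL, dag = NULL,
                           namespace = NULL, index = NULL, alpha = 0.01,
                           method = c("parentchild", "classic"),
                           variant = c("union", "intersection"),
                           min_node_size = 1L, comparison = NULL) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  if (is.null(index)) {
    index <- build_term_index(annotations, universe, dag, namespace,
      min_node_size = min_node_size
    )
  }
  s <- set_members(sample)
  out <- setdiff(s, index$universe)
  if (length(out) > 0) {
    rlang::warn(paste0(
      length(out), " sample gene(s) outside the feasible universe dropped"
    ))
    s <- intersect(s, index$universe)
  }
  if (length(s) == 0) rlang::abort("no sample genes left after universe restriction")

  terms <- names(index$index)
  n_univ <- lengths(index$index)
  n_samp <- vapply(index$index, function(g) length(intersect(s, g)), integer(1))
  p <- if (method == "classic") {
    vapply(terms, function(t) fisher_classic(s, index, t), numeric(1))
  } else {
    vapply(terms, function(t) parent_child_p(s, index, t, variant = variant), numeric(1))
  }
  fdr <- bh_fdr(p)
  tbl <- tibble::tibble(
    term = terms,
    namespace = index$namespace,
    n_universe = unname(n_univ),
    n_sample = unname(n_samp),
    p_value = unname(p),
    fdr = unname(fdr),
    significant = unname(fdr) < alpha
  ) |>
    dplyr::arrange(.data$fdr, .data$term)
  attr(tbl, "comparison") <- comparison
  attr(tbl, "alpha") <- alpha
  attr(tbl, "n_dropped_sample") <- length(out)
  class(tbl) <- c("enrichment_table", class(tbl))
  tbl
}
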