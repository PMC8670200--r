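# Wang graph-based semantic similarity and a deterministic 2-D layout.

#' Wang S-values of a GO term
#'
#' Encodes a term's semantics as contributions of its ancestors: the focal
#' term contributes 1; an ancestor's S-value is the maximum over its child
#' edges (within the focal term's ancestor subgraph) of the edge weight
#' times the child's S-value. The semantic value SV is the sum of all
#' S-values.
#'
#' @param dag A [go_dag()].
#' @param term Term id.
#' @param weights Named semantic-contribution weights per relation
#'   (defaults `is_a` 0.8, `part_of` 0.6, the standard Wang constants).
#' @return Object of class `wang_svalues`: list with `term`, `s` (named
#'   numeric over ancestors-or-self) and `sv`.
#' @export
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (any(weights <= 0 | weights >= 1)) {
    rlang::abort("semantic weights must lie in (0, 1)")
  }
  term <- resolve_term_ids(dag, term)
  if (!(term %in% dag$terms$id)) rlang::abort(paste0("unknown term id: ", term))
  sub <- c(term, go_ancestors(dag, term, relations = names(weights)))
  s <- stats::setNames(rep(-Inf, length(sub)), sub)
  s[[term]] <- 1
  # relax edges child -> parent until fixed point (subgraph is a DAG, so at
  # most |sub| sweeps; typically far fewer)
  repeat {
    changed <- FALSE
    for (ch in sub) {
      p <- dag$parents[[ch]]
      if (is.null(p) || !is.finite(s[[ch]])) next
      p <- p[names(p) %in% sub & p %in% names(weights)]
      for (j in seq_along(p)) {
        cand <- unname(weights[[p[[j]]]]) * s[[ch]]
        if (cand > s[[names(p)[j]]]) {
          s[[names(p)[j]]] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  s <- s[is.finite(s)]
  structure(list(term = term, s = s, sv = sum(s)), class = "wang_svalues")
}

#' Wang semantic similarity between two terms
#'
#' The similarity is the summed S-values of the shared ancestors (counted
#' from both sides) over the sum of the two semantic values; it lies in
#' `[0, 1]` and equals 1 for identical terms.
#'
#' @param a,b `wang_svalues` objects from the same DAG.
#' @return A similarity in `[0, 1]`.
#' @export
wang_similarity <- function(a, b) {
  common <- intersect(names(a$s), names(b$s))
  if (length(common) == 0) {
    return(0)
  }
  sum(a$s[common] + b$s[common]) / (a$sv + b$sv)
}

#' Pairwise Wang similarity matrix
#'
#' @param dag A [go_dag()].
#' @param terms Character vector of term ids, all in one namespace.
#' @param weights As in [wang_svalues()].
#' @return Symmetric numeric matrix with unit diagonal, dimnames = terms.
#' @export
similarity_matrix <- function(dag, terms, weights = c(is_a = 0.8, part_of = 0.6)) {
  terms <- resolve_term_ids(dag, terms)
  ns <- unique(dag$terms$namespace[match(terms, dag$terms$id)])
  if (length(ns) > 1) {
    rlang::abort(paste0("terms span multiple namespaces: ", paste(ns, collapse = ", ")))
  }
  sv <- lapply(terms, function(t) wang_svalues(dag, t, weights))
  n <- length(terms)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- wang_similarity(sv[[i]], sv[[j]])
      }
    }
  }
  dimnames(m) <- list(terms, terms)
  m
}

#' Two-dimensional semantic-similarity layout
#'
#' Classical (Torgerson) metric scaling of the dissimilarity `1 - sim`:
#' double-centred Gram matrix, top-2 eigenpairs, coordinates scaled by the
#' square root of the eigenvalue. Each axis is oriented so that its
#' largest-magnitude coordinate is positive, making the layout deterministic.
#' Fit is reported as Kruskal stress-1.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param gen_ratio Optional named numeric (term -> GenRatio percentage)
#'   carried into the coordinates table for node sizing.
#' @return Object of class `semsim_embedding`: list with `coords` tibble
#'   (`term`, `x`, `y`, optional `gen_ratio`), `stress` and `eigenvalues`.
#' @export
mds_embedding <- function(sim, gen_ratio = NULL) {
  if (nrow(sim) < 2) rlang::abort("need at least two terms to embed")
  d <- 1 - sim
  k <- min(2L, nrow(d) - 1L)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < 2) {
    rlang::warn("fewer than two positive eigenvalues; remaining axis set to 0")
    pts <- cbind(pts, matrix(0, nrow = nrow(d), ncol = 2 - ncol(pts)))
  }
  for (j in 1:2) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  dhat <- as.matrix(stats::dist(pts))
  lower <- lower.tri(d)
  denom <- sum(d[lower]^2)
  stress <- if (denom == 0) 0 else sqrt(sum((dhat[lower] - d[lower])^2) / denom)
  coords <- tibble::tibble(term = rownames(sim), x = unname(pts[, 1]), y = unname(pts[, 2]))
  if (!is.null(gen_ratio)) coords$gen_ratio <- unname(gen_ratio[coords$term])
  structure(
    list(coords = coords, stress = stress, eigenvalues = fit$eig),
    class = "semsim_embedding"
  )
}

#' @export
print.semsim_embedding <- function(x, ...) {
  cat(
    "<semsim_embedding> ", nrow(x$coords), " terms, stress-1 = ",
    format(x$stress, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname mds_embedding
#' @param x,object A `semsim_embedding`.
#' @param ... Unused.
#' @export
tidy.semsim_embedding <- function(x, ...) x$coords

#' @rdname mds_embedding
#' @export
autoplot.semsim_embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if ("gen_ratio" %in% names(object$coords)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$gen_ratio), alpha = 0.7) +
      ggplot2::scale_size_area(name = "GenRatio (%)")
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), vjust = -1, size = 2.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2")
}

#' Export the ancestor closure of terms as a DOT graph
#'
#' Writes the subgraph induced by the selected terms and all their
#' ancestors, with solid edges for `is_a` and dashed for `part_of`; useful
#' for rendering the DAG neighbourhood of high-GenRatio terms.
#'
#' @param dag A [go_dag()].
#' @param terms Character vector of focal term ids.
#' @param file Optional path; when `NULL` the DOT text is returned
#'   invisibly.
#' @return Character vector of DOT lines (invisibly when written to file).
#' @export
export_dot <- function(dag, terms, file = NULL) {
  terms <- resolve_term_ids(dag, terms)
  nodes <- unique(c(terms, unlist(lapply(terms, function(t) go_ancestors(dag, t)))))
  e <- dag$edges[dag$edges$child %in% nodes & dag$edges$parent %in% nodes, ]
  lab <- dag$terms$name[match(nodes, dag$terms$id)]
  lines <- c(
    "digraph GO {",
    "  rankdir=BT;",
    sprintf(
      '  "%s" [label="%s\\n%s"%s];', nodes, nodes, gsub('"', "'", lab),
      ifelse(nodes %in% terms, " style=filled fillcolor=lightgrey", "")
    ),
    sprintf(
      '  "%s" -> "%s" [style=%s];', e$child, e$parent,
      ifelse(e$relation == "is_a", "solid", "dashed")
    ),
    "}"
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
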