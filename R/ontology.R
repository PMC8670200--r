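# GO DAG container, OBO parsing, ancestor queries and true-path-rule
# annotation propagation.

#' Construct a GO DAG object
#'
#' Low-level constructor used by [parse_obo()] and [make_toy_dag()]. Validates
#' acyclicity, edge endpoints and that obsolete terms carry no edges.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`, `obsolete`.
#' @param edges Tibble with columns `child`, `parent`,
#'   `relation` (`"is_a"` or `"part_of"`).
#' @param alt_ids Named character vector mapping secondary accessions to
#'   primary ids (may be empty).
#'
#' @return An object of class `go_dag` with elements `terms`, `edges`,
#'   `parents` (per-term named character vector, names = parent ids, values =
#'   relation labels), `children`, `roots` (namespace -> root id) and
#'   `alt_ids`.
#' @export
go_dag <- function(terms, edges, alt_ids = character()) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(
    all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
    all(c("child", "parent", "relation") %in% names(edges))
  )
  if (anyDuplicated(terms$id)) {
    rlang::abort(paste0(
      "duplicate term ids: ",
      paste(unique(terms$id[duplicated(terms$id)]), collapse = ", ")
    ))
  }
  missing_ep <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing_ep) > 0) {
    rlang::abort(paste0(
      "edge endpoints absent from term table: ",
      paste(utils::head(missing_ep, 5), collapse = ", ")
    ))
  }
  obs <- terms$id[terms$obsolete]
  if (any(edges$child %in% obs | edges$parent %in% obs)) {
    rlang::abort("obsolete terms must not participate in edges")
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    rlang::abort(paste0("unsupported relation(s): ", paste(bad_rel, collapse = ", ")))
  }

  parents <- lapply(split(edges[c("parent", "relation")], edges$child), function(df) {
    stats::setNames(df$relation, df$parent)
  })
  children <- lapply(split(edges$child, edges$parent), unique)

  cyc <- find_cycle(terms$id, parents)
  if (!is.null(cyc)) {
    rlang::abort(paste0("ontology graph contains a cycle: ", paste(cyc, collapse = " -> ")))
  }

  # namespace roots: non-obsolete terms without parents
  live <- terms[!terms$obsolete, ]
  parentless <- live$id[!(live$id %in% names(parents))]
  roots <- character()
  for (ns in unique(live$namespace)) {
    r <- intersect(parentless, live$id[live$namespace == ns])
    if (length(r) > 1) {
      rlang::warn(paste0(
        "namespace '", ns, "' has ", length(r),
        " parentless terms; using ", r[1], " as root"
      ))
    }
    if (length(r) >= 1) roots[ns] <- r[1]
  }

  structure(
    list(
      terms = terms, edges = edges, parents = parents, children = children,
      roots = roots, alt_ids = alt_ids
    ),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(
    "<go_dag> ", nrow(x$terms), " terms (", sum(x$terms$obsolete), " obsolete), ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  for (ns in names(x$roots)) cat("  ", ns, ": root ", x$roots[[ns]], "\n", sep = "")
  invisible(x)
}

# Kahn's algorithm on the child->parent graph; NULL if acyclic, otherwise one
# cycle as a character vector of ids.
find_cycle <- function(ids, parents) {
  n_par <- vapply(ids, function(i) {
    p <- parents[[i]]
    if (is.null(p)) 0L else length(p)
  }, integer(1))
  names(n_par) <- ids
  kids <- list()
  for (ch in names(parents)) {
    for (p in names(parents[[ch]])) kids[[p]] <- c(kids[[p]], ch)
  }
  queue <- ids[n_par == 0L]
  done <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    done <- done + 1L
    for (ch in kids[[v]]) {
      n_par[[ch]] <- n_par[[ch]] - 1L
      if (n_par[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done == length(ids)) {
    return(NULL)
  }
  # walk parent pointers among the residual nodes until a repeat
  residual <- names(n_par)[n_par > 0L]
  v <- residual[[1]]
  path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(names(parents[[v]]), residual)[[1]]
  }
  c(path[which(path == v):length(path)], v)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas from OBO-format text. `is_a` and
#' `relationship: part_of` edges are retained; other relationship types
#' (e.g. `regulates`) are dropped, matching the traversal behaviour of the
#' standard GO tooling. Obsolete terms are kept in the term table for lookup
#' but excluded from the edge set. Secondary accessions (`alt_id`) resolve to
#' the primary id.
#'
#' @param x Path to an OBO file, or a character vector of OBO text lines.
#' @return A [go_dag()] object.
#' @examples
#' obo <- c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root"
#' )
#' parse_obo(obo)
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }

  stanza <- NA_character_
  cur <- NULL
  acc <- list()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) acc[[length(acc) + 1L]] <<- cur
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[[i]])
    ln <- sub("^\\s+", "", ln)
    if (ln == "" || startsWith(ln, "!")) next
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      stanza <- substr(ln, 2, nchar(ln) - 1)
      if (stanza == "Term") cur <- list(parents = list(), alt = character())
      next
    }
    if (!identical(stanza, "Term")) next
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) {
      rlang::abort(paste0("malformed OBO stanza at line ", i, ": '", ln, "'"))
    }
    tag <- substr(ln, 1, colon - 1)
    val <- sub("^\\s+", "", substr(ln, colon + 1, nchar(ln)))
    val <- sub("\\s*!.*$", "", val) # strip trailing comment
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "namespace") {
      cur$namespace <- val
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(val, "true")
    } else if (tag == "alt_id") {
      cur$alt <- c(cur$alt, val)
    } else if (tag == "is_a") {
      if (val == "") rlang::abort(paste0("malformed is_a at line ", i))
      cur$parents[[length(cur$parents) + 1L]] <- c(val, "is_a")
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) rlang::abort(paste0("malformed relationship at line ", i))
      if (parts[[1]] == "part_of") {
        cur$parents[[length(cur$parents) + 1L]] <- c(parts[[2]], "part_of")
      } # other relation types dropped
    }
    # unknown tags tolerated
  }
  flush()
  if (length(acc) == 0) rlang::abort("no [Term] stanzas found")

  terms <- tibble::tibble(
    id = vapply(acc, function(t) t$id, character(1)),
    name = vapply(acc, function(t) t$name %||% t$id, character(1)),
    namespace = vapply(acc, function(t) t$namespace %||% NA_character_, character(1)),
    obsolete = vapply(acc, function(t) isTRUE(t$obsolete), logical(1))
  )
  edges <- dplyr::bind_rows(lapply(acc, function(t) {
    if (isTRUE(t$obsolete) || length(t$parents) == 0) {
      return(NULL)
    }
    tibble::tibble(
      child = t$id,
      parent = vapply(t$parents, `[[`, character(1), 1),
      relation = vapply(t$parents, `[[`, character(1), 2)
    )
  }))
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(child = character(), parent = character(), relation = character())
  }
  alt <- unlist(lapply(acc, function(t) {
    if (length(t$alt) == 0) {
      return(NULL)
    }
    stats::setNames(rep(t$id, length(t$alt)), t$alt)
  }))
  go_dag(terms, edges, alt_ids = alt %||% character())
}

#' Resolve possibly-secondary term ids to primary accessions
#'
#' @param dag A [go_dag()].
#' @param ids Character vector of term ids.
#' @return Character vector with `alt_id`s replaced by their primary id;
#'   ids unknown to the DAG pass through unchanged.
#' @export
resolve_term_ids <- function(dag, ids) {
  hit <- ids %in% names(dag$alt_ids)
  ids[hit] <- dag$alt_ids[ids[hit]]
  ids
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by repeatedly following parent edges whose
#' relation label is in `relations`; the focal term itself is excluded.
#'
#' @param dag A [go_dag()].
#' @param term A term id present in the DAG.
#' @param relations Relation labels to traverse (default both `is_a` and
#'   `part_of`).
#' @return Character vector of ancestor ids (unordered).
#' @export
go_ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  term <- resolve_term_ids(dag, term)
  if (!(term %in% dag$terms$id)) {
    rlang::abort(paste0("unknown term id: ", term))
  }
  out <- character()
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character()
    for (t in frontier) {
      p <- dag$parents[[t]]
      if (!is.null(p)) nxt <- c(nxt, names(p)[p %in% relations])
    }
    nxt <- setdiff(unique(nxt), c(out, term))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# Ancestor closure for every non-obsolete term, computed in one topological
# sweep (parents before children). Returns a named list id -> character vector
# of ancestors (excluding self).
ancestor_index <- function(dag, relations = c("is_a", "part_of")) {
  live <- dag$terms$id[!dag$terms$obsolete]
  n_par <- vapply(live, function(i) {
    p <- dag$parents[[i]]
    if (is.null(p)) 0L else sum(p %in% relations)
  }, integer(1))
  names(n_par) <- live
  anc <- stats::setNames(vector("list", length(live)), live)
  queue <- live[n_par == 0L]
  for (t in queue) anc[[t]] <- character()
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (ch in dag$children[[v]]) {
      rel <- dag$parents[[ch]][[v]]
      if (!(rel %in% relations)) next
      anc[[ch]] <- unique(c(anc[[ch]], v, anc[[v]]))
      n_par[[ch]] <- n_par[[ch]] - 1L
      if (n_par[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  # children reached only via non-traversed relations still need entries
  for (t in live) if (is.null(anc[[t]])) anc[[t]] <- go_ancestors(dag, t, relations)
  anc
}

#' Propagate gene annotations up the GO hierarchy (true path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. Propagation follows `is_a` and `part_of` edges by default, as
#' the standard GO tooling does.
#'
#' @param dag A [go_dag()].
#' @param direct Named list: gene id -> character vector of directly annotated
#'   term ids. A two-column data frame (`gene`, `term`) is also accepted.
#' @param relations Relation labels to traverse.
#' @param on_unknown What to do with annotations to ids absent from the DAG
#'   (after `alt_id` resolution): `"skip"` drops them with a warning,
#'   `"error"` aborts.
#' @return An object of class `go_annotation`: list with `direct` and
#'   `propagated` (named lists gene -> term ids) and the `dag` namespaces per
#'   term available through the stored `term_namespace` vector.
#' @export
propagate_annotations <- function(dag, direct, relations = c("is_a", "part_of"),
                                  on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  if (is.data.frame(direct)) {
    stopifnot(ncol(direct) >= 2)
    direct <- split(as.character(direct[[2]]), as.character(direct[[1]]))
  }
  direct <- lapply(direct, function(ts) unique(resolve_term_ids(dag, as.character(ts))))
  live <- dag$terms$id[!dag$terms$obsolete]
  unknown <- setdiff(unique(unlist(direct)), live)
  if (length(unknown) > 0) {
    msg <- paste0(
      "annotations to ", length(unknown), " term(s) not in the DAG: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    )
    if (on_unknown == "error") rlang::abort(msg)
    rlang::warn(paste0(msg, " (skipped)"))
    direct <- lapply(direct, function(ts) intersect(ts, live))
  }
  direct <- direct[lengths(direct) > 0]
  anc <- ancestor_index(dag, relations)
  propagated <- lapply(direct, function(ts) unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  structure(
    list(
      direct = direct,
      propagated = propagated,
      term_namespace = stats::setNames(dag$terms$namespace, dag$terms$id)
    ),
    class = "go_annotation"
  )
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(
    "<go_annotation> ", length(x$direct), " genes; ",
    length(unique(unlist(x$propagated))), " terms after propagation\n",
    sep = ""
  )
  invisible(x)
}

#' Read a GAF 2.x gene-association file
#'
#' Consumes columns 2 (object id) and 5 (GO id); lines starting with `!` are
#' header/comment. Column 7 (evidence code) can be filtered; by default all
#' evidence, including IEA, is kept.
#'
#' @param path File path.
#' @param evidence_keep Optional character vector of evidence codes to keep.
#' @return Tibble with columns `gene`, `term` (and `evidence`).
#' @export
read_gaf <- function(path, evidence_keep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0) rlang::abort("no annotation rows in GAF file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 7)
  if (length(short) > 0) {
    rlang::abort(paste0("GAF row with <7 columns at data line ", short[[1]]))
  }
  out <- tibble::tibble(
    gene = vapply(fields, `[[`, character(1), 2),
    term = vapply(fields, `[[`, character(1), 5),
    evidence = vapply(fields, `[[`, character(1), 7)
  )
  if (!is.null(evidence_keep)) out <- out[out$evidence %in% evidence_keep, ]
  dplyr::distinct(out)
}

#' Read a two-column gene-to-GO annotation table
#'
#' Expects `gene_id<TAB>GO_id` rows; `#` comment lines and blank lines are
#' ignored.
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `term`.
#' @export
read_annotation_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short) > 0) {
    rlang::abort(paste0("annotation row with <2 columns at data line ", short[[1]]))
  }
  dplyr::distinct(tibble::tibble(
    gene = vapply(fields, `[[`, character(1), 1),
    term = vapply(fields, `[[`, character(1), 2)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
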