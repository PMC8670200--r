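# Small in-code fixtures shared across the suite.

# R <- A <- B <- C chain (is_a throughout)
chain_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
      name = c("root", "A", "B", "C"),
      namespace = "biological_process",
      obsolete = FALSE
    ),
    edges = tibble::tibble(
      child = c("GO:0000002", "GO:0000003", "GO:0000004"),
      parent = c("GO:0000001", "GO:0000002", "GO:0000003"),
      relation = "is_a"
    )
  )
}

# diamond: D -> B -> R (is_a, is_a), D -> C -> R (part_of, is_a)
diamond_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
      name = c("R", "B", "C", "D"),
      namespace = "biological_process",
      obsolete = FALSE
    ),
    edges = tibble::tibble(
      child = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000004"),
      parent = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000003"),
      relation = c("is_a", "is_a", "is_a", "part_of")
    )
  )
}

toy_obo_lines <- function() {
  c(
    "format-version: 1.2",
    "ontology: go",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: A",
    "namespace: biological_process",
    "alt_id: GO:0999999",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: B",
    "namespace: biological_process",
    "relationship: part_of GO:0000002 ! A",
    "relationship: regulates GO:0000001 ! dropped",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of"
  )
}

# independent reachability oracle on the raw edge table
bfs_ancestors_oracle <- function(dag, term, relations = c("is_a", "part_of")) {
  e <- dag$edges[dag$edges$relation %in% relations, ]
  seen <- character()
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(e$parent[e$child %in% frontier]), c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# exhaustive upper-tail hypergeometric sum from binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  if (K == 0 || n == 0) return(1)
  j <- max(k, 0):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# naive parent-child p-value recomputed from the annotation map and edge
# table, independent of the term_index machinery
naive_parent_child <- function(sample, dag, propagated, universe, term,
                               namespace = "biological_process") {
  ns_ids <- dag$terms$id[dag$terms$namespace == namespace & !dag$terms$obsolete]
  genes_of <- function(t) {
    u <- intersect(names(propagated), universe)
    u[vapply(propagated[u], function(ts) t %in% ts, logical(1))]
  }
  feasible <- intersect(names(propagated), universe)
  feasible <- feasible[vapply(
    propagated[feasible],
    function(ts) any(ts %in% ns_ids), logical(1)
  )]
  parents <- dag$edges$parent[dag$edges$child == term]
  parents <- intersect(parents, ns_ids)
  if (length(parents) == 0) return(1)
  pool <- unique(unlist(lapply(parents, genes_of)))
  pool <- intersect(pool, feasible)
  tg <- intersect(genes_of(term), feasible)
  s <- intersect(sample, feasible)
  hyper_tail_oracle(
    k = length(intersect(s, tg)),
    K = length(intersect(tg, pool)),
    N = length(pool),
    n = length(intersect(s, pool))
  )
}
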