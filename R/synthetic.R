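# Seeded synthetic scenarios: toy GO DAGs, annotation maps, bimodal score
# tables with missing flags, exact-cardinality reference-set layouts and
# planted-enrichment samples. Every generator is deterministic given its
# seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

go_id <- function(i) sprintf("GO:%07d", i)

#' Synthetic AGI-style locus ids
#'
#' Deterministic ids following the AGI pattern `AT<chr>G<5 digits>`.
#'
#' @param n Number of ids.
#' @return Character vector of `n` distinct locus ids.
#' @export
agi_ids <- function(n) {
  i <- seq_len(n) - 1L
  sprintf("AT%dG%05d", i %% 5L + 1L, i %/% 5L + 1L)
}

#' Generate a random toy GO DAG
#'
#' Grows each namespace root-down: every new term attaches to one or two
#' already-existing parents chosen uniformly, so the graph is acyclic by
#' construction. Relation labels mix `is_a` and `part_of`.
#'
#' @param n_terms Named integer vector, number of terms per namespace, e.g.
#'   `c(biological_process = 30)`; an unnamed scalar means one
#'   biological-process namespace.
#' @param seed Integer seed.
#' @param p_second_parent Probability that a term gets a second parent.
#' @param part_of_frac Fraction of edges labelled `part_of`.
#' @return A [go_dag()].
#' @export
make_toy_dag <- function(n_terms = 30, seed = 1, p_second_parent = 0.3,
                         part_of_frac = 0.2) {
  if (is.null(names(n_terms))) {
    names(n_terms) <- "biological_process"
  }
  if (any(n_terms < 1)) rlang::abort("each namespace needs at least one term")
  with_seed(seed, {
    terms <- list()
    edges <- list()
    counter <- 0L
    for (ns in names(n_terms)) {
      ids <- go_id(counter + seq_len(n_terms[[ns]]))
      counter <- counter + n_terms[[ns]]
      terms[[ns]] <- tibble::tibble(
        id = ids,
        name = paste0(ns, " term ", seq_along(ids)),
        namespace = ns,
        obsolete = FALSE
      )
      if (length(ids) > 1) {
        for (i in 2:length(ids)) {
          n_par <- 1L + (i > 2 && stats::runif(1) < p_second_parent)
          par <- sample(ids[seq_len(i - 1)], min(n_par, i - 1))
          rel <- ifelse(stats::runif(length(par)) < part_of_frac, "part_of", "is_a")
          edges[[length(edges) + 1L]] <- tibble::tibble(
            child = ids[i], parent = par, relation = rel
          )
        }
      }
    }
    edges <- if (length(edges) > 0) {
      dplyr::bind_rows(edges)
    } else {
      tibble::tibble(child = character(), parent = character(), relation = character())
    }
    go_dag(dplyr::bind_rows(terms), edges)
  })
}

#' Random gene-to-term annotation map over a toy DAG
#'
#' Each gene receives between `min_terms` and `max_terms` direct annotations
#' drawn uniformly from the non-root terms of the DAG (annotating directly
#' to the root would make propagation trivial).
#'
#' @param dag A [go_dag()].
#' @param genes Character vector of gene ids.
#' @param seed Integer seed.
#' @param min_terms,max_terms Range of direct annotations per gene.
#' @return Named list gene -> character vector of term ids, suitable for
#'   [propagate_annotations()].
#' @export
make_toy_annotations <- function(dag, genes, seed = 1, min_terms = 1, max_terms = 3) {
  pool <- setdiff(dag$terms$id[!dag$terms$obsolete], unname(dag$roots))
  if (length(pool) == 0) pool <- dag$terms$id[!dag$terms$obsolete]
  with_seed(seed, {
    out <- lapply(genes, function(g) {
      k <- sample(min_terms:max_terms, 1)
      sample(pool, min(k, length(pool)))
    })
    stats::setNames(out, genes)
  })
}

#' Reference-set layout with exact cardinalities and overlap
#'
#' Builds a genome and two phosphoproteome sets with exactly the requested
#' sizes and pairwise overlap, using AGI-style ids, so the overlap
#' arithmetic of the reference-construction stage can be exercised at the
#' published scale.
#'
#' @param n_exp,n_pred Sizes of the experimental and predicted sets.
#' @param n_overlap Size of their intersection.
#' @param n_genome Genome size.
#' @param seed Integer seed (controls which ids land in which set).
#' @return List of [ref_set()]s: `genome`, `exprs`, `predrs`.
#' @export
make_reference_scenario <- function(n_exp = 13137, n_pred = 17156,
                                    n_overlap = 12024, n_genome = 27655,
                                    seed = 1) {
  if (n_overlap > min(n_exp, n_pred)) {
    rlang::abort("overlap cannot exceed either set size")
  }
  n_union <- n_exp + n_pred - n_overlap
  if (n_union > n_genome) rlang::abort("union exceeds the genome size")
  genome <- agi_ids(n_genome)
  with_seed(seed, {
    perm <- sample(genome)
    both <- perm[seq_len(n_overlap)]
    exp_only <- perm[n_overlap + seq_len(n_exp - n_overlap)]
    pred_only <- perm[n_exp + seq_len(n_pred - n_overlap)]
    list(
      genome = ref_set(genome, "GenRS", normalize = FALSE),
      exprs = ref_set(c(both, exp_only), "ExpRS", normalize = FALSE),
      predrs = ref_set(c(both, pred_only), "PredRS", normalize = FALSE)
    )
  })
}

#' Bimodal synthetic gene scores with labels
#'
#' Positive-class genes draw scores from a high Beta component, negatives
#' from a low one; a fraction of genes carries the `-1` missing flag. This
#' mimics the per-gene prediction scores a site-level phosphorylation
#' predictor produces after max-aggregation.
#'
#' @param n_genes Universe size.
#' @param pos_frac Fraction of genes in the positive class.
#' @param pos_shape,neg_shape Beta shape parameters `c(a, b)` of the two
#'   score components (defaults place the modes near 0.9 and 0.1).
#' @param missing_rate Fraction of genes flagged `-1` (must be < 1).
#' @param seed Integer seed.
#' @return List: `scores` tibble (`gene`, `score`), `positives` and
#'   `universe` [ref_set()]s.
#' @export
make_score_sets <- function(n_genes = 2000, pos_frac = 0.4,
                            pos_shape = c(8, 2), neg_shape = c(2, 8),
                            missing_rate = 0.05, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1) {
    rlang::abort("missing_rate must lie in [0, 1)")
  }
  genes <- agi_ids(n_genes)
  with_seed(seed, {
    n_pos <- round(pos_frac * n_genes)
    pos <- sample(genes, n_pos)
    score <- numeric(n_genes)
    names(score) <- genes
    score[pos] <- stats::rbeta(n_pos, pos_shape[1], pos_shape[2])
    neg <- setdiff(genes, pos)
    score[neg] <- stats::rbeta(length(neg), neg_shape[1], neg_shape[2])
    miss <- stats::runif(n_genes) < missing_rate
    score[miss] <- -1
    list(
      scores = tibble::tibble(gene = genes, score = unname(score)),
      positives = ref_set(pos, "positives", normalize = FALSE),
      universe = ref_set(genes, "universe", normalize = FALSE)
    )
  })
}

#' Sample with planted GO-term enrichment
#'
#' Draws a gene sample from the universe in which the genes of the planted
#' terms are included with probability `effect` and all other genes with
#' probability `background_rate`, creating true over-representation of the
#' planted terms of tunable strength.
#'
#' @param annotations A `go_annotation` ([propagate_annotations()]).
#' @param universe [ref_set()] or character vector.
#' @param planted_terms Term ids to enrich.
#' @param effect Inclusion probability for planted-term genes (must be >=
#'   `background_rate`; equality gives a null sample).
#' @param background_rate Inclusion probability for all other genes.
#' @param seed Integer seed.
#' @return A [ref_set()] named `"sample"`.
#' @export
make_enriched_sample <- function(annotations, universe, planted_terms,
                                 effect, background_rate, seed = 1) {
  if (effect < background_rate) {
    rlang::abort("effect must be at least background_rate")
  }
  u <- set_members(universe)
  planted_genes <- names(annotations$propagated)[vapply(
    annotations$propagated,
    function(ts) any(planted_terms %in% ts), logical(1)
  )]
  unknown <- setdiff(planted_terms, unlist(annotations$propagated, use.names = FALSE))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "planted term(s) annotate no gene: ", paste(unknown, collapse = ", ")
    ))
  }
  p <- ifelse(u %in% planted_genes, effect, background_rate)
  with_seed(seed, {
    ref_set(u[stats::runif(length(u)) < p], "sample", normalize = FALSE)
  })
}
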