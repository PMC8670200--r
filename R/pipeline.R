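# End-to-end contrast strategy: reference construction, augmentation, the
# three enrichment comparisons, pattern grouping, specific-term calls,
# GenRatio and the semantic-similarity layout.

#' Run the full phosphoproteome GO-contrast strategy
#'
#' Executes the complete workflow for one sample: builds the union
#' phosphoproteome reference from the experimental and predicted sets,
#' augments it with the sample's novel phosphoproteins (so the sample is
#' fully contained in the reference universe), runs the three parent-child
#' Fisher comparisons per namespace (sample vs genome, reference vs genome,
#' sample vs reference), assembles binary significance matrices, assigns
#' contrast groups, calls sample-specific terms (significant in both sample
#' comparisons), computes their GenRatio, and lays the specific terms out by
#' Wang semantic similarity.
#'
#' @param sample [ref_set()] or character vector of sample phosphoprotein
#'   loci.
#' @param exprs,predrs Experimental and predicted reference [ref_set()]s.
#' @param genome Genome [ref_set()] (the universe for the genome
#'   comparisons).
#' @param dag A [go_dag()].
#' @param annotations A `go_annotation` from [propagate_annotations()], or a
#'   direct gene -> terms map (propagated automatically).
#' @param namespaces Namespaces to analyse (default: all in the DAG).
#' @param alpha FDR significance level (default 0.01).
#' @param min_node_size Minimum term size for testing (default 1).
#' @param weights Wang semantic-contribution weights.
#' @return Object of class `phosgo_run`: list with `refsets`, `report`,
#'   `tables` (per namespace, named `sample_vs_genome`, `ref_vs_genome`,
#'   `sample_vs_ref`), `matrices`, `groups`, `specific`, `gen_ratio`,
#'   `embedding` and `provenance`.
#' @export
run_contrast_strategy <- function(sample, exprs, predrs, genome, dag, annotations,
                                  namespaces = NULL, alpha = 0.01,
                                  min_node_size = 1L,
                                  weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!inherits(annotations, "go_annotation")) {
    annotations <- propagate_annotations(dag, annotations)
  }
  sample <- if (inherits(sample, "ref_set")) sample else ref_set(sample, "sample")
  unrs <- ensemble_or(exprs, predrs, name = "UnRS")
  aug <- augment_reference(unrs, sample)
  n_novel <- attr(aug, "n_new")
  report <- set_report(list(exprs, predrs, unrs, aug, sample), genome)

  if (is.null(namespaces)) {
    namespaces <- unique(dag$terms$namespace[!dag$terms$obsolete])
  }

  tables <- list()
  matrices <- list()
  specific <- list()
  gr <- list()
  embedding <- list()
  genome_index <- list()
  for (ns in namespaces) {
    idx_gen <- build_term_index(annotations, genome, dag, ns, min_node_size)
    idx_ref <- build_term_index(annotations, aug, dag, ns, min_node_size)
    genome_index[[ns]] <- idx_gen
    tabs <- list(
      sample_vs_genome = run_comparison(sample,
        index = idx_gen, alpha = alpha,
        comparison = "sample_vs_genome"
      ),
      sample_vs_ref = run_comparison(sample,
        index = idx_ref, alpha = alpha,
        comparison = "sample_vs_ref"
      ),
      ref_vs_genome = run_comparison(aug,
        index = idx_gen, alpha = alpha,
        comparison = "ref_vs_genome"
      )
    )
    tables[[ns]] <- tabs
    matrices[[ns]] <- significance_matrix(tabs, alpha = alpha)
    specific[[ns]] <- specific_terms(matrices[[ns]], "sample_vs_genome", "sample_vs_ref")
    if (length(specific[[ns]]) > 0) {
      gr[[ns]] <- gen_ratio(specific[[ns]], sample, idx_gen)
      if (length(specific[[ns]]) >= 2) {
        sim <- similarity_matrix(dag, specific[[ns]], weights)
        ratios <- stats::setNames(gr[[ns]]$gen_ratio, gr[[ns]]$term)
        embedding[[ns]] <- mds_embedding(sim, gen_ratio = ratios)
      }
    }
  }
  groups <- group_patterns(matrices, prefix = "CG")

  structure(
    list(
      refsets = list(
        exprs = exprs, predrs = predrs, unrs = unrs,
        reference = aug, sample = sample, genome = genome
      ),
      report = report,
      tables = tables,
      matrices = matrices,
      groups = groups,
      specific = specific,
      gen_ratio = gr,
      embedding = embedding,
      genome_index = genome_index,
      provenance = list(
        alpha = alpha, min_node_size = min_node_size, weights = weights,
        n_sample = length(sample$members), n_novel = n_novel,
        namespaces = namespaces,
        n_specific = vapply(specific, length, integer(1)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "phosgo_run"
  )
}

#' @export
print.phosgo_run <- function(x, ...) {
  cat("<phosgo_run>\n")
  cat(
    "  sample:", x$provenance$n_sample, "genes (",
    x$provenance$n_novel, "novel, added to the reference )\n"
  )
  cat(
    "  reference:", length(x$refsets$reference$members), "genes; genome:",
    length(x$refsets$genome$members), "genes\n"
  )
  for (ns in names(x$matrices)) {
    cat(
      "  ", ns, ": ", nrow(x$matrices[[ns]]), " terms in the matrix, ",
      length(x$specific[[ns]]), " specific\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @rdname run_contrast_strategy
#' @param x,object A `phosgo_run`.
#' @param ... Unused.
#' @return `tidy()`: one row per term and comparison with p-value, FDR and
#'   group label; `glance()`: one row per namespace with matrix and
#'   specific-term counts.
#' @export
tidy.phosgo_run <- function(x, ...) {
  rows <- list()
  for (ns in names(x$tables)) {
    for (cmp in names(x$tables[[ns]])) {
      t <- tibble::as_tibble(x$tables[[ns]][[cmp]])
      t$comparison <- cmp
      rows[[length(rows) + 1L]] <- t
    }
  }
  out <- dplyr::bind_rows(rows)
  lab <- x$groups$assignment
  if (nrow(lab) > 0) {
    out <- dplyr::left_join(out, lab[c("term", "namespace", "label")],
      by = c("term", "namespace")
    )
  } else {
    out$label <- NA_character_
  }
  dplyr::relocate(out, "comparison", .after = "namespace")
}

#' @rdname run_contrast_strategy
#' @export
glance.phosgo_run <- function(x, ...) {
  tibble::tibble(
    namespace = names(x$matrices),
    n_terms = vapply(x$matrices, nrow, integer(1)),
    n_specific = vapply(names(x$matrices), function(ns) length(x$specific[[ns]]), integer(1), USE.NAMES = FALSE),
    alpha = x$provenance$alpha
  )
}

#' Write the result bundle of a run to disk
#'
#' Emits the overlap report, per-namespace enrichment tables, significance
#' matrices, group assignment, specific-term lists and GenRatio tables as
#' TSV, plus a JSON provenance record.
#'
#' @param run A `phosgo_run`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(run$report$sets, "refset_sizes.tsv")
  if (!is.null(run$report$pairs)) emit(run$report$pairs, "refset_overlaps.tsv")
  for (ns in names(run$tables)) {
    for (cmp in names(run$tables[[ns]])) {
      emit(run$tables[[ns]][[cmp]], paste0("enrichment_", ns, "_", cmp, ".tsv"))
    }
    emit(run$matrices[[ns]], paste0("matrix_", ns, ".tsv"))
    if (!is.null(run$gen_ratio[[ns]])) emit(run$gen_ratio[[ns]], paste0("genratio_", ns, ".tsv"))
    if (!is.null(run$embedding[[ns]])) emit(run$embedding[[ns]]$coords, paste0("semsim_", ns, ".tsv"))
  }
  if (nrow(run$groups$assignment) > 0) emit(run$groups$assignment, "groups.tsv")
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(run$provenance, pj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pj)
  invisible(paths)
}
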