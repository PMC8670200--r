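# Reference-set construction: ID normalisation, study aggregation,
# site -> protein -> gene score collapse, thresholding, OR-ensembling and
# overlap reporting.

#' Create a named reference set of gene loci
#'
#' A reference set is a named set of splice-variant-free, uppercase locus ids
#' (set semantics: unique, unordered).
#'
#' @param members Character vector of gene ids (normalised with
#'   [normalize_gene_id()] unless `normalize = FALSE`).
#' @param name Set label, e.g. `"ExpRS"`.
#' @param normalize Normalise members on construction (default `TRUE`).
#' @return Object of class `ref_set`.
#' @export
ref_set <- function(members, name = "set", normalize = TRUE) {
  if (!nzchar(name)) rlang::abort("reference set name must be non-empty")
  members <- as.character(members)
  if (normalize && length(members) > 0) members <- normalize_gene_id(members)
  structure(
    list(name = name, members = sort(unique(members))),
    class = "ref_set"
  )
}

#' @export
print.ref_set <- function(x, ...) {
  cat("<ref_set '", x$name, "'> ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.ref_set <- function(x) length(x$members)

#' @export
as.character.ref_set <- function(x, ...) x$members

# Accept either a ref_set or a plain character vector.
set_members <- function(x) {
  if (inherits(x, "ref_set")) x$members else sort(unique(as.character(x)))
}

#' Normalise a gene identifier to its locus form
#'
#' Strips surrounding whitespace, removes a trailing `.<integer>`
#' splice-variant suffix and uppercases, so that all isoforms of a locus
#' collapse to one id (e.g. `"at1g01010.2"` -> `"AT1G01010"`).
#'
#' @param raw Character vector of raw ids.
#' @return Character vector of normalised locus ids.
#' @examples
#' normalize_gene_id(c("AT1G01010.1", "at1g01010", " AT5G10140 "))
#' @export
normalize_gene_id <- function(raw) {
  raw <- trimws(as.character(raw))
  if (any(!nzchar(raw)) || any(is.na(raw))) {
    rlang::abort("empty or missing gene id")
  }
  toupper(sub("\\.[0-9]+$", "", raw))
}

#' Read a plain-text gene list
#'
#' One id per line; `#` comments and blank lines are ignored.
#'
#' @param path File path.
#' @return Character vector of raw ids (not normalised).
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Build the experimental phosphoproteome reference set
#'
#' Union of the normalised gene ids across mass-spectrometry study lists.
#' Each element of `studies` is either a file path (read with
#' [read_gene_list()]) or a character vector of ids.
#'
#' @param studies List of study gene lists (paths or character vectors).
#' @param name Label for the resulting set.
#' @return A [ref_set()]; attribute `"provenance"` holds a tibble with
#'   per-study raw counts, normalised counts and cumulative union size.
#' @export
build_experimental_set <- function(studies, name = "ExpRS") {
  if (length(studies) < 1) rlang::abort("at least one study list is required")
  if (is.character(studies)) studies <- as.list(studies)
  acc <- character()
  prov <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    ids <- if (is.character(s) && length(s) == 1 && file.exists(s)) read_gene_list(s) else as.character(s)
    norm <- unique(normalize_gene_id(ids))
    acc <- union(acc, norm)
    prov[[i]] <- tibble::tibble(
      study = i, n_raw = length(ids), n_normalized = length(norm),
      n_union = length(acc)
    )
  }
  if (length(acc) == 0) rlang::abort("union of study lists is empty")
  out <- ref_set(acc, name = name, normalize = FALSE)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Read a per-site phosphorylation score table
#'
#' Tab-separated with a header and columns `protein_id`, `residue`,
#' `position`, `score`. Scores lie in `[0, 1]`; `-1` flags a missing
#' prediction.
#'
#' @param path File path.
#' @return Tibble of validated site records.
#' @export
read_site_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein_id", "residue", "position", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(paste0("site-score table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[need])
  validate_site_scores(out)
  out
}

validate_site_scores <- function(sites) {
  bad <- !(sites$score == -1 | (sites$score >= 0 & sites$score <= 1))
  if (any(bad, na.rm = TRUE) || anyNA(sites$score)) {
    rlang::abort("site scores must lie in [0, 1] or be the missing flag -1")
  }
  if (any(sites$position < 1)) rlang::abort("site positions are 1-based (>= 1)")
  if (any(!sites$residue %in% c("S", "T", "Y"))) {
    rlang::abort("residue must be one of S, T, Y")
  }
  invisible(sites)
}

#' Collapse per-site scores to per-gene scores
#'
#' Protein score = maximum over that protein's site scores (the missing flag
#' `-1` ranks below any real score); gene score = maximum over the protein
#' scores of the locus's isoforms. A gene whose sites are all missing scores
#' `-1`.
#'
#' @param sites Tibble with columns `protein_id`, `residue`, `position`,
#'   `score` (see [read_site_scores()]).
#' @return Tibble with columns `gene`, `score`, one row per locus.
#' @export
gene_scores_from_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  validate_site_scores(sites)
  sites |>
    dplyr::mutate(gene = normalize_gene_id(.data$protein_id)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Threshold gene scores into a predicted reference set
#'
#' A gene is called phosphorylated when its score is greater than or equal to
#' the threshold; the missing flag `-1` is never positive.
#'
#' @param scores Tibble with columns `gene`, `score` (a gene-score table).
#' @param threshold Cutoff in `[0, 1]`.
#' @param name Label for the resulting set.
#' @return A [ref_set()] of positive genes.
#' @export
classify_genes <- function(scores, threshold, name = "predicted") {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold < 0 || threshold > 1) rlang::abort("threshold must lie in [0, 1]")
  pos <- scores$gene[scores$score >= threshold & scores$score != -1]
  ref_set(pos, name = name, normalize = FALSE)
}

#' Combine two predictors by union (OR-ensemble)
#'
#' A gene is positive in the ensemble if either component predicts it
#' positive.
#'
#' @param a,b [ref_set()] objects (or character vectors of normalised ids).
#' @param name Label for the union.
#' @return A [ref_set()] with `members = a` \eqn{\cup} `b`.
#' @export
ensemble_or <- function(a, b, name = "union") {
  ref_set(union(set_members(a), set_members(b)), name = name, normalize = FALSE)
}

#' Augment a phosphoproteome reference with newly observed phosphoproteins
#'
#' Adds sample phosphoproteins absent from the base reference (the step that
#' turns the union reference into its sample-updated form before a
#' sample-vs-reference comparison).
#'
#' @param base Base [ref_set()].
#' @param novel Candidate new members ([ref_set()] or character vector; ids
#'   are normalised).
#' @param name Label for the augmented set.
#' @return A [ref_set()]; attribute `"n_new"` records how many ids were
#'   genuinely new.
#' @export
augment_reference <- function(base, novel, name = NULL) {
  novel <- normalize_gene_id(set_members(novel))
  base_m <- set_members(base)
  new_ids <- setdiff(novel, base_m)
  nm <- name %||% paste0(if (inherits(base, "ref_set")) base$name else "base", "+", length(new_ids))
  out <- ref_set(c(base_m, new_ids), name = nm, normalize = FALSE)
  attr(out, "n_new") <- length(new_ids)
  out
}

#' Overlap report for phosphoproteome reference sets
#'
#' Sizes, genome percentages and all pairwise overlaps, with exact
#' inclusion-exclusion. Sets are expected to be contained in the genome;
#' violations are listed, not dropped.
#'
#' @param sets List of [ref_set()] objects (names taken from the sets).
#' @param genome Genome [ref_set()] (the universe).
#' @return Object of class `refset_report`: list with tibbles `sets`
#'   (name, size, pct_genome at one decimal), `pairs` (pairwise
#'   intersection/only_a/only_b/union sizes and union genome percentage) and
#'   `violations` (ids outside the genome per set).
#' @export
set_report <- function(sets, genome) {
  if (inherits(sets, "ref_set")) sets <- list(sets)
  g <- set_members(genome)
  nm <- vapply(sets, function(s) if (inherits(s, "ref_set")) s$name else "set", character(1))
  mem <- lapply(sets, set_members)

  viol <- purrr::map2(mem, nm, function(m, n) {
    out <- setdiff(m, g)
    if (length(out) == 0) NULL else tibble::tibble(set = n, gene = out)
  })
  viol <- dplyr::bind_rows(viol)
  if (nrow(viol) > 0) {
    rlang::warn(paste0(nrow(viol), " gene(s) fall outside the genome reference"))
  }

  sizes <- tibble::tibble(
    set = nm,
    size = lengths(mem),
    pct_genome = round(100 * lengths(mem) / length(g), 1)
  )

  pairs <- NULL
  if (length(sets) >= 2) {
    idx <- utils::combn(seq_along(sets), 2)
    pairs <- purrr::map(seq_len(ncol(idx)), function(j) {
      ma <- mem[[idx[1, j]]]
      mb <- mem[[idx[2, j]]]
      inter <- length(intersect(ma, mb))
      un <- length(ma) + length(mb) - inter
      tibble::tibble(
        a = nm[idx[1, j]], b = nm[idx[2, j]],
        size_a = length(ma), size_b = length(mb),
        intersection = inter,
        only_a = length(ma) - inter,
        only_b = length(mb) - inter,
        union = un,
        union_pct_genome = round(100 * un / length(g), 1)
      )
    })
    pairs <- dplyr::bind_rows(pairs)
  }

  structure(
    list(
      sets = sizes, pairs = pairs, violations = viol,
      genome_size = length(g)
    ),
    class = "refset_report"
  )
}

#' @export
print.refset_report <- function(x, ...) {
  cat("<refset_report> genome of", x$genome_size, "genes\n")
  print(x$sets)
  if (!is.null(x$pairs)) print(x$pairs)
  if (nrow(x$violations) > 0) {
    cat("!!", nrow(x$violations), "gene(s) outside the genome:\n")
    print(x$violations)
  }
  invisible(x)
}
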