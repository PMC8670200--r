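# build an enrichment_table by hand for matrix-level tests
fake_table <- function(terms, fdr, namespace = "biological_process") {
  tbl <- tibble::tibble(
    term = terms, namespace = namespace,
    n_universe = 10L, n_sample = 5L,
    p_value = fdr, fdr = fdr, significant = fdr < 0.01
  )
  class(tbl) <- c("enrichment_table", class(tbl))
  tbl
}

test_that("significance matrix keeps terms significant somewhere, binarised at alpha", {
  t1 <- fake_table(c("GO:0000010", "GO:0000011", "GO:0000012"), c(0.001, 0.5, 0.5))
  t2 <- fake_table(c("GO:0000010", "GO:0000011", "GO:0000012"), c(0.001, 0.002, 0.5))
  t3 <- fake_table(c("GO:0000010", "GO:0000011", "GO:0000012"), c(0.5, 0.5, 0.009))
  m <- significance_matrix(list(a = t1, b = t2, c = t3))
  expect_equal(nrow(m), 3)
  expect_equal(m$a[m$term == "GO:0000012"], 0L)
  expect_equal(m$c[m$term == "GO:0000012"], 1L)
  expect_equal(unlist(m[m$term == "GO:0000010", c("a", "b", "c")], use.names = FALSE), c(1L, 1L, 0L))
  # nothing significant anywhere -> empty matrix
  empty <- significance_matrix(list(
    a = fake_table("GO:0000010", 0.9),
    b = fake_table("GO:0000010", 0.9)
  ))
  expect_equal(nrow(empty), 0)
  # untested terms score 0 with a warning
  expect_warning(
    m2 <- significance_matrix(list(
      a = fake_table(c("GO:0000010", "GO:0000011"), c(0.001, 0.9)),
      b = fake_table("GO:0000011", 0.001)
    )),
    "untested"
  )
  expect_equal(m2$b[m2$term == "GO:0000010"], 0L)
  expect_error(
    significance_matrix(list(
      a = fake_table("GO:0000010", 0.001),
      b = fake_table("GO:0000010", 0.001, namespace = "molecular_function")
    )),
    "namespace"
  )
})

test_that("pattern groups are labelled by descending BP count with binary tie-break", {
  # construct matrices with known pattern counts
  mk <- function(patterns, ns) {
    terms <- sprintf("GO:%07d", seq_along(patterns))
    cells <- do.call(rbind, lapply(strsplit(patterns, ""), as.integer))
    out <- tibble::tibble(term = terms, x = cells[, 1], y = cells[, 2], z = cells[, 3])
    attr(out, "comparisons") <- c("x", "y", "z")
    attr(out, "namespace") <- ns
    class(out) <- c("sig_matrix", class(out))
    out
  }
  bp <- mk(c("111", "111", "111", "110", "110", "001"), "biological_process")
  mf <- mk(c("110", "001", "001", "001"), "molecular_function")
  g <- group_patterns(list(biological_process = bp, molecular_function = mf))
  expect_equal(g$groups$label, c("G1", "G2", "G3"))
  expect_equal(g$groups$pattern, c("111", "110", "001"))
  expect_equal(g$groups$n_biological_process, c(3L, 2L, 1L))
  expect_equal(g$groups$n_molecular_function, c(0L, 1L, 3L))
  # every row assigned exactly once; group sizes sum to row counts
  expect_equal(nrow(g$assignment), nrow(bp) + nrow(mf))
  expect_false(anyNA(g$assignment$label))
  expect_equal(sum(g$groups$n_biological_process), nrow(bp))
  # tie on BP count broken by descending binary value
  bp2 <- mk(c("101", "101", "010", "010"), "biological_process")
  g2 <- group_patterns(list(biological_process = bp2))
  expect_equal(g2$groups$pattern, c("101", "010")) # 5 before 2
  # three comparisons admit at most 7 distinct non-zero patterns
  all_pats <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  expect_equal(length(setdiff(all_pats, "000")), 7)
})

test_that("specific terms require significance in both sample comparisons", {
  rows <- tibble::tibble(
    term = sprintf("GO:%07d", 1:4),
    svg = c(1L, 1L, 1L, 0L),
    svr = c(1L, 1L, 0L, 0L),
    rvg = c(0L, 1L, 1L, 1L)
  )
  attr(rows, "comparisons") <- c("svg", "svr", "rvg")
  class(rows) <- c("sig_matrix", class(rows))
  expect_equal(specific_terms(rows, "svg", "svr"), sprintf("GO:%07d", 1:2))
  # invariant to the reference-vs-genome column values
  rows2 <- rows
  rows2$rvg <- 1L - rows2$rvg
  expect_equal(specific_terms(rows2, "svg", "svr"), specific_terms(rows, "svg", "svr"))
  expect_error(specific_terms(rows, "svg", "nope"), "unknown comparison")
  empty <- rows[0, ]
  attr(empty, "comparisons") <- c("svg", "svr", "rvg")
  class(empty) <- c("sig_matrix", class(empty))
  expect_equal(specific_terms(empty, "svg", "svr"), character(0))
})

test_that("GenRatio is an exact percentage, monotone in the sample", {
  dag <- chain_dag()
  genes <- agi_ids(10)
  ann <- propagate_annotations(
    dag,
    stats::setNames(as.list(rep("GO:0000004", 10)), genes)
  )
  idx <- build_term_index(ann, genes, dag, "biological_process")
  gr <- gen_ratio("GO:0000004", genes[1:5], idx)
  expect_equal(gr$ratio, 50)
  expect_equal(gr$gen_ratio, 50.0)
  expect_equal(gen_ratio("GO:0000004", genes, idx)$ratio, 100)
  # one-decimal display rounding with the exact rational kept
  gr3 <- gen_ratio("GO:0000004", genes[1:3], idx) # 3/10
  expect_equal(gr3$ratio, 30)
  gr7 <- gen_ratio("GO:0000004", genes[1:7], idx)
  expect_equal(gr7$gen_ratio, 70.0)
  # monotonicity
  small <- gen_ratio("GO:0000004", genes[1:2], idx)$ratio
  big <- gen_ratio("GO:0000004", genes[1:6], idx)$ratio
  expect_gte(big, small)
  expect_error(gen_ratio("GO:9999999", genes, idx), "not in index")
})

test_that("end-to-end contrast separates sample-specific from reference-default enrichment", {
  dag <- make_toy_dag(c(biological_process = 40), seed = 13)
  genes <- agi_ids(1000)
  ann <- propagate_annotations(dag, make_toy_annotations(dag, genes, seed = 14))
  idx_gen <- build_term_index(ann, genes, dag, "biological_process")
  sizes <- lengths(idx_gen$index)
  mid <- names(sizes)[sizes >= 40 & sizes <= 250]
  ref_term <- mid[[1]] # default-enriched in the phospho-reference
  samp_term <- mid[[length(mid)]] # enriched only in the sample
  reference <- make_enriched_sample(ann, genes, ref_term,
    effect = 0.9, background_rate = 0.35, seed = 15
  )
  # sample drawn from the reference, enriched for samp_term at the same
  # relative strength the reference has for ref_term
  sample <- make_enriched_sample(ann, reference, samp_term,
    effect = 0.9, background_rate = 0.2, seed = 16
  )
  idx_ref <- build_term_index(ann, reference, dag, "biological_process")
  tabs <- list(
    sample_vs_genome = run_comparison(sample, index = idx_gen),
    sample_vs_ref = run_comparison(sample, index = idx_ref),
    ref_vs_genome = run_comparison(reference, index = idx_gen)
  )
  m <- significance_matrix(tabs)
  spec <- specific_terms(m, "sample_vs_genome", "sample_vs_ref")
  expect_true(samp_term %in% spec)
  expect_false(ref_term %in% spec)
})
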