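test_that("Wang S-values follow the max-product recursion", {
  root_only <- go_dag(
    tibble::tibble(
      id = "GO:0000001", name = "r",
      namespace = "biological_process", obsolete = FALSE
    ),
    tibble::tibble(child = character(), parent = character(), relation = character())
  )
  sv <- wang_svalues(root_only, "GO:0000001")
  expect_equal(sv$s, c("GO:0000001" = 1))
  expect_equal(sv$sv, 1)

  dag <- chain_dag() # C is_a B is_a A is_a root, all 0.8
  sv <- wang_svalues(dag, "GO:0000002") # A is_a root
  expect_equal(sv$s[["GO:0000002"]], 1)
  expect_equal(sv$s[["GO:0000001"]], 0.8)
  expect_equal(sv$sv, 1.8)
  svc <- wang_svalues(dag, "GO:0000004")
  expect_equal(unname(svc$s[c("GO:0000004", "GO:0000003", "GO:0000002", "GO:0000001")]),
    c(1, 0.8, 0.64, 0.512),
    tolerance = 1e-15
  )

  # diamond: two routes to the root; S = max of the path products
  dia <- diamond_dag() # D -is_a-> B -is_a-> R; D -part_of-> C -is_a-> R
  svd <- wang_svalues(dia, "GO:0000004")
  expect_equal(svd$s[["GO:0000002"]], 0.8)
  expect_equal(svd$s[["GO:0000003"]], 0.6)
  expect_equal(svd$s[["GO:0000001"]], max(0.8 * 0.8, 0.6 * 0.8))
  expect_error(wang_svalues(dia, "GO:1111111"), "unknown term")
  expect_error(wang_svalues(dia, "GO:0000004", weights = c(is_a = 1.2, part_of = 0.6)), "weights")
})

test_that("Wang similarity is 1 on self, 0 across namespaces, 4/9 for siblings", {
  sib <- go_dag(
    tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003"),
      name = c("r", "a", "b"),
      namespace = "biological_process", obsolete = FALSE
    ),
    tibble::tibble(
      child = c("GO:0000002", "GO:0000003"),
      parent = "GO:0000001", relation = "is_a"
    )
  )
  a <- wang_svalues(sib, "GO:0000002")
  b <- wang_svalues(sib, "GO:0000003")
  expect_equal(wang_similarity(a, a), 1)
  expect_equal(wang_similarity(a, b), (0.8 + 0.8) / (1.8 + 1.8))
  expect_equal(wang_similarity(a, b), 4 / 9, tolerance = 1e-12)

  two_ns <- make_toy_dag(c(biological_process = 5, molecular_function = 5), seed = 1)
  bp_term <- two_ns$terms$id[two_ns$terms$namespace == "biological_process"][3]
  mf_term <- two_ns$terms$id[two_ns$terms$namespace == "molecular_function"][3]
  expect_equal(
    wang_similarity(wang_svalues(two_ns, bp_term), wang_svalues(two_ns, mf_term)),
    0
  )
})

test_that("similarity matrices are symmetric, bounded, order-equivariant and locally stable", {
  dag <- make_toy_dag(c(biological_process = 20), seed = 5)
  terms <- dag$terms$id[c(2, 5, 9, 14, 20)]
  m <- similarity_matrix(dag, terms)
  expect_equal(diag(m), stats::setNames(rep(1, 5), terms))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  perm <- c(3, 1, 5, 2, 4)
  m2 <- similarity_matrix(dag, terms[perm])
  expect_equal(m2, m[perm, perm])
  # single term
  expect_equal(similarity_matrix(dag, terms[1]), matrix(1, 1, 1, dimnames = list(terms[1], terms[1])))
  # chain pairs match hand computation
  ch <- chain_dag()
  mc <- similarity_matrix(ch, c("GO:0000002", "GO:0000003", "GO:0000004"))
  sv <- lapply(c("GO:0000002", "GO:0000003", "GO:0000004"), function(t) wang_svalues(ch, t))
  expect_equal(mc["GO:0000002", "GO:0000003"], wang_similarity(sv[[1]], sv[[2]]))
  expect_equal(mc["GO:0000002", "GO:0000004"], wang_similarity(sv[[1]], sv[[3]]))
  # adding an unrelated subtree leaves existing similarities unchanged
  extra <- suppressWarnings(go_dag(
    dplyr::bind_rows(
      dag$terms,
      tibble::tibble(
        id = c("GO:0100001", "GO:0100002"), name = c("x", "y"),
        namespace = "biological_process", obsolete = FALSE
      )
    ),
    dplyr::bind_rows(
      dag$edges,
      tibble::tibble(child = "GO:0100002", parent = "GO:0100001", relation = "is_a")
    )
  ))
  m3 <- similarity_matrix(extra, terms)
  expect_equal(m3, m)
  mixed <- make_toy_dag(c(biological_process = 4, molecular_function = 4), seed = 2)
  expect_error(similarity_matrix(mixed, mixed$terms$id[c(2, 6)]), "namespaces")
})

test_that("classical MDS reproduces low-rank geometry deterministically", {
  # two terms at dissimilarity 0.6 -> points at +/- 0.3 on the first axis
  s2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("GO:1", "GO:2"), c("GO:1", "GO:2")))
  e2 <- suppressWarnings(mds_embedding(s2))
  expect_equal(sort(abs(e2$coords$x)), c(0.3, 0.3), tolerance = 1e-9)
  expect_equal(e2$coords$y, c(0, 0))
  expect_equal(stats::dist(cbind(e2$coords$x, e2$coords$y))[1], 0.6, tolerance = 1e-9)

  # three equidistant terms embed as an equilateral triangle
  s3 <- matrix(0.5, 3, 3, dimnames = list(paste0("T", 1:3), paste0("T", 1:3)))
  diag(s3) <- 1
  e3 <- mds_embedding(s3)
  d3 <- as.numeric(stats::dist(cbind(e3$coords$x, e3$coords$y)))
  expect_equal(d3, rep(0.5, 3), tolerance = 1e-9)
  expect_lt(e3$stress, 1e-9)

  # rank-2 Euclidean input is reproduced to 1e-8
  withr::with_seed(3, {
    pts <- cbind(stats::runif(6), stats::runif(6))
  })
  d <- as.matrix(stats::dist(pts))
  d <- d / (max(d) * 2) # keep dissimilarities in [0,1]
  sim <- 1 - d
  dimnames(sim) <- list(paste0("T", 1:6), paste0("T", 1:6))
  emb <- mds_embedding(sim)
  dhat <- as.matrix(stats::dist(cbind(emb$coords$x, emb$coords$y)))
  expect_equal(unname(dhat), unname(d), tolerance = 1e-8)
  expect_lt(emb$stress, 1e-8)

  # determinism: identical input -> identical coordinates
  emb2 <- mds_embedding(sim)
  expect_identical(emb$coords, emb2$coords)
  # centroid at the origin
  expect_equal(mean(emb$coords$x), 0, tolerance = 1e-12)
  expect_equal(mean(emb$coords$y), 0, tolerance = 1e-12)

  # duplicated terms land on coincident points
  sdup <- matrix(c(1, 1, 0.4, 1, 1, 0.4, 0.4, 0.4, 1), 3,
    dimnames = list(paste0("T", 1:3), paste0("T", 1:3))
  )
  edup <- suppressWarnings(mds_embedding(sdup))
  gap <- sqrt((edup$coords$x[1] - edup$coords$x[2])^2 +
    (edup$coords$y[1] - edup$coords$y[2])^2)
  expect_lt(gap, 1e-7)
  expect_error(mds_embedding(s2[1, 1, drop = FALSE]), "at least two")
})

test_that("DOT export covers the ancestor closure with relation styling", {
  dia <- diamond_dag()
  dot <- export_dot(dia, "GO:0000004")
  expect_true(any(grepl("digraph", dot)))
  for (id in dia$terms$id) expect_true(any(grepl(id, dot, fixed = TRUE)))
  expect_true(any(grepl("style=dashed", dot))) # the part_of edge
  f <- tempfile(fileext = ".dot")
  export_dot(dia, "GO:0000004", file = f)
  expect_true(file.exists(f))
})
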