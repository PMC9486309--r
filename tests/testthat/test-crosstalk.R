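test_that("coefficients follow their set definitions", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(jaccard(c("A", "B"), c("C")), 0.0)
  expect_equal(overlap_coefficient(c("A", "B", "C"), c("A", "B")), 1.0)
  expect_equal(overlap_coefficient(c("A"), c("B")), 0.0)
  expect_equal(crosstalk_score(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(crosstalk_score(c("A"), c("B")), 0.0)
  expect_error(jaccard(character(0), character(0)), "empty")
  expect_error(overlap_coefficient(character(0), "A"), "nonempty")
})

test_that("coefficients are symmetric and JC <= OC on random sets", {
  withr::local_seed(7)
  pool <- sprintf("G%02d", 1:30)
  for (i in 1:50) {
    A <- sample(pool, sample(1:15, 1))
    B <- sample(pool, sample(1:15, 1))
    jc <- jaccard(A, B); oc <- overlap_coefficient(A, B)
    expect_true(jc >= 0 && jc <= oc && oc <= 1)
    expect_equal(jaccard(B, A), jc)
    expect_equal(overlap_coefficient(B, A), oc)
  }
})

test_that("the worked pathway pair scores as set arithmetic dictates", {
  paths <- read_gmt(amd_fixture("pathways"))
  hif <- paths$genes[[which(paths$pathway_id == "HIF_1_SIGNALING_PATHWAY")]]
  est <- paths$genes[[
    which(paths$pathway_id == "PLASMA_MEMBRANE_ESTROGEN_RECEPTOR_SIGNALING")]]
  expect_equal(sort(intersect(hif, est)), c("IGF1R", "NOS3"))
  expect_equal(jaccard(hif, est), 2 / 13)
  expect_equal(overlap_coefficient(hif, est), 2 / 5)
  expect_equal(crosstalk_score(hif, est), (2 / 13 + 2 / 5) / 2)
})

test_that("edge construction applies the shared-gene rule exactly", {
  recs <- tibble::tibble(
    pathway_id = c("P1", "P2", "P3"),
    observed = list(c("a", "b", "c", "d"), c("c", "d", "e"), c("e", "f"))
  )
  e <- build_crosstalk_edges(recs)
  expect_equal(nrow(e), 1L)
  expect_equal(e$pathway_a, "P1"); expect_equal(e$pathway_b, "P2")
  expect_equal(e$shared[[1]], c("c", "d"))

  twin <- tibble::tibble(pathway_id = c("A", "B"),
                         observed = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(build_crosstalk_edges(twin)$score, 1.0)

  disj <- tibble::tibble(pathway_id = c("A", "B"),
                         observed = list(c("x", "y"), c("u", "v")))
  expect_equal(nrow(build_crosstalk_edges(disj)), 0L)

  expect_error(build_crosstalk_edges(recs[1, ]), "at least two")
})

test_that("edge construction equals brute-force pair enumeration", {
  withr::local_seed(13)
  for (i in 1:20) {
    col <- random_collection(sample(3:20, 1), min_size = 2, max_size = 10)
    recs <- tibble::tibble(pathway_id = col$pathway_id,
                           observed = col$genes)
    got <- build_crosstalk_edges(recs, min_shared = 2)
    # oracle: every unordered pair, straight set arithmetic
    expected <- list()
    exp_keys <- character(0)
    ids <- col$pathway_id
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b) next
      sh <- intersect(col$genes[[a]], col$genes[[b]])
      if (length(sh) >= 2) {
        key <- paste(sort(c(ids[a], ids[b])), collapse = "|")
        expected[[key]] <- sort(sh)
        exp_keys <- c(exp_keys, key)
      }
    }
    got_keys <- paste(got$pathway_a, got$pathway_b, sep = "|")
    expect_setequal(got_keys, exp_keys)
    for (j in seq_len(nrow(got))) {
      expect_equal(got$shared[[j]], expected[[got_keys[j]]])
      A <- col$genes[[match(got$pathway_a[j], ids)]]
      B <- col$genes[[match(got$pathway_b[j], ids)]]
      expect_equal(got$score[j], (jaccard(A, B) + overlap_coefficient(A, B)) / 2)
    }
  }
})

test_that("top-fraction selection uses ceiling and keeps cutoff ties", {
  mk <- function(scores) {
    n <- length(scores)
    structure(tibble::tibble(
      pathway_a = sprintf("A%02d", 1:n), pathway_b = sprintf("B%02d", 1:n),
      shared = replicate(n, c("x", "y"), simplify = FALSE),
      shared_count = 2L, jc = scores, oc = scores, score = scores
    ), class = c("amdnet_crosstalk", class(tibble::tibble())))
  }
  e5 <- mk(c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(nrow(select_top_fraction(e5, 0.5)), 3L)
  expect_equal(nrow(select_top_fraction(e5, 1.0)), 5L)
  e4 <- mk(rep(0.5, 4))
  expect_equal(nrow(select_top_fraction(e4, 0.5)), 4L)
  # idempotence and monotonicity
  top <- select_top_fraction(e5, 0.4)
  expect_equal(select_top_fraction(top, 1.0), top)
  small <- select_top_fraction(e5, 0.2)
  big <- select_top_fraction(e5, 0.8)
  expect_true(all(paste(small$pathway_a, small$pathway_b) %in%
                    paste(big$pathway_a, big$pathway_b)))
  expect_error(select_top_fraction(e5[0, ], 0.5), "no edges")
  expect_error(select_top_fraction(e5, 0), "fraction")
})

test_that("module detection matches exhaustive modularity search on a toy", {
  # two triangles joined through a connector: 1-2-3 clique, 5-6-7 clique,
  # node 4 linking 3 and 5
  edges <- tibble::tibble(
    pathway_a = c("P1", "P1", "P2", "P3", "P4", "P5", "P5", "P6"),
    pathway_b = c("P2", "P3", "P3", "P4", "P5", "P6", "P7", "P7")
  )
  edges$shared <- replicate(nrow(edges), c("x", "y"), simplify = FALSE)
  edges$shared_count <- 2L
  edges$jc <- 0.5; edges$oc <- 0.5; edges$score <- 0.5
  class(edges) <- c("amdnet_crosstalk", class(edges))
  net <- detect_modules(edges)
  expect_equal(length(unique(net$nodes$module)), 2L)
  expect_true(net$nodes$bridge[net$nodes$pathway_id == "P4"])
  expect_false(net$nodes$bridge[net$nodes$pathway_id == "P1"])

  # oracle: enumerate every partition of the 7 nodes (restricted growth
  # strings) and maximize weighted modularity
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  n <- igraph::vcount(g)
  best <- -Inf
  part <- integer(n); max_used <- integer(n)
  recurse <- function(i, maxu, part) {
    if (i > n) {
      q <- igraph::modularity(g, part, weights = igraph::E(g)$score)
      best <<- max(best, q)
      return(invisible())
    }
    for (lab in 1:(maxu + 1)) {
      part[i] <- lab
      recurse(i + 1, max(maxu, lab), part)
    }
  }
  igraph::E(g)$score <- 0.5
  recurse(1, 0, part)
  expect_equal(net$modularity, best, tolerance = 1e-12)
})

test_that("degenerate networks partition sensibly", {
  tri <- tibble::tibble(
    pathway_a = c("A", "A", "B"), pathway_b = c("B", "C", "C"),
    shared = replicate(3, c("x", "y"), simplify = FALSE),
    shared_count = 2L, jc = 1, oc = 1, score = 1
  )
  class(tri) <- c("amdnet_crosstalk", class(tri))
  net <- detect_modules(tri)
  expect_equal(length(unique(net$nodes$module)), 1L)
  expect_false(any(net$nodes$bridge))

  two <- tibble::tibble(
    pathway_a = c("A", "C"), pathway_b = c("B", "D"),
    shared = replicate(2, c("x", "y"), simplify = FALSE),
    shared_count = 2L, jc = 1, oc = 1, score = 1
  )
  class(two) <- c("amdnet_crosstalk", class(two))
  expect_equal(length(unique(detect_modules(two)$nodes$module)), 2L)
  expect_error(detect_modules(two[0, ]), "edgeless")
})

test_that("graph exports round-trip", {
  one <- tibble::tibble(
    pathway_a = "A", pathway_b = "B",
    shared = list(c("x", "y")), shared_count = 2L,
    jc = 0.25, oc = 0.5, score = 0.375
  )
  class(one) <- c("amdnet_crosstalk", class(one))
  sif <- withr::local_tempfile()
  expect_warning(export_graph(one, "SIF", sif), "module")
  expect_equal(readLines(sif), "A crosstalk B")

  withr::local_seed(3)
  pool <- sprintf("G%02d", 1:20)
  recs <- tibble::tibble(
    pathway_id = sprintf("P%02d", 1:8),
    observed = lapply(1:8, function(i) {
      unique(c(pool[i:(i + 4)], sample(pool, 3)))
    })
  )
  e <- build_crosstalk_edges(recs, min_shared = 2)
  expect_gte(nrow(e), 10L)
  net <- detect_modules(e)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, "GraphML", gml)
  back <- read_crosstalk_graphml(gml)
  expect_equal(back$score, e$score, tolerance = 1e-5)
  expect_equal(back$jc, e$jc, tolerance = 1e-5)
  expect_equal(back$oc, e$oc, tolerance = 1e-5)
  expect_equal(back$shared_count, e$shared_count)
  nodes <- attr(back, "nodes")
  expect_equal(sort(nodes$pathway_id), sort(net$nodes$pathway_id))
  expect_s3_class(autoplot(net), "ggplot")
  expect_equal(glance(net)$n_edges, nrow(e))
})
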