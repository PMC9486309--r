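path_graph <- function(nodes) {
  as_interactome(data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
                 quiet = TRUE)
}

test_that("interactome reading canonicalizes edges with counts", {
  f <- withr::local_tempfile(lines = c("a\tb", "b\ta", "c\tc"))
  expect_message(g <- read_interactome(f), "1 self-loop.*1 duplicate")
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)

  f2 <- withr::local_tempfile(
    lines = paste(sprintf("n%d", 1:5), sprintf("n%d", 2:6), sep = "\t"))
  g2 <- read_interactome(f2, quiet = TRUE)
  expect_equal(igraph::vcount(g2), 6L)
  expect_equal(igraph::ecount(g2), 5L)

  f3 <- withr::local_tempfile(lines = "a\tb\tc")
  expect_error(read_interactome(f3), "line\\(s\\) 1")
  f4 <- withr::local_tempfile(lines = "# nothing")
  expect_error(read_interactome(f4), "no edges")
})

test_that("seed-pair betweenness on hand-enumerable graphs", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  b <- seed_pair_betweenness(g, c("A", "E"))
  expect_equal(setNames(b$betweenness, b$gene),
               c(A = 0, B = 1, C = 1, D = 1, E = 0))

  cyc <- as_interactome(data.frame(from = c("A", "B", "C", "D"),
                                   to = c("B", "C", "D", "A")), quiet = TRUE)
  b2 <- seed_pair_betweenness(cyc, c("A", "C"))
  expect_equal(setNames(b2$betweenness, b2$gene),
               c(A = 0, B = 1, C = 0, D = 1))

  star <- as_interactome(data.frame(from = rep("H", 4),
                                    to = paste0("L", 1:4)), quiet = TRUE)
  b3 <- seed_pair_betweenness(star, paste0("L", 1:4))
  expect_equal(b3$betweenness[b3$gene == "H"], 6)
  expect_true(all(b3$betweenness[b3$gene != "H"] == 0))

  expect_warning(b4 <- seed_pair_betweenness(g, c("A", "E", "ZZ")), "absent")
  expect_equal(attr(b4, "dropped_seeds"), "ZZ")
  expect_error(suppressWarnings(seed_pair_betweenness(g, c("A", "ZZ"))),
               "at least 2")
})

test_that("betweenness equals brute-force geodesic enumeration", {
  withr::local_seed(21)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    g <- random_named_graph(n, p = runif(1, 0.2, 0.6))
    seeds <- sample(igraph::V(g)$name, sample(2:min(4, n), 1))
    got <- seed_pair_betweenness(g, seeds)
    want <- oracle_seed_betweenness(g, seeds)
    expect_equal(setNames(got$betweenness, got$gene), want[got$gene])
  }
})

test_that("per-pair geodesic counts satisfy the conservation identity", {
  # sum over interior v of sigma_st(v) = sigma_st * (d(s,t) - 1)
  withr::local_seed(33)
  for (i in 1:20) {
    g <- random_named_graph(sample(5:10, 1), p = 0.4)
    nm <- igraph::V(g)$name
    st <- sample(nm, 2)
    d <- igraph::distances(g, st[1], st[2])[1, 1]
    if (!is.finite(d) || d < 1) next
    paths <- suppressWarnings(
      igraph::all_shortest_paths(g, st[1], st[2])$res)
    sigma_st <- length(paths)
    b <- seed_pair_betweenness(g, st)
    expect_equal(sum(b$betweenness), sigma_st * (d - 1))
  }
})

test_that("betweenness is equivariant under node relabeling", {
  cyc <- as_interactome(data.frame(from = c("A", "B", "C", "D"),
                                   to = c("B", "C", "D", "A")), quiet = TRUE)
  rot <- as_interactome(data.frame(from = c("B", "C", "D", "A"),
                                   to = c("C", "D", "A", "B")), quiet = TRUE)
  b1 <- seed_pair_betweenness(cyc, c("A", "C"))
  b2 <- seed_pair_betweenness(rot, c("B", "D"))
  # the automorphism A->B, B->C, C->D, D->A maps one problem onto the other
  m1 <- setNames(b1$betweenness, b1$gene)
  m2 <- setNames(b2$betweenness, b2$gene)
  mapped <- setNames(m1[c("A", "B", "C", "D")], c("B", "C", "D", "A"))
  expect_equal(m2[names(mapped)], mapped)
})

test_that("permutation null is reproducible and respects graph structure", {
  g <- random_named_graph(12, 0.4)
  n1 <- permutation_null(g, 4, n_perm = 10, rng_seed = 99)
  n2 <- permutation_null(g, 4, n_perm = 10, rng_seed = 99)
  expect_identical(n1, n2)
  n3 <- permutation_null(g, 4, n_perm = 10, rng_seed = 100)
  expect_false(identical(n1, n3))

  k5 <- as_interactome(as.data.frame(t(utils::combn(paste0("K", 1:5), 2))),
                       quiet = TRUE)
  expect_true(all(permutation_null(k5, 3, n_perm = 20, rng_seed = 1) == 0))

  p6 <- path_graph(paste0("P", 1:6))
  null <- permutation_null(p6, 2, n_perm = 200, rng_seed = 7)
  mid <- rowMeans(null)[c("P3", "P4")]
  ends <- rowMeans(null)[c("P1", "P6")]
  expect_true(min(mid) > max(ends))

  expect_error(permutation_null(p6, 10, 10, 1), "exceeds")
  expect_error(permutation_null(p6, 2, 0, 1), "n_perm")
})

test_that("permutation FDR applies the strict-count formula", {
  actual <- tibble::tibble(gene = c("A", "B", "C"),
                           betweenness = c(10, 50, 0))
  null <- matrix(0, nrow = 3, ncol = 100,
                 dimnames = list(c("A", "B", "C"), NULL))
  null["A", 1:3] <- 99      # 3 of 100 strictly exceed 10
  null["B", ] <- 7          # none exceed 50
  r <- permutation_fdr(actual, null)
  expect_equal(r$fdr, c(0.03, 0, 0))   # C: all null 0, strict => 0
  expect_equal(r$positive_perm_count, c(3, 100, 0))
  expect_error(permutation_fdr(actual[1:2, ], null), "same genes")
})

test_that("candidate selection applies all three strict filters", {
  recs <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    betweenness_actual = c(5123, 900, 2000, 2000),
    fdr = c(0.0, 0.0, 0.10, 0.0),
    positive_perm_count = c(10, 5, 5, 80)
  )
  class(recs) <- c("amdnet_prioritization", class(recs))
  sel <- select_candidates(recs)
  expect_equal(sel$gene, "g1")

  # Monotonicity: relaxing any threshold never shrinks the set
  base <- select_candidates(recs, b_min = 1500, fdr_max = 0.05, hub_max = 50)
  wider <- select_candidates(recs, b_min = 800, fdr_max = 0.2, hub_max = 90)
  expect_true(all(base$gene %in% wider$gene))

  expect_equal(nrow(select_candidates(recs, b_min = 1e7)), 0L)
})

test_that("the packaged candidate fixture passes the published filter", {
  cand <- read_candidate_table(amd_fixture("candidates"))
  recs <- tibble::tibble(
    gene = cand$gene, betweenness_actual = cand$betweenness,
    fdr = 0, positive_perm_count = 0L
  )
  class(recs) <- c("amdnet_prioritization", class(recs))
  sel <- select_candidates(recs)
  expect_equal(nrow(sel), 42L)
  expect_equal(sel$gene[1], "ABCG5")
})

test_that("seed annotation counts the candidate/seed overlap", {
  cand <- tibble::tibble(gene = c("A", "B", "C"))
  a <- annotate_candidates(cand, c("B", "C", "D"))
  expect_equal(attr(a, "overlap_count"), 2L)
  expect_equal(a$is_seed, c(FALSE, TRUE, TRUE))
  expect_equal(attr(annotate_candidates(cand, "Z"), "overlap_count"), 0L)
  expect_equal(attr(annotate_candidates(cand, c("A", "B", "C", "D")),
                    "overlap_count"), 3L)
})

test_that("prioritize composes the stages and exports a subnetwork", {
  withr::local_seed(2)
  g <- random_named_graph(30, 0.15)
  g <- igraph::simplify(g)
  seeds <- sample(igraph::V(g)$name, 5)
  pri <- prioritize(g, seeds, n_perm = 20, rng_seed = 5, b_min = 0)
  expect_s3_class(pri, "amdnet_prioritization")
  expect_true(all(pri$fdr %in% ((0:20) / 20)))
  expect_true(all(c("selected", "is_seed") %in% names(pri)))
  gl <- glance(pri)
  expect_equal(gl$n_genes, igraph::vcount(g))

  out <- withr::local_tempfile(fileext = ".graphml")
  export_candidate_subnetwork(g, pri, seeds, out)
  sub <- igraph::read_graph(out, format = "graphml")
  expect_true(all(seeds %in% igraph::V(sub)$name))

  expect_warning(p0 <- prioritize(g, seeds, n_perm = 0), "betweenness only")
  expect_true(all(is.na(p0$fdr)))
})
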