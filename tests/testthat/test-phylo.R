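test_that("similarity_matrix equals independent pairwise calls and is symmetric", {
  ms <- list(fix_monomer("rad52-long", seed = 7L),
             fix_monomer("rad52-short", seed = 9L),
             fix_monomer("sak3-like", seed = 5L))
  s <- structure_set(ms)
  sim <- similarity_matrix(s)
  expect_equal(diag(sim$values), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sim$values, t(sim$values))
  for (i in 1:2) for (j in (i + 1):3) {
    a <- align_structures(ms[[i]], ms[[j]])
    expect_equal(sim$values[i, j], (a$tm_norm_a + a$tm_norm_b) / 2)
  }
})

test_that("identical structures have off-diagonal similarity 1", {
  m <- fix_monomer("rad52-long", seed = 7L)
  m2 <- m; m2$id <- "copy"
  sim <- similarity_matrix(structure_set(list(m, m2)))
  expect_equal(sim$values[1, 2], 1.0, tolerance = 1e-6)
})

test_that("UPGMA reproduces the hand-worked 3-leaf case", {
  V <- matrix(c(1, 0.9, 0.5, 0.9, 1, 0.5, 0.5, 0.5, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- average_linkage(as_similarity_matrix(V))
  expect_equal(t$height, c(0.1, 0.5))
  expect_equal(t$merge[1, ], c(-1L, -2L))   # (A, B) first
  expect_equal(to_newick(t), "((A:0.05,B:0.05):0.2,C:0.25);")
})

test_that("identical structures merge at zero height", {
  V <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t <- average_linkage(as_similarity_matrix(V))
  expect_equal(t$height[1], 0)
})

test_that("UPGMA matches the textbook oracle on random matrices", {
  set.seed(6)
  for (trial in 1:30) {
    n <- sample(3:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 1)
    D <- D + t(D)
    ids <- paste0("s", seq_len(n))
    dimnames(D) <- list(ids, ids)
    t <- average_linkage(as_similarity_matrix(1 - D))
    orc <- upgma_oracle(D)
    expect_equal(sort(t$height), sort(orc$heights), tolerance = 1e-9)
    # partitions agree at every k
    hc <- as.hclust(t)
    for (k in seq_len(n)) {
      expect_identical(canonical_partition(cutree(hc, k)),
                       canonical_partition(as.integer(factor(
                         strsplit(orc$partitions[[as.character(k)]], ",")[[1]]))))
    }
  }
})

test_that("UPGMA heights are non-decreasing and input must be symmetric", {
  set.seed(7)
  D <- matrix(runif(49), 7, 7); D <- (D + t(D)) / 2; diag(D) <- 0
  ids <- letters[1:7]; dimnames(D) <- list(ids, ids)
  t <- average_linkage(as_similarity_matrix(1 - D))
  expect_true(all(diff(t$height) >= -1e-12))
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 0.1
  expect_error(as_similarity_matrix(1 - Dbad), "symmetric")
})

test_that("newick output round-trips through an independent parser", {
  skip_if_not_installed("ape")
  V <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- average_linkage(as_similarity_matrix(V))
  expect_equal(to_newick(t2), "(A:0.1,B:0.1);")
  expect_equal(to_newick("solo"), "solo;")
  set.seed(8)
  D <- matrix(runif(36, 0.1, 1), 6, 6); D <- (D + t(D)) / 2; diag(D) <- 0
  ids <- paste0("L", 1:6); dimnames(D) <- list(ids, ids)
  t6 <- average_linkage(as_similarity_matrix(1 - D))
  ph <- ape::read.tree(text = to_newick(t6))
  expect_setequal(ph$tip.label, ids)
  # ultrametric: root-to-tip depth = max height / 2 for every tip
  depths <- ape::node.depth.edgelength(ph)[seq_len(6)]
  expect_equal(depths, rep(max(t6$height) / 2, 6), tolerance = 1e-6)
})

test_that("select_representatives: k = n, medoid rule, errors", {
  set.seed(9)
  n <- 6
  D <- matrix(runif(n * n, 0.1, 0.9), n, n); D <- (D + t(D)) / 2; diag(D) <- 0
  ids <- paste0("m", 1:n); dimnames(D) <- list(ids, ids)
  sim <- as_similarity_matrix(1 - D)
  t <- average_linkage(sim)
  all_reps <- select_representatives(t, sim, n)
  expect_setequal(all_reps$representatives, ids)
  # medoid equals brute-force argmax of mean similarity within each cluster
  rs <- select_representatives(t, sim, 2)
  for (g in unique(rs$clusters)) {
    members <- names(rs$clusters)[rs$clusters == g]
    if (length(members) == 1) { expect_true(members %in% rs$representatives); next }
    ms <- vapply(members, function(i) mean(sim$values[i, setdiff(members, i)]), 0)
    expect_true(members[which.max(ms)] %in% rs$representatives)
  }
  expect_error(select_representatives(t, sim, 0), "out of range")
  expect_error(select_representatives(t, sim, n + 1), "out of range")
  # override forces the representative
  ov <- select_representatives(t, sim, 2, override = ids[1])
  expect_true(ids[1] %in% ov$representatives)
})

test_that("two generator families yield one representative each", {
  f1 <- fix_family("rad52-long", n = 5L, seed = 81L)
  f2 <- fix_family("rect-like", n = 5L, seed = 82L)
  s <- structure_set(c(f1$members, f2$members),
                     labels = c(f1$labels, f2$labels))
  sim <- similarity_matrix(s)
  rs <- select_representatives(average_linkage(sim), sim, 2)
  fams <- s$labels[rs$representatives]
  expect_setequal(unname(fams), c("rad52-long", "rect-like"))
})

test_that("sequence similarity: pinned examples and oracle agreement", {
  s1 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPI"
  expect_equal(sequence_pair_score(s1, s1), 1.0)
  expect_equal(sequence_pair_score(s1, substr(s1, 1, 18)), 0.5)
  expect_error(sequence_similarity_matrix(c(a = "MK", b = "")), "empty")
  # mutated full-length copies: unambiguous optimum, must match the
  # hand-rolled Smith-Waterman oracle exactly
  set.seed(10)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (trial in 1:5) {
    a <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    bv <- strsplit(a, "")[[1]]
    mut <- runif(30) < 0.15
    bv[mut] <- sample(aa, sum(mut), replace = TRUE)
    b <- paste(bv, collapse = "")
    orc <- sw_oracle(a, b)
    expect_equal(sequence_pair_score(a, b),
                 (orc$nmatch / orc$cols) * min(1, orc$cols / 30))
  }
  sm <- sequence_similarity_matrix(c(x = s1, y = substr(s1, 1, 18)))
  expect_equal(sm$values["x", "y"], 0.5)
  expect_equal(diag(sm$values), c(1, 1), ignore_attr = TRUE)
})
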