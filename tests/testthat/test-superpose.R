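test_that("kabsch recovers exact rigid motions and the identity", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  tr <- kabsch(A, B)
  expect_lt(tr$rmsd, 1e-6)
  expect_lt(max(abs(apply_transform(A, tr) - B)), 1e-6)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-8)

  tr0 <- kabsch(A, A)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-8)
  expect_lt(tr0$rmsd, 1e-9)
})

test_that("kabsch RMSD matches the quaternion oracle on noisy cases", {
  set.seed(2)
  for (rep in 1:25) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    B <- A %*% random_rotation() +
      matrix(rnorm(3, sd = 3), 10, 3, byrow = TRUE) + matrix(rnorm(30, sd = 0.1), 10, 3)
    expect_equal(kabsch(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-6)
  }
})

test_that("kabsch input validation", {
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 5, 3)), "length")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("tm_d0 closed form and tm_score formula anchors", {
  expect_equal(tm_d0(30), max(0.5, 1.24 * 15^(1 / 3) - 1.8))
  expect_equal(tm_d0(10), 0.5)  # floor engages below L = 15
  m <- fix_monomer("sak3-like", seed = 5L)
  n <- n_residues(m)
  idmap <- cbind(seq_len(n), seq_len(n))
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                     class = "RigidTransform")
  expect_equal(tm_score(idmap, m, m, ident, n), 1.0)
  # single pair at distance exactly d0, l_norm = 100 -> 0.5 / 100
  d0 <- tm_d0(100)
  a <- structure_model("a", "ALA", matrix(c(0, 0, 0), 1, 3), 90)
  b <- structure_model("b", "ALA", matrix(c(d0, 0, 0), 1, 3), 90)
  expect_equal(tm_score(cbind(1L, 1L), a, b, ident, 100), 0.005)
  # empty mapping scores 0, not an error
  expect_equal(tm_score(idmap[0, , drop = FALSE], m, m, ident, n), 0)
})

test_that("TM is bounded and monotone non-increasing in mapped distance", {
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                     class = "RigidTransform")
  a <- structure_model("a", rep("ALA", 5), make_strand(5), rep(90, 5))
  shift <- seq(0, 10, by = 0.5)
  tms <- vapply(shift, function(s) {
    b <- structure_model("b", rep("ALA", 5), make_strand(5) +
                           matrix(c(0, s, 0), 5, 3, byrow = TRUE), rep(90, 5))
    tm_score(cbind(1:5, 1:5), a, b, ident, 5)
  }, 0)
  expect_true(all(tms >= 0 & tms <= 1))
  expect_true(all(diff(tms) <= 1e-12))
})

test_that("self-alignment is exact for every preset monomer", {
  for (preset in c("rad52-long", "rad52-short", "redbeta-like", "rect-like",
                   "sak3-like")) {
    m <- fix_monomer(preset, seed = 19L)
    a <- align_structures(m, m)
    expect_equal(a$aligned_length, n_residues(m))
    expect_equal(a$tm_norm_a, 1.0, tolerance = 1e-6)
    expect_equal(a$tm_norm_b, 1.0, tolerance = 1e-6)
    expect_lt(a$rmsd_aligned, 1e-6)
    expect_equal(a$seq_identity_aligned, 1.0)
  }
})

test_that("alignment is invariant under rigid motion of either structure", {
  m <- fix_monomer("redbeta-like", seed = 23L)
  q <- fix_monomer("rad52-long", seed = 24L)
  a0 <- align_structures(m, q)
  set.seed(3)
  q2 <- transform_structure(q, random_rotation(), rnorm(3, sd = 20))
  a1 <- align_structures(m, q2)
  expect_equal(a1$tm_norm_a, a0$tm_norm_a, tolerance = 1e-6)
  expect_equal(a1$tm_norm_b, a0$tm_norm_b, tolerance = 1e-6)
  expect_equal(a1$aligned_length, a0$aligned_length)
})

test_that("long vs short beta-sheet monomers: same fold, partial alignment", {
  long <- make_ssap_monomer(family_params(strand_len = 12L, seed = 61L))
  short <- make_ssap_monomer(family_params(strand_len = 7L, seed = 62L))
  a <- align_structures(long, short)
  tm <- (a$tm_norm_a + a$tm_norm_b) / 2
  expect_gt(tm, 0.5)
  expect_lt(tm, 1.0)
  expect_lt(a$aligned_length, min(n_residues(long), n_residues(short)))
})

test_that("unrelated random-coil decoys align poorly", {
  tms <- vapply(1:5, function(i) {
    d1 <- make_decoy(100, seed = 100 + i)
    d2 <- make_decoy(100, seed = 200 + i)
    a <- align_structures(d1, d2)
    max(a$tm_norm_a, a$tm_norm_b)
  }, 0)
  expect_true(all(tms < 0.35))
})

test_that("mapping is strictly increasing in both coordinates", {
  a <- align_structures(fix_monomer("rad52-long", seed = 7L),
                        fix_monomer("rect-like", seed = 8L))
  expect_true(all(diff(a$mapping[, 1]) > 0))
  expect_true(all(diff(a$mapping[, 2]) > 0))
  expect_error(align_structures(
    structure_model("t", rep("ALA", 4), make_strand(4), rep(90, 4)),
    fix_monomer("rad52-long", seed = 7L)), "5 residues")
})

test_that("seq_identity_on_alignment counts identical residue pairs", {
  m <- fix_monomer("rad52-long", seed = 7L)
  n <- n_residues(m)
  full <- cbind(seq_len(n), seq_len(n))
  expect_equal(seq_identity_on_alignment(full, m, m), 1.0)
  # 10 pairs, exactly 1 identical
  a <- structure_model("a", c("ALA", rep("GLY", 9)), make_strand(10), rep(90, 10))
  b <- structure_model("b", c("ALA", rep("SER", 9)), make_strand(10), rep(90, 10))
  expect_equal(seq_identity_on_alignment(cbind(1:10, 1:10), a, b), 0.1)
  # random sequences match brute-force count
  set.seed(9)
  ra <- sample(names(annealr:::AA3TO1), 40, replace = TRUE)
  rb <- sample(names(annealr:::AA3TO1), 40, replace = TRUE)
  ma <- structure_model("ra", ra, make_strand(40), rep(90, 40))
  mb <- structure_model("rb", rb, make_strand(40), rep(90, 40))
  expect_equal(seq_identity_on_alignment(cbind(1:40, 1:40), ma, mb),
               sum(ra == rb) / 40)
})

test_that("alignment_report returns the documented columns", {
  m <- fix_monomer("rad52-long", seed = 7L)
  q <- fix_monomer("rad52-short", seed = 9L)
  df <- alignment_report(list(list(a = m, b = q, aln = align_structures(m, q))))
  expect_named(df, c("id_a", "id_b", "len_a", "len_b", "aligned_length",
                     "rmsd", "tm_norm_a", "tm_norm_b", "seq_identity"))
  expect_equal(df$len_a, n_residues(m))
})
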