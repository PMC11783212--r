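test_that("ideal helix and strand geometry is labeled correctly", {
  h <- structure_model("h", rep("ALA", 20), make_helix(20), rep(90, 20))
  ss <- strsplit(assign_ss(h), "")[[1]]
  expect_gte(mean(ss == "H"), 0.9)
  s <- structure_model("s", rep("ALA", 10), make_strand(10), rep(90, 10))
  ss <- strsplit(assign_ss(s), "")[[1]]
  expect_gte(mean(ss == "E"), 0.8)
})

test_that("random coils are mostly coil; short chains are all C", {
  frac <- vapply(1:20, function(i) {
    ss <- strsplit(assign_ss(make_decoy(80, seed = 300 + i)), "")[[1]]
    mean(ss != "C")
  }, 0)
  expect_lt(mean(frac), 0.2)
  expect_identical(assign_ss(structure_model("t", rep("ALA", 4),
                                             matrix(rnorm(12), 4, 3),
                                             rep(90, 4))), "CCCC")
})

test_that("assign_ss is rigid-motion invariant", {
  m <- fix_monomer("rect-like", seed = 3L)
  ss0 <- assign_ss(m)
  set.seed(4)
  m2 <- transform_structure(m, random_rotation(), rnorm(3, sd = 15))
  expect_identical(assign_ss(m2), ss0)
})

test_that("motif_annotation validates spans", {
  expect_error(motif_annotation(list(c(1, 10)), list(c(5, 12))), "overlap")
  ann <- motif_annotation(list(c(1, 10), c(20, 25)), list(c(30, 40)))
  expect_s3_class(ann, "MotifAnnotation")
})

test_that("motif_composition: self-transfer counts designed labels", {
  m <- fix_monomer("rad52-long", seed = 12L)
  ann <- attr(m, "motifs")
  aln <- align_structures(m, m)
  comp <- motif_composition(m, m, ann, aln)
  # the sheet motif contains the traversing helix (15 residues designed)
  expect_equal(comp$sheet_h, 15L)
  # three strands of 12 -> 36 designed strand residues
  expect_gte(comp$sheet_s, 33L)
  expect_lte(comp$sheet_s, 36L)
  expect_false(comp$empty_transfer)
})

test_that("motif counts shrink monotonically as the mapping shrinks", {
  m <- fix_monomer("rad52-long", seed = 12L)
  ann <- attr(m, "motifs")
  aln <- align_structures(m, m)
  full <- motif_composition(m, m, ann, aln)
  aln_half <- aln
  keep <- seq_len(nrow(aln$mapping)) %% 2 == 1
  aln_half$mapping <- aln$mapping[keep, , drop = FALSE]
  half <- motif_composition(m, m, ann, aln_half)
  for (f in c("sheet_h", "sheet_s", "hairpin_h", "hairpin_s"))
    expect_lte(half[[f]], full[[f]])
  # empty mapping -> zero counts, flagged
  aln_half$mapping <- aln$mapping[0, , drop = FALSE]
  none <- motif_composition(m, m, ann, aln_half)
  expect_equal(none$sheet_s + none$sheet_h + none$hairpin_s + none$hairpin_h, 0)
  expect_true(none$empty_transfer)
})

test_that("aggregate_composition medians and population SD", {
  one <- list(fake_comp(10, 20, 5, 8))
  agg <- aggregate_composition(one)
  expect_equal(agg$median, c(10, 20, 5, 8))
  expect_equal(agg$std, rep(0, 4))
  three <- list(fake_comp(10, 10, 10, 10), fake_comp(20, 20, 20, 20),
                fake_comp(30, 30, 30, 30))
  agg3 <- aggregate_composition(three)
  expect_equal(agg3$median, rep(20, 4))
  expect_equal(agg3$std, rep(sqrt(mean((c(10, 20, 30) - 20)^2)), 4))
  # brute-force recomputation on 100 random members
  set.seed(5)
  vals <- replicate(100, fake_comp(sample(0:30, 1), sample(0:40, 1),
                                   sample(0:30, 1), sample(0:20, 1)),
                    simplify = FALSE)
  agg100 <- aggregate_composition(vals)
  v <- vapply(vals, function(x) x$sheet_s, 0)
  expect_equal(agg100$median[agg100$field == "sheet_s"], median(v))
  expect_equal(agg100$std[agg100$field == "sheet_s"], sqrt(mean((v - mean(v))^2)))
  expect_error(aggregate_composition(list()), "empty")
})

test_that("family parameter recovery separates long from short strands", {
  # two families differing in strand length are separable by sheet_s medians
  med <- vapply(c(12L, 7L), function(sl) {
    fam <- make_family(8, family_params(strand_len = sl, seed = 70L + sl),
                       divergence_sigma = 0.4, family = paste0("f", sl))
    rep_id <- names(fam$members)[1]
    rep_m <- fam$members[[rep_id]]
    comps <- lapply(fam$members, function(mm) {
      motif_composition(mm, rep_m, attr(fam, "motifs")[[rep_id]],
                        align_structures(rep_m, mm))
    })
    agg <- aggregate_composition(comps)
    agg$median[agg$field == "sheet_s"]
  }, 0)
  expect_gt(med[1], med[2] + 6)  # 36 vs 21 designed
})

test_that("motif span TSV round-trips", {
  ann <- list(repA = motif_annotation(list(c(1, 12), c(17, 28)), list(c(40, 52))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_spans(ann, f)
  back <- read_motif_spans(f)
  expect_equal(back$repA$sheet_span, ann$repA$sheet_span)
  expect_equal(back$repA$hairpin_span, ann$repA$hairpin_span)
})
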