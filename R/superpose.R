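#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `coords_a`
#' transformed onto `coords_b`. Reflections are excluded by determinant
#' correction. Row-vector convention: `transformed = coords %*% rotation +
#' translation`.
#'
#' @param coords_a,coords_b Numeric matrices (n x 3), equal n >= 3.
#' @return A `RigidTransform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets differ in length")
  if (nrow(coords_a) < 3) stop("need at least 3 points")
  res <- cpp_kabsch(coords_a, coords_b)
  structure(list(rotation = res$rotation,
                 translation = as.numeric(res$translation),
                 rmsd = res$rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param xyz Numeric matrix (n x 3).
#' @param transform A `RigidTransform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% transform$rotation, 2, -transform$translation, "-")
}

#' TM-score distance scale d0
#'
#' `d0(L) = max(0.5, 1.24 * (L - 15)^(1/3) - 1.8)`; the cube root is taken with
#' sign for L < 15.
#'
#' @param l_norm Normalizing length (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm) cpp_d0(as.double(l_norm))

#' TM-score of a residue mapping under a transform
#'
#' `TM = (1 / l_norm) * sum over mapped pairs of 1 / (1 + (d_i / d0)^2)` with
#' `d_i` the post-transform Calpha distance and `d0 = tm_d0(l_norm)`.
#'
#' @param mapping Integer matrix (k x 2) of 1-based residue index pairs
#'   (column 1 into `a`, column 2 into `b`), strictly increasing in both.
#' @param a,b `StructureModel`s.
#' @param transform `RigidTransform` applied to `a`.
#' @param l_norm Normalizing length.
#' @return TM-score in `[0, 1]`. An empty mapping scores 0.
#' @export
tm_score <- function(mapping, a, b, transform, l_norm) {
  if (l_norm < 1) stop("l_norm must be >= 1")
  if (is.null(mapping) || nrow(mapping) == 0) return(0)
  at <- apply_transform(a$ca[mapping[, 1], , drop = FALSE], transform)
  bt <- b$ca[mapping[, 2], , drop = FALSE]
  d2 <- rowSums((at - bt)^2)
  d0 <- tm_d0(l_norm)
  sum(1 / (1 + d2 / d0^2)) / l_norm
}

#' Sequence identity over an alignment mapping
#' @param mapping Integer matrix (k x 2) of 1-based residue pairs.
#' @param a,b `StructureModel`s.
#' @return Fraction of mapped pairs with identical residue type; 0 for an
#'   empty mapping.
#' @export
seq_identity_on_alignment <- function(mapping, a, b) {
  if (is.null(mapping) || nrow(mapping) == 0) return(0)
  mean(a$resname[mapping[, 1]] == b$resname[mapping[, 2]])
}

# Gapless threading seeds: pairs (i, i + o) for offsets o on a grid.
threading_seeds <- function(na, nb, step = 5L, min_overlap = 10L, cap = 40L) {
  offs <- seq(-(nb - min_overlap), na - min_overlap, by = step)
  offs <- offs[order(abs(offs))]  # prefer small offsets when capping
  if (length(offs) > cap) offs <- offs[seq_len(cap)]
  lapply(offs, function(o) {
    i <- max(1L, 1L + o):min(na, nb + o)
    cbind(i, i - o)
  })
}

# Secondary-structure-string seed: DP on a label-match score matrix.
sse_seed <- function(ssa, ssb) {
  la <- strsplit(ssa, "")[[1]]
  lb <- strsplit(ssb, "")[[1]]
  S <- outer(la, lb, function(x, y) ifelse(x == y & x != "C", 1, ifelse(x == y, 0.2, 0)))
  mp <- cpp_dp(S, 0.5)
  if (nrow(mp) >= 3) mp else NULL
}

#' Heuristic pairwise structural alignment with TM-score
#'
#' A TM-align-style heuristic: seed mappings from gapless threading at multiple
#' offsets and from matching secondary-structure strings are each superposed
#' once; the best seeds are refined by iterating superposition, a
#' `1/(1+(d/d0)^2)` score matrix, and dynamic programming (gap-open penalty,
#' no extension penalty, diagonal-preferring traceback) until the mapping
#' repeats or `max_iter` iterations. The result maximizing the TM-score is
#' returned, with TM reported under both normalizations. Deterministic for
#' fixed inputs.
#'
#' @param a,b `StructureModel`s with at least 5 residues each.
#' @param gap_open Gap-open penalty (positive; default 0.6).
#' @param max_iter Maximum refinement iterations per seed.
#' @param max_seeds Cap on threading seeds.
#' @param top_seeds Number of top-ranked seeds refined fully.
#' @return An `AlignmentResult`: list with `mapping` (k x 2 integer matrix),
#'   `transform` (`RigidTransform` taking `a` onto `b`), `rmsd_aligned`,
#'   `tm_norm_a`, `tm_norm_b` (normalized by length of `a` resp. `b`),
#'   `aligned_length`, `seq_identity_aligned`.
#' @export
align_structures <- function(a, b, gap_open = 0.6, max_iter = 30L,
                             max_seeds = 40L, top_seeds = 8L) {
  na <- n_residues(a)
  nb <- n_residues(b)
  if (na < 5 || nb < 5) stop("structures must have at least 5 residues")
  seeds <- threading_seeds(na, nb, cap = max_seeds)
  sse <- sse_seed(assign_ss(a), assign_ss(b))
  if (!is.null(sse)) seeds <- c(seeds, list(sse))
  res <- cpp_align(a$ca, b$ca, seeds, gap_open, as.integer(max_iter),
                   as.integer(top_seeds))
  mapping <- res$mapping
  transform <- structure(list(rotation = res$rotation,
                              translation = as.numeric(res$translation)),
                         class = "RigidTransform")
  at <- apply_transform(a$ca[mapping[, 1], , drop = FALSE], transform)
  bt <- b$ca[mapping[, 2], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((at - bt)^2)))
  structure(list(
    mapping = mapping,
    transform = transform,
    rmsd_aligned = rmsd,
    tm_norm_a = tm_score(mapping, a, b, transform, na),
    tm_norm_b = tm_score(mapping, a, b, transform, nb),
    aligned_length = nrow(mapping),
    seq_identity_aligned = seq_identity_on_alignment(mapping, a, b)
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %d residues aligned, RMSD %.2f A, TM %.3f / %.3f\n",
              x$aligned_length, x$rmsd_aligned, x$tm_norm_a, x$tm_norm_b))
  invisible(x)
}

#' Pairwise alignment report rows
#'
#' @param pairs List of lists with elements `a`, `b` (`StructureModel`s) and
#'   `aln` (`AlignmentResult`).
#' @return Data frame with one row per pair: id_a, id_b, len_a, len_b,
#'   aligned_length, rmsd, tm_norm_a, tm_norm_b, seq_identity.
#' @export
alignment_report <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) data.frame(
    id_a = p$a$id, id_b = p$b$id,
    len_a = n_residues(p$a), len_b = n_residues(p$b),
    aligned_length = p$aln$aligned_length,
    rmsd = p$aln$rmsd_aligned,
    tm_norm_a = p$aln$tm_norm_a, tm_norm_b = p$aln$tm_norm_b,
    seq_identity = p$aln$seq_identity_aligned,
    stringsAsFactors = FALSE)))
}
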