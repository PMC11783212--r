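#' Pairwise structural similarity matrix
#'
#' TM-score similarity for every unordered pair: `sim(a, b) = mean(tm_norm_a,
#' tm_norm_b)` from one [align_structures()] call per pair. Diagonal is
#' exactly 1; the matrix is symmetric by construction.
#'
#' @param s A `StructureSet` with >= 2 members.
#' @param verbose Log progress every 200 pairs.
#' @return A `SimilarityMatrix`: list with `ids` and `values` (n x n numeric,
#'   dimnames = ids).
#' @export
similarity_matrix <- function(s, verbose = FALSE) {
  ids <- names(s$members)
  n <- length(ids)
  if (n < 2) stop("need at least 2 members")
  V <- diag(1, n)
  dimnames(V) <- list(ids, ids)
  done <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- align_structures(s$members[[i]], s$members[[j]])
      V[i, j] <- V[j, i] <- (aln$tm_norm_a + aln$tm_norm_b) / 2
      done <- done + 1L
      if (verbose && done %% 200L == 0L)
        log_msg("INFO", sprintf("similarity: %d pairs done", done))
    }
  }
  structure(list(ids = ids, values = V), class = "SimilarityMatrix")
}

#' Construct a SimilarityMatrix from a plain matrix
#' @param values Symmetric numeric matrix in `[0, 1]` with unit diagonal;
#'   dimnames used as ids if `ids` is `NULL`.
#' @param ids Optional id vector.
#' @return `SimilarityMatrix`.
#' @export
as_similarity_matrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (max(abs(values - t(values))) > 1e-9) stop("matrix not symmetric")
  dimnames(values) <- list(ids, ids)
  diag(values) <- 1
  structure(list(ids = ids, values = values), class = "SimilarityMatrix")
}

#' Average-linkage (UPGMA) clustering of a similarity matrix
#'
#' Distance = 1 - similarity. Deterministic tie-break: among pairs at the
#' minimum distance, the pair whose (lexicographically smallest member id,
#' then second id) sorts first is merged. Merge heights are non-decreasing
#' (ultrametric).
#'
#' @param d A `SimilarityMatrix` (or symmetric distance matrix with class
#'   `"dist_matrix"` semantics via `is_distance = TRUE`).
#' @param is_distance If `TRUE`, `d$values` is already a distance matrix.
#' @return A `ClusterTree`: list with `merge` (hclust convention), `height`,
#'   `labels`.
#' @export
average_linkage <- function(d, is_distance = FALSE) {
  ids <- d$ids
  D <- if (is_distance) d$values else 1 - d$values
  if (max(abs(D - t(D))) > 1e-9) stop("matrix not symmetric")
  n <- length(ids)
  size <- rep(1, n)
  lab <- ids                  # lexicographic label of each active cluster
  node <- -seq_len(n)         # hclust merge coding: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  Dw <- D
  diag(Dw) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    # minimum distance among active pairs
    sub <- Dw[idx, idx, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub <= mn + 1e-15, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break by sorted label pair
    key <- apply(cand, 1, function(r) {
      p <- sort(c(lab[idx[r[1]]], lab[idx[r[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    a <- idx[pick[1]]; b <- idx[pick[2]]
    merge[step, ] <- as.integer(c(node[a], node[b]))
    height[step] <- Dw[a, b]
    # UPGMA update into slot a
    for (c_ in idx) {
      if (c_ == a || c_ == b) next
      Dw[a, c_] <- Dw[c_, a] <-
        (size[a] * Dw[a, c_] + size[b] * Dw[b, c_]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    lab[a] <- min(lab[a], lab[b])
    node[a] <- step
    active[b] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = ids),
            class = "ClusterTree")
}

#' Convert a ClusterTree to an hclust object
#' @param x A `ClusterTree`.
#' @param ... Unused.
#' @return `stats::hclust` object.
#' @export
as.hclust.ClusterTree <- function(x, ...) {
  # leaf order by recursive traversal
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0) ord <<- c(ord, -k)
    else { walk(x$merge[k, 1]); walk(x$merge[k, 2]) }
  }
  if (nrow(x$merge)) walk(nrow(x$merge)) else ord <- 1L
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average"),
            class = "hclust")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d leaves, %d merges (UPGMA)\n",
              length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Newick serialization of a ClusterTree
#'
#' Ultrametric convention: a node at merge height `h` sits at depth `h / 2`,
#' so branch lengths are height differences over two. A single-leaf tree
#' serializes as `"A;"`.
#'
#' @param t A `ClusterTree`, or a single id for the trivial tree.
#' @return Newick string.
#' @export
to_newick <- function(t) {
  if (is.character(t) && length(t) == 1) return(paste0(t, ";"))
  if (length(t$labels) == 1) return(paste0(t$labels, ";"))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  node_str <- function(k, parent_h) {
    if (k < 0) {
      sprintf("%s:%s", t$labels[-k], fmt(parent_h / 2))
    } else {
      h <- t$height[k]
      sprintf("(%s,%s):%s", node_str(t$merge[k, 1], h),
              node_str(t$merge[k, 2], h), fmt((parent_h - h) / 2))
    }
  }
  root <- nrow(t$merge)
  h <- t$height[root]
  sprintf("(%s,%s);", node_str(t$merge[root, 1], h),
          node_str(t$merge[root, 2], h))
}

#' Select cluster representatives (medoids)
#'
#' Cuts the tree into `k` clusters (at the `k - 1` highest merges) and picks
#' in each cluster the medoid: the member maximizing mean similarity to its
#' cluster co-members (a singleton represents itself). Ties break to the
#' lexicographically smallest id. Chosen representatives can be overridden.
#'
#' @param t `ClusterTree`.
#' @param sim `SimilarityMatrix` over the same ids.
#' @param k Number of clusters, `1 <= k <=` leaf count.
#' @param override Optional character vector of ids; any cluster containing an
#'   override id uses it as representative (mirrors manual refinement of
#'   automatically chosen representatives).
#' @return A `RepresentativeSet`: list with `representatives` (ids, one per
#'   cluster) and `clusters` (named integer vector id -> cluster).
#' @export
select_representatives <- function(t, sim, k, override = NULL) {
  n <- length(t$labels)
  if (k < 1 || k > n) stop("k out of range")
  cl <- cutree(as.hclust.ClusterTree(t), k = k)
  names(cl) <- t$labels
  reps <- vapply(sort(unique(cl)), function(g) {
    ids <- names(cl)[cl == g]
    ov <- intersect(override %||% character(0), ids)
    if (length(ov)) return(sort(ov)[1])
    if (length(ids) == 1) return(ids)
    ms <- vapply(ids, function(i)
      mean(sim$values[i, setdiff(ids, i)]), 0)
    ids[order(-ms, ids)][1]
  }, "")
  structure(list(representatives = unname(reps), clusters = cl),
            class = "RepresentativeSet")
}

#' @export
print.RepresentativeSet <- function(x, ...) {
  cat(sprintf("RepresentativeSet: %d clusters; representatives: %s\n",
              length(x$representatives),
              paste(x$representatives, collapse = ", ")))
  invisible(x)
}

#' Cluster assignment table
#' @param rs A `RepresentativeSet`.
#' @return Data frame: id, cluster, is_representative.
#' @export
cluster_assignment <- function(rs) {
  data.frame(id = names(rs$clusters), cluster = unname(rs$clusters),
             is_representative = names(rs$clusters) %in% rs$representatives,
             stringsAsFactors = FALSE)
}

#' Pairwise sequence similarity matrix (identity x coverage)
#'
#' Local alignment (Smith-Waterman via Biostrings) with BLOSUM62, gap open 11,
#' gap extend 1. For each unordered pair: identity = identical positions /
#' alignment columns; coverage = alignment columns / max(length a, length b),
#' capped at 1 (symmetric in the two sequences, and equal to the
#' query-normalized coverage when the query is the longer sequence); score =
#' identity x coverage. Diagonal is 1.
#'
#' @param seqs Named character vector of amino-acid sequences (>= 2,
#'   non-empty).
#' @return `SimilarityMatrix`.
#' @export
sequence_similarity_matrix <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  ids <- names(seqs) %||% paste0("s", seq_along(seqs))
  n <- length(seqs)
  V <- diag(1, n)
  dimnames(V) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      V[i, j] <- V[j, i] <- sequence_pair_score(seqs[[i]], seqs[[j]])
    }
  }
  structure(list(ids = ids, values = V), class = "SimilarityMatrix")
}

#' Identity x coverage score for one sequence pair
#' @param sa,sb Amino-acid sequences.
#' @return Score in `[0, 1]`.
#' @export
sequence_pair_score <- function(sa, sb) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0) return(0)
  identity <- Biostrings::nmatch(aln) / cols
  coverage <- min(1, cols / max(nchar(sa), nchar(sb)))
  identity * coverage
}
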