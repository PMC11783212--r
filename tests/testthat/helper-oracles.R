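# Independent oracles used by the tests. These deliberately re-derive results
# by different algorithms than the package (quaternion superposition, textbook
# UPGMA, brute-force distance enumeration, hand-rolled Smith-Waterman).

# Horn's quaternion method for optimal superposition RMSD (a onto b).
quaternion_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- t(Ac) %*% Bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lmax) / nrow(A)
  sqrt(max(0, msd))
}

# Textbook UPGMA on a distance matrix: returns sorted merge heights and the
# partition at every k (as canonical strings), for comparison with
# average_linkage() + cutree.
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  Dw <- D; diag(Dw) <- Inf
  size <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  part_string <- function() {
    grp <- integer(n)
    for (k in which(active)) grp[clusters[[k]]] <- min(clusters[[k]])
    paste(grp, collapse = ",")
  }
  partitions[[as.character(n)]] <- part_string()
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in idx) for (b in idx) if (a < b && Dw[a, b] < bd) {
      bd <- Dw[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bd)
    for (c_ in idx) {
      if (c_ == a || c_ == b) next
      Dw[a, c_] <- Dw[c_, a] <-
        (size[a] * Dw[a, c_] + size[b] * Dw[b, c_]) / (size[a] + size[b])
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
    partitions[[as.character(n - step)]] <- part_string()
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(grp) {
  # canonical string of a set partition given any integer labeling
  first_seen <- match(grp, unique(grp))
  paste(first_seen, collapse = ",")
}

# Brute-force clash count: distinct atoms of X1 within cutoff of any X2 atom.
clash_oracle <- function(X1, X2, cutoff) {
  hits <- 0L
  for (i in seq_len(nrow(X1))) {
    d2 <- rowSums(sweep(X2, 2, X1[i, ])^2)
    if (min(d2) < cutoff^2) hits <- hits + 1L
  }
  hits
}

# Hand-rolled local (Smith-Waterman) alignment with affine gaps, returning
# alignment column count and identical-position count.
sw_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1); Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    M[i, j] <- max(0, S[av[i - 1], bv[j - 1]] +
                     max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]))
    if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
  }
  if (best == 0) return(list(cols = 0L, nmatch = 0L, score = 0))
  # traceback
  i <- bi; j <- bj; state <- "M"; cols <- 0L; nm <- 0L
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] == 0) break
      cols <- cols + 1L
      if (av[i - 1] == bv[j - 1]) nm <- nm + 1L
      prev <- M[i, j] - S[av[i - 1], bv[j - 1]]
      state <- if (abs(M[i - 1, j - 1] - prev) < 1e-9) "M"
               else if (abs(Ix[i - 1, j - 1] - prev) < 1e-9) "Ix" else "Iy"
      i <- i - 1; j <- j - 1
      if (state == "M" && M[i, j] == 0) break
    } else if (state == "Ix") {
      cols <- cols + 1L
      state <- if (abs(M[i - 1, j] - gap_open - gap_ext - Ix[i, j]) < 1e-9) "M" else "Ix"
      i <- i - 1
    } else {
      cols <- cols + 1L
      state <- if (abs(M[i, j - 1] - gap_open - gap_ext - Iy[i, j]) < 1e-9) "M" else "Iy"
      j <- j - 1
    }
  }
  list(cols = cols, nmatch = nm, score = best)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
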