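# Synthetic SSAP-like structure generator.
#
# Emulates the geometry the analysis assumes: a monomeric fold with a
# three-stranded antiparallel beta-sheet traversed by an alpha-helix plus a
# beta-hairpin (with an optional inserted helix), family-specific element
# lengths, chain-correlated coordinate divergence within families, pLDDT-like
# confidence in the B-factor column, fragment decoys, and n-mer ring
# templates. Backbone-only plus a Cbeta stub per residue; side-chain realism
# is irrelevant to every statistic computed downstream.

#' Ideal alpha-helix Calpha trace
#'
#' Radius 2.3 A, rise 1.5 A/residue, 100 degrees/residue, axis along +x.
#'
#' @param n Number of residues (>= 1).
#' @return n x 3 coordinate matrix.
#' @export
make_helix <- function(n) {
  if (n < 1) stop("n must be >= 1")
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(i * 1.5, 2.3 * cos(ang), 2.3 * sin(ang))
}

#' Ideal extended-strand Calpha trace
#'
#' Calpha step 3.8 A with alternating pleat (d(i, i+2) about 6.8 A), axis
#' along +x, pleat in z.
#'
#' @param n Number of residues (>= 1).
#' @return n x 3 coordinate matrix.
#' @export
make_strand <- function(n) {
  if (n < 1) stop("n must be >= 1")
  i <- seq_len(n) - 1
  cbind(i * 3.4, 0, 0.849 * (-1)^i)
}

# Irregular coil connecting P to Q with n residues: a tight spiral along the
# P->Q axis whose local geometry registers as neither helix nor strand.
make_loop <- function(P, Q, n) {
  if (n < 1) return(matrix(numeric(0), 0, 3))
  axis <- Q - P
  len <- sqrt(sum(axis^2))
  if (len < 1e-6) axis <- c(0, 0, 1) else axis <- axis / len
  u <- ortho(axis)
  v <- pracma_cross(axis, u)
  d <- len / (n + 1)
  k <- seq_len(n)
  phi <- k * 140 * pi / 180
  base <- matrix(P, n, 3, byrow = TRUE) + outer(k * d, axis)
  base + 1.4 * (outer(cos(phi), u) + outer(sin(phi), v))
}

# Place a segment built along +x at `origin` running in direction `dir`
# (unit), with its local y-axis along `up`.
place_segment <- function(coords, origin, dir, up = NULL) {
  dir <- unit(dir)
  if (is.null(up)) up <- ortho(dir)
  up <- unit(up - sum(up * dir) * dir)
  w <- pracma_cross(dir, up)
  R <- rbind(dir, up, w)  # local axes as rows: x' = local %*% R
  sweep(coords %*% R, 2, origin, "+")
}

#' Family generator parameters
#'
#' Element lengths (residues) and divergence for one synthetic SSAP family.
#' `hairpin_helix_len = 0` gives a bare hairpin (Sak3-like).
#'
#' @param n_strands Number of sheet strands (default 3).
#' @param strand_len Residues per sheet strand.
#' @param sheet_helix_len Residues of the helix traversing the sheet.
#' @param hairpin_len Residues per hairpin strand.
#' @param hairpin_helix_len Residues of the helix inserted in the hairpin
#'   (0 allowed).
#' @param loop_len Residues per connecting loop.
#' @param noise_sigma Within-structure coordinate noise (A).
#' @param seed Integer seed.
#' @param helix_side Which face of the sheet the traversing helix packs
#'   against (+1 or -1).
#' @param helix_tilt Angle (degrees) between the traversing helix axis and the
#'   strand axis, in the sheet plane.
#' @param hairpin_tilt Rotation (degrees) of the hairpin block out of the
#'   sheet plane about the strand axis.
#' @return Object of class `FamilyParams`.
#' @export
family_params <- function(n_strands = 3L, strand_len = 10L,
                          sheet_helix_len = 18L, hairpin_len = 6L,
                          hairpin_helix_len = 12L, loop_len = 4L,
                          noise_sigma = 0, seed = 1L, helix_side = 1,
                          helix_tilt = 0, hairpin_tilt = 0) {
  p <- list(n_strands = as.integer(n_strands), strand_len = as.integer(strand_len),
            sheet_helix_len = as.integer(sheet_helix_len),
            hairpin_len = as.integer(hairpin_len),
            hairpin_helix_len = as.integer(hairpin_helix_len),
            loop_len = as.integer(loop_len),
            noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed),
            helix_side = sign(helix_side), helix_tilt = as.numeric(helix_tilt),
            hairpin_tilt = as.numeric(hairpin_tilt))
  stopifnot(p$n_strands >= 1, p$strand_len >= 1, p$loop_len >= 0,
            p$hairpin_len >= 1, p$hairpin_helix_len >= 0,
            p$sheet_helix_len >= 0, p$noise_sigma >= 0)
  structure(p, class = "FamilyParams")
}

#' Preset family parameters
#'
#' Five presets whose sheet/hairpin helix and strand lengths echo the median
#' helix (H) and strand (S) residue counts observed across the SSAP families
#' (per-strand length = sheet S median / 3):
#' `"rad52-long"` (eukaryotic-Rad52-like, long sheet strands),
#' `"rad52-short"` (bacterial-Rad52-like), `"redbeta-like"`, `"rect-like"`
#' (long traversing and hairpin helices), `"sak3-like"` (no hairpin helix).
#' Besides element lengths the presets differ in packing layout (helix face
#' and tilt, hairpin tilt), mirroring the arrangement differences that
#' distinguish the real families beyond strand/helix length alone.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [family_params()].
#' @return `FamilyParams`.
#' @export
preset_family_params <- function(name = c("rad52-long", "rad52-short",
                                          "redbeta-like", "rect-like",
                                          "sak3-like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "rad52-long"   = list(strand_len = 12L, sheet_helix_len = 15L,
                          hairpin_len = 6L, hairpin_helix_len = 18L,
                          helix_side = 1, helix_tilt = 0, hairpin_tilt = 0),
    "rad52-short"  = list(strand_len = 9L, sheet_helix_len = 17L,
                          hairpin_len = 7L, hairpin_helix_len = 12L,
                          helix_side = 1, helix_tilt = -15, hairpin_tilt = 55),
    "redbeta-like" = list(strand_len = 11L, sheet_helix_len = 26L,
                          hairpin_len = 7L, hairpin_helix_len = 28L,
                          helix_side = -1, helix_tilt = 10, hairpin_tilt = -40),
    "rect-like"    = list(strand_len = 12L, sheet_helix_len = 32L,
                          hairpin_len = 6L, hairpin_helix_len = 42L,
                          helix_side = 1, helix_tilt = 25, hairpin_tilt = 90),
    "sak3-like"    = list(strand_len = 9L, sheet_helix_len = 15L,
                          hairpin_len = 8L, hairpin_helix_len = 0L,
                          helix_side = -1, helix_tilt = -25, hairpin_tilt = -70))
  do.call(family_params, modifyList(base, list(...)))
}

AA20 <- names(AA3TO1)

# Backbone stub atoms (N, C, O, CB) around each Calpha, placed in a local
# frame from the chain direction. Deterministic.
backbone_stubs <- function(ca, resname) {
  n <- nrow(ca)
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(3.8, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(3.8, 0, 0)
    t <- nxt - prev
    tn <- sqrt(sum(t^2)); t <- if (tn > 1e-6) t / tn else c(1, 0, 0)
    u <- ortho(t)
    w <- pracma_cross(t, u)
    pos <- rbind(
      ca[i, ] - 1.46 * t + 0.4 * u,            # N
      ca[i, ] + 1.52 * t + 0.4 * u,            # C
      ca[i, ] + 1.52 * t + 0.4 * u + 1.23 * w, # O
      ca[i, ] - 1.53 * u + 0.5 * w             # CB
    )
    nm <- c("N", "C", "O", "CB")
    if (resname[i] == "GLY") { pos <- pos[1:3, , drop = FALSE]; nm <- nm[1:3] }
    atoms[[i]] <- data.frame(res = i, name = c(nm[1], "CA", nm[-1]),
                             x = c(pos[1, 1], ca[i, 1], pos[-1, 1]),
                             y = c(pos[1, 2], ca[i, 2], pos[-1, 2]),
                             z = c(pos[1, 3], ca[i, 3], pos[-1, 3]),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, atoms)
}

# Chain-correlated Gaussian displacement field, rescaled so per-coordinate
# SD = sigma. Models low-frequency elastic deformation rather than
# independent per-atom jitter (which would destroy local Calpha geometry).
correlated_noise <- function(n, sigma, window = 9L) {
  if (sigma <= 0 || n == 0) return(matrix(0, n, 3))
  raw <- matrix(rnorm(3 * (n + window)), n + window, 3)
  sm <- apply(raw, 2, function(v) stats::filter(v, rep(1 / window, window),
                                                sides = 2))
  sm <- sm[seq_len(n) + floor(window / 2), , drop = FALSE]
  sm * sigma * sqrt(window)
}

#' Generate a synthetic SSAP-like monomer
#'
#' Assembles strand-loop-strand-loop-strand antiparallel sheet, a helix packed
#' along the sheet axis, and a strand-turn-strand hairpin with an optional
#' inserted helix, connected by irregular coil. Chain-correlated Gaussian
#' noise of SD `noise_sigma` is added; confidence is drawn from N(90, 5)
#' clipped to `[0, 100]`. Deterministic for a fixed seed.
#'
#' @param p A [family_params()] object.
#' @param id Identifier for the model.
#' @return A `StructureModel` with attributes `motifs` (a
#'   [motif_annotation()]: strands + traversing helix as the sheet motif,
#'   hairpin strands/turn/helix as the hairpin motif) and `true_ss`
#'   (the designed secondary-structure string).
#' @export
make_ssap_monomer <- function(p, id = sprintf("synth_%d", p$seed)) {
  with_seed(p$seed, {
    segs <- list()    # list of (coords, kind)
    add <- function(coords, kind) segs[[length(segs) + 1]] <<- list(coords, kind)

    sep <- 4.8   # inter-strand spacing
    slen <- (p$strand_len - 1) * 3.4
    # sheet strands (antiparallel, along +/- x at y = 0, sep, 2*sep, ...)
    ends <- list()
    for (s in seq_len(p$n_strands)) {
      dirx <- if (s %% 2 == 1) c(1, 0, 0) else c(-1, 0, 0)
      x0 <- if (s %% 2 == 1) 0 else slen
      coords <- place_segment(make_strand(p$strand_len),
                              origin = c(x0, (s - 1) * sep, 0),
                              dir = dirx, up = c(0, 1, 0))
      add(coords, "E")
    }
    # traversing helix packed against one sheet face, tilted in-plane
    if (p$sheet_helix_len > 0) {
      ht <- p$helix_tilt * pi / 180
      hdir <- c(cos(ht), sin(ht), 0)
      hlen <- (p$sheet_helix_len - 1) * 1.5
      mid <- c(slen / 2, (p$n_strands - 1) * sep / 2, 7.5 * p$helix_side)
      hx <- place_segment(make_helix(p$sheet_helix_len),
                          origin = mid - hlen / 2 * hdir,
                          dir = hdir, up = c(0, 1, 0))
      add(hx, "H")
    }
    # hairpin block (two antiparallel strands + optional helix) built in a
    # local frame anchored at the sheet edge, then tilted out of the sheet
    # plane about the strand axis
    hplen <- (p$hairpin_len - 1) * 3.4
    anchor <- c(0, -sep, 0)
    Rt <- rot_about(c(1, 0, 0), p$hairpin_tilt * pi / 180)
    hp_place <- function(coords, offset, dir, up) {
      local <- place_segment(coords, origin = offset, dir = dir, up = up)
      sweep(local %*% Rt, 2, anchor, "+")
    }
    add(hp_place(make_strand(p$hairpin_len), c(0, 0, 0),
                 c(1, 0, 0), c(0, 1, 0)), "E")
    add(hp_place(make_strand(p$hairpin_len), c(hplen, -sep, 0),
                 c(-1, 0, 0), c(0, 1, 0)), "T")  # 2nd hairpin strand
    if (p$hairpin_helix_len > 0) {
      add(hp_place(make_helix(p$hairpin_helix_len), c(0, -2 * sep - 2, 6.0),
                   c(1, 0, 0), c(0, 1, 0)), "H2")
    }

    # stitch segments with loops; record spans
    ca <- matrix(numeric(0), 0, 3)
    ss <- character(0)
    spans <- list()
    for (k in seq_along(segs)) {
      if (k > 1) {
        P <- ca[nrow(ca), ]
        Q <- segs[[k]][[1]][1, ]
        nl <- if (identical(segs[[k]][[2]], "T")) max(2L, p$loop_len - 1L) else p$loop_len
        lp <- make_loop(P, Q, nl)
        ca <- rbind(ca, lp)
        ss <- c(ss, rep("C", nrow(lp)))
      }
      co <- segs[[k]][[1]]
      spans[[k]] <- c(nrow(ca) + 1L, nrow(ca) + nrow(co))
      ca <- rbind(ca, co)
      kind <- segs[[k]][[2]]
      ss <- c(ss, rep(if (kind %in% c("H", "H2")) "H" else "E", nrow(co)))
    }

    n <- nrow(ca)
    ca <- ca + correlated_noise(n, p$noise_sigma)
    resname <- sample(AA20, n, replace = TRUE)
    conf <- pmin(100, pmax(0, rnorm(n, 90, 5)))

    kinds <- vapply(segs, function(s) s[[2]], "")
    sheet_idx <- which(kinds == "E" | kinds == "H")
    hairpin_idx <- which(kinds == "T" | kinds == "H2")
    # hairpin strand 1 is the E segment right before the T segment
    hp1 <- which(kinds == "T") - 1L
    sheet_idx <- setdiff(sheet_idx, hp1)
    hairpin_idx <- sort(c(hairpin_idx, hp1))

    m <- structure_model(id = id, resname = resname, ca = ca, conf = conf,
                         atoms = backbone_stubs(ca, resname))
    attr(m, "motifs") <- motif_annotation(spans[sheet_idx], spans[hairpin_idx])
    attr(m, "true_ss") <- paste(ss, collapse = "")
    m
  })
}

#' Generate a synthetic family of perturbed monomers
#'
#' `n_members` copies of the family fold with per-member seeds derived from
#' the master seed, chain-correlated coordinate divergence of SD
#' `divergence_sigma`, small loop-length jitter, and a few residue-type
#' mutations (5%). Optionally emits truncated fragments.
#'
#' @param n_members Number of members (>= 1).
#' @param p `FamilyParams` (its `seed` is the master seed).
#' @param divergence_sigma Within-family coordinate divergence (A), default 0.5.
#' @param family Family label recorded in the manifest.
#' @param fragment_fraction If non-`NULL`, fraction in (0, 1): each member is
#'   also emitted truncated to its first `fragment_fraction` residues with id
#'   suffix `"_frag"`.
#' @return A `StructureSet` with attribute `manifest` (data frame: id, family,
#'   length, seed, is_fragment) and attribute `motifs` (named list of true
#'   `MotifAnnotation` per member).
#' @export
make_family <- function(n_members, p, divergence_sigma = 0.5,
                        family = "familyA", fragment_fraction = NULL) {
  stopifnot(n_members >= 1)
  members <- list()
  motifs <- list()
  rows <- list()
  for (i in seq_len(n_members)) {
    si <- derive_seed(p$seed, i)
    jit <- with_seed(si, sample(-1:1, 1))
    pi <- p
    pi$seed <- si
    pi$loop_len <- max(2L, p$loop_len + jit)
    pi$noise_sigma <- divergence_sigma
    id <- sprintf("%s_%02d", family, i)
    m <- make_ssap_monomer(pi, id = id)
    # 5% residue-type mutations (seeded)
    m$resname <- with_seed(si + 7L, {
      mut <- runif(length(m$resname)) < 0.05
      rn <- m$resname
      rn[mut] <- sample(AA20, sum(mut), replace = TRUE)
      rn
    })
    members[[id]] <- m
    motifs[[id]] <- attr(m, "motifs")
    rows[[length(rows) + 1]] <- data.frame(
      id = id, family = family, length = n_residues(m), seed = si,
      is_fragment = FALSE, stringsAsFactors = FALSE)
    if (!is.null(fragment_fraction)) {
      fm <- truncate_structure(m, fragment_fraction, id = paste0(id, "_frag"))
      members[[fm$id]] <- fm
      rows[[length(rows) + 1]] <- data.frame(
        id = fm$id, family = family, length = n_residues(fm), seed = si,
        is_fragment = TRUE, stringsAsFactors = FALSE)
    }
  }
  s <- structure_set(members,
                     labels = stats::setNames(rep(family, length(members)),
                                              names(members)))
  attr(s, "manifest") <- do.call(rbind, rows)
  attr(s, "motifs") <- motifs
  s
}

#' Truncate a structure to its first fraction of residues
#' @param m `StructureModel`.
#' @param fraction Fraction in (0, 1].
#' @param id New identifier.
#' @return Truncated `StructureModel`.
#' @export
truncate_structure <- function(m, fraction, id = paste0(m$id, "_frag")) {
  k <- max(5L, floor(n_residues(m) * fraction))
  structure_model(id = id, resname = m$resname[seq_len(k)],
                  ca = m$ca[seq_len(k), , drop = FALSE],
                  conf = m$conf[seq_len(k)],
                  atoms = m$atoms[m$atoms$res <= k, , drop = FALSE],
                  chain = m$chain, resid = m$resid[seq_len(k)])
}

# One attempt at a compact self-avoiding walk; NULL if the head gets caged
# (no candidate satisfies both the exclusion distance and the relaxed cap).
decoy_walk_attempt <- function(length, rcap) {
  ca <- matrix(0, length, 3)
  for (i in 2:length) {
    placed <- FALSE
    cap <- rcap
    for (relax in 1:25) {
      for (try in 1:60) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- ca[i - 1, ] + 3.8 * u
        cen <- colMeans(ca[seq_len(i - 1), , drop = FALSE])
        if (sqrt(sum((cand - cen)^2)) > cap) next
        if (i > 2) {
          d2 <- rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < 3.5^2) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (placed) break
      cap <- cap * 1.1
    }
    if (!placed) return(NULL)
  }
  ca
}

#' Compact self-avoiding random-coil decoy
#'
#' Calpha walk with step 3.8 A, minimum non-consecutive separation 3.5 A, and
#' a radius-of-gyration-style cap (`3 * n^(1/3)` A from the running centroid,
#' relaxed if the walk gets stuck). A walk whose head gets caged is restarted
#' from a derived seed, so generation is deterministic per seed and always
#' terminates.
#'
#' @param length Number of residues (>= 10).
#' @param seed Integer seed.
#' @param id Identifier.
#' @return `StructureModel`.
#' @export
make_decoy <- function(length, seed = 1L, id = sprintf("decoy_%d", seed)) {
  if (length < 10) stop("length must be >= 10")
  rcap <- 3.0 * length^(1 / 3)
  ca <- NULL
  for (attempt in 0:100) {
    ca <- with_seed(derive_seed(seed, attempt), decoy_walk_attempt(length, rcap))
    if (!is.null(ca)) break
  }
  if (is.null(ca)) stop("decoy generation failed")  # unreachable in practice
  with_seed(derive_seed(seed, 999999L), {
    resname <- sample(AA20, length, replace = TRUE)
    structure_model(id = id, resname = resname, ca = ca,
                    conf = pmin(100, pmax(0, rnorm(length, 90, 5))),
                    atoms = backbone_stubs(ca, resname))
  })
}

#' Demo structure set: five preset families plus decoys
#'
#' @param n_per_family Members per family (default 10).
#' @param n_decoys Number of random-coil decoys (default 5).
#' @param seed Master seed.
#' @param divergence_sigma Within-family divergence (A).
#' @return `StructureSet` with `labels`, `manifest` and `motifs` attributes.
#' @export
make_demo_set <- function(n_per_family = 10L, n_decoys = 5L, seed = 1L,
                          divergence_sigma = 0.5) {
  presets <- c("rad52-long", "rad52-short", "redbeta-like", "rect-like",
               "sak3-like")
  members <- list()
  labels <- character(0)
  manifest <- list()
  motifs <- list()
  for (f in seq_along(presets)) {
    p <- preset_family_params(presets[f], seed = derive_seed(seed, f * 1000L))
    fam <- make_family(n_per_family, p, divergence_sigma = divergence_sigma,
                       family = presets[f])
    members <- c(members, fam$members)
    labels <- c(labels, fam$labels)
    manifest[[f]] <- attr(fam, "manifest")
    motifs <- c(motifs, attr(fam, "motifs"))
  }
  dl <- if (n_decoys > 0) {
    lapply(seq_len(n_decoys), function(i) {
      make_decoy(100L, seed = derive_seed(seed, 9000L + i),
                 id = sprintf("decoy_%02d", i))
    })
  } else list()
  for (d in dl) {
    members[[d$id]] <- d
    labels[d$id] <- "decoy"
    manifest[[length(manifest) + 1]] <- data.frame(
      id = d$id, family = "decoy", length = n_residues(d), seed = NA_integer_,
      is_fragment = FALSE, stringsAsFactors = FALSE)
  }
  s <- structure_set(members, labels = labels)
  attr(s, "manifest") <- do.call(rbind, manifest)
  attr(s, "motifs") <- motifs
  s
}

#' Build a symmetric n-mer ring template from a monomer
#'
#' The monomer is centered and oriented by its principal axes (longest axis
#' along the ring axis z, middle axis tangential) so subunits pack side-on,
#' then `n_copies` are placed around the z axis at the given radius with
#' n-fold symmetry. In auto mode (`radius = NULL`) the smallest radius
#' (0.5 A grid) whose adjacent copies have zero clashes at 2.0 + 0.5 A margin
#' is used.
#'
#' @param monomer `StructureModel`.
#' @param n_copies Number of subunits (>= 3), default 11.
#' @param radius Ring radius (A) or `NULL` for auto.
#' @return An `Assembly` (see [build_assembly()]) with ring topology;
#'   `attr(, "radius")` records the radius used.
#' @export
make_ring <- function(monomer, n_copies = 11L, radius = NULL) {
  if (n_copies < 3) stop("n_copies must be >= 3")
  cen <- colMeans(monomer$ca)
  # principal-axis orientation: eigenvectors of the Calpha covariance,
  # middle axis radial (x), smallest axis tangential (y) so neighbors meet
  # across the fold's thin dimension, longest axis along the ring axis z;
  # deterministic sign convention, det +1
  ev <- eigen(stats::cov(monomer$ca), symmetric = TRUE)$vectors
  ax <- ev[, c(2, 3, 1)]
  for (k in 1:3) if (ax[which.max(abs(ax[, k])), k] < 0) ax[, k] <- -ax[, k]
  if (det(ax) < 0) ax[, 1] <- -ax[, 1]
  m0 <- transform_structure(monomer, ax, -as.numeric(cen %*% ax))
  xyz0 <- as.matrix(m0$atoms[, c("x", "y", "z")])
  place <- function(r) {
    lapply(seq_len(n_copies) - 1L, function(k) {
      R <- rot_about(c(0, 0, 1), 2 * pi * k / n_copies)
      mk <- transform_structure(m0, R, as.numeric(c(r, 0, 0) %*% R))
      mk$id <- sprintf("%s_ring%02d", monomer$id, k + 1L)
      mk$chain <- LETTERS[(k %% 26) + 1L]
      mk
    })
  }
  if (is.null(radius)) {
    ext <- max(sqrt(rowSums(sweep(xyz0, 2, colMeans(xyz0))^2)))
    r <- max(1, round(2 * ext * sin(pi / n_copies) / 2, 1))  # start small
    R1 <- rot_about(c(0, 0, 1), 2 * pi / n_copies)
    repeat {
      x1 <- sweep(xyz0, 2, -c(r, 0, 0))
      x2 <- sweep(xyz0 %*% R1, 2, -as.numeric(c(r, 0, 0) %*% R1))
      if (length(cpp_clash_atoms(x1, x2, 2.5)) == 0) break
      r <- r + 0.5
    }
    radius <- r
  }
  copies <- place(radius)
  a <- assembly(copies, topology = "ring")
  attr(a, "radius") <- radius
  a
}

#' Apply a rigid transform to a whole StructureModel
#' @param m `StructureModel`.
#' @param rotation 3 x 3 rotation matrix (row-vector convention).
#' @param translation Length-3 translation.
#' @return Transformed `StructureModel`.
#' @export
transform_structure <- function(m, rotation, translation) {
  m$ca <- sweep(m$ca %*% rotation, 2, -translation, "-")
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rotation
  m$atoms$x <- xyz[, 1] + translation[1]
  m$atoms$y <- xyz[, 2] + translation[2]
  m$atoms$z <- xyz[, 3] + translation[3]
  m
}
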