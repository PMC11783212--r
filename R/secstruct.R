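#' Assign secondary structure from Calpha geometry
#'
#' P-SEA-style rules on Calpha(i)-Calpha(i+2/3/4) distances and the
#' Calpha pseudo-dihedral. Window start `i` passes the helix test when
#' `d(i, i+3) in [4.7, 5.7]` and `d(i, i+4) in [5.7, 7.0]` Angstrom, and the
#' strand test when `d(i, i+2) in [6.4, 7.4]` and the pseudo-dihedral
#' `tau(i..i+3)` (mod 360) lies in `[150, 215]` degrees. Two consecutive
#' passing starts are required — the conditions must hold over a >= 6-residue
#' (helix) resp. >= 5-residue (strand) span — and the spanned residues of all
#' passing runs are labeled, so one mid-element miss (e.g. from coordinate
#' noise) does not erase an element while isolated chance hits in coil are
#' ignored. Helix takes priority over strand; everything else (including
#' termini) is coil.
#'
#' @param m A `StructureModel` (or an n x 3 Calpha matrix).
#' @return Character string over `{H, E, C}`, length = residue count.
#'   Models shorter than 5 residues are all-coil.
#' @export
assign_ss <- function(m) {
  ca <- if (is.matrix(m)) m else m$ca
  n <- nrow(ca)
  if (n < 5) return(paste(rep("C", n), collapse = ""))

  dk <- function(k) sqrt(rowSums((ca[seq_len(n - k) + k, , drop = FALSE] -
                                  ca[seq_len(n - k), , drop = FALSE])^2))
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)

  # pseudo-dihedral tau(i) over ca[i..i+3], degrees in [0, 360)
  b1 <- ca[2:(n - 2), ] - ca[1:(n - 3), ]
  b2 <- ca[3:(n - 1), ] - ca[2:(n - 2), ]
  b3 <- ca[4:n, ] - ca[3:(n - 1), ]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  tau <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  tau <- (tau + 360) %% 360

  hcond <- d3[seq_len(n - 4)] >= 4.7 & d3[seq_len(n - 4)] <= 5.7 &
    d4 >= 5.7 & d4 <= 7.0                      # starts i = 1..n-4
  scond <- d2[seq_len(n - 3)] >= 6.4 & d2[seq_len(n - 3)] <= 7.4 &
    tau >= 150 & tau <= 215                    # starts i = 1..n-3

  lab <- rep("C", n)
  mark_runs <- function(cond, min_run, extend, letter) {
    r <- rle(cond)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (isTRUE(r$values[k]) && r$lengths[k] >= min_run) {
        idx <- start[k]:(end[k] + extend)
        lab[idx][lab[idx] == "C"] <<- letter
      }
    }
  }
  mark_runs(hcond, 2L, 4L, "H")
  mark_runs(scond, 2L, 3L, "E")
  paste(lab, collapse = "")
}

#' Construct a motif annotation
#'
#' Residue spans of the beta-sheet motif (three strands plus the traversing
#' helix) and the beta-hairpin motif on a representative structure.
#'
#' @param sheet_span,hairpin_span Lists of integer ranges `c(from, to)`
#'   (1-based, inclusive). The two motifs must not overlap.
#' @return Object of class `MotifAnnotation`.
#' @export
motif_annotation <- function(sheet_span, hairpin_span) {
  norm <- function(spans) lapply(spans, function(r) {
    r <- as.integer(r)
    stopifnot(length(r) == 2, r[1] >= 1, r[2] >= r[1])
    r
  })
  sheet_span <- norm(sheet_span); hairpin_span <- norm(hairpin_span)
  su <- unlist(lapply(sheet_span, function(r) r[1]:r[2]))
  hu <- unlist(lapply(hairpin_span, function(r) r[1]:r[2]))
  if (length(intersect(su, hu))) stop("sheet and hairpin spans overlap")
  structure(list(sheet_span = sheet_span, hairpin_span = hairpin_span),
            class = "MotifAnnotation")
}

span_residues <- function(spans) {
  if (!length(spans)) return(integer())
  sort(unique(unlist(lapply(spans, function(r) r[1]:r[2]))))
}

#' Helix/strand composition of motifs transferred onto a member
#'
#' Transfers the representative's motif spans onto a member structure through
#' a structural alignment mapping, assigns secondary structure on the member,
#' and counts H and E residues inside each transferred span (E is reported as
#' "S", strand). Counts cover mapped residues only; an empty transferred span
#' yields zero counts with `empty_transfer = TRUE`.
#'
#' @param member,rep `StructureModel`s.
#' @param rep_motifs `MotifAnnotation` on `rep`.
#' @param aln `AlignmentResult` mapping `rep` (first mapping column) onto
#'   `member` (second column), e.g. `align_structures(rep, member)`.
#' @return Object of class `MotifComposition`: `sheet_h`, `sheet_s`,
#'   `hairpin_h`, `hairpin_s` residue counts.
#' @export
motif_composition <- function(member, rep, rep_motifs, aln) {
  ss <- strsplit(assign_ss(member), "")[[1]]
  mp <- aln$mapping
  transfer <- function(spans) {
    idx <- span_residues(spans)
    mp[mp[, 1] %in% idx, 2]
  }
  count <- function(res, letter) sum(ss[res] == letter)
  sheet <- transfer(rep_motifs$sheet_span)
  hairpin <- transfer(rep_motifs$hairpin_span)
  structure(list(
    sheet_h = count(sheet, "H"), sheet_s = count(sheet, "E"),
    hairpin_h = count(hairpin, "H"), hairpin_s = count(hairpin, "E"),
    empty_transfer = length(sheet) == 0 || length(hairpin) == 0
  ), class = "MotifComposition")
}

#' Aggregate motif compositions: per-field median and population SD
#'
#' @param group Non-empty list of `MotifComposition` objects.
#' @return Data frame with one row per field (`sheet_h`, `sheet_s`,
#'   `hairpin_h`, `hairpin_s`) and columns `field`, `median`, `std`
#'   (population standard deviation).
#' @export
aggregate_composition <- function(group) {
  if (!length(group)) stop("empty group")
  fields <- c("sheet_h", "sheet_s", "hairpin_h", "hairpin_s")
  rows <- lapply(fields, function(f) {
    v <- vapply(group, function(g) as.numeric(g[[f]]), 0)
    data.frame(field = f, median = median(v),
               std = sqrt(mean((v - mean(v))^2)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read/write motif span configuration
#'
#' Plain TSV with columns `id`, `motif` (`sheet` or `hairpin`), `from`, `to`;
#' one row per span. Editable by hand so spans can be annotated on real
#' representatives.
#'
#' @param path TSV file path.
#' @return Named list of `MotifAnnotation` (one per `id`).
#' @export
read_motif_spans <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  out <- lapply(split(df, df$id), function(d) {
    motif_annotation(
      sheet_span = lapply(which(d$motif == "sheet"), function(i) c(d$from[i], d$to[i])),
      hairpin_span = lapply(which(d$motif == "hairpin"), function(i) c(d$from[i], d$to[i]))
    )
  })
  out
}

#' @rdname read_motif_spans
#' @param annotations Named list of `MotifAnnotation`.
#' @export
write_motif_spans <- function(annotations, path) {
  rows <- list()
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    for (r in ann$sheet_span)
      rows[[length(rows) + 1]] <- data.frame(id = id, motif = "sheet",
                                             from = r[1], to = r[2])
    for (r in ann$hairpin_span)
      rows[[length(rows) + 1]] <- data.frame(id = id, motif = "hairpin",
                                             from = r[1], to = r[2])
  }
  write_tsv_meta(do.call(rbind, rows), path)
}
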