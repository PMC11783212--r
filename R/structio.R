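#' Construct a StructureModel
#'
#' A `StructureModel` is the package's in-memory representation of one protein
#' chain: ordered residues with Calpha coordinates, all heavy atoms, and a
#' per-residue confidence score (pLDDT convention, 0-100, stored in the
#' B-factor column of model files).
#'
#' @param id Character identifier.
#' @param resname Character vector of 3-letter residue codes.
#' @param ca Numeric matrix (n x 3) of Calpha coordinates in Angstrom.
#' @param conf Numeric vector of per-residue confidence in `[0, 100]`.
#' @param atoms Data frame with columns `res` (1-based residue index into the
#'   model), `name` (atom name), `x`, `y`, `z`. Must include one CA per residue.
#' @param chain Chain identifier (single character).
#' @param resid Optional integer vector of author residue numbers.
#'
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(id, resname, ca, conf, atoms = NULL, chain = "A",
                            resid = NULL) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  stopifnot(length(resname) == n, length(conf) == n, ncol(ca) == 3)
  if (any(conf < 0 | conf > 100)) stop("confidence must lie in [0, 100]")
  if (is.null(resid)) resid <- seq_len(n)
  if (is.null(atoms)) {
    atoms <- data.frame(res = seq_len(n), name = "CA",
                        x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        stringsAsFactors = FALSE)
  }
  structure(list(id = id, chain = chain, resname = as.character(resname),
                 resid = as.integer(resid), ca = unname(ca),
                 conf = as.numeric(conf), atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel %s (chain %s): %d residues, %d atoms, mean confidence %.1f\n",
              x$id, x$chain, length(x$resname), nrow(x$atoms), mean(x$conf)))
  invisible(x)
}

#' Number of residues in a StructureModel
#' @param m A `StructureModel`.
#' @return Integer residue count.
#' @export
n_residues <- function(m) nrow(m$ca)

#' Read a structure from PDB-format text
#'
#' Parses fixed-column ATOM/HETATM records. Only the first MODEL of a
#' multi-model file is read; alternate locations are resolved by keeping the
#' first encountered; residues are ordered by (residue number, insertion code);
#' residues lacking a Calpha atom are dropped (the count is available in
#' `attr(, "dropped_no_ca")`). Per-residue confidence is taken from the
#' B-factor field of the Calpha atom.
#'
#' @param x Path to a PDB file, or PDB text (single string with newlines, or a
#'   character vector of lines).
#' @param chain Chain identifier to extract; `NULL` takes the first chain.
#' @param id Identifier for the resulting model; defaults to the file base name
#'   or `"structure"`.
#' @return A [structure_model()].
#' @export
read_structure <- function(x, chain = NULL, id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(x))
  } else {
    lines <- if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  }
  if (is.null(id)) id <- "structure"

  # first MODEL only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]

  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM records in input")

  fld <- function(a, b) trimws(substr(lines, a, b))
  atom_name <- fld(13, 16)
  altloc <- substr(lines, 17, 17)
  resname <- fld(18, 20)
  ch <- substr(lines, 22, 22)
  resseq <- as.integer(substr(lines, 23, 26))
  icode <- substr(lines, 27, 27)
  xx <- as.numeric(substr(lines, 31, 38))
  yy <- as.numeric(substr(lines, 39, 46))
  zz <- as.numeric(substr(lines, 47, 54))
  bf <- suppressWarnings(as.numeric(substr(lines, 61, 66)))
  bf[is.na(bf)] <- 0
  elem <- fld(77, 78)

  if (is.null(chain)) chain <- ch[1]
  sel <- ch == chain
  if (!any(sel)) stop(sprintf("chain '%s' not found", chain))
  atom_name <- atom_name[sel]; altloc <- altloc[sel]; resname <- resname[sel]
  resseq <- resseq[sel]; icode <- icode[sel]
  xx <- xx[sel]; yy <- yy[sel]; zz <- zz[sel]; bf <- bf[sel]; elem <- elem[sel]

  # drop hydrogens (models are heavy-atom only by convention)
  is_h <- elem == "H" | elem == "D" | (elem == "" & grepl("^[0-9]*H", atom_name))
  if (any(is_h)) {
    k <- !is_h
    atom_name <- atom_name[k]; altloc <- altloc[k]; resname <- resname[k]
    resseq <- resseq[k]; icode <- icode[k]
    xx <- xx[k]; yy <- yy[k]; zz <- zz[k]; bf <- bf[k]
  }

  # altloc: keep first occurrence of (residue, atom name)
  rkey <- paste(resseq, icode, sep = "|")
  dup <- duplicated(paste(rkey, atom_name, sep = "|"))
  if (any(dup)) {
    k <- !dup
    atom_name <- atom_name[k]; resname <- resname[k]
    resseq <- resseq[k]; icode <- icode[k]
    xx <- xx[k]; yy <- yy[k]; zz <- zz[k]; bf <- bf[k]
    rkey <- rkey[k]
  }

  # order residues by (resseq, icode)
  ukey <- unique(rkey)
  urs <- as.integer(sub("\\|.*", "", ukey))
  uic <- sub(".*\\|", "", ukey)
  ord <- order(urs, uic)
  ukey <- ukey[ord]

  ridx <- match(rkey, ukey)
  ca_at <- atom_name == "CA"
  has_ca <- ukey %in% rkey[ca_at]
  dropped <- sum(!has_ca)

  kept_keys <- ukey[has_ca]
  new_idx <- match(rkey, kept_keys)  # NA for dropped residues
  keep_atom <- !is.na(new_idx)

  n <- length(kept_keys)
  ca_rows <- which(ca_at & keep_atom)
  ca_rows <- ca_rows[!duplicated(new_idx[ca_rows])]
  ca_rows <- ca_rows[order(new_idx[ca_rows])]

  m <- structure_model(
    id = id,
    resname = resname[ca_rows],
    ca = cbind(xx[ca_rows], yy[ca_rows], zz[ca_rows]),
    conf = pmin(100, pmax(0, bf[ca_rows])),
    atoms = data.frame(res = new_idx[keep_atom], name = atom_name[keep_atom],
                       x = xx[keep_atom], y = yy[keep_atom], z = zz[keep_atom],
                       stringsAsFactors = FALSE)[order(new_idx[keep_atom]), ],
    chain = chain,
    resid = as.integer(sub("\\|.*", "", kept_keys))
  )
  attr(m, "dropped_no_ca") <- dropped
  m
}

#' Serialize a StructureModel to PDB-format text
#'
#' Confidence is written to the B-factor column (AlphaFold convention).
#'
#' @param m A `StructureModel`.
#' @param chain Chain identifier override.
#' @param serial_start First atom serial number.
#' @return Character vector of PDB lines (no END record).
#' @export
structure_to_pdb <- function(m, chain = NULL, serial_start = 1L) {
  chain <- chain %||% m$chain
  at <- m$atoms
  n <- nrow(at)
  resname <- m$resname[at$res]
  resid <- m$resid[at$res]
  conf <- m$conf[at$res]
  # PDB atom-name column: names < 4 chars start in column 14
  nm <- ifelse(nchar(at$name) >= 4, at$name, paste0(" ", formatC(at$name, width = -3)))
  # columns: serial 7-11, name 13-16, altLoc 17, resName 18-20, chain 22,
  # resSeq 23-26, iCode 27, x/y/z 31-54, occupancy 55-60, B(confidence) 61-66
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          (seq_len(n) + serial_start - 1L) %% 100000L, nm, resname, chain,
          resid %% 10000L, at$x, at$y, at$z, 1.0, conf)
}

#' Write a StructureModel to a PDB file
#' @param m A `StructureModel`.
#' @param path Output file path.
#' @param chain Optional chain identifier override.
#' @return `path`, invisibly.
#' @export
write_structure <- function(m, path, chain = NULL) {
  writeLines(c(structure_to_pdb(m, chain = chain), "END"), path)
  invisible(path)
}

#' Mean per-residue confidence (pLDDT)
#' @param m A `StructureModel`.
#' @return Mean confidence in `[0, 100]`.
#' @export
mean_confidence <- function(m) {
  if (!length(m$conf)) stop("empty model")
  mean(m$conf)
}

#' Construct a StructureSet
#'
#' @param members List of `StructureModel`s (ids must be unique).
#' @param labels Optional named character vector mapping id to a group label
#'   (family, superkingdom).
#' @return An object of class `StructureSet`.
#' @export
structure_set <- function(members, labels = NULL) {
  ids <- vapply(members, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("duplicate ids in structure set")
  names(members) <- ids
  if (!is.null(labels) && is.null(names(labels))) names(labels) <- ids
  structure(list(members = members, labels = labels), class = "StructureSet")
}

#' @export
print.StructureSet <- function(x, ...) {
  cat(sprintf("StructureSet: %d members\n", length(x$members)))
  invisible(x)
}

#' @export
length.StructureSet <- function(x) length(x$members)

#' Filter a StructureSet by mean confidence
#'
#' Removes models whose mean pLDDT is strictly lower than `threshold`
#' (models exactly at the threshold are kept). The removal log is attached as
#' `attr(, "removal_log")`: a data frame with id, mean_confidence, kept.
#'
#' @param s A `StructureSet`.
#' @param threshold Confidence threshold, default 70.
#' @return Filtered `StructureSet`.
#' @export
filter_by_confidence <- function(s, threshold = 70) {
  means <- vapply(s$members, mean_confidence, 0)
  kept <- means >= threshold
  out <- structure_set(s$members[kept],
                       if (!is.null(s$labels)) s$labels[names(s$members)[kept]])
  attr(out, "removal_log") <- data.frame(
    id = names(s$members), mean_confidence = unname(means), kept = unname(kept),
    stringsAsFactors = FALSE)
  out
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

#' Extract the one-letter amino-acid sequence
#'
#' Unknown or non-standard residue codes map to `"X"`.
#'
#' @param m A `StructureModel`.
#' @return Character string of length `n_residues(m)`.
#' @export
extract_sequence <- function(m) {
  aa <- AA3TO1[m$resname]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write the confidence-filter removal log as TSV
#' @param s A filtered `StructureSet` (output of [filter_by_confidence()]).
#' @param path Output TSV path.
#' @param meta Character vector of metadata header lines.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(s, path, meta = character()) {
  log <- attr(s, "removal_log")
  if (is.null(log)) stop("no removal log attached; run filter_by_confidence first")
  write_tsv_meta(log, path, meta)
}
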