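#' Construct an Assembly
#'
#' An ordered collection of (transformed) `StructureModel` copies with an
#' adjacency list. Ring topology includes the wrap-around pair; filament does
#' not.
#'
#' @param copies List of `StructureModel`s (>= 2).
#' @param topology `"ring"` or `"filament"`.
#' @return Object of class `Assembly` with `copies`, `adjacency`
#'   (2-column integer matrix) and `topology`.
#' @export
assembly <- function(copies, topology = c("ring", "filament")) {
  topology <- match.arg(topology)
  n <- length(copies)
  if (n < 2) stop("assembly needs at least 2 copies")
  adj <- cbind(seq_len(n - 1), 2:n)
  if (topology == "ring" && n > 2) adj <- rbind(adj, c(n, 1L))
  structure(list(copies = copies, adjacency = adj, topology = topology),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly (%s): %d copies, %d interfaces\n", x$topology,
              length(x$copies), nrow(x$adjacency)))
  invisible(x)
}

#' Build an assembly by superposing a monomer onto template chains
#'
#' For each template chain, the monomer is structurally aligned to it
#' ([align_structures()]) and the resulting rigid transform is applied to all
#' monomer atoms; adjacency follows consecutive template chain order.
#'
#' @param monomer `StructureModel`.
#' @param template_chains List of `StructureModel`s (>= 2), in chain order.
#' @param topology `"ring"` or `"filament"`.
#' @return An `Assembly` of transformed monomer copies.
#' @export
build_assembly <- function(monomer, template_chains,
                           topology = c("ring", "filament")) {
  topology <- match.arg(topology)
  if (length(template_chains) < 2) stop("need at least 2 template chains")
  copies <- lapply(seq_along(template_chains), function(k) {
    aln <- align_structures(monomer, template_chains[[k]])
    mk <- transform_structure(monomer, aln$transform$rotation,
                              aln$transform$translation)
    mk$id <- sprintf("%s_copy%02d", monomer$id, k)
    mk$chain <- LETTERS[(k - 1) %% 26 + 1]
    mk
  })
  assembly(copies, topology)
}

atom_xyz <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

#' Count inter-chain atomic clashes in an assembly
#'
#' A clash is a heavy atom of one copy within `cutoff` (strict `<`) of any
#' heavy atom of a neighboring (adjacent in chain order) copy. The headline
#' count is the number of distinct atoms of the reference copy that clash
#' with any of its adjacent neighbors. Non-adjacent contacts are reported
#' separately and excluded from the headline count. Implemented with a
#' uniform spatial hash (cell size = cutoff).
#'
#' @param a An `Assembly`.
#' @param cutoff Distance cutoff in Angstrom (default 2.0).
#' @param reference Index of the reference copy (default 1).
#' @return A `ClashReport`: list with `cutoff`, `per_interface` (data frame:
#'   copy_i, copy_j, clash_atom_count = distinct atoms of copy_i within cutoff
#'   of copy_j), `clashing_atoms_of_reference_monomer`,
#'   `total_atoms_of_reference_monomer`, `non_adjacent_contacts`.
#' @export
count_clashes <- function(a, cutoff = 2.0, reference = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- lapply(a$copies, atom_xyz)
  per <- do.call(rbind, lapply(seq_len(nrow(a$adjacency)), function(r) {
    i <- a$adjacency[r, 1]; j <- a$adjacency[r, 2]
    data.frame(copy_i = i, copy_j = j,
               clash_atom_count = length(cpp_clash_atoms(xyz[[i]], xyz[[j]], cutoff)))
  }))
  # reference copy: distinct atoms clashing with any adjacent neighbor
  nb <- unique(c(a$adjacency[a$adjacency[, 1] == reference, 2],
                 a$adjacency[a$adjacency[, 2] == reference, 1]))
  hit <- integer(0)
  for (j in nb) hit <- union(hit, cpp_clash_atoms(xyz[[reference]], xyz[[j]], cutoff))
  # non-adjacent contacts (reference vs all non-neighbors)
  others <- setdiff(seq_along(a$copies), c(reference, nb))
  nonadj <- 0L
  for (j in others) nonadj <- nonadj +
      length(cpp_clash_atoms(xyz[[reference]], xyz[[j]], cutoff))
  structure(list(
    cutoff = cutoff,
    per_interface = per,
    clashing_atoms_of_reference_monomer = length(hit),
    total_atoms_of_reference_monomer = nrow(xyz[[reference]]),
    non_adjacent_contacts = nonadj
  ), class = "ClashReport")
}

#' @export
print.ClashReport <- function(x, ...) {
  cat(sprintf("ClashReport: %d / %d reference-monomer atoms clash at %.1f A\n",
              x$clashing_atoms_of_reference_monomer,
              x$total_atoms_of_reference_monomer, x$cutoff))
  invisible(x)
}

#' Write an assembly as a multi-chain PDB file
#' @param a An `Assembly` (chains written as A, B, C, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(a, path) {
  lines <- character(0)
  serial <- 1L
  for (k in seq_along(a$copies)) {
    ck <- LETTERS[(k - 1) %% 26 + 1]
    lk <- structure_to_pdb(a$copies[[k]], chain = ck, serial_start = serial)
    serial <- serial + length(lk)
    lines <- c(lines, lk, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read all chains of a multi-chain PDB file
#' @param path PDB file path.
#' @param id_prefix Identifier prefix for per-chain models.
#' @return List of `StructureModel`, one per chain, in file order.
#' @export
read_assembly_chains <- function(path, id_prefix = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  ch <- unique(substr(lines[rec == "ATOM  " | rec == "HETATM"], 22, 22))
  if (is.null(id_prefix)) id_prefix <- sub("\\.(pdb|ent)$", "", basename(path))
  lapply(ch, function(c_) read_structure(lines, chain = c_,
                                         id = paste0(id_prefix, "_", c_)))
}
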