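#' Structure coordinates
#'
#' A `structure_coords` object holds one point per alignment column: the
#' Calpha position of a residue (3D, from a PDB file) or a point of a
#' synthetic 2D lattice.  Units are Angstroms.
#'
#' @param coords numeric matrix, one row per site, 2 or 3 columns.
#' @param site_id identifiers, one per row (default `1..N`).
#' @param column optional alignment-column index per site (set by
#'   [map_structure_to_alignment()]).
#' @return An object of class `structure_coords`.
#' @export
structure_coords <- function(coords, site_id = NULL, column = NULL) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), ncol(coords) %in% c(2L, 3L),
            all(is.finite(coords)))
  if (is.null(site_id)) site_id <- seq_len(nrow(coords))
  stopifnot(length(site_id) == nrow(coords))
  structure(list(coords = coords, site_id = site_id, column = column),
            class = "structure_coords")
}

#' @export
print.structure_coords <- function(x, ...) {
  cat("Structure coordinates: ", nrow(x$coords), " sites in ",
      ncol(x$coords), "D", sep = "")
  if (!is.null(attr(x, "grid")))
    cat(" (", attr(x, "grid")["rows"], "x", attr(x, "grid")["cols"],
        " grid, spacing ", attr(x, "grid")["spacing"], " A)", sep = "")
  cat("\n")
  invisible(x)
}

#' Synthetic 2D lattice protein structure
#'
#' A rows x cols regular grid with the given spacing between adjacent
#' points, in row-major site order.  The default 5 Angstrom spacing is
#' comparable to the Calpha distance of physically interacting residues in
#' real proteins.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param spacing lattice constant in Angstroms.
#' @return A [structure_coords()] with a `grid` attribute.
#' @examples
#' g <- make_2d_grid(20, 20)   # the 400-residue toy protein
#' @export
make_2d_grid <- function(rows, cols, spacing = 5) {
  stopifnot(rows >= 1, cols >= 1, spacing > 0)
  ri <- rep(seq_len(rows), each = cols)
  ci <- rep(seq_len(cols), times = rows)
  out <- structure_coords(cbind(x = (ci - 1) * spacing, y = (ri - 1) * spacing))
  attr(out, "grid") <- c(rows = rows, cols = cols, spacing = spacing)
  out
}

#' Read Calpha coordinates from a PDB file
#'
#' Takes the Calpha atom of every residue of one chain, in residue order,
#' from the first model of the file.  Alternate locations other than the
#' first (' ' or 'A') and insertion-code duplicates are dropped; residues
#' without a Calpha are skipped with a warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier (single letter).
#' @return A [structure_coords()] with residue numbers as `site_id`.
#' @export
read_pdb_ca <- function(path, chain) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB read error: ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains)
    stop("chain '", chain, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  nres_total <- length(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[is.na(ca$alt) | ca$alt %in% c("", " ", "A"), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0) stop("chain '", chain, "' has no Calpha atoms")
  if (nrow(ca) < nres_total)
    warning(nres_total - nrow(ca), " residue(s) in chain '", chain,
            "' lack a Calpha atom and were skipped")
  structure_coords(cbind(ca$x, ca$y, ca$z), site_id = ca$resno)
}

#' Map structure residues to alignment columns
#'
#' Assigns each structure residue to the alignment column where the
#' reference taxon (the sequence whose structure is known) has a residue.
#' Columns where the reference is gapped have no coordinates and are
#' excluded from the spatial model; their indices are reported in the
#' `excluded_columns` attribute.
#'
#' @param coords a [structure_coords()], one point per ungapped reference
#'   residue, in sequence order.
#' @param alignment an [aa_alignment()] containing `ref_taxon`.
#' @param ref_taxon name of the reference sequence.
#' @return A [structure_coords()] whose `column` field gives the alignment
#'   column of each site.
#' @export
map_structure_to_alignment <- function(coords, alignment, ref_taxon) {
  stopifnot(inherits(coords, "structure_coords"),
            inherits(alignment, "aa_alignment"))
  if (!ref_taxon %in% rownames(alignment))
    stop("reference taxon '", ref_taxon, "' not in the alignment")
  ref <- alignment[ref_taxon, ]
  ungapped <- which(ref != "-")
  if (length(ungapped) != nrow(coords$coords))
    stop("length mismatch: reference sequence has ", length(ungapped),
         " residues but the structure has ", nrow(coords$coords), " sites")
  out <- structure_coords(coords$coords, site_id = coords$site_id,
                          column = ungapped)
  attr(out, "excluded_columns") <- setdiff(seq_len(ncol(alignment)), ungapped)
  out
}

#' Pairwise Euclidean distance matrix
#'
#' @param coords a [structure_coords()] (or a bare coordinate matrix).
#' @return Symmetric N x N matrix of distances in Angstroms, zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  m <- if (inherits(coords, "structure_coords")) coords$coords else as.matrix(coords)
  D <- as.matrix(dist(m))
  dimnames(D) <- NULL
  D
}
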