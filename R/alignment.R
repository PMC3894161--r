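#' Protein multiple sequence alignments
#'
#' An `aa_alignment` is a character matrix with one row per taxon and one
#' column per alignment site.  Residues are upper-case one-letter amino-acid
#' codes; `-` marks an alignment gap and `X` an unknown or ambiguous residue.
#' Both are treated as missing data by the likelihood.
#'
#' @param x character matrix (taxa in rows) or a list of equal-length
#'   character vectors / single strings, named by taxon.
#' @return An object of class `aa_alignment`.
#' @examples
#' aln <- aa_alignment(list(s1 = "ARND", s2 = "ARNE"))
#' n_sites(aln)
#' @export
aa_alignment <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, function(s) {
      if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "")[[1]] else as.character(s)
    })
    len <- vapply(x, length, integer(1))
    if (length(unique(len)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(len), collapse = ", "), ")")
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("'x' must be a character matrix or list of sequences")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("seq", seq_len(nrow(x)))
  x[] <- toupper(x)
  x[x %in% GAP_CHARS] <- "-"
  known <- x %in% c(AA_ALPHABET, "-")
  x[!known] <- "X"
  structure(x, class = c("aa_alignment", "matrix"))
}

#' @rdname aa_alignment
#' @param aln an `aa_alignment`.
#' @export
n_sites <- function(aln) ncol(aln)

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment: ", nrow(x), " taxa, ", ncol(x), " sites\n", sep = "")
  show <- min(ncol(x), 60L)
  for (i in seq_len(min(nrow(x), 10L)))
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  invisible(x)
}

#' @export
`[.aa_alignment` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("aa_alignment", "matrix")
  out
}

#' Read a protein alignment from FASTA or PHYLIP
#'
#' Sequences are upper-cased; any symbol other than the 20 canonical
#' amino acids or the gap character is mapped to `X` (unknown, treated as
#' missing data).  The format is sniffed from the first non-blank character
#' (`>` means FASTA) unless given explicitly.
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (default), `"fasta"` or `"phylip"`.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("alignment format error: empty file '", path, "'")
    format <- if (startsWith(trimws(first[1]), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    seqs <- tryCatch(
      seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE,
                         forceDNAtolower = FALSE),
      error = function(e) stop("alignment format error: ", conditionMessage(e)))
    if (length(seqs) < 2L) stop("alignment format error: fewer than 2 sequences")
    len <- vapply(seqs, length, integer(1))
    if (length(unique(len)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(len), collapse = ", "), ")")
    aa_alignment(do.call(rbind, seqs))
  } else {
    a <- tryCatch(seqinr::read.alignment(path, format = "phylip"),
                  error = function(e)
                    stop("alignment format error: ", conditionMessage(e)))
    if (is.na(a$nb) || a$nb < 2L || any(!nzchar(trimws(a$nam))))
      stop("alignment format error: could not parse PHYLIP file '", path, "'")
    seqs <- lapply(a$seq, function(s) strsplit(s, "")[[1]])
    names(seqs) <- trimws(a$nam)
    len <- vapply(seqs, length, integer(1))
    if (length(unique(len)) != 1L || any(len == 0L))
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(len), collapse = ", "), ")")
    aa_alignment(do.call(rbind, seqs))
  }
}

#' Write an alignment to FASTA
#'
#' @param aln an [aa_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path)
  invisible(path)
}

# Integer encoding used by the pruning algorithm: 1..20 for amino acids,
# NA for gap/unknown (missing data).
encode_alignment <- function(aln) {
  m <- match(unclass(aln), AA_ALPHABET)
  dim(m) <- dim(aln)
  rownames(m) <- rownames(aln)
  m
}
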