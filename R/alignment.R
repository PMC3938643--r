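AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ALN_ALPHABET <- c(AA20, "X", "-")

#' Construct a family-labelled protein alignment
#'
#' Holds an aligned set of amino-acid sequences together with a per-sequence
#' family label (e.g. eEF1A vs EFL), the shared column space over which
#' family consensus profiles are compared.
#'
#' @param seqs named character vector of aligned sequences (equal lengths;
#'   alphabet: the 20 amino acids, `X`, and the gap `-`), or a character
#'   matrix with sequence ids as rownames.
#' @param family named character vector mapping every sequence id to its
#'   family; exactly two families, each with at least two sequences.
#' @return object of class `labelled_alignment`: list with `mat` (character
#'   matrix, rows = sequences), `family` (named factor), `ids`.
#' @export
labelled_alignment <- function(seqs, family) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    ids0 <- names(seqs)
    seqs <- setNames(toupper(as.character(seqs)), ids0)
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != lens[1]][1]
      stop("ragged alignment: sequence \"", bad, "\" has length ",
           nchar(seqs[[bad]]), ", expected ", lens[1])
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) < 1L) stop("alignment has zero columns")
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequence ids must be unique")
  bad <- which(!(mat %in% ALN_ALPHABET))
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(mat))
    stop(sprintf("illegal character \"%s\" in sequence \"%s\" (column %d)",
                 mat[pos[1], pos[2]], ids[pos[1]], pos[2]))
  }
  if (is.null(names(family))) {
    if (length(family) != nrow(mat)) stop("family labels must be named or per-row")
    names(family) <- ids
  }
  unmapped <- setdiff(ids, names(family))
  if (length(unmapped)) stop("no family for sequence id(s): ",
                             paste(unmapped, collapse = ", "))
  family <- factor(as.character(family[ids]))
  names(family) <- ids
  if (nlevels(family) != 2L) stop("exactly two families are required, got ",
                                  nlevels(family))
  small <- table(family) < 2L
  if (any(small)) stop("each family needs >= 2 sequences; too few in: ",
                       paste(names(which(small)), collapse = ", "))
  if (any(colSums(mat != "-") == 0L)) {
    stop("alignment has all-gap column(s): ",
         paste(utils::head(which(colSums(mat != "-") == 0L)), collapse = ", "))
  }
  structure(list(mat = mat, family = family, ids = ids),
            class = "labelled_alignment")
}

#' Read a labelled alignment from aligned FASTA
#'
#' @param path aligned FASTA file (all records the same length).
#' @param family_map either a two-column TSV file (`id<TAB>family`, no
#'   header required; a header line `id family` is tolerated) or a named
#'   character vector mapping sequence ids to families.
#' @return a [labelled_alignment()].
#' @export
read_alignment <- function(path, family_map) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs)) # first token of FASTA header
  if (is.character(family_map) && length(family_map) == 1L &&
      is.null(names(family_map)) && file.exists(family_map)) {
    fm <- utils::read.delim(family_map, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#",
                            colClasses = "character")
    if (ncol(fm) < 2L) stop("family map must have two columns: id, family")
    if (tolower(fm[1, 1]) %in% c("id", "taxon", "sequence")) fm <- fm[-1, ]
    family_map <- setNames(fm[[2]], fm[[1]])
  }
  labelled_alignment(seqs, family_map)
}

#' Write a labelled alignment (or any named sequences) as FASTA
#'
#' @param x a [labelled_alignment()] or named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqs <- if (inherits(x, "labelled_alignment")) {
    setNames(apply(x$mat, 1, paste, collapse = ""), x$ids)
  } else {
    x
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @export
print.labelled_alignment <- function(x, ...) {
  cat("labelled alignment:", nrow(x$mat), "sequences x", ncol(x$mat),
      "columns\n")
  print(table(x$family))
  invisible(x)
}

#' Map an alignment column to a residue position
#'
#' Converts a 1-based alignment column to the 1-based residue position in one
#' ungapped sequence: the count of non-gap characters in that row up to and
#' including the column.  Returns `NA` (gap marker) when the sequence has a
#' gap at that column.
#'
#' @param aln a [labelled_alignment()].
#' @param seq_id sequence identifier.
#' @param column 1-based alignment column.
#' @return integer residue position, or `NA` for a gap.
#' @examples
#' aln <- labelled_alignment(c(s1 = "A-CD", s2 = "AACD", t1 = "AAC-",
#'                             t2 = "AACD"),
#'                           c(s1 = "A", s2 = "A", t1 = "B", t2 = "B"))
#' map_column(aln, "s1", 3) # 2
#' @export
map_column <- function(aln, seq_id, column) {
  stopifnot(inherits(aln, "labelled_alignment"))
  if (!seq_id %in% aln$ids) stop("unknown sequence id: ", seq_id)
  L <- ncol(aln$mat)
  if (column < 1L || column > L) stop("column out of range 1..", L)
  row <- aln$mat[seq_id, ]
  if (row[column] == "-") return(NA_integer_)
  sum(row[seq_len(column)] != "-")
}
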