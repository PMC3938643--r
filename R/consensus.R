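SITE_CATEGORIES <- c("STRONG_DIFFERENTIAL", "CONSERVED_A_ONLY",
                     "CONSERVED_B_ONLY", "IDENTICALLY_CONSERVED",
                     "UNCONSERVED", "INDEL")

#' Tiered consensus of one family over the shared column space
#'
#' Per column, over all sequences of the family (gaps and `X` count toward the
#' denominator):
#' \itemize{
#'   \item `-` when the gap fraction reaches `threshold_high`;
#'   \item an UPPERCASE residue when its frequency reaches `threshold_high`;
#'   \item a lowercase residue when the plurality residue reaches
#'     `threshold_low` but not `threshold_high` (ties broken alphabetically);
#'   \item `.` when no residue reaches `threshold_low`.
#' }
#' `X` is never reported as the consensus letter.  The result is deterministic
#' and invariant to sequence order.
#'
#' @param aln a [labelled_alignment()].
#' @param family family label (must have >= 2 sequences).
#' @param threshold_high conservation threshold for the uppercase tier,
#'   in (0, 1]; default 0.70.
#' @param threshold_low plurality threshold for the lowercase tier, in
#'   (0, `threshold_high`); default 0.50.
#' @return object of class `consensus_profile`: list with `symbols`
#'   (character vector), `counts` (residue x column tallies), `n`
#'   (sequences in family), the thresholds and the family label.
#' @examples
#' aln <- labelled_alignment(
#'   c(a1 = "ACDE", a2 = "ACDE", b1 = "ACDF", b2 = "ACDF"),
#'   c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
#' as.character(consensus(aln, "A"))
#' @export
consensus <- function(aln, family, threshold_high = 0.70,
                      threshold_low = 0.50) {
  stopifnot(inherits(aln, "labelled_alignment"))
  if (!(threshold_high > 0 && threshold_high <= 1)) {
    stop("threshold_high must be in (0, 1]")
  }
  if (!(threshold_low > 0 && threshold_low < threshold_high)) {
    stop("threshold_low must be in (0, threshold_high)")
  }
  if (!family %in% levels(aln$family)) stop("unknown family: ", family)
  sub <- aln$mat[aln$family == family, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) stop("family ", family, " has fewer than 2 sequences")
  counts <- apply(sub, 2, function(col) {
    tabulate(match(col, ALN_ALPHABET), nbins = length(ALN_ALPHABET))
  })
  rownames(counts) <- ALN_ALPHABET
  eps <- 1e-9
  symbols <- vapply(seq_len(ncol(counts)), function(j) {
    cj <- counts[, j]
    if (cj[["-"]] >= threshold_high * n - eps) return("-")
    res <- cj[AA20]
    top <- which(res == max(res))[1] # alphabetical tie-break (AA20 sorted)
    if (res[top] >= threshold_high * n - eps) return(AA20[top])
    if (res[top] >= threshold_low * n - eps) return(tolower(AA20[top]))
    "."
  }, character(1))
  structure(list(symbols = symbols, counts = counts, n = n,
                 threshold_high = threshold_high,
                 threshold_low = threshold_low, family = family),
            class = "consensus_profile")
}

#' @export
as.character.consensus_profile <- function(x, ...) {
  paste(x$symbols, collapse = "")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus of family %s (%d sequences, thresholds %.2f/%.2f)\n",
              x$family, x$n, x$threshold_high, x$threshold_low))
  s <- as.character(x)
  for (i in seq(1, nchar(s), by = 60)) {
    cat(sprintf("%5d %s\n", i, substr(s, i, min(i + 59, nchar(s)))))
  }
  invisible(x)
}

is_upper_sym <- function(s) s %in% AA20
is_lower_sym <- function(s) s %in% tolower(AA20)

#' Classify alignment columns by differential conservation
#'
#' Compares two family consensus profiles column by column:
#' \itemize{
#'   \item `STRONG_DIFFERENTIAL`: both uppercase, different residues;
#'   \item `IDENTICALLY_CONSERVED`: both uppercase, same residue;
#'   \item `CONSERVED_A_ONLY` / `CONSERVED_B_ONLY`: uppercase in one family
#'     while the other is neither uppercase nor gap;
#'   \item `INDEL`: exactly one profile is a gap;
#'   \item `UNCONSERVED`: everything else.
#' }
#' `chemical_flag` is `TRUE` for strongly differential columns whose two
#' residues fall in different chemical classes (see [chemical_difference()]).
#'
#' @param consA,consB [consensus()] profiles over the same column space.
#' @return data frame of class `site_classification` with columns `column`,
#'   `consA`, `consB`, `category`, `chemical_flag`.
#' @export
classify_sites <- function(consA, consB) {
  stopifnot(inherits(consA, "consensus_profile"),
            inherits(consB, "consensus_profile"))
  a <- consA$symbols; b <- consB$symbols
  if (length(a) != length(b)) {
    stop("profiles differ in length: ", length(a), " vs ", length(b))
  }
  upA <- is_upper_sym(a); upB <- is_upper_sym(b)
  gapA <- a == "-"; gapB <- b == "-"
  category <- rep("UNCONSERVED", length(a))
  category[upA & upB & a == b] <- "IDENTICALLY_CONSERVED"
  category[upA & upB & a != b] <- "STRONG_DIFFERENTIAL"
  category[upA & !upB & !gapB] <- "CONSERVED_A_ONLY"
  category[upB & !upA & !gapA] <- "CONSERVED_B_ONLY"
  category[xor(gapA, gapB)] <- "INDEL"
  chem <- rep(FALSE, length(a))
  sd <- category == "STRONG_DIFFERENTIAL"
  if (any(sd)) chem[sd] <- chemical_difference(a[sd], b[sd])
  out <- data.frame(column = seq_along(a), consA = a, consB = b,
                    category = factor(category, levels = SITE_CATEGORIES),
                    chemical_flag = chem, stringsAsFactors = FALSE)
  class(out) <- c("site_classification", "data.frame")
  out
}

CHEM_CLASSES <- list(aliphatic = c("A", "V", "L", "I", "M", "C"),
                     aromatic = c("F", "W", "Y", "H"),
                     polar = c("S", "T", "N", "Q"),
                     basic = c("K", "R"),
                     acidic = c("D", "E"),
                     glycine = "G",
                     proline = "P")

#' Are two residues chemically different?
#'
#' Residues are grouped into seven fixed chemical classes:
#' \{A,V,L,I,M,C\} aliphatic/sulfur, \{F,W,Y,H\} aromatic, \{S,T,N,Q\} polar,
#' \{K,R\} basic, \{D,E\} acidic, \{G\}, \{P\}.  Two residues are chemically
#' different when they fall in different classes.  `X` is indeterminate and
#' reported as not different.
#'
#' @param resA,resB amino-acid letters (vectorized).
#' @return logical vector.
#' @examples
#' chemical_difference("D", "P") # TRUE
#' chemical_difference("K", "R") # FALSE
#' @export
chemical_difference <- function(resA, resB) {
  resA <- toupper(resA); resB <- toupper(resB)
  ok <- c(AA20, "X")
  if (!all(resA %in% ok) || !all(resB %in% ok)) {
    stop("residues must be amino-acid letters (or X)")
  }
  class_of <- function(r) {
    idx <- vapply(CHEM_CLASSES, function(cl) r %in% cl, logical(1))
    if (!any(idx)) NA_character_ else names(CHEM_CLASSES)[which(idx)]
  }
  mapply(function(x, y) {
    if (x == "X" || y == "X") return(FALSE) # indeterminate
    class_of(x) != class_of(y)
  }, resA, resB, USE.NAMES = FALSE)
}

#' Detect family-specific insertions and deletions from consensus profiles
#'
#' Finds the maximal column runs where exactly one consensus profile is a gap:
#' runs where profile A is the gap are insertions in family B relative to A
#' (`insertion_in_B`); runs where B is the gap are deletions in B
#' (`deletion_in_B`).  A run is flagged `conserved` when at least
#' `min_conserved_fraction` of its columns carry a consensus letter (upper or
#' lower case) in the non-gap profile.
#'
#' @param consA,consB [consensus()] profiles over the same column space.
#' @param min_conserved_fraction run-level conservation threshold.
#' @return data frame of class `indel_report` with columns `start`, `end`
#'   (1-based inclusive), `length`, `direction`, `conserved`; runs are
#'   non-overlapping and sorted.
#' @export
detect_indels <- function(consA, consB, min_conserved_fraction = 0.5) {
  stopifnot(inherits(consA, "consensus_profile"),
            inherits(consB, "consensus_profile"))
  a <- consA$symbols; b <- consB$symbols
  if (length(a) != length(b)) stop("profiles differ in length")
  key <- ifelse(a == "-" & b != "-", "insertion_in_B",
                ifelse(b == "-" & a != "-", "deletion_in_B", "none"))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  rows <- lapply(which(keep), function(i) {
    cols <- starts[i]:ends[i]
    prof <- if (r$values[i] == "insertion_in_B") b[cols] else a[cols]
    cons <- mean(is_upper_sym(prof) | is_lower_sym(prof)) >=
      min_conserved_fraction
    data.frame(start = starts[i], end = ends[i], length = r$lengths[i],
               direction = r$values[i], conserved = cons,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               direction = character(0), conserved = logical(0),
               stringsAsFactors = FALSE)
  class(out) <- c("indel_report", "data.frame")
  out
}

#' Mean C-terminal extension of one family beyond the other
#'
#' For each sequence of family `family_a`, counts the residues lying
#' C-terminal to the last column where the `family_b` consensus is non-gap,
#' and returns the mean over family-A sequences (in amino acids).
#'
#' @param aln a [labelled_alignment()].
#' @param family_a family whose tails are measured (default: first level).
#' @param family_b reference family (default: second level).
#' @param threshold_high,threshold_low thresholds for the family-B consensus.
#' @return mean extension length (non-negative real).
#' @export
cterm_extension <- function(aln, family_a = levels(aln$family)[1],
                            family_b = levels(aln$family)[2],
                            threshold_high = 0.70, threshold_low = 0.50) {
  stopifnot(inherits(aln, "labelled_alignment"))
  consB <- consensus(aln, family_b, threshold_high, threshold_low)
  nz <- which(consB$symbols != "-")
  lastB <- if (length(nz)) max(nz) else 0L
  L <- ncol(aln$mat)
  rows <- aln$mat[aln$family == family_a, , drop = FALSE]
  if (lastB >= L) return(0)
  tailcols <- (lastB + 1L):L
  mean(rowSums(rows[, tailcols, drop = FALSE] != "-"))
}

#' Write a site classification as TSV
#'
#' @param x a [classify_sites()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_classification <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
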