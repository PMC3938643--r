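FACTOR_STATES <- c("PRESENT", "DIVERGENT", "ABSENT")

parse_state_token <- function(token) {
  key <- tolower(trimws(token))
  out <- rep(NA_character_, length(key))
  out[key %in% c("present", "p", "1")] <- "PRESENT"
  out[key %in% c("divergent", "d", "0.5", ".5")] <- "DIVERGENT"
  out[key %in% c("absent", "a", "0")] <- "ABSENT"
  out
}

#' Construct a taxon-by-factor presence table
#'
#' A `factor_table` records, per taxon, the state of each of the three
#' elongation factors as `PRESENT`, `DIVERGENT` (detectable but decaying
#' sequence) or `ABSENT`.
#'
#' @param taxon character vector of unique taxon identifiers.
#' @param eEF1A,eEF1Ba,EFL per-taxon state tokens (case-insensitive
#'   present/divergent/absent, or 1/0.5/0).
#' @param lineage optional per-taxon group label.
#' @return a data frame of class `factor_table` with columns `taxon`,
#'   `lineage`, `eEF1A`, `eEF1Ba`, `EFL`.
#' @export
factor_table <- function(taxon, eEF1A, eEF1Ba, EFL, lineage = NULL) {
  taxon <- gsub("\\s+", " ", trimws(as.character(taxon)))
  n <- length(taxon)
  if (n < 1L) stop("factor table must have at least one taxon")
  if (anyDuplicated(taxon)) {
    stop("duplicate taxon identifier(s): ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  }
  states <- list(eEF1A = eEF1A, eEF1Ba = eEF1Ba, EFL = EFL)
  for (col in names(states)) {
    if (length(states[[col]]) != n) stop("column ", col, " has wrong length")
    parsed <- parse_state_token(states[[col]])
    if (anyNA(parsed)) {
      i <- which(is.na(parsed))[1]
      stop(sprintf("unknown state token \"%s\" (taxon \"%s\", column %s)",
                   states[[col]][i], taxon[i], col))
    }
    states[[col]] <- parsed
  }
  if (is.null(lineage)) lineage <- rep(NA_character_, n)
  out <- data.frame(taxon = taxon, lineage = as.character(lineage),
                    eEF1A = states$eEF1A, eEF1Ba = states$eEF1Ba,
                    EFL = states$EFL, stringsAsFactors = FALSE)
  class(out) <- c("factor_table", "data.frame")
  out
}

#' Read a taxon-by-factor table from TSV
#'
#' Expects a header row naming the taxon column, an optional `lineage` column,
#' and the three factor columns (`eEF1A`, `eEF1Ba`/`eEF1Balpha`/`eEF1Bα`,
#' `EFL`, in any order); one row per taxon.  State tokens are
#' case-insensitive `present`/`divergent`/`absent` or `1`/`0.5`/`0`.
#'
#' @param path path to a tab-separated file.
#' @return a [factor_table].
#' @export
read_factor_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  if (nrow(raw) < 1L) stop("factor table file has no data rows: ", path)
  nm <- names(raw)
  find_gene_col <- function(gene) {
    hit <- which(vapply(nm, function(x) {
      ok <- tryCatch(normalize_gene(x), error = function(e) NA_character_)
      identical(ok, gene)
    }, logical(1)))
    if (length(hit) != 1L) {
      stop("factor table must have exactly one column for ", gene)
    }
    hit
  }
  gcols <- vapply(RATCHET_GENES, find_gene_col, 1L)
  lin_col <- which(tolower(nm) == "lineage")
  tax_col <- which(tolower(nm) %in% c("taxon", "taxa", "species"))
  if (length(tax_col) == 0L) {
    tax_col <- setdiff(seq_along(nm), c(gcols, lin_col))[1]
    if (is.na(tax_col)) stop("no taxon column found")
  } else {
    tax_col <- tax_col[1]
  }
  factor_table(taxon = raw[[tax_col]],
               eEF1A = raw[[gcols["eEF1A"]]],
               eEF1Ba = raw[[gcols["eEF1Ba"]]],
               EFL = raw[[gcols["EFL"]]],
               lineage = if (length(lin_col)) raw[[lin_col[1]]] else NULL)
}

#' Write a factor table to TSV
#'
#' @param table a [factor_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_factor_table <- function(table, path) {
  stopifnot(inherits(table, "factor_table"))
  out <- as.data.frame(table)
  for (col in RATCHET_GENES) out[[col]] <- tolower(out[[col]])
  out$lineage <- ifelse(is.na(out$lineage), "", out$lineage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.factor_table <- function(x, ...) {
  cat("factor table:", nrow(x), "taxa\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Binarize three-valued factor states
#'
#' `PRESENT` maps to `TRUE` and `ABSENT` to `FALSE` always; `DIVERGENT`
#' follows the chosen convention.  Reporting results under both conventions
#' shows whether conclusions depend on how decaying sequences are scored.
#'
#' @param table a [factor_table].
#' @param convention `"divergent_as_present"` or `"divergent_as_absent"`.
#' @return logical matrix (taxa x factors) with taxon rownames.
#' @export
binarize <- function(table, convention = c("divergent_as_present",
                                           "divergent_as_absent")) {
  convention <- match.arg(convention)
  stopifnot(inherits(table, "factor_table"))
  m <- as.matrix(table[, RATCHET_GENES])
  out <- m == "PRESENT" |
    (m == "DIVERGENT" & convention == "divergent_as_present")
  rownames(out) <- table$taxon
  out
}

#' Tabulate EFL presence against other-factor presence
#'
#' Builds the 2x2 contingency table with rows EFL present/absent and columns
#' comparison-factor present/absent, where the comparison factor is eEF1A,
#' eEF1Ba, or both jointly (`"both"` = eEF1A AND eEF1Ba present).
#'
#' @param table a [factor_table] with at least one taxon.
#' @param convention divergent-handling flag, see [binarize()].
#' @param comparison `"EFL_vs_both"`, `"EFL_vs_eEF1A"` or `"EFL_vs_eEF1Ba"`.
#' @return 2x2 integer matrix; counts sum to the number of taxa.
#' @export
contingency <- function(table,
                        convention = c("divergent_as_present",
                                       "divergent_as_absent"),
                        comparison = c("EFL_vs_both", "EFL_vs_eEF1A",
                                       "EFL_vs_eEF1Ba")) {
  convention <- match.arg(convention)
  comparison <- match.arg(comparison)
  stopifnot(inherits(table, "factor_table"))
  if (nrow(table) < 1L) stop("empty factor table")
  b <- binarize(table, convention)
  efl <- b[, "EFL"]
  other <- switch(comparison,
    EFL_vs_both = b[, "eEF1A"] & b[, "eEF1Ba"],
    EFL_vs_eEF1A = b[, "eEF1A"],
    EFL_vs_eEF1Ba = b[, "eEF1Ba"])
  counts <- matrix(c(sum(efl & other), sum(efl & !other),
                     sum(!efl & other), sum(!efl & !other)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c("EFL_present", "EFL_absent"),
                                   c("other_present", "other_absent")))
  storage.mode(counts) <- "integer"
  counts
}

#' Collapse a factor table to one pseudo-taxon per lineage
#'
#' Taxa sharing a lineage label are not independent observations; this
#' reduces each lineage to a single row carrying the majority state per
#' factor (ties broken in favour of the more intact state:
#' PRESENT > DIVERGENT > ABSENT).  Rows without a lineage label are kept
#' as they are.
#'
#' @param table a [factor_table] with lineage labels.
#' @return a [factor_table] with one row per lineage.
#' @export
collapse_by_lineage <- function(table) {
  stopifnot(inherits(table, "factor_table"))
  has_lin <- !is.na(table$lineage) & nzchar(table$lineage)
  majority <- function(x) {
    tab <- table(factor(x, levels = FACTOR_STATES))
    FACTOR_STATES[which.max(tab)] # ties: first level wins (PRESENT first)
  }
  groups <- split(which(has_lin), table$lineage[has_lin])
  rows <- lapply(names(groups), function(lin) {
    idx <- groups[[lin]]
    data.frame(taxon = lin, lineage = lin,
               eEF1A = majority(table$eEF1A[idx]),
               eEF1Ba = majority(table$eEF1Ba[idx]),
               EFL = majority(table$EFL[idx]), stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, rows),
               as.data.frame(table)[!has_lin, , drop = FALSE])
  factor_table(out$taxon, out$eEF1A, out$eEF1Ba, out$EFL, out$lineage)
}

#' Association report across comparisons and conventions
#'
#' Runs the exact association test for all three EFL-versus-other
#' comparisons under both divergent-handling conventions (6 results).
#'
#' @param table a [factor_table].
#' @return data frame of class `association_report` with one row per result:
#'   comparison, convention, the four cell counts, odds ratio, two-sided p,
#'   and the degenerate flag.
#' @export
association_report <- function(table) {
  stopifnot(inherits(table, "factor_table"))
  comparisons <- c("EFL_vs_both", "EFL_vs_eEF1A", "EFL_vs_eEF1Ba")
  conventions <- c("divergent_as_present", "divergent_as_absent")
  rows <- list()
  for (cmp in comparisons) {
    for (cv in conventions) {
      counts <- contingency(table, cv, cmp)
      res <- exact_association_test(counts)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp, convention = cv,
        efl_pos_other_pos = counts[1, 1], efl_pos_other_neg = counts[1, 2],
        efl_neg_other_pos = counts[2, 1], efl_neg_other_neg = counts[2, 2],
        odds_ratio = res$odds_ratio, p_two_sided = res$p_two_sided,
        degenerate = res$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("association_report", "data.frame")
  out
}

#' Write an association report as TSV or JSON
#'
#' @param report an [association_report()] result.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
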