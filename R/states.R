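# Gene-content state space for the elongation-factor ratchet.
#
# One-step mode: a state is a subset of {eEF1A, eEF1Ba, EFL}, encoded as a
# 3-bit integer (eEF1A = 1, eEF1Ba = 2, EFL = 4).  Two-step mode: each gene is
# present (P), divergent (D, nonfunctional) or absent (A), encoded base-3.

RATCHET_GENES <- c("eEF1A", "eEF1Ba", "EFL")
GENE_BITS <- c(eEF1A = 1L, eEF1Ba = 2L, EFL = 4L)
TRIT_LETTERS <- c("A", "D", "P") # value 0, 1, 2

#' Normalize elongation-factor gene names
#'
#' Accepts common spellings of the three factors, including ASCII aliases for
#' the Greek-lettered GEF subunit ("eEF1Ba", "eEF1Balpha", "eEF1Bα").
#'
#' @param x character vector of gene names.
#' @return character vector with elements in `c("eEF1A", "eEF1Ba", "EFL")`.
#' @export
normalize_gene <- function(x) {
  key <- tolower(trimws(x))
  out <- character(length(key))
  out[key %in% c("eef1a", "ef1a")] <- "eEF1A"
  out[key %in% c("eef1ba", "eef1balpha", "eef1b-alpha",
                 "eef1bα", "ef1ba", "ef1balpha")] <- "eEF1Ba"
  out[key == "efl"] <- "EFL"
  bad <- !nzchar(out)
  if (any(bad)) {
    stop("unknown gene name(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Encode a gene set as a state code
#'
#' @param genes character vector of gene names forming one state (empty vector
#'   or `"none"` for the empty set), or a single `"g1+g2"` style label.
#' @return integer state code in 0..7.
#' @export
state_code <- function(genes) {
  if (length(genes) == 0L) return(0L)
  if (length(genes) == 1L) {
    if (!nzchar(genes) || tolower(genes) == "none") return(0L)
    genes <- strsplit(genes, "+", fixed = TRUE)[[1]]
  }
  sum(GENE_BITS[unique(normalize_gene(genes))])
}

#' Decode a state code into its gene set
#'
#' @param code integer state code in 0..7.
#' @return character vector of gene names.
#' @export
state_genes <- function(code) {
  stopifnot(length(code) == 1L, code >= 0, code <= 7)
  RATCHET_GENES[bitwAnd(as.integer(code), GENE_BITS) > 0L]
}

#' Human-readable label for state codes
#'
#' One-step codes (0..7) render as `"eEF1A+eEF1Ba"`-style gene lists (`"none"`
#' for the empty set).  Two-step codes render as three letters from
#' \{P, D, A\} (present / divergent / absent) in gene order eEF1A, eEF1Ba, EFL,
#' e.g. `"PPA"`.
#'
#' @param code integer vector of state codes.
#' @param mode `"one_step"` or `"two_step"`.
#' @return character vector of labels.
#' @export
state_label <- function(code, mode = c("one_step", "two_step")) {
  mode <- match.arg(mode)
  code <- as.integer(code)
  if (mode == "one_step") {
    vapply(code, function(s) {
      if (is.na(s)) return(NA_character_)
      if (s < 0L) return("extinct")
      g <- state_genes(s)
      if (length(g) == 0L) "none" else paste(g, collapse = "+")
    }, character(1))
  } else {
    vapply(code, function(s) {
      if (is.na(s)) return(NA_character_)
      if (s < 0L) return("extinct")
      v <- trits(s)
      paste(TRIT_LETTERS[v + 1L], collapse = "")
    }, character(1))
  }
}

trits <- function(code) {
  c(code %% 3L, (code %/% 3L) %% 3L, code %/% 9L)
}

from_trits <- function(v) {
  as.integer(v[1] + 3L * v[2] + 9L * v[3])
}

as_state_code <- function(state, mode = "one_step") {
  if (is.numeric(state)) {
    code <- as.integer(state)
    lim <- if (mode == "one_step") 7L else 26L
    if (any(code < 0L | code > lim)) stop("state code out of range")
    return(code)
  }
  if (is.character(state)) {
    if (mode == "one_step") {
      if (length(state) > 1L) return(state_code(state)) # a gene set
      return(vapply(state, state_code, 1L, USE.NAMES = FALSE))
    }
    # two-step: letter triples like "PPA"
    return(vapply(state, function(s) {
      v <- match(strsplit(s, "")[[1]], TRIT_LETTERS) - 1L
      if (length(v) != 3L || anyNA(v)) stop("bad two-step state label: ", s)
      from_trits(v)
    }, 1L, USE.NAMES = FALSE))
  }
  stop("cannot interpret state of class ", class(state)[1])
}

# Functional gene content of a state: logical triple (eEF1A, eEF1Ba, EFL).
functional_genes <- function(code, mode) {
  if (mode == "one_step") {
    bitwAnd(code, GENE_BITS) > 0L
  } else {
    trits(code) == 2L
  }
}

viable_code <- function(code, mode) {
  f <- functional_genes(code, mode)
  f[3] || (f[1] && f[2])
}

#' Viability of a gene-content state
#'
#' A state is viable when it retains a working elongation system: either EFL is
#' present, or both eEF1A and its exchange factor eEF1Ba are present.  Five of
#' the eight gene-content subsets are viable; the empty set, eEF1A alone and
#' eEF1Ba alone are lethal.
#'
#' @param state integer state code(s) in 0..7, a `"g1+g2"` label vector, or a
#'   character vector of gene names forming a single state.
#' @return logical vector.
#' @examples
#' viable("EFL")
#' viable(c("eEF1A+eEF1Ba", "eEF1A", "none"))
#' @export
viable <- function(state) {
  code <- as_state_code(state)
  vapply(code, viable_code, logical(1), mode = "one_step")
}

one_step_codes <- 0:7
two_step_codes <- 0:26
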