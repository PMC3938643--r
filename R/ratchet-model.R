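#' Specify a gene gain/loss ratchet model
#'
#' Defines a continuous-time Markov process over gene-content states of the
#' elongation-factor triple \{eEF1A, eEF1Ba, EFL\}.  Genes are lost
#' independently at per-gene rates; EFL (and only EFL) can be regained by
#' horizontal gene transfer.  Loss events whose end state would be lethal (no
#' working elongation system, see [viable()]) are either rejected (purifying
#' selection, the default) or kill the lineage (`lethal_policy = "extinct"`).
#' Because neither eEF1A nor eEF1Ba has a gain channel, loss of either factor
#' while EFL is present is irreversible: the pawl of the ratchet.
#'
#' In `two_step` divergence mode each gene passes through an intermediate
#' `divergent` (nonfunctional) stage: intact -> divergent at `divergence_rate`,
#' divergent -> absent at `loss_rate`.  Viability counts intact copies only.
#'
#' Rates are per unit branch length; the time scale is set by the tree.
#' Default rates are placeholders and carry no empirical meaning: set them (or
#' estimate them with [fit_rates()]) for any real analysis.
#'
#' @param loss_rate nonnegative per-gene loss rate; scalar or named length-3
#'   vector over `c("eEF1A", "eEF1Ba", "EFL")`.
#' @param hgt_rate nonnegative EFL gain rate, active only while EFL is absent.
#' @param divergence_mode `"one_step"` (present -> absent) or `"two_step"`
#'   (present -> divergent -> absent).
#' @param divergence_rate intact -> divergent rate for `two_step` mode; scalar
#'   or named length-3 vector.  Defaults to `loss_rate`.
#' @param lethal_policy `"reject"` (lethal transitions are suppressed) or
#'   `"extinct"` (lethal transitions kill the lineage; simulation only).
#' @param root_state state at the tree root: a state code, a label, or a
#'   character vector of gene names.  Must be viable.  Default is the inferred
#'   eukaryote ancestral condition, eEF1A + eEF1Ba without EFL.
#' @return an object of class `ratchet_model`.
#' @examples
#' m <- ratchet_model(loss_rate = 0.5, hgt_rate = 0.1,
#'                    root_state = c("eEF1A", "eEF1Ba", "EFL"))
#' rate_matrix(m)
#' @export
ratchet_model <- function(loss_rate = 0.1, hgt_rate = 0,
                          divergence_mode = c("one_step", "two_step"),
                          divergence_rate = loss_rate,
                          lethal_policy = c("reject", "extinct"),
                          root_state = c("eEF1A", "eEF1Ba")) {
  divergence_mode <- match.arg(divergence_mode)
  lethal_policy <- match.arg(lethal_policy)
  loss_rate <- expand_gene_rate(loss_rate, "loss_rate")
  divergence_rate <- expand_gene_rate(divergence_rate, "divergence_rate")
  if (length(hgt_rate) != 1L || is.na(hgt_rate) || hgt_rate < 0) {
    stop("hgt_rate must be a single nonnegative number")
  }
  root <- as_state_code(root_state, "one_step")
  if (length(root) != 1L) stop("root_state must be a single state")
  if (!viable(root)) stop("root_state must be viable")
  if (divergence_mode == "two_step") {
    # lift the gene-set root to all-intact trits
    bits <- functional_genes(root, "one_step")
    root <- from_trits(ifelse(bits, 2L, 0L))
  }
  m <- structure(
    list(loss_rate = loss_rate, hgt_rate = as.numeric(hgt_rate),
         divergence_mode = divergence_mode, divergence_rate = divergence_rate,
         lethal_policy = lethal_policy, root_state = root),
    class = "ratchet_model"
  )
  m
}

expand_gene_rate <- function(r, what) {
  if (length(r) == 1L) r <- rep(as.numeric(r), 3L)
  if (is.null(names(r)) || !all(nzchar(names(r)))) {
    names(r) <- RATCHET_GENES
  } else {
    names(r) <- normalize_gene(names(r))
    if (!setequal(names(r), RATCHET_GENES)) {
      stop(what, " must name all of ", paste(RATCHET_GENES, collapse = ", "))
    }
    r <- r[RATCHET_GENES]
  }
  if (anyNA(r) || any(r < 0)) stop(what, " must be nonnegative")
  r
}

#' @export
print.ratchet_model <- function(x, ...) {
  cat("Elongation-factor ratchet model (", x$divergence_mode, ", lethal = ",
      x$lethal_policy, ")\n", sep = "")
  cat("  loss rates:      ",
      paste(sprintf("%s=%g", names(x$loss_rate), x$loss_rate), collapse = ", "),
      "\n", sep = "")
  if (x$divergence_mode == "two_step") {
    cat("  divergence rates:",
        paste(sprintf("%s=%g", names(x$divergence_rate), x$divergence_rate),
              collapse = ", "), "\n", sep = " ")
  }
  cat("  EFL HGT rate:    ", x$hgt_rate, "\n", sep = "")
  cat("  root state:      ", state_label(x$root_state, x$divergence_mode),
      "\n", sep = "")
  invisible(x)
}

# Enumerate the outgoing moves of every state.  Returns a list with one entry
# per state code (index = code + 1): list(target, rate, event, gene, total).
# Under the reject policy, moves into inviable states are dropped; under
# extinct they are kept (the simulator then kills the lineage).
state_moves <- function(model) {
  mode <- model$divergence_mode
  codes <- if (mode == "one_step") one_step_codes else two_step_codes
  reject <- model$lethal_policy == "reject"
  lapply(codes, function(s) {
    tg <- integer(0); rt <- numeric(0); ev <- character(0); gn <- character(0)
    if (mode == "one_step") {
      for (i in seq_along(RATCHET_GENES)) {
        if (bitwAnd(s, GENE_BITS[i]) > 0L) {
          t <- s - GENE_BITS[i]
          if (!reject || viable_code(t, mode)) {
            tg <- c(tg, t); rt <- c(rt, model$loss_rate[i])
            ev <- c(ev, "loss"); gn <- c(gn, RATCHET_GENES[i])
          }
        }
      }
      if (bitwAnd(s, GENE_BITS["EFL"]) == 0L) {
        tg <- c(tg, s + GENE_BITS[["EFL"]]); rt <- c(rt, model$hgt_rate)
        ev <- c(ev, "gain"); gn <- c(gn, "EFL")
      }
    } else {
      v <- trits(s)
      for (i in 1:3) {
        if (v[i] == 2L) { # intact -> divergent
          w <- v; w[i] <- 1L; t <- from_trits(w)
          if (!reject || viable_code(t, mode)) {
            tg <- c(tg, t); rt <- c(rt, model$divergence_rate[i])
            ev <- c(ev, "divergence"); gn <- c(gn, RATCHET_GENES[i])
          }
        } else if (v[i] == 1L) { # divergent -> absent (never changes viability)
          w <- v; w[i] <- 0L
          tg <- c(tg, from_trits(w)); rt <- c(rt, model$loss_rate[i])
          ev <- c(ev, "loss"); gn <- c(gn, RATCHET_GENES[i])
        }
      }
      if (v[3] == 0L) {
        w <- v; w[3] <- 2L
        tg <- c(tg, from_trits(w)); rt <- c(rt, model$hgt_rate)
        ev <- c(ev, "gain"); gn <- c(gn, "EFL")
      }
    }
    keep <- rt > 0
    list(target = tg[keep], rate = rt[keep], event = ev[keep],
         gene = gn[keep], total = sum(rt[keep]))
  })
}

viable_codes <- function(mode) {
  codes <- if (mode == "one_step") one_step_codes else two_step_codes
  codes[vapply(codes, viable_code, logical(1), mode = mode)]
}

#' Transition rate matrix over viable states
#'
#' Builds the infinitesimal generator Q of the ratchet process restricted to
#' viable states under the rejection (purifying-selection) policy: one row and
#' column per viable state, off-diagonal entries equal to the per-gene loss
#' rate for each permitted single-gene loss and to the HGT rate for EFL gain,
#' diagonal entries set so rows sum to zero.  There is no flux into inviable
#' states by construction.
#'
#' @param model a [ratchet_model()] with `lethal_policy = "reject"`.
#' @return square numeric matrix with state labels as dimnames.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "ratchet_model"))
  if (model$lethal_policy != "reject") {
    stop("rate_matrix is defined only for lethal_policy = \"reject\"")
  }
  mode <- model$divergence_mode
  codes <- viable_codes(mode)
  moves <- state_moves(model)
  k <- length(codes)
  Q <- matrix(0, k, k,
              dimnames = rep(list(state_label(codes, mode)), 2L))
  idx <- setNames(seq_len(k), as.character(codes))
  for (i in seq_len(k)) {
    mv <- moves[[codes[i] + 1L]]
    for (j in seq_along(mv$target)) {
      Q[i, idx[[as.character(mv$target[j])]]] <-
        Q[i, idx[[as.character(mv$target[j])]]] + mv$rate[j]
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  attr(Q, "codes") <- codes
  attr(Q, "mode") <- mode
  Q
}
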