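#' Simulate the ratchet process along a phylogeny
#'
#' Exact (Gillespie) stochastic simulation of the gene gain/loss process on a
#' rooted tree with branch lengths: along each branch, waiting times are drawn
#' from the exponential distribution with the current state's total outflow
#' rate and events are chosen proportionally to their rates; children inherit
#' the parent's end state.  Branches are visited in deterministic preorder, so
#' results are reproducible given `seed`.
#'
#' Under `lethal_policy = "extinct"` a lethal transition marks the lineage and
#' all its descendants `extinct`; under the default `reject` policy lethal
#' transitions never fire.
#'
#' @param object a [ratchet_model()].
#' @param nsim number of independent histories.
#' @param seed optional integer seed.
#' @param tree a rooted `phylo` tree with positive branch lengths.
#' @param ... unused.
#' @return for `nsim = 1` a `ratchet_history`: list with the tree, the model,
#'   `node_states` (codes for every node), `tip_states` (named labels),
#'   `tip_codes`, and an event log data frame (`edge`, `parent`, `child`,
#'   `time` along the branch, `event`, `gene`, `from`, `to`, `reversal`).
#'   For `nsim > 1`, a list of histories (class `ratchet_history_list`).
#' @examples
#' tr <- make_tree(8, seed = 1)
#' m <- ratchet_model(loss_rate = 1, root_state = c("eEF1A", "eEF1Ba", "EFL"))
#' h <- simulate(m, seed = 42, tree = tr)
#' summary(h)
#' @export
simulate.ratchet_model <- function(object, nsim = 1, seed = NULL, tree, ...) {
  if (!is.null(seed)) set.seed(seed)
  check_tree(tree)
  if (nsim == 1L) return(sim_one_history(object, tree, seed))
  out <- lapply(seq_len(nsim), function(i) sim_one_history(object, tree, NULL))
  class(out) <- "ratchet_history_list"
  out
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

sim_one_history <- function(model, tree, seed) {
  mode <- model$divergence_mode
  moves <- state_moves(model)
  vmask <- vapply(
    if (mode == "one_step") one_step_codes else two_step_codes,
    viable_code, logical(1), mode = mode)
  extinct_policy <- model$lethal_policy == "extinct"

  tree <- ape::reorder.phylo(tree, "cladewise") # preorder: parents first
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- rep(NA_integer_, nnode)
  lostmask <- integer(nnode) # bitmask of genes that suffered a loss event
  root <- ntip + 1L
  states[root] <- model$root_state

  ev_edge <- integer(0); ev_time <- numeric(0); ev_event <- character(0)
  ev_gene <- character(0); ev_from <- integer(0); ev_to <- integer(0)
  ev_child <- integer(0); ev_parent <- integer(0); ev_rev <- logical(0)

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    s <- states[parent]; lost <- lostmask[parent]
    if (s < 0L) { states[child] <- -1L; lostmask[child] <- lost; next }
    tpos <- 0
    repeat {
      mv <- moves[[s + 1L]]
      if (mv$total <= 0) break
      w <- rexp(1L, mv$total)
      if (tpos + w > len) break
      tpos <- tpos + w
      j <- if (length(mv$rate) == 1L) 1L else
        sample.int(length(mv$rate), 1L, prob = mv$rate)
      gbit <- GENE_BITS[[mv$gene[j]]]
      rev <- mv$event[j] == "gain" && bitwAnd(lost, gbit) > 0L
      ev_edge <- c(ev_edge, e); ev_time <- c(ev_time, tpos)
      ev_event <- c(ev_event, mv$event[j]); ev_gene <- c(ev_gene, mv$gene[j])
      ev_from <- c(ev_from, s); ev_to <- c(ev_to, mv$target[j])
      ev_child <- c(ev_child, child); ev_parent <- c(ev_parent, parent)
      ev_rev <- c(ev_rev, rev)
      if (mv$event[j] == "loss") lost <- bitwOr(lost, gbit)
      s <- mv$target[j]
      if (extinct_policy && !vmask[s + 1L]) { s <- -1L; break }
    }
    states[child] <- s
    lostmask[child] <- lost
  }

  events <- data.frame(edge = ev_edge, parent = ev_parent, child = ev_child,
                       time = ev_time, event = ev_event, gene = ev_gene,
                       from = ev_from, to = ev_to, reversal = ev_rev,
                       stringsAsFactors = FALSE)
  tip_codes <- states[seq_len(ntip)]
  names(tip_codes) <- tree$tip.label
  structure(
    list(tree = tree, model = model, node_states = states,
         tip_codes = tip_codes,
         tip_states = setNames(state_label(tip_codes, mode), tree$tip.label),
         events = events, seed = seed),
    class = "ratchet_history")
}

#' Sample end states of the ratchet process on a single branch
#'
#' Runs `n` independent realizations of the jump process from `state` for
#' duration `t` and returns the end-state codes.  This is the Monte-Carlo
#' counterpart of [propagate()] for one branch, useful for calibration checks
#' and large-replicate experiments without building trees.
#'
#' @param model a [ratchet_model()].
#' @param t branch length (>= 0).
#' @param n number of replicates.
#' @param seed optional integer seed.
#' @param state starting state (default: the model's root state).
#' @return integer vector of `n` end-state codes (`-1` = extinct).
#' @export
ratchet_branch_sample <- function(model, t, n = 1L, seed = NULL,
                                  state = model$root_state) {
  stopifnot(inherits(model, "ratchet_model"), t >= 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mode <- model$divergence_mode
  s0 <- as_state_code(state, mode)
  moves <- state_moves(model)
  vmask <- vapply(
    if (mode == "one_step") one_step_codes else two_step_codes,
    viable_code, logical(1), mode = mode)
  extinct_policy <- model$lethal_policy == "extinct"
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- s0; tpos <- 0
    repeat {
      mv <- moves[[s + 1L]]
      if (mv$total <= 0) break
      tpos <- tpos + rexp(1L, mv$total)
      if (tpos > t) break
      j <- if (length(mv$rate) == 1L) 1L else
        sample.int(length(mv$rate), 1L, prob = mv$rate)
      s <- mv$target[j]
      if (extinct_policy && !vmask[s + 1L]) { s <- -1L; break }
    }
    out[i] <- s
  }
  out
}

#' Replay the event log of a simulated history
#'
#' Reconstructs all node states by applying the logged events from the root
#' state down the tree.  Used to verify the internal consistency of a
#' `ratchet_history`: the replayed tip states must equal the stored ones.
#'
#' @param history a `ratchet_history`.
#' @return integer vector of node state codes, as in `history$node_states`.
#' @export
replay_history <- function(history) {
  stopifnot(inherits(history, "ratchet_history"))
  tree <- history$tree
  ntip <- length(tree$tip.label)
  states <- rep(NA_integer_, ntip + tree$Nnode)
  states[ntip + 1L] <- history$model$root_state
  ev <- history$events
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    s <- states[parent]
    if (!is.na(s) && s >= 0L) {
      rows <- which(ev$edge == e)
      if (length(rows)) {
        rows <- rows[order(ev$time[rows])]
        for (r in rows) {
          if (ev$from[r] != s) stop("event log inconsistent on edge ", e)
          s <- ev$to[r]
        }
      }
      if (history$model$lethal_policy == "extinct" &&
          !viable_code(s, history$model$divergence_mode)) s <- -1L
    }
    states[child] <- s
  }
  states
}

#' @export
print.ratchet_history <- function(x, ...) {
  cat("ratchet history:", length(x$tip_codes), "tips,",
      nrow(x$events), "events\n")
  print(table(x$tip_states))
  invisible(x)
}

#' Summary statistics of a simulated ratchet history
#'
#' Tabulates tip states and counts the process features of interest: the
#' number of replacement events (eEF1A losses that occurred while EFL was
#' present — the ratchet's pawl engaging), tips co-maintaining eEF1A and EFL,
#' and reversal events (gain of a gene that had previously been lost on the
#' same lineage; necessarily zero when the HGT rate is zero).
#'
#' @param object a `ratchet_history`.
#' @param ... unused.
#' @return list of class `ratchet_history_summary` with elements
#'   `tip_state_freq`, `n_tips`, `n_events`, `n_replacements`,
#'   `n_comaintained`, `n_reversals`, `n_extinct`.
#' @export
summary.ratchet_history <- function(object, ...) {
  mode <- object$model$divergence_mode
  ev <- object$events
  from_f <- vapply(ev$from, function(s) functional_genes(s, mode)[3],
                   logical(1))
  n_repl <- sum(ev$event == "loss" & ev$gene == "eEF1A" & from_f)
  tipf <- t(vapply(object$tip_codes, function(s) {
    if (s < 0L) c(FALSE, FALSE, FALSE) else functional_genes(s, mode)
  }, logical(3)))
  n_co <- sum(tipf[, 1] & tipf[, 3])
  structure(
    list(tip_state_freq = table(factor(object$tip_states)),
         n_tips = length(object$tip_codes),
         n_events = nrow(ev),
         n_replacements = n_repl,
         n_comaintained = n_co,
         n_reversals = sum(ev$reversal),
         n_extinct = sum(object$tip_codes < 0L)),
    class = "ratchet_history_summary")
}

#' @export
print.ratchet_history_summary <- function(x, ...) {
  cat("Ratchet history summary\n")
  cat("  tips:", x$n_tips, " events:", x$n_events, "\n")
  cat("  eEF1A replacements (loss with EFL present):", x$n_replacements, "\n")
  cat("  tips co-maintaining eEF1A and EFL:", x$n_comaintained, "\n")
  cat("  reversal events:", x$n_reversals, "\n")
  if (x$n_extinct > 0) cat("  extinct tips:", x$n_extinct, "\n")
  cat("  tip-state frequencies:\n")
  print(x$tip_state_freq)
  invisible(x)
}
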