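#' Propagate a state distribution along a branch
#'
#' Solves the master equation dP/dt = Q' P of the ratchet process over viable
#' states for a branch of length `t`, using scaling-and-squaring matrix
#' exponentiation (`Matrix::expm`).  This is the analytic counterpart of
#' [ratchet_branch_sample()].
#'
#' @param model a [ratchet_model()] with `lethal_policy = "reject"`.
#' @param p numeric vector of probabilities over the viable states (in the
#'   order of `rate_matrix(model)` rows, or named by state label); must sum
#'   to 1.
#' @param t branch length (>= 0).
#' @return named probability vector over viable states.
#' @examples
#' m <- ratchet_model(loss_rate = 0.3, root_state = c("eEF1A", "eEF1Ba", "EFL"))
#' p0 <- c(0, 0, 0, 0, 1) # all mass on eEF1A+eEF1Ba+EFL (last state)
#' propagate(m, p0, t = 2)
#' @export
propagate <- function(model, p, t) {
  Q <- rate_matrix(model)
  k <- nrow(Q)
  if (t < 0) stop("t must be nonnegative")
  if (length(p) != k) stop("p must have one entry per viable state (", k, ")")
  if (!is.null(names(p))) {
    if (!setequal(names(p), rownames(Q))) stop("unknown state names in p")
    p <- p[rownames(Q)]
  }
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("p must be a probability distribution over viable states")
  }
  if (t == 0) return(setNames(as.numeric(p), rownames(Q)))
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  out <- drop(as.numeric(p) %*% P)
  setNames(pmax(out, 0), rownames(Q))
}

# Per-edge transition probability matrices for one generator and many branch
# lengths.  Fast path: eigendecomposition of Q (checked against Q itself);
# falls back to scaling-and-squaring expm when Q is defective.
edge_transition_mats <- function(Q, lens) {
  k <- nrow(Q)
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  ok <- !is.null(Vi) &&
    max(Mod(eg$vectors %*% diag(eg$values, k) %*% Vi - Q)) < 1e-9
  if (ok) {
    lapply(lens, function(t) {
      P <- Re(eg$vectors %*% diag(exp(eg$values * t), k) %*% Vi)
      pmin(pmax(P, 0), 1)
    })
  } else {
    lapply(lens, function(t) {
      pmin(pmax(as.matrix(Matrix::expm(Matrix::Matrix(Q * t))), 0), 1)
    })
  }
}

#' Tip-state likelihood matrix from a factor table
#'
#' Converts a three-state [factor_table] into per-gene presence calls for
#' likelihood computation: `PRESENT` maps to present, `ABSENT` to absent, and
#' `DIVERGENT` follows the chosen convention.  Use `NA` entries (or
#' `convention = "unknown"` for divergent states) for partial observations.
#'
#' @param table a [factor_table].
#' @param convention `"divergent_as_present"`, `"divergent_as_absent"`, or
#'   `"divergent_as_unknown"` (divergent entries become unobserved).
#' @return logical matrix (taxa x genes, `NA` = unobserved), suitable as
#'   `tip_states` for [tip_likelihood()] and [fit_rates()].
#' @export
tips_from_factor_table <- function(table,
                                   convention = c("divergent_as_present",
                                                  "divergent_as_absent",
                                                  "divergent_as_unknown")) {
  convention <- match.arg(convention)
  stopifnot(inherits(table, "factor_table"))
  m <- as.matrix(table[, RATCHET_GENES])
  out <- matrix(NA, nrow(m), 3L,
                dimnames = list(table$taxon, RATCHET_GENES))
  out[m == "PRESENT"] <- TRUE
  out[m == "ABSENT"] <- FALSE
  out[m == "DIVERGENT"] <- switch(convention,
    divergent_as_present = TRUE,
    divergent_as_absent = FALSE,
    divergent_as_unknown = NA)
  out
}

# Build the ntip x nstate 0/1 compatibility matrix from the accepted
# tip_states forms: named label vector, logical taxa x gene matrix (NA =
# unobserved), or a list of label vectors.
tip_compat_matrix <- function(tip_states, tips, codes, mode) {
  k <- length(codes)
  L <- matrix(0, length(tips), k, dimnames = list(tips, NULL))
  labels <- state_label(codes, mode)
  if (is.matrix(tip_states) || is.data.frame(tip_states)) {
    tip_states <- as.matrix(tip_states)
    if (is.null(rownames(tip_states))) stop("tip_states matrix needs rownames")
    colnames(tip_states) <- normalize_gene(colnames(tip_states))
    tip_states <- tip_states[, RATCHET_GENES, drop = FALSE]
    fun <- t(vapply(codes, functional_genes, logical(3), mode = mode))
    for (tip in tips) {
      if (!tip %in% rownames(tip_states)) stop("tip not observed: ", tip)
      obs <- as.logical(tip_states[tip, ])
      comp <- rep(TRUE, k)
      for (g in 1:3) {
        if (!is.na(obs[g])) comp <- comp & (fun[, g] == obs[g])
      }
      L[tip, comp] <- 1
    }
  } else if (is.list(tip_states)) {
    for (tip in tips) {
      lab <- tip_states[[tip]]
      if (is.null(lab)) stop("tip not observed: ", tip)
      idx <- match(lab, labels)
      if (anyNA(idx)) stop("unknown state label for tip ", tip)
      L[tip, idx] <- 1
    }
  } else if (is.character(tip_states)) {
    if (is.null(names(tip_states))) stop("tip_states vector must be named")
    for (tip in tips) {
      lab <- tip_states[[tip]]
      if (is.null(lab) || is.na(lab)) stop("tip not observed: ", tip)
      idx <- match(lab, labels)
      if (is.na(idx)) stop("unknown or inviable state label: ", lab)
      L[tip, idx] <- 1
    }
  } else {
    stop("unsupported tip_states form")
  }
  L
}

#' Log-likelihood of observed tip states under the ratchet model
#'
#' Felsenstein pruning over the viable-state CTMC: per-branch transition
#' probabilities from the matrix exponential of [rate_matrix()], combined in
#' post-order, with the root distribution a point mass at the model's root
#' state.  Partial observations (per-gene `NA`) are handled by summing over
#' all compatible states.
#'
#' @param model a [ratchet_model()] with `lethal_policy = "reject"`.
#' @param tree rooted `phylo` with branch lengths; tip labels must match
#'   `tip_states`.
#' @param tip_states one of: a named character vector of state labels; a
#'   logical taxa x gene matrix with `NA` for unobserved (see
#'   [tips_from_factor_table()]); a named list of compatible state-label
#'   vectors.
#' @return log-likelihood (a single number, `-Inf` for impossible data).
#' @export
tip_likelihood <- function(model, tree, tip_states) {
  check_tree(tree)
  Q <- rate_matrix(model)
  codes <- attr(Q, "codes")
  mode <- attr(Q, "mode")
  k <- nrow(Q)
  root_idx <- match(model$root_state, codes)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  L <- matrix(1, ntip + tr$Nnode, k)
  L[seq_len(ntip), ] <- tip_compat_matrix(tip_states, tr$tip.label,
                                          codes, mode)[tr$tip.label, ]
  Ps <- edge_transition_mats(Q, tr$edge.length)
  logscale <- 0
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    v <- Ps[[e]] %*% L[child, ]
    m <- max(v)
    if (m <= 0) return(-Inf)
    L[parent, ] <- L[parent, ] * (v / m)
    logscale <- logscale + log(m)
  }
  lik <- L[ntip + 1L, root_idx]
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}
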