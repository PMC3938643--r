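# Independent oracles used across tests.

# Brute-force two-sided Fisher p: enumerate every 2x2 table with the observed
# margins via stats::dhyper and sum the probabilities of tables no more
# probable than the observed one.
fisher_p_oracle <- function(counts) {
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  obs <- probs[ks == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Character-by-character prefix scan for alignment-column mapping.
map_column_oracle <- function(row_chars, column) {
  if (row_chars[column] == "-") return(NA_integer_)
  pos <- 0L
  for (i in seq_len(column)) if (row_chars[i] != "-") pos <- pos + 1L
  pos
}

# Brute-force tip likelihood: marginalize over all internal-node state
# assignments, with per-branch transition probabilities from independent
# matrix exponentials (Matrix::expm), root fixed at the model's root state.
tip_likelihood_oracle <- function(model, tree, tip_labels) {
  Q <- rate_matrix(model)
  codes <- attr(Q, "codes")
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Ps <- lapply(tree$edge.length,
               function(t) as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
  tip_idx <- match(tip_labels[tree$tip.label], rownames(Q))
  stopifnot(!anyNA(tip_idx))
  internal <- ntip + seq_len(nnode)
  root <- ntip + 1L
  root_idx <- match(model$root_state, codes)
  combos <- do.call(expand.grid, rep(list(seq_len(k)), nnode))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_state <- integer(ntip + nnode)
    assign_state[seq_len(ntip)] <- tip_idx
    assign_state[internal] <- as.integer(combos[r, ])
    if (assign_state[root] != root_idx) next
    p <- 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][assign_state[tree$edge[e, 1]],
                       assign_state[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  log(total)
}
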