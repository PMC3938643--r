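# Seeded generators producing ground-truth-labelled inputs for closed-loop
# testing of the conservation, association and ratchet analyses.

#' Recipe for a synthetic two-family alignment
#'
#' Describes an alignment with planted per-column conservation categories,
#' planted family-specific insertion blocks, an i.i.d. substitution noise
#' level, and a uniform C-terminal tail on family A.  Defaults mirror the
#' statistical structure of the study alignment: ~460 core columns, five
#' multi-column insertions in family B plus one single-column deletion, and a
#' 17-residue family-A tail.
#'
#' @param n_a,n_b sequences per family (>= 2).
#' @param length number of core (non-indel) columns.
#' @param category_fractions named fractions over the five non-indel site
#'   categories; must sum to 1.
#' @param insertions data frame with columns `after` (core column after which
#'   the block is spliced), `width`, and `family` (the family that carries
#'   residues; the other family gets gaps).  `family = "B"` plants an
#'   insertion in B, `family = "A"` a deletion in B.  The default (`NULL`)
#'   plants five insertions in B of widths 4, 3, 6, 3, 4 and one
#'   single-column deletion, spread over the core columns.
#' @param noise per-sequence per-column substitution probability in [0, 0.5):
#'   each planted residue is replaced by a uniform draw from the other 19
#'   amino acids with this probability.
#' @param tail_length_a number of C-terminal columns where only family A has
#'   residues.
#' @param family_names labels for the two families (A then B).
#' @param seed optional integer seed.
#' @return object of class `alignment_recipe`.
#' @export
alignment_recipe <- function(n_a = 20L, n_b = 20L, length = 460L,
                             category_fractions = c(
                               IDENTICALLY_CONSERVED = 0.35,
                               UNCONSERVED = 0.35,
                               STRONG_DIFFERENTIAL = 0.10,
                               CONSERVED_A_ONLY = 0.10,
                               CONSERVED_B_ONLY = 0.10),
                             insertions = NULL,
                             noise = 0, tail_length_a = 17L,
                             family_names = c("eEF1A", "EFL"),
                             seed = NULL) {
  stopifnot(n_a >= 2L, n_b >= 2L, length >= 1L,
            noise >= 0, noise < 0.5, tail_length_a >= 0L)
  want <- c("IDENTICALLY_CONSERVED", "UNCONSERVED", "STRONG_DIFFERENTIAL",
            "CONSERVED_A_ONLY", "CONSERVED_B_ONLY")
  if (!setequal(names(category_fractions), want)) {
    stop("category_fractions must name: ", paste(want, collapse = ", "))
  }
  if (abs(sum(category_fractions) - 1) > 1e-8) {
    stop("category fractions must sum to 1")
  }
  if (is.null(insertions)) {
    insertions <- data.frame(
      after = pmin(as.integer(round(length *
                                    c(0.13, 0.20, 0.26, 0.33, 0.46, 0.65))),
                   length),
      width = c(4L, 3L, 1L, 6L, 3L, 4L),
      family = c("B", "B", "A", "B", "B", "B"),
      stringsAsFactors = FALSE)
  }
  if (nrow(insertions) &&
      (any(insertions$after < 0L) || any(insertions$after > length) ||
       any(insertions$width < 1L) ||
       !all(insertions$family %in% c("A", "B")))) {
    stop("bad insertion specification")
  }
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 length = as.integer(length),
                 category_fractions = category_fractions[want],
                 insertions = insertions[order(insertions$after), ,
                                         drop = FALSE],
                 noise = noise, tail_length_a = as.integer(tail_length_a),
                 family_names = family_names, seed = seed),
            class = "alignment_recipe")
}

# Residues for a deliberately unconserved column: a shuffled balanced multiset
# of k distinct residues, so the plurality frequency stays well below the
# lowercase threshold (for n >= 3).
unconserved_column <- function(n) {
  k <- min(6L, n)
  res <- sample(AA20, k)
  sample(rep(res, length.out = n))
}

apply_noise <- function(col, noise) {
  if (noise <= 0) return(col)
  hit <- runif(length(col)) < noise & col != "-"
  if (any(hit)) {
    col[hit] <- vapply(col[hit],
                       function(r) sample(setdiff(AA20, r), 1L),
                       character(1))
  }
  col
}

#' Generate a synthetic labelled alignment with planted truth
#'
#' Emits an alignment realizing the recipe: per core column a category is
#' drawn from the recipe fractions and family residues are planted
#' accordingly (conserved residues at frequency 1 before noise; unconserved
#' columns as balanced multisets that stay below the consensus thresholds),
#' insertion blocks appear as conserved residues in one family and gaps in
#' the other, and family A carries a uniform C-terminal tail.  Deterministic
#' given the recipe seed.
#'
#' @param recipe an [alignment_recipe()].
#' @return list of class `synthetic_alignment` with `alignment` (a
#'   [labelled_alignment()]) and `truth` (per-column categories, the planted
#'   indel runs with final coordinates, tail length, and the recipe).
#' @export
make_alignment <- function(recipe) {
  stopifnot(inherits(recipe, "alignment_recipe"))
  if (!is.null(recipe$seed)) set.seed(recipe$seed)
  n_a <- recipe$n_a; n_b <- recipe$n_b
  core <- recipe$length
  cats <- sample(names(recipe$category_fractions), core, replace = TRUE,
                 prob = recipe$category_fractions)

  col_a <- vector("list", core); col_b <- vector("list", core)
  res_a <- rep(NA_character_, core); res_b <- rep(NA_character_, core)
  for (j in seq_len(core)) {
    switch(cats[j],
      IDENTICALLY_CONSERVED = {
        r <- sample(AA20, 1L)
        res_a[j] <- r; res_b[j] <- r
        col_a[[j]] <- rep(r, n_a); col_b[[j]] <- rep(r, n_b)
      },
      STRONG_DIFFERENTIAL = {
        rr <- sample(AA20, 2L)
        res_a[j] <- rr[1]; res_b[j] <- rr[2]
        col_a[[j]] <- rep(rr[1], n_a); col_b[[j]] <- rep(rr[2], n_b)
      },
      CONSERVED_A_ONLY = {
        res_a[j] <- sample(AA20, 1L)
        col_a[[j]] <- rep(res_a[j], n_a)
        col_b[[j]] <- unconserved_column(n_b)
      },
      CONSERVED_B_ONLY = {
        res_b[j] <- sample(AA20, 1L)
        col_a[[j]] <- unconserved_column(n_a)
        col_b[[j]] <- rep(res_b[j], n_b)
      },
      UNCONSERVED = {
        col_a[[j]] <- unconserved_column(n_a)
        col_b[[j]] <- unconserved_column(n_b)
      })
  }

  # splice insertion blocks into the core column sequence
  ins <- recipe$insertions
  pieces_cat <- character(0)
  A_cols <- list(); B_cols <- list()
  indel_rows <- list()
  pos <- 0L # running final-column counter
  core_done <- 0L
  emit_core <- function(upto) {
    while (core_done < upto) {
      core_done <<- core_done + 1L
      pos <<- pos + 1L
      A_cols[[pos]] <<- col_a[[core_done]]
      B_cols[[pos]] <<- col_b[[core_done]]
      pieces_cat[pos] <<- cats[core_done]
    }
  }
  if (nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      emit_core(ins$after[i])
      start <- pos + 1L
      for (w in seq_len(ins$width[i])) {
        pos <- pos + 1L
        r <- sample(AA20, 1L)
        if (ins$family[i] == "B") {
          A_cols[[pos]] <- rep("-", n_a); B_cols[[pos]] <- rep(r, n_b)
        } else {
          A_cols[[pos]] <- rep(r, n_a); B_cols[[pos]] <- rep("-", n_b)
        }
        pieces_cat[pos] <- "INDEL"
      }
      indel_rows[[length(indel_rows) + 1L]] <- data.frame(
        start = start, end = pos, length = ins$width[i],
        direction = if (ins$family[i] == "B") "insertion_in_B"
                    else "deletion_in_B",
        is_tail = FALSE, stringsAsFactors = FALSE)
    }
  }
  emit_core(core)
  if (recipe$tail_length_a > 0L) {
    start <- pos + 1L
    for (w in seq_len(recipe$tail_length_a)) {
      pos <- pos + 1L
      A_cols[[pos]] <- sample(AA20, n_a, replace = TRUE)
      B_cols[[pos]] <- rep("-", n_b)
      pieces_cat[pos] <- "INDEL"
    }
    indel_rows[[length(indel_rows) + 1L]] <- data.frame(
      start = start, end = pos, length = recipe$tail_length_a,
      direction = "deletion_in_B", is_tail = TRUE, stringsAsFactors = FALSE)
  }

  A <- do.call(cbind, A_cols)
  B <- do.call(cbind, B_cols)
  if (recipe$noise > 0) {
    A <- apply(A, 2, apply_noise, noise = recipe$noise)
    B <- apply(B, 2, apply_noise, noise = recipe$noise)
  }
  ids_a <- sprintf("%s_%02d", recipe$family_names[1], seq_len(n_a))
  ids_b <- sprintf("%s_%02d", recipe$family_names[2], seq_len(n_b))
  mat <- rbind(A, B)
  rownames(mat) <- c(ids_a, ids_b)
  fam <- setNames(rep(recipe$family_names, c(n_a, n_b)), rownames(mat))
  aln <- labelled_alignment(mat, fam)

  truth <- list(
    columns = data.frame(column = seq_len(pos), category = pieces_cat,
                         stringsAsFactors = FALSE),
    indels = if (length(indel_rows)) do.call(rbind, indel_rows) else
      data.frame(start = integer(0), end = integer(0), length = integer(0),
                 direction = character(0), is_tail = logical(0)),
    tail_length = recipe$tail_length_a,
    recipe = recipe)
  structure(list(alignment = aln, truth = truth),
            class = "synthetic_alignment")
}

#' Recipe for a synthetic factor table
#'
#' In `ratchet_history` mode the table is produced by simulating the ratchet
#' process on a seeded unit-height Yule tree and reading the tip states;
#' genes lost on a tip's terminal branch are re-emitted as `DIVERGENT` with
#' probability `divergent_fraction`, mimicking ongoing gene degradation
#' caught in the act.  In `independent_bernoulli` mode each factor is an
#' independent coin flip per taxon (a null model for test calibration).
#'
#' @param n_taxa number of taxa (tree tips).
#' @param mode `"ratchet_history"` or `"independent_bernoulli"`.
#' @param model a [ratchet_model()] for ratchet mode.  The default plants
#'   strong lineage sorting: loss rate 1.5 per unit height, no HGT, root
#'   carrying all three genes.
#' @param divergent_fraction probability that a terminal-branch loss is
#'   emitted as `DIVERGENT`.
#' @param p_present per-factor presence probability for bernoulli mode.
#' @param seed optional integer seed.
#' @return object of class `table_recipe`.
#' @export
table_recipe <- function(n_taxa = 60L,
                         mode = c("ratchet_history", "independent_bernoulli"),
                         model = ratchet_model(
                           loss_rate = 1.5, hgt_rate = 0,
                           root_state = c("eEF1A", "eEF1Ba", "EFL")),
                         divergent_fraction = 0.15,
                         p_present = c(eEF1A = 0.5, eEF1Ba = 0.5, EFL = 0.5),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_taxa >= 2L, divergent_fraction >= 0, divergent_fraction <= 1,
            all(p_present >= 0), all(p_present <= 1))
  structure(list(n_taxa = as.integer(n_taxa), mode = mode, model = model,
                 divergent_fraction = divergent_fraction,
                 p_present = expand_gene_rate(p_present, "p_present"),
                 seed = seed),
            class = "table_recipe")
}

#' Generate a synthetic factor table with generating truth
#'
#' @param recipe a [table_recipe()].
#' @return list of class `synthetic_table` with `table` (a [factor_table()]),
#'   and `truth`: the binary presence matrix before divergent relabelling,
#'   plus (ratchet mode) the tree and simulated history.
#' @export
make_table <- function(recipe) {
  stopifnot(inherits(recipe, "table_recipe"))
  if (!is.null(recipe$seed)) set.seed(recipe$seed)
  n <- recipe$n_taxa
  if (recipe$mode == "independent_bernoulli") {
    pres <- vapply(RATCHET_GENES,
                   function(g) runif(n) < recipe$p_present[[g]],
                   logical(n))
    rownames(pres) <- sprintf("taxon_%03d", seq_len(n))
    states <- ifelse(pres, "present", "absent")
    tab <- factor_table(rownames(pres), states[, "eEF1A"],
                        states[, "eEF1Ba"], states[, "EFL"])
    return(structure(list(table = tab,
                          truth = list(presence = pres, recipe = recipe)),
                     class = "synthetic_table"))
  }
  tree <- make_tree(n)
  hist <- sim_one_history(recipe$model, tree, NULL)
  mode <- recipe$model$divergence_mode
  pres <- t(vapply(hist$tip_codes, functional_genes, logical(3), mode = mode))
  colnames(pres) <- RATCHET_GENES
  states <- ifelse(pres, "present", "absent")
  if (mode == "two_step") {
    div <- t(vapply(hist$tip_codes, function(s) trits(s) == 1L, logical(3)))
    states[div] <- "divergent"
  }
  # terminal-branch losses caught mid-decay
  ntip <- length(hist$tree$tip.label)
  ev <- hist$events
  term <- ev$event == "loss" & ev$child <= ntip
  for (r in which(term)) {
    tip <- ev$child[r]; gene <- ev$gene[r]
    if (!pres[tip, gene] && runif(1) < recipe$divergent_fraction) {
      states[tip, gene] <- "divergent"
    }
  }
  tab <- factor_table(hist$tree$tip.label, states[, "eEF1A"],
                      states[, "eEF1Ba"], states[, "EFL"])
  structure(list(table = tab,
                 truth = list(presence = pres, tree = tree, history = hist,
                              recipe = recipe)),
            class = "synthetic_table")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Generates a binary ultrametric tree under the Yule process and rescales
#' its height to `height` so ratchet rates read as events per tree height.
#' Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @param height tree height after rescaling.
#' @return a `phylo` tree.
#' @export
make_tree <- function(n_tips, seed = NULL, height = 1) {
  stopifnot(n_tips >= 2L, height > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * height
  tr
}
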