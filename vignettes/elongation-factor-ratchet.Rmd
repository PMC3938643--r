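---
title: "Methods: elongation-factor profiling and the gain/loss ratchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elongation-factor profiling and the gain/loss ratchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eflratchet)
```

## The biological problem

eEF1A is the eukaryotic GTPase that delivers aminoacyl-tRNA to the ribosome.
After each round it is stuck with GDP and needs its exchange factor, the
eEF1B alpha subunit (eEF1Bα, written `eEF1Ba` throughout the package), to
recharge with GTP. A paralog, EFL ("EF1A-like"), has a patchy distribution
across eukaryotes and is usually found *instead of* eEF1A — and, tellingly,
instead of eEF1Bα as well, suggesting EFL recharges on its own.

This package treats three questions quantitatively:

* Is EFL presence statistically associated with loss of eEF1A and eEF1Bα
  across taxa?
* Which alignment positions distinguish the two families strongly enough to
  explain EFL's independence from the exchange factor?
* What evolutionary dynamics does the observed distribution imply, if loss
  of either eEF1A or eEF1Bα in the presence of EFL is effectively
  irreversible (a ratchet)?

## Exact association testing

A `factor_table` records each taxon's state for the three factors as
`PRESENT`, `DIVERGENT` (a recognizable but decaying sequence) or `ABSENT`.
Divergent sequences are genuinely ambiguous — a gene caught mid-loss — so
every analysis is run under both conventions (`divergent_as_present`,
`divergent_as_absent`); a conclusion that holds under both does not depend
on the scoring choice. `contingency()` tabulates EFL presence against eEF1A,
eEF1Bα, or their conjunction ("both": a working ancestral pair), and
`association_report()` computes all six combinations.

The test is Fisher's exact test, written out from the hypergeometric mass
function rather than called from a library routine: conditioning on the
margins, the two-sided p is the sum of the probabilities of all same-margin
tables whose point probability does not exceed the observed one (the
minimum-likelihood criterion). Masses are accumulated in log space via
`lchoose`, so tables beyond n = 170 do not overflow, and the tie comparison
uses a relative tolerance of 1e-12 to make floating-point ties
deterministic. Tables with a zero margin carry no information about
association and are returned as `p = 1` with a `degenerate` flag. The unit
tests check this implementation against exhaustive enumeration for every
2×2 table with n ≤ 30 and against `stats::fisher.test`.

Taxa are treated as independent observations, which they are not — related
species share their gene content by descent. This mirrors the usual survey
practice and keeps results comparable; `collapse_by_lineage()` offers a
cruder but more conservative alternative that reduces each labelled lineage
to a single majority-state pseudo-taxon.

The bundled survey table (`inst/extdata/ef_survey_synthetic.tsv`) is a
*synthetic reconstruction*, not original survey data: the species whose
states the underlying survey reports explicitly are encoded as reported, and
the remaining rows fill in the well-established distribution of the three
factors across the major eukaryote lineages. It exists so the association
pipeline has a realistic, documented input; its p-values (~1e-17 to 1e-21)
should be read as "the described pattern is overwhelmingly non-random", not
as exact reproductions of published statistics.

## Tiered consensus and site classification

`consensus()` summarizes one family per alignment column with a
four-tier symbol: an UPPERCASE residue at conservation ≥ `threshold_high`
(default 0.70), a lowercase residue when the plurality residue reaches
`threshold_low` (default 0.50) but not `threshold_high`, `.` when nothing
reaches the lower threshold, and `-` when gaps themselves reach
`threshold_high`. Three conventions deserve mention because published
consensus strings rarely state them:

* **The denominator includes gaps and `X`.** A column that is half gaps can
  never reach 70% conservation, which is what makes family-specific
  insertion blocks render as `-` in the other family's consensus.
* **The lowercase tier** is defined here as plurality ≥ 50% and < 70%, with
  alphabetical tie-breaking, so the output is deterministic.
* Threshold comparisons are made as `count ≥ threshold × n − 1e-9`, so a
  column with exactly 7 of 10 residues passes a 0.70 threshold regardless of
  floating-point representation.

`classify_sites()` compares two profiles column-wise into six mutually
exclusive categories: `STRONG_DIFFERENTIAL` (both uppercase, different
residues — the interesting sites), `IDENTICALLY_CONSERVED`,
`CONSERVED_A_ONLY` / `CONSERVED_B_ONLY`, `INDEL` (exactly one profile
gapped) and `UNCONSERVED`. Strongly differential pairs are additionally
flagged when the two residues fall in different chemical classes; because
"chemically different" has no universal definition, the package fixes an
explicit 7-group partition — {A,V,L,I,M,C}, {F,W,Y,H}, {S,T,N,Q}, {K,R},
{D,E}, {G}, {P} — with `X` indeterminate (never "different").

`detect_indels()` reports maximal runs where exactly one profile is gapped,
flagged as conserved when at least half the run's columns (tunable) carry a
consensus letter in the non-gap family. `map_column()` converts alignment
columns to residue positions in a chosen sequence (1-based, inclusive, `NA`
at gaps); all user-facing coordinates in the package are 1-based inclusive.
`cterm_extension()` measures the mean number of residues one family extends
past the last non-gap column of the other family's consensus.

## The ratchet model

Gene content is a state: a subset of {eEF1A, eEF1Bα, EFL}. A state is
*viable* when it has a working elongation system — EFL present, or the
complete eEF1A+eEF1Bα pair — leaving 5 viable states out of 8. The dynamics
are a continuous-time Markov chain:

* each gene present is lost at rate λ (optionally per-gene),
* EFL, and only EFL, can be (re)gained, at HGT rate *h*, while absent,
* transitions into lethal states are **rejected** by default: purifying
  selection removes such mutations, so observed lineages never pass through
  them. (An `extinct` policy, where a lethal transition kills the lineage,
  is available for exploration in the simulator; the generator matrix and
  likelihood machinery are defined for the rejection semantics.)

The absence of any gain channel for eEF1A and eEF1Bα encodes the ratchet's
pawl — "a return to the ancestral state would require the lost gene to be
re-transferred before its partner decays" is approximated as probability
zero. This is a model assumption, not an empirical fact. Under it, from the
state eEF1A+eEF1Bα (no EFL) the only possible move is gaining EFL, and the
EFL-only state is absorbing. Whether the ratchet is *processive* — whether
lineage after lineage can be pushed through replacement — is exactly the
question of whether *h* > 0.

Rates are per unit branch length; the tree defines the clock, and the
default `loss_rate = 0.1, hgt_rate = 0` are placeholders with no empirical
standing (the survey literature provides no rate estimates), to be replaced
by the user or by `fit_rates()`.

A `two_step` divergence mode interposes a `divergent` (nonfunctional for
viability) stage between intact and absent, at a separate divergence rate;
it exists to generate data resembling the observed "caught mid-decay"
divergent sequences. The one-step mode is the default for analysis.

`simulate()` is an exact Gillespie simulation along each branch in
deterministic preorder from a single seeded RNG stream (simple and fully
reproducible given the seed); children inherit parent end-states, and the
event log records every transition with its pre/post state, which makes the
history replayable (`replay_history()`) and lets `summary()` count
replacements, co-maintained tips and reversals by direct scan.
`propagate()` solves the master equation with scaling-and-squaring matrix
exponentiation; the test suite requires Monte-Carlo tip frequencies and the
analytic distribution to agree within 3 binomial standard errors at 10⁵
replicates, and the pure-single-gene-loss case to match exp(−λt).

`tip_likelihood()` is Felsenstein pruning over the viable states with the
root fixed at the model's root state; per-edge transition matrices use an
eigendecomposition fast path (validated against the generator to 1e-9,
falling back to the matrix exponential when the generator is defective).
Partial observations — per-gene `NA`, or divergent states scored as
unknown — are handled by summing over all compatible states. Pruning is
checked against brute-force marginalization over internal-node states on all
rooted trees with up to 4 tips.

`fit_rates()` maximizes the pruning likelihood over (λ, h) on a log-scale
grid (default 7×7 over [1e-3, 20]) refined by Nelder-Mead on the log scale,
clamped to the bounds; a flat surface yields a degenerate-fit warning with
the grid returned. Estimating a shared λ and h is deliberate: tip
presence/absence data on one tree cannot support per-gene rates and an HGT
rate simultaneously.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage has a closed loop
(generate → analyse → compare to planted truth), seeded and reproducible.

`make_alignment()` plants a category per column and emits residues
accordingly. Conserved residues are planted at frequency 1 (noise aside), so
they sit 30 percentage points above the uppercase threshold; "unconserved"
columns are shuffled balanced multisets of up to 6 distinct residues, whose
plurality frequency stays well below the lowercase threshold for families of
≥ 4 sequences — at zero noise, category recovery is therefore exact by
construction, and the tests demand exactly that. Noise is i.i.d. uniform
substitution over the other 19 residues — the simplest model that stresses
the threshold logic. It deliberately omits phylogenetic autocorrelation,
realistic substitution matrices, and alignment error; passing the
closed-loop tests shows the classification machinery is correct, not that
it is robust to real alignment pathologies. Default dimensions mirror the
study alignment's shape: 20 sequences per family, 460 core columns, five
multi-column insertions in the EFL family plus one single-column deletion,
and a 17-residue C-terminal extension of the eEF1A family.

`make_table()` produces factor tables either from a simulated ratchet
history on a unit-height Yule tree (default: loss rate 1.5, no HGT, root
carrying all three genes — strong lineage sorting, the regime the observed
distribution suggests) or as independent per-factor coin flips, the null
model used to check that the exact test's type-I error at α = 0.05 stays at
or below nominal (it is conservative, as exact conditional tests are).
Genes lost on a tip's terminal branch are re-emitted as `DIVERGENT` with
probability `divergent_fraction` (default 0.15), mimicking degradation
caught in progress; relabelling only terminal-branch losses keeps the
divergent calls recent without tracking residue-level decay.

`make_tree()` draws Yule (pure-birth) trees rescaled to unit height (or any
chosen height), so rates are interpretable as expected events per tree
height.

## Problem sizes and numerical choices

The shipped validation runs use: exhaustive exact-test verification over all
2×2 tables with n ≤ 30; 10⁴ histories for the irreversibility check; 10⁵
single-branch replicates per parameter draw (5 draws) for the
simulation-vs-analytics comparison; 20 replicate fits on 200-tip trees of
height 3 at (λ = 0.2, h = 0.5), rooted at the ancestral eEF1A+eEF1Bα state,
requiring both estimates within a factor of 2 of truth in ≥ 90% of
replicates; and 10⁴ null tables of 40 taxa for calibration. Tree height 3
for the recovery study was chosen so that both loss events (λ·T = 0.6 per
gene per lineage) and gains (h·T = 1.5) are expected along root-to-tip
paths; with the root already carrying EFL the HGT rate is close to
unidentifiable, since gains can only be observed on lineages that first
lost EFL.

Other numerical choices: probability distributions must sum to 1 within
1e-8 on input and are conserved within 1e-10 by propagation; transition
probabilities are clamped to [0, 1] after exponentiation; pruning rescales
partial likelihoods per edge to avoid underflow and returns −Inf for
impossible observations (e.g. a changed tip under zero rates).

## Known limitations

* Taxon non-independence in the association test (see above).
* The ratchet model ignores within-genome duplicates, gene conversion and
  any back-transfer of eEF1A/eEF1Bα; "divergent" is a binary stage, not a
  dose.
* The HGT rate is assumed constant across the tree; lineage-specific
  transfer rates (e.g. barriers in particular groups) are not modelled.
* The synthetic alignment generator does not simulate evolution on a tree;
  family members are exchangeable, which real paralog families are not.
* EFL's origin is modelled through the root state plus HGT; an explicit
  one-time duplication event at an internal node is not implemented —
  placing EFL in the root state (or fitting with an EFL-bearing root) is
  the available approximation.
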