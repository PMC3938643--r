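# eflratchet

Tools for studying an unusual pattern in eukaryote genomes: the essential
translation elongation factor eEF1A, which delivers aminoacyl-tRNA to the
ribosome and needs the exchange factor eEF1Bα (here written `eEF1Ba`) to swap
GDP for GTP, has been replaced in many independent lineages by its paralog
EFL, which apparently manages without an exchange factor. Across eukaryotes,
EFL presence is strongly associated with loss of *both* eEF1A and eEF1Bα —
the signature of a ratchet: once either partner of the eEF1A:eEF1Bα pair
decays in the presence of EFL, there is no way back to the ancestral state.

The package implements three connected analyses plus the synthetic data
needed to validate them end to end:

1. **Phylogenetic profiling and exact association testing.** Three-state
   (present / divergent / absent) taxon × factor tables; 2×2 contingency
   tabulation of EFL presence against eEF1A and/or eEF1Bα presence; a
   two-sided Fisher exact test implemented from the hypergeometric mass in
   log space (minimum-likelihood criterion), reported under both conventions
   for scoring divergent sequences.

2. **Differential conservation profiling.** Tiered consensus calling on a
   two-family protein alignment (UPPERCASE at ≥ 70% conservation, lowercase
   at ≥ 50%, `.` below, `-` for gap-dominated columns); per-column
   classification into strongly differentially conserved, family-specific,
   identically conserved, unconserved and indel sites; detection of conserved
   family-specific insertions/deletions; alignment-column ↔ residue-position
   mapping; mean C-terminal extension of one family beyond the other.

3. **The ratchet as a continuous-time Markov model.** Gene content evolves
   over subsets of {eEF1A, eEF1Bα, EFL}; states without a working elongation
   system (neither EFL nor the complete eEF1A+eEF1Bα pair) are lethal and,
   under the default rejection policy, unreachable. Genes are lost at rate λ
   per unit branch length; EFL alone can be regained, by horizontal transfer
   at rate *h*. The generator over the five viable states gives master
   equation propagation `dP/dt = Qᵀ P`; `simulate()` runs exact Gillespie
   realizations along a phylogeny; `tip_likelihood()` computes Felsenstein
   pruning likelihoods of observed tip states; `fit_rates()` estimates
   (λ, h) by grid-refined maximum likelihood. Because eEF1A and eEF1Bα have
   no gain channel, their loss while EFL is present is the irreversible pawl.

## Worked example

```r
library(eflratchet)

# Association between EFL presence and loss of the eEF1A:eEF1Ba pair,
# on the bundled survey table (a synthetic reconstruction of the published
# presence/absence distribution; see inst/extdata/ef_survey_synthetic.tsv)
tab <- read_factor_table(system.file("extdata", "ef_survey_synthetic.tsv",
                                     package = "eflratchet"))
exact_association_test(contingency(tab, "divergent_as_absent", "EFL_vs_both"))
#> Exact test of association (2x2, two-sided)
#>             other_present other_absent
#> EFL_present             0           34
#> EFL_absent             36            0
#> odds ratio = 0, p = 9.16842e-21

# Ratchet simulation and rate recovery
tr <- make_tree(200, seed = 42, height = 3)
m  <- ratchet_model(loss_rate = 0.2, hgt_rate = 0.5,
                    root_state = c("eEF1A", "eEF1Ba"))
h  <- simulate(m, seed = 7, tree = tr)
summary(h)
#> Ratchet history summary
#>   tips: 200  events: 55
#>   eEF1A replacements (loss with EFL present): 15
#>   tips co-maintaining eEF1A and EFL: 89
#>   reversal events: 4
#>   tip-state frequencies:
#>     eEF1A+eEF1Ba eEF1A+eEF1Ba+EFL        eEF1A+EFL       eEF1Ba+EFL
#>               53               66               23               19
#>              EFL
#>               39
coef(fit_rates(tr, h$tip_states, root_state = c("eEF1A", "eEF1Ba")))
#>      loss       hgt
#> 0.2334409 0.4530485
```

The fitted rates land close to the generating values (0.2, 0.5): the loss
rate is identified by how far lineage sorting has progressed, the HGT rate
by how often EFL appears on a background that started without it.

A command-line interface wrapping the same functions is available via
`inst/scripts/efl-ratchet` (subcommands `assoc`, `classify`, `simulate`,
`fit`, `synth`; every run writes a JSON manifest with the seed and input
checksums).

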