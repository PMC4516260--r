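# coevoscan

Correlated mutation analysis for species-matched protein alignments:
pseudocount-corrected mutual information with Z-value normalization,
mean-field direct coupling analysis (DCA), structure-contact benchmarking,
and phylogenetic robustness diagnostics — with a ground-truth simulator of
coevolving alignments so every stage is testable.

## The problem

When two proteins interact and the interaction matters for fitness, a
mutation at the interface in one protein can be compensated by a mutation in
the other.  Across a panel of species, such compensatory pairs show up as
*covarying* alignment columns.  Detecting them is routine when thousands of
homologs exist; for vertebrate-specific proteins (the motivating case is
α-synuclein and glucocerebrosidase, with ~72 usable species) the species
panel is small, estimates are noisy, and shared ancestry can fake
covariation.  This package implements the analysis stack for exactly that
regime — small species-matched panels, intra- and inter-protein — together
with the diagnostics needed to tell functional coupling from phylogenetic
artifact.

## Methods at the core

**MI Z-values.**  For columns *i*, *j*, amino-acid frequencies (21 symbols,
gap included) are smoothed with a pseudocount λ (default 1.5) over *s*
species:

    f'_i(m)    = (s / (s + 21λ)) (λ/s + f_i(m))
    f'_ij(m,n) = (s / (s + 42λ)) (λ/s f'_i(m) + λ/s f'_j(n) + f_ij(m,n))

    MI_ij = Σ_{m,n} f'_ij(m,n) ln [ f'_ij(m,n) / (f'_i(m) f'_j(n)) ]

MI is then normalized per column pair against each member column's
background over all its possible partners:

    Z_ij = 0.5 [ (MI_ij − MI_i,av)/σ_i + (MI_ij − MI_j,av)/σ_j ]

**Mean-field DCA.**  Sequence reweighting at identity threshold θ (θ = 0 ⇒
uniform weights), regularized frequencies (pseudocount weight 0.5),
couplings from the negative inverse covariance matrix over 20 non-reference
symbols per column, and per-pair direct information

    DI_ij = Σ_{m,n} P_ij(m,n) ln [ P_ij(m,n) / (f_i(m) f_j(n)) ]

where `P_ij` is the two-site model of the pair's coupling block with
marginals matched to the regularized frequencies.  DI discounts the
transitive correlations that inflate plain MI.

**Diagnostics.**  Leave-species-out rank trajectories, the non-sister-clade
support criterion (a credible pair must have arisen in ≥ 2 independent
clades), a row-permutation null for inter-protein pairs, conserved-region
detection, and precision-at-k against contact maps extracted from PDB/mmCIF
structures (closest heavy-atom distance ≤ 7 Å, union over conformers).

## Worked example

```r
library(coevoscan)

tree <- simulate_tree(72, seed = 42)
cl   <- tree_clades(tree, 8)
cfg  <- coevol_config(tree = tree, length_a = 30, length_b = 30,
                      site_rate = 0.4, seed = 42,
                      planted_pairs = data.frame(col_a = c(5, 12),
                                                 col_b = c(9, 21),
                                                 rho   = c(1, 0.6)))
sim <- evolve_pair_msas(cfg)
z   <- z_matrix(mi_matrix(sim$paired))
rank_pairs(z, 5)
#>   rank col_a col_b ref_a ref_b score
#> 1    1     5     9    NA    NA  4.48
#> 2    2    16     5    NA    NA  2.69
#> 3    3     1    24    NA    NA  2.61
#> 4    4    10     2    NA    NA  2.48
#> 5    5    30     1    NA    NA  2.40
```

The fully compensatory planted pair (columns 5 and 9, ρ = 1) tops the
ranking with Z = 4.48, well clear of the background (≤ 2.7).  The
diagnostics agree that it looks like repeated, independent co-substitution
rather than a single-lineage artifact:

```r
clade_support(sim$paired, c(5, 9), cl$annotation)$n_clades
#> [1] 4        # minority state present in 4 non-sister clades: passes
permutation_null(sim$paired, c(5, 9), n_perm = 200, seed = 7)$p_value
#> [1] 0.00498  # far out in the species-permutation null
rank_pairs(dca_pipeline(sim$paired), 3)
#>   rank col_a col_b ref_a ref_b score
#> 1    1    12    21    NA    NA 0.430
#> 2    2     5     9    NA    NA 0.430
#> 3    3     8    27    NA    NA 0.369
```

Both planted pairs (ρ = 1 and ρ = 0.6) occupy the top two DI ranks.
With real alignments the entry point is `read_alignment()` +
`pair_by_species()`, and `rank_pairs(..., reference_a = "Homo_sapiens")`
reports pairs in human residue numbering.  A thin shell wrapper for the
`score` and `simulate` operations is installed under `exec/coevoscan`.

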