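---
title: "Detecting correlated mutations in small species panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting correlated mutations in small species panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscan)
```

# Scope and model

coevoscan scores covariation between alignment columns, within one protein
(intra mode) or between two proteins restricted to their shared species
(inter mode).  Two scoring routes are provided because they fail
differently: mutual information with Z-value normalization (the primary
statistic, robust in the small-panel regime) and mean-field direct coupling
analysis (which removes transitive correlations but needs more sequences to
be stable).  Around the scores sit diagnostics that ask the question any
phylogeneticist will ask of a top-ranked pair: *would this survive removing
a clade of close relatives, and did the pattern arise more than once?*

The working assumptions are:

* sequences are species-labelled, one per species, already aligned;
* the 21-symbol alphabet (20 amino acids + gap) is exhaustive — ambiguity
  codes are rejected at the door rather than coerced, because a misread
  symbol in a 72-row alignment is enough to fabricate a covariation signal;
* invariant columns carry no signal and are excluded from every score axis;
* identity between rows is counted over mutually non-gap columns.

## Frequencies and mutual information

With $s$ species and pseudocount $\lambda$ (default **1.5**, dimensionless),

$$f'_i(m) = \frac{s}{s + 21\lambda}\Big(\frac{\lambda}{s} + f_i(m)\Big),
\qquad
f'_{ij}(m,n) = \frac{s}{s + 42\lambda}\Big(\frac{\lambda}{s} f'_i(m)
  + \frac{\lambda}{s} f'_j(n) + f_{ij}(m,n)\Big)$$

both of which sum to one exactly (algebraic identity; asserted to 1e-12 in
the tests).  The joint correction deliberately reuses the *corrected*
single-site frequencies inside its pseudocount term, and the corrected
joint is **not** re-marginalized: $\sum_n f'_{ij}(m,n) \ne f'_i(m)$ in
general.  The formulas are implemented literally; re-marginalizing would
change every MI value downstream.

$$MI_{ij} = \sum_{m,n} f'_{ij}(m,n)\,
  \ln\frac{f'_{ij}(m,n)}{f'_i(m) f'_j(n)}$$

in nats, over all $21\times 21$ symbol pairs.  At $\lambda = 0$ the terms
with zero joint mass contribute zero by convention ($0\ln 0 \equiv 0$);
with $\lambda > 0$ no term is zero.  Why a pseudocount at all: at small $s$
a single coincident pair of rare symbols — one sequencing error in each
protein of the same species suffices — yields a large raw MI.  The uniform
prior mass damps exactly these single-observation cells.

## Z-values

$$Z_{ij} = \tfrac12\Big[\frac{MI_{ij} - \overline{MI_i}}{\sigma_i}
  + \frac{MI_{ij} - \overline{MI_j}}{\sigma_j}\Big]$$

where the averages run over all non-invariant partner columns of the
opposite axis (inter mode) or all other non-invariant columns of the same
protein, self-pair excluded (intra mode).  Design points:

* **Population standard deviation** (divide by $N$), not sample: the
  partner set is the entire population of interest, not a sample from it.
* **Averaging population**: invariant columns are excluded from the
  averages, because they are excluded from the analysis entirely.
* **$\sigma$-guard**: a column whose MI values are all equal has no spread;
  its term is defined as 0.  The guard triggers below $10^{-9}$ nats rather
  than at exactly zero: a mathematically constant row accumulates
  $\sim 10^{-16}$ of floating noise, and dividing by it produces huge,
  asymmetric garbage (observed against the brute-force oracle on degenerate
  fixtures).  MI values are of order 0.1–3 nats, so $10^{-9}$ is five
  orders of magnitude below any real spread.
* **Ties in ranking** break lexicographically on (column A, column B), so
  rankings are bit-reproducible.
* No sequence-separation filter is applied to near-diagonal intra pairs.

## Mean-field DCA

The DCA route follows the standard mean-field formulation: sequence weights
$w_k = 1/|\{l: \mathrm{id}(k,l) \ge 1-\theta\}|$; weighted frequencies mixed
with the uniform distribution at pseudocount weight 0.5; covariance
$C_{ij}(m,n) = \tilde f_{ij}(m,n) - \tilde f_i(m)\tilde f_j(n)$ over 20
states per column (the gap is the reference symbol dropped in the
reduction); couplings $e = -C^{-1}$; and per-pair direct information from a
two-site model whose single-site fields are fitted by alternating marginal
matching (fixed-point tolerance $10^{-8}$, max 500 iterations — in practice
tens of iterations suffice).  Same-column blocks of the pair-frequency
matrix are diagonal and regularized toward $(pc/21)\,I$, keeping them
consistent with the single-site statistics.

Two deliberate choices deserve a note:

* **$\theta = 0$ is special-cased to uniform weights.**  Read literally,
  "identity $\ge 1-\theta$" at $\theta = 0$ would still down-weight exact
  duplicates.  But $\theta = 0$ *means* "reweighting off" — every sequence
  counts equally — and that is how the default behaves.  Increasing
  $\theta$ never increases the effective sequence count (tested).
* **Regularization bias.**  With the uniform mixing applied independently
  to singles and pairs, two truly independent columns retain an asymptotic
  cross-covariance
  $C_{ij} = pc(1-pc)\,(f_i - \tfrac1{21})(f_j - \tfrac1{21})^\top$ —
  a rank-one term that does not vanish with sample size.  Raw coupling-block
  norms therefore plateau at a regularization floor instead of shrinking to
  zero.  DI, which passes the couplings through the marginal-matched
  two-site model, does shrink with sample size on independent data, and
  that is the property the test suite asserts.
* **$pc = 0$ is rejected** with an actionable error: the covariance of
  one-hot indicators is rank-deficient without regularization.

## Coordinates and reporting

Alignment columns are 1-based throughout (the R convention; every container
here is an R matrix, and a 0-based internal convention would guarantee
off-by-one errors at each subscript).  Reports translate columns to 1-based
residue numbers along the ungapped row of a chosen reference species;
columns gapped in the reference are reported as `NA`, never silently
renumbered.

# Robustness diagnostics

**Leave-species-out** recomputes the full MI/Z analysis after removing
species cumulatively (the default; a one-at-a-time mode exists, since
published removal protocols are often ambiguous between the two readings)
and records the tracked pair's Z and rank.  If the tracked columns become
invariant, the rank is `NA`, not an error.

**Clade support** operationalizes "the pattern must have arisen at least
twice independently": find the *minority joint state* at the tracked pair —
the symbol pair with the smaller species count, ties broken toward the
state absent from a designated reference species — and count the distinct
clades containing at least one carrier.  Sister clades, if declared,
collapse into one group (union–find over the declared adjacency); absent a
declaration, all distinct labels count as non-sister.  That default is
permissive by design: a false "passes" sends a pair on to more scrutiny,
while a false "fails" discards it.

**Permutation null**: whole rows of protein B's block are permuted,
preserving each protein's internal phylogenetic structure while destroying
the cross-protein species correspondence.  Row permutation leaves column
compositions — hence invariance and single-site frequencies — untouched, so
only the tracked pair's row/column MI profiles are recomputed per
permutation.  The p-value uses the add-one estimator
$(1 + \#\{Z_{null} \ge Z_{obs}\})/(n_{perm}+1)$, which can never return 0.
On independent data these p-values are approximately uniform (checked
across seeds); they are a guard against chance covariation, not a
substitute for the clade criterion, which targets *phylogenetic* (shared-
ancestry) covariation that a row permutation preserves nothing of.

**Conserved regions**: maximal runs of reference-mapped columns whose modal
symbol frequency is at least `min_identity` (default 0.9) over at least
`min_length` residues (default 5).  There is no community-standard
definition of a "conserved region" at this granularity; the defaults are
deliberately strict on identity and short on length so that short conserved
interaction motifs are not swallowed by a long-run requirement, and both
are exposed as arguments.

# Contact benchmarking

A contact is a residue pair with closest **heavy-atom** distance at or
below the cutoff (default 7 Å) in *any* source structure — the union over
conformers matters because complexes breathe (oxy/deoxy-type conformational
pairs can each contribute contacts the other lacks).  Hydrogens are
excluded because crystal structures rarely resolve them and a 7 Å cutoff is
far coarser than a hydrogen radius; waters and heteroatoms are excluded;
only the highest-occupancy alternate conformer is kept.  Residue identity
follows the author numbering of the structure file, matched against the
reference-species numbering of the ranked list, and unmapped residues count
as misses rather than being dropped.  `precision_at_k` and the rank
histogram then summarize how contact-enriched the top of a ranking is.

# The simulator: what it emulates, and what it does not

`evolve_pair_msas` generates a paired alignment down a shared species tree
(user-supplied or coalescent):

* **Neutral columns** substitute independently per branch with probability
  $1 - e^{-\mathrm{rate}\cdot\ell}$, drawing uniformly among the 19
  alternative amino acids.
* **Planted pairs** follow a two-state compensatory cycle
  ($a\!\leftrightarrow\!a'$, $b\!\leftrightarrow\!b'$).  On each branch,
  column A toggles at the neutral rate; with probability $\rho$ column B
  mirrors A's event on that branch, otherwise it toggles independently at
  the same rate.  So $\rho = 0$ is exactly independent two-state drift
  (the marginal substitution rate of B does not depend on $\rho$), and
  $\rho = 1$ is perfect compensation.
* **Clade artifacts** place one joint substitution on the stem of a named
  clade: every member carries the mutant pair, no one else does.  This is
  the canonical "high Z, single origin" confound; `clade_support` returns 1
  on it by construction, which is the end-to-end diagnostic the pipeline
  exists to make.
* **Errors and gaps**: each final symbol is independently misread
  (uniformly among the other 19 amino acids) with `error_rate`, and gapped
  with `gap_rate`; both default to 0.  With errors on, the suite asserts
  the directional property that $\lambda = 1.5$ yields no more extreme-Z
  pairs on null data than $\lambda = 0$.

Defaults were fixed once as the study conditions: 72 species (the size of a
realistic vertebrate panel for a neuron-specific protein), `site_rate` 0.3
per unit branch on a coalescent tree — which leaves a hemoglobin-like
majority of columns variable at 72 species — and error/gap injection off.
Recovery experiments use 300 species and `site_rate` 1 ("many sequences,
fast sites"), the regime where both statistics should work.

What the simulator does **not** emulate, and therefore what passing tests
do not show about real data: empirical amino-acid exchangeabilities and
site-rate heterogeneity (substitutions are uniform over 19 targets at one
shared rate); indel processes with phylogenetic structure (gaps are i.i.d.
noise here); selection gradients along the sequence; correlated *groups* of
sites beyond pairs; and alignment error, which in real pipelines is
confounded with everything else.  Recovery rates measured here are an upper
bound on what the same statistics achieve on real alignments.

# Numerical and degenerate-input policy

* Normalization identities hold to 1e-12 (asserted); MI/Z equal an
  independent brute-force implementation to 1e-10 on exhaustive small
  fixtures.
* An alignment with fewer than two non-invariant columns on an axis is an
  error naming the condition (this is also what a `site_rate = 0`
  simulation produces).
* Zero co-aligned columns make percent identity an error, not `NaN`.
* `rank_pairs` with `k` beyond the pair count warns and returns all pairs.
* All simulation and permutation randomness is seed-derived; identical
  configs give byte-identical alignments.

# Known limitations

* Mean-field DCA is implemented from the standard formulation; published DI
  values from other implementations will differ in value (pseudocount
  placement differs between codebases) though rank orders agree closely —
  comparisons against external DI tables should be rank-based.
* The Z-value averaging convention for intra mode (symmetric over both
  member columns' partner sets) is one of two defensible readings of the
  formula; the inter-mode convention is unambiguous.
* Clade support without a sister-adjacency declaration over-counts
  independence when two listed clades are in fact sisters.
* Contact extraction trusts author residue numbering; structures renumbered
  against the alignment reference must be reconciled by the user (mismatches
  are reported, never silently dropped).

# Problem sizes

The shipped test-and-acceptance workload uses alignments up to 300 species
by 28 columns, 20–50 seeded replicates per stochastic property, 200
permutations per null, and toy structures of a handful of atoms; the full
suite runs in well under a minute on one CPU.  All sizes are arguments, and
the pipeline has no hard-coded limits; cost scales as
$O(L^2 s + L^2 \cdot 441)$ for MI matrices and $O((20L)^3)$ for the DCA
inversion.
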