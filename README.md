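# famcons

Per-site conservation and structure-network analysis for protein families
with a glutathione S-transferase (GST)-like fold, built around GDAP1 — the
mitochondrial outer-membrane protein whose missense mutations cause
Charcot-Marie-Tooth (CMT) disease. The package answers two linked
questions: *which residues are conserved within a subfamily or across the
whole superfamily*, and *how do those residues participate in the
intramolecular interaction networks that disease mutations disturb*.

## What it computes

**Sequence side.** Given a multiple sequence alignment projected onto a
reference sequence (columns where the reference has a gap are removed, so
every site carries a reference residue number), the package computes:

- Per-site Shannon entropy with a base-20 logarithm,
  `S = -Σ_j p_j log20 p_j`, over the 20 amino-acid types, gaps and
  ambiguity codes treated as missing data. `S` runs from 0 (fully
  conserved) to 1 (uniform over all 20 types); sites with `S < 0.2` are
  called conserved and `S < 0.1` highly conserved, reported together with
  the fraction of non-gap characters at the site.
- Bidirectional Kullback-Leibler divergence between two subfamilies at each
  site, `D = Σ_j p_j ln(p_j / q_j)` on pseudocount-smoothed frequencies,
  computed with either group as the reference distribution. Sites that are
  conserved in one group but different in the other — candidate
  specificity-determining positions — rank highest by `max(KL_1, KL_2)`.
- Representative-set reduction for phylogeny input: the pairwise
  identity-distance matrix is thinned by repeatedly removing one member of
  the closest remaining pair until `k` sequences remain, keeping the most
  even possible spread; reduced sets can be merged with duplicate removal.

**Structure side.** Given PDB structures of a wild-type protein and
variants:

- Kabsch least-squares superposition and per-residue Cα deviation profiles
  of each variant against the wild type.
- Hydrogen-bond and salt-bridge networks between annotated core helices
  (heavy-atom criteria: donor–acceptor ≤ 3.5 Å with antecedent angle
  ≥ 90°, ionic N–O ≤ 4.0 Å; all cutoffs configurable, with a grid-scan
  helper because published contact counts rarely state their criteria).
- Conservation painting into the B-factor column for molecular viewers,
  and a classification of residues as CMT-mutated, highly conserved, both,
  or neither — including the residues contacting a focus segment such as
  the α6–α7 loop.

A synthetic-data module generates alignments with known per-site
distributions (explicit vectors or symmetric-Dirichlet draws), two-group
families with injected divergent sites, and ideal toy helices with known
per-residue displacements, so every estimator is validated against ground
truth.

## Worked example

Two subfamilies of 150 sequences, 12 sites, with divergence injected at
sites 4 and 9 (group 1 fixed to C/D, group 2 to W/Y):

```r
library(famcons)
aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
point <- function(l) { p <- setNames(rep(0, 20), aa); p[l] <- 1; p }

gen <- generate_two_groups(
  family_spec(150, sites = rep(list(4), 12), seed = 20),
  divergent_sites = list(`4` = list(point("C"), point("W")),
                         `9` = list(point("D"), point("Y"))))

prof <- entropy_profile(gen$proj, "group1")
conserved_sites(prof, s_max = 0.1, frac_min = 0.7)
#>   residue entropy frac amino_acid
#> 1       4       0    1          C
#> 2       9       0    1          D

dp <- divergence_profile(gen$proj, "group1", "group2")
head(dp[, c("site","kl_1","kl_2","s_1","s_2","modal_1","modal_2")], 4)
#>   site  kl_1  kl_2   s_1   s_2 modal_1 modal_2
#> 1    4 5.350 5.350 0.000 0.000       C       W
#> 2    9 5.350 5.350 0.000 0.000       D       Y
#> 3    7 0.221 0.190 0.969 0.935       N       K
#> 4    1 0.112 0.154 0.925 0.939       D       D
```

The two injected sites are fully conserved within each group (`S = 0`),
differ between groups (C vs W, D vs Y), and occupy the top divergence
ranks; background sites drawn from a shared Dirichlet distribution show
high within-group entropy and near-zero divergence.

End-to-end runs are driven by a single YAML config
(`run_sequence_pipeline()`, `run_structure_pipeline()`); a default config
with curator-supplied GDAP1 helix ranges, α6–α7-loop focus segment and CMT
site list ships in `inst/extdata/gdap1_default_config.yaml`.

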