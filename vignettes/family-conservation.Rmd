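---
title: "Conservation, divergence and structure networks in GST-fold families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation, divergence and structure networks in GST-fold families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcons)
```

## The problem

GDAP1 is a mitochondrial outer-membrane protein with a glutathione
S-transferase (GST)-like fold; dozens of missense mutations in it cause
Charcot-Marie-Tooth (CMT) neuropathy. Understanding which residues matter
requires two complementary views: sequence conservation within the
GDAP1/GDAP1L1 subfamily and across the much broader GST superfamily, and
the intramolecular interaction networks of the folded protein that
mutations can disturb. `famcons` implements both views as a reusable,
fully testable pipeline operating on user-supplied alignments and
structures.

## Conservation model

All per-site statistics are computed on a *reference projection*: the
alignment restricted to columns where a chosen reference sequence has a
residue, numbered 1..L along the ungapped reference so that every site
carries a reference residue number (Arg120, Ala247, ...). Projection
discards insertions relative to the reference; this loses information but
makes every result directly interpretable on the reference sequence and
its structure.

At each site the amino-acid distribution `p` is estimated from the column,
counting only the 20 standard residue types. Gaps and ambiguity codes
(B, Z, X, U, O, J) are missing data: they appear in neither the numerator
nor the denominator of `p`, but do lower the site's *non-gap fraction*
(observed residues over rows analysed), which is reported alongside every
score and used as a filter so that sparsely populated columns are not
over-interpreted.

Conservation is Shannon entropy with a base-20 logarithm,

$$S = -\sum_{j=1}^{20} p_j \log_{20} p_j,$$

which spans exactly [0, 1]: 0 for a single residue type, 1 for a column
uniform over all 20 types. The terms with `p_j = 0` contribute zero. Sites
with no observed residues are *undefined* (`NA`), deliberately distinct
from 0, which would mean perfect conservation. Default reporting
thresholds are `S <= 0.1` ("highly conserved", used within a subfamily),
`S < 0.2` ("conserved", appropriate across a superfamily as diverse as the
GSTs) and non-gap fraction `> 0.7`.

Between two subfamilies, per-site divergence is the Kullback-Leibler
divergence

$$D = \sum_{j=1}^{20} p_j \ln\frac{p_j}{q_j},$$

computed in both directions because KL is asymmetric, with the within-group
entropies and modal residues reported next to it. Entropy uses base 20 and
KL the natural logarithm; the two scales are conventional for each
statistic and are deliberately not harmonised. Empirical frequencies
contain zeros, under which KL is infinite whenever `q` lacks support, so
both distributions are smoothed by an additive pseudocount on the 20
counts (default 0.5, a Jeffreys-style choice; configurable, and
`pseudocount = 0` is allowed for distributions with shared support). Sites
are ranked by `max(KL_1, KL_2)`; a flag marks sites that are conserved in
at least one group (`S` below the conserved threshold) with differing
modal residues — the classic signature of specificity-determining
positions.

Two reporting conventions deal with gap-heavy sites. In the divergence
table a group's residue is printed as `-` when the group is gap-majority
at the site (non-gap fraction <= 0.5), making "mostly deletion" visibly
different from "no clear consensus" (ties are broken alphabetically).
Whether the non-gap fraction's denominator should be the analysed group or
the full alignment is genuinely ambiguous; the package uses the analysed
row subset, since that is the population the frequencies are estimated
from.

## Representative selection

For phylogeny input a large set is thinned to `k` representatives using
the pairwise distance matrix (1 minus fractional identity over mutually
non-gap columns; pairs with no comparable columns get distance 1). The
procedure repeatedly finds the globally closest remaining pair and removes
one member until `k` remain. Which member to remove is underdetermined by
"most even spread", so the package removes the member whose next-nearest
remaining neighbour is closer — the more redundant sequence — keeping
isolated ones; remaining ties fall back to lexicographic id, making the
procedure fully deterministic. On small clustered instances (n <= 8, where
exhaustive search over all k-subsets is feasible) the greedy result
attains the optimal minimum retained pairwise distance; the test suite
verifies this, and also that the minimum retained spread is monotone
non-decreasing as `k` decreases. Merging reduced sets deduplicates on
identical id *or* identical residue string, keeping first occurrences and
logging what was removed.

## Structure analysis

Structures are read from PDB format (first model; alternate locations
resolved to the highest-occupancy conformer, ties to altloc A; waters and
heteroatoms kept but flagged). Superposition is the closed-form Kabsch
solution on shared Cα atoms — proper rotation enforced via the SVD
determinant correction — and the per-residue Cα deviation profile is the
Cα–Cα distance after fitting. The fit set defaults to all shared Cα;
restricting the *report* to a subset (for instance the hydrogen-bond
network residues) is a presentation choice and does not change the fit.
Whether a published deviation plot used whole-chain or sub-selection
fitting is usually unstated; fitting on everything is the conservative
default and is exposed as `fit_selection` for sensitivity checks.

Polar contacts are detected on heavy atoms, since crystal structures lack
hydrogens: a hydrogen bond is a donor N/O (with hydrogen implied by
residue chemistry) within `h_max` (default 3.5 Å) of an acceptor N/O,
with the angle at the donor between its covalent antecedent and the
acceptor at least `angle_min` (default 90°, a loose proxy that mainly
rejects geometrically impossible approaches); an ionic interaction is a
side-chain charged-group nitrogen of Arg/Lys/His within `i_max` (default
4.0 Å) of a side-chain carboxylate oxygen of Asp/Glu, and outranks the
hydrogen-bond label when both apply. Published contact counts rarely state
their criteria or whether they are residue-pair- or atom-pair-level, so
the network report always emits both counts (residue pairs deduplicated to
the closest atom pair by default, all-pairs switchable) and
`contact_cutoff_grid()` recomputes the counts across a cutoff grid rather
than asserting any single setting.

Helix boundary ranges are required configuration: they come from a
secondary-structure assignment the package does not perform. The shipped
default config (`inst/extdata/gdap1_default_config.yaml`) encodes
curator-supplied ranges for the GDAP1 core helices α3, α6, α7, α8 in the
reference numbering, the α6–α7 loop focus segment (236–246), and the list
of CMT missense sites; all are plainly editable data, not code.

Conservation painting writes `scale × S` (default scale 100) into the
B-factor of every atom of each scored residue, clamped to the PDB field
range [0, 999.99]; unscored residues get a sentinel (default −1) and are
listed, so downstream colouring cannot silently mix "conserved" with
"unknown". The mutation-overlap report classifies every residue seen in
the network, the CMT list or the conserved set as both / CMT-only /
conserved-only / neither, and lists the classified partners contacting the
focus segment.

## Synthetic data: what it does and does not emulate

The generators exist so that every estimator can be checked against known
truth. Alignment columns are drawn site-independently: a column
distribution is either given explicitly or drawn once from a symmetric
Dirichlet (concentration small = near-conserved, large = near-uniform),
and rows are i.i.d. from it, with gaps injected as independent masking at
a configurable rate. This matches the exchangeable-rows assumption the
entropy and KL estimators themselves make, which is exactly why it is the
right null for testing them — and why passing these tests says nothing
about phylogenetic correlation between real sequences, insertion/deletion
evolution, or alignment error, none of which are simulated. Two-group
families share realized distributions except at chosen divergent sites,
whose known identities must be recovered as the top divergence ranks.

Toy structures are ideal poly-alanine helices (rise 1.5 Å and turn 100°
per residue, radius 2.3 Å, consecutive Cα–Cα ≈ 3.8 Å) carrying backbone
N, CA, C, O; side-chain donor/acceptor pseudo-atoms for contact fixtures
are placed explicitly at engineered geometries (`add_atom()`), and
`perturb_structure()` applies known per-residue displacements and rigid
motions whose magnitudes must be recovered by the deviation profile.

## Validation design and problem sizes

The test suite checks the analytic anchors exactly (entropy 0 and 1 at the
two extremes; `log20 2` for a 50/50 column; the closed-form KL of
(0.5, 0.5) against (0.25, 0.75); a brute-force re-evaluation of the
smoothed KL sum), and the statistical properties at sizes chosen to keep
the full suite in seconds: entropy recovery at 50/500/5000 rows with
maximum absolute error required to shrink with n and fall below 0.02 at
5000; divergence recovery with 5 injected sites in 2 × 200 rows required
to occupy the top 5 ranks; representative selection compared against
exhaustive search at n <= 8; structure recovery of a 2.0 Å injected
displacement to 10⁻³ Å. The bio3d superposition serves as an independent
cross-check of the package's Kabsch implementation on a jittered helix.

## Known limitations

- Conservation scores ignore phylogenetic non-independence; a clade of
  near-duplicates inflates apparent conservation. No sequence weighting is
  applied.
- KL values depend on the pseudocount at sparsely populated sites; compare
  values only across sites computed with the same settings.
- Contact chemistry covers the 20 standard residues; modified residues are
  skipped (logged), and donor antecedents missing from the coordinates
  waive the angle test for that donor.
- Projection discards insertions relative to the reference, so sites
  unique to the other subfamily are invisible by construction.
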