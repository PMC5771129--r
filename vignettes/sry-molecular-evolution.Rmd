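---
title: "Methods: stem-branch substitutions and binding-energy bookkeeping for therian SRY"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stem-branch substitutions and binding-energy bookkeeping for therian SRY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sryevol)
```

# The scientific problem

SRY, the Y-chromosomal male-determining gene of therian mammals, arose from
the X-linked *SOX3* in the common ancestor of marsupials and placentals. Its
DNA-binding HMG domain (~78 residues) is the only part of the protein
conserved between the two therian lineages. Three questions structure the
analysis this package implements:

1. **How similar are marsupial and eutherian SRY HMG domains**, within and
   between clades, and is the gene under purifying selection (dN/dS)?
2. **Which amino-acid substitutions happened on which ancestral branch** —
   the stem of Theria (where SRY and SOX3 diverged), the stem of the
   marsupials, and the stem of the eutherians — and which of those derived
   residues have been conserved within each clade since?
3. **Do clade-specific conserved residues matter for DNA binding**, as probed
   by MM/PB-SA binding free energies computed over molecular-dynamics
   snapshots of SRY–DNA complexes?

The package provides each step as a tested function, a pipeline that runs
them in order, and seeded simulators that generate inputs with known ground
truth so every estimator can be validated by parameter recovery.

# Models and procedures

## Similarity and distances

"Similarity" is implemented as percent identity over mutually ungapped
columns, averaged over sequence pairs (cross-clade pairs for between-clade
values, unordered pairs excluding self for within-clade values). This is the
parsimonious reading of a percent similarity on an amino-acid alignment;
physico-chemical similarity groups (BLOSUM-style) are deliberately out of
scope. `X` is treated as missing, exactly like a gap.

Distance matrices for tree building use either the proportion of differing
sites (p-distance) or the Poisson correction $-\ln(1-p)$. Both require a
gap-free alignment; `complete_deletion()` removes every column containing a
gap or `X` first (the convention used for the published 58-column tree).

## Nei–Gojobori dN/dS

`nei_gojobori()` implements the unweighted-pathway NG86 estimator:

* *Potential sites.* Each codon position contributes the fraction of its
  three possible changes that are synonymous; changes creating a stop codon
  count as nonsynonymous. Sites are averaged over the two sequences.
* *Observed differences.* For codon pairs differing at 2 or 3 positions,
  synonymous and nonsynonymous steps are averaged over all minimal
  mutational pathways; pathways through a stop codon are excluded (all
  pathways are used if every one is blocked).
* *Correction.* Jukes–Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$, applied to
  both proportions; $\tfrac43 p \ge 1$ is a saturation error.

The aggregate over an alignment is `overall_dnds()` = mean(dN)/mean(dS)
across all unordered pairs. The mean-of-ratios alternative is unstable
whenever a pair's dS is near zero, which is the normal situation for
closely related Y-linked sequences, so the ratio-of-means is the default and
only aggregation. A subtlety worth knowing: when two *synonymous* changes
hit the same codon on different lineages, pathway averaging can register
fractional nonsynonymous steps (e.g. CGG→AGG and CGG→CGT meet through the
serine intermediate AGT), so "only synonymous changes" guarantees dN = 0
only while no codon carries two hits.

## Neighbor joining, bootstrap, rooting

`neighbor_joining()` is the classic Saitou–Nei agglomeration with two
determinism decisions: ties on the Q-criterion (within 1e-12) are broken by
the lexicographically smallest label pair, and a negative branch length is
clamped to zero with the deficit transferred to its sibling so the joined
pair's mutual distance is preserved. On additive matrices the algorithm is
exact, which the tests exploit (100 random additive matrices; a
least-squares sweep over all 15 five-taxon topologies; agreement with
`ape::nj` topologies). Bootstrap supports resample columns with replacement
and count bipartitions of the point-estimate tree across replicate NJ trees;
only NJ is offered because minimum-evolution, parsimony and likelihood tree
searches add no new information when the published topologies agree.
Rooting is on an outgroup (the sea-squirt SOXB1 gene in the canonical
setup), via `ape`.

## Parsimony reconstruction and stem classification

`fitch_reconstruct()` computes, per gap-free column, the minimum number of
unordered state changes on the rooted tree. It is implemented as an
equal-cost Sankoff dynamic program over the observed residues, which gives
identical scores to set-based Fitch parsimony and, more importantly, exact
*MPR sets* (the states each node can take in at least one minimal
labelling) and an exact per-edge necessity test: a change is *forced* onto
an edge precisely when constraining parent and child to share a state
raises the tree score. Resolutions:

* **DELTRAN** (default): the parent's state is retained wherever it remains
  optimal, pushing changes toward the tips.
* **ACCTRAN**: a change is taken as early as optimality allows; kept for
  cross-checks.

`map_substitutions()` emits one event per (branch, site) where the DELTRAN
states differ, flagging an event **ambiguous** when an equally parsimonious
labelling removes it from that branch (the per-edge necessity test). This
definition was chosen over the looser "DELTRAN and ACCTRAN disagree" check
because the latter misses symmetric cases — for tip states K,Q,K,Q on a
balanced quartet both resolutions park the changes on the same two terminal
branches even though two other placements are equally parsimonious —
while the necessity test is exact. Events whose branch is certain but whose
endpoint residues vary between labellings are *not* flagged: counts concern
placement, not state identity.

`classify_stem_substitutions()` then assigns events to the three stem
branches (edges subtending all therian SRY leaves, all marsupial SRY
leaves, all eutherian SRY leaves) and reports unambiguous counts as the
headline numbers, with ambiguous events tallied separately. Clades must be
monophyletic in the supplied tree; violations are reported with the
offending leaves.

## Substitution tempo

`tempo_test()` compares two lineages' stem substitution rates with a
two-tailed Fisher exact test (minimum-likelihood summation over tables with
fixed margins; `fisher_exact()` is validated against full hypergeometric
enumeration for every table with total count up to 40). Two table
constructions are offered because the published comparison does not pin one
down: `per_site` uses (count, sites − count) rows; `per_time` scales the
opportunity by branch duration in million years, rounding
sites × duration to integer exposure. Per-site is the default; the
million-year spans of the fixture tree (≈30 for the therian stem) are
carried as an attribute for per-time use.

## MM/PB-SA aggregation

Molecular dynamics and Poisson–Boltzmann solving are out of scope; the
module consumes per-snapshot component energies (the upstream solver's
dielectrics, 1.0 solute / 80.0 solvent, are metadata here). Per snapshot
and molecule,

$$G = E_\mathrm{internal} + E_\mathrm{electrostatic} + E_\mathrm{vdW}
      + G^\mathrm{polar}_\mathrm{solv} + G^\mathrm{nonpolar}_\mathrm{solv},
\qquad G^\mathrm{nonpolar}_\mathrm{solv} = \gamma A + b,$$

and the binding energy is $\Delta G = G(\mathrm{complex}) -
G(\mathrm{apoprotein}) - G(\mathrm{free\ ligand})$, averaged over snapshots
with a sample (n−1) standard deviation. The entropy term is disabled and
cannot be switched on: the upstream protocol does not compute it, and
accepting a TS column silently would invite inconsistent comparisons.
Defaults $\gamma = 0.00542$ kcal/mol/Å², $b = 0.92$ kcal/mol are the
conventional MM/PB-SA surface-tension constants; both are configurable.
Under a single-trajectory protocol (apoprotein and DNA conformations
extracted from the complex trajectory) the internal-energy component
cancels exactly, which the toy-table tests assert. The production sampling
window, 20–50 ns at 300 ps, holds exactly 100 snapshots
(`snapshot_count()`).

Variant ranking (`compare_variants()`) orders by mean ΔG ascending (more
negative = higher predicted affinity). The pooled-SD z-scores are
descriptive only: snapshots along one trajectory are autocorrelated, so no
formal test is attached.

# The synthetic-data generator

`simulate_alignment()` evolves a root sequence down a tree: per branch, a
Poisson(rate × branch length × sites) number of background substitutions
(uniform site, uniform alternative residue), then any *planted* events,
applied deterministically. The full event log is returned, so recovery can
be scored exactly. The bundled scenario is:

* **Tree** (`fixture_tree()`): 17 leaves — sea-squirt SOXB1 outgroup at the
  root, SOX1/SOX2/SOX3 clades, and a therian SRY clade sister to SOX3 with
  five eutherian and five marsupial leaves. Branch lengths are in
  substitutions/site, set from the published divergence scales (within-clade
  identity around 79–85%, SRY vs SOX3 around 48 differing sites of 78) —
  short terminal branches inside the SRY clade, 0.12–0.2 stems, long SOX
  and outgroup branches.
* **Root** (`fixture_root_seq()`): a 78-residue HMG-like sequence carrying
  the ancestral residues I55, K59, V64, E68.
* **Planted events** (`fixture_planted_events()`): 4 on the therian stem,
  7 on the marsupial stem, 13 on the eutherian stem, at 24 distinct sites;
  the eutherian set includes I55F, K59Q, E68K and the marsupial set V64K, so
  the conservation caller has its canonical positions to find.

Two background-rate regimes are used deliberately:

* `0` and `0.02`/site for **reconstruction studies**: at 0 the pipeline must
  return exactly 4/7/13 with no ambiguity; at 0.02 roughly nine background
  events land across the tree per replicate.
* `1.0` for **tree-building studies**: branch lengths are then realized
  directly as expected substitutions/site, giving leaf divergences on the
  scale of the real data.

What the generator does *not* emulate: site-specific constraint,
exchangeability structure, rate heterogeneity and indels. The main visible
consequence is that deep divergences saturate faster than real protein
sequences do — with 78 sites and a uniform 20-state model, the SOX3+SRY
sister grouping is recovered from sequence data in only about 72% of
replicates even though the therian SRY clade and both subclades are
recovered essentially always. Passing tests therefore demonstrate correct
*method* behaviour under the stated model, not that 78 real sites always
suffice for every deep node.

`simulate_codons()` plants requested numbers of synonymous and
nonsynonymous changes, each in a distinct codon (so the planted counts are
exactly the observable differences), on a star phylogeny — every sequence
descends independently from the root. A star suffices for everything the
codon stages need; a full tree version would only re-test machinery already
covered by the amino-acid simulator. `generate_energy_table()` draws
independent normals per component, species and snapshot;
`energy_means_for_target()` builds component means under the
single-trajectory convention (internal energies cancel; 1500 Å² buried on
binding) whose implied ΔG equals a requested target, and
`implied_delta_g_sd()` gives the exact ΔG spread, so estimator-consistency
tests can use 4σ/√n bounds with no free constants.

# Parameter-recovery results the tests enforce

* Rate 0: the pipeline reports exactly 4/7/13 unambiguous stem events.
* Rate 0.02, 200 seeded replicates: every planted event is mapped to its
  true branch in ≥95% of replicates (measured 97%). The stricter demand
  that unambiguous stem *counts* equal the background-inclusive truth holds
  in 83–90% — the shortfall is genuine parsimony ambiguity: when a
  background event hits a planted site on an adjacent stem branch, several
  labelings tie and no parsimony method can prefer one. This is a property
  of the inference problem, not of the implementation, and it is why
  ambiguous events are reported separately rather than silently resolved.
* Fisher exact equals full enumeration for all 2×2 tables with N ≤ 40;
  Nei–Gojobori equals a pathway-enumeration oracle on random codon pairs;
  NJ recovers generating trees from additive matrices exactly; parsimony
  scores equal exhaustive-labelling minima on all random trees up to six
  leaves; binding-energy means recover generator targets within 4σ/√n.

# Numerical choices and degenerate inputs

* NJ Q-ties broken lexicographically; negative branches clamped with
  transfer; MPR/necessity comparisons use a 1e-9 slack on integer-valued
  scores; Fisher tie detection uses the conventional 1e-7 relative
  tolerance.
* Zero-distance leaves (identical sequences) join deterministically via the
  tie rule, so rate-0 alignments still yield usable trees.
* Degenerate Fisher margins return p = 1 with a warning; a pair with no
  mutually ungapped column is dropped from similarity averages with a
  warning, and an error is raised only if every pair drops.
* Terminal stop codons are trimmed with a message; internal stops are
  errors; codons containing gaps or `N` are skipped pairwise.
* dS = 0 leaves the dN/dS ratio `NA` with `ratio_defined = FALSE` rather
  than an infinity.

# Problem sizes

Default test and validation runs use the 17-leaf fixture with 78 sites, 200
replicates for recovery studies, 100-snapshot energy tables, and bootstrap
counts of 25–2000 depending on the check — sizes at which the full suite
and the reproduction script each complete in a few minutes on one core
while keeping Monte-Carlo error well inside the asserted bounds.

# Known limitations

* Similarity is percent identity; if a similarity-group definition was
  intended upstream, between-clade values shift by a few points.
* The ancestral reconstruction is parsimony-only (no ML/Bayesian marginal
  states) and skips gapped columns entirely; indel history is not modelled.
* The substitution-tempo contingency construction is underdetermined by the
  published analyses; both offered constructions are reasonable, neither is
  canonical.
* Binding energies depend on upstream MD/PB output; the module validates
  bookkeeping and estimator consistency, not force fields. The wild-type
  generator presets reproduce published mean binding energies *by
  construction* (they are generator parameters, not predictions).
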