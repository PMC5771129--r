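# sryevol

Molecular-evolution analysis of the therian sex-determining gene **SRY** and
its SOX relatives, for researchers studying how a duplicate of *SOX3* became
the mammalian male-determining gene. The package covers the complete
analysis chain around the ~78-residue HMG DNA-binding domain:

* **Alignment statistics** — HMG-domain windows, within/between-clade
  percent identity, complete deletion of gapped columns.
* **Selection** — pairwise Nei–Gojobori dN/dS (unweighted pathways,
  Jukes–Cantor correction) and an overall mean(dN)/mean(dS) ratio.
* **Phylogeny** — neighbor-joining from p-distance or Poisson-corrected
  amino-acid distances, column-bootstrap supports, outgroup rooting.
* **Ancestral substitutions** — Fitch parsimony reconstruction with exact
  detection of placement ambiguity, mapping of substitutions onto branches,
  and classification onto the therian / marsupial / eutherian **stem
  branches** together with within-clade conservation calls (the I55F, K59Q,
  E68K, V64K pattern).
* **Substitution tempo** — exact two-tailed Fisher tests comparing stem
  branches per site or per million years.
* **Binding energetics** — MM/PB-SA bookkeeping over per-snapshot MD energy
  components:
  ΔG_binding = G(complex) − {G(apoprotein) + G(free ligand)}, with
  G = ⟨E_int⟩ + ⟨E_elec⟩ + ⟨E_vdW⟩ + ⟨G_polar⟩ + ⟨γA + b⟩ and no entropy
  term, plus variant ranking by mean ΔG.
* **Simulators** — seeded generators for alignments evolved on the SRY/SOX
  topology with planted stem substitutions, codon sets with controlled
  synonymous/nonsynonymous changes, and snapshot energy tables; every
  generator returns its exact ground truth.

See `vignettes/sry-molecular-evolution.Rmd` for the models, parameter
choices and validation design.

## Worked example

The bundled fixture is a 17-leaf SRY/SOX tree (sea-squirt SOXB1 outgroup,
SOX1–3 clades, therian SRY clade sister to SOX3) with 4 + 7 + 13
substitutions planted on the therian, marsupial and eutherian stem
branches of a 78-residue HMG-like root sequence.

```r
library(sryevol)

sim <- simulate_alignment(sim_spec(background_rate = 0, seed = 42))
sim$alignment
#> aligned_set: 17 sequences x 78 columns
#> clades: eutheria=5, marsupialia=5, other=1, sox_outgroup=6

rec <- fitch_reconstruct(fixture_tree(), sim$alignment)
rec
#> fitch_recon: 78 sites reconstructed (0 skipped), total parsimony score 24

classify_stem_substitutions(map_substitutions(rec),
                            fixture_tree(), fixture_clades())
#> stem substitution report (unambiguous events):
#>   therian_stem       4   (+0 ambiguous)
#>   marsupial_stem     7   (+0 ambiguous)
#>   eutherian_stem    13   (+0 ambiguous)
#>   other              0   (+0 ambiguous)
```

With no background noise the planted 4/7/13 come back exactly. Adding
background substitutions (0.02/site) shows how genuinely ambiguous
placements are reported rather than silently resolved — here the simulator's
true stem counts were 6/7/13 and two events tie between branches:

```r
sim <- simulate_alignment(sim_spec(background_rate = 0.02, seed = 42))
rec <- fitch_reconstruct(fixture_tree(), sim$alignment)
classify_stem_substitutions(map_substitutions(rec),
                            fixture_tree(), fixture_clades())
#> stem substitution report (unambiguous events):
#>   therian_stem       5   (+0 ambiguous)
#>   marsupial_stem     7   (+1 ambiguous)
#>   eutherian_stem    12   (+1 ambiguous)
#>   other              5   (+3 ambiguous)

clade_similarity(sim$alignment, "marsupialia", "eutheria")
#> [1] 74.1  (percent identity, attribute n_pairs = 25)
```

Binding-energy aggregation over a 100-snapshot energy table generated at
the human wild-type mean:

```r
tab <- generate_energy_table(100, energy_means_for_target(-243.42), seed = 1)
delta_g_binding(tab)
#> dG_binding = -240.85 kcal/mol (sd 16.29, n = 100 snapshots)
#> component means: e_internal=0.82, e_elec=-2498.43, e_vdw=-180.64,
#>                  g_polar=2446.49, g_np=-9.08
```

The full chain — similarity table, dN/dS, NJ tree with bootstrap, stem
report, conservation calls, tempo tests, tab-separated outputs plus a
summary — runs from one seeded configuration:

```r
res <- run_full_analysis(run_config(
  alignment = sim$alignment, outgroup = "seasquirt_SOXB1",
  bootstrap = 1000, seed = 42, out_dir = "run1"))
```

Real data plug in the same way: an aligned amino-acid FASTA, a two-column
name→clade map, optionally a codon FASTA and a newick tree
(`read_aligned_fasta()`, `read_clade_map()`, `read_codon_fasta()`,
`read_newick()`).

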