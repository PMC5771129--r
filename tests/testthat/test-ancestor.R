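test_that("fitch reconstruction matches direct expectations on tiny cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # invariant column: score 0, every node that residue
  aln0 <- aln_from_strings(c(A = "K", B = "K", C = "K", D = "K"))
  r0 <- fitch_reconstruct(tr, aln0)
  expect_equal(r0$score, 0L)
  expect_true(all(r0$deltran == "K"))
  expect_equal(nrow(map_substitutions(r0)), 0)

  # K,K,Q,Q: score 1, placement ambiguous between the two basal edges
  aln1 <- aln_from_strings(c(A = "K", B = "K", C = "Q", D = "Q"))
  r1 <- fitch_reconstruct(tr, aln1)
  expect_equal(r1$score, 1L)
  expect_equal(oracle_parsimony_min(tr, c(A = "K", B = "K", C = "Q", D = "Q")), 1)
  ev1 <- map_substitutions(r1)
  expect_equal(nrow(ev1), 1)
  expect_true(all(ev1$ambiguous))

  # K,Q,K,Q: score 2, both events movable
  aln2 <- aln_from_strings(c(A = "K", B = "Q", C = "K", D = "Q"))
  r2 <- fitch_reconstruct(tr, aln2)
  expect_equal(r2$score, 2L)
  ev2 <- map_substitutions(r2)
  expect_equal(nrow(ev2), 2)
  expect_true(all(ev2$ambiguous))

  expect_error(fitch_reconstruct(tr, aln_from_strings(c(A = "K", B = "K", C = "K"))),
               "missing from alignment")
})

test_that("per-site score equals the exhaustive labelling minimum on random trees", {
  for (s in 1:50) {
    case <- random_parsimony_case(3000 + s)
    aln <- aligned_set(matrix(case$states, ncol = 1,
                              dimnames = list(names(case$states), NULL)))
    r <- fitch_reconstruct(case$tree, aln)
    expect_equal(r$score, oracle_parsimony_min(case$tree, case$states),
                 info = paste("seed", 3000 + s))
    # the DELTRAN resolution is itself a minimal labelling
    lab <- r$deltran[, 1]
    changes <- sum(lab[case$tree$edge[, 1]] != lab[case$tree$edge[, 2]])
    expect_equal(changes, r$score)
    # total mapped events per site >= score; equal when none ambiguous
    ev <- map_substitutions(r)
    expect_gte(nrow(ev), r$score)
    if (nrow(ev) > 0 && !any(ev$ambiguous)) expect_equal(nrow(ev), r$score)
  }
})

test_that("gapped columns are skipped with the complete-deletion convention", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- aln_from_strings(c(A = "K-A", B = "KQA", C = "KQX", D = "KQA"))
  expect_message(r <- fitch_reconstruct(tr, aln), "skipped")
  expect_equal(r$sites, 1L)
  expect_equal(r$skipped_sites, c(2L, 3L))
})

test_that("planted single changes are recovered unambiguously on their branch", {
  tr <- fixture_tree()
  euth_node <- branch_node(tr, names(fixture_clades())[fixture_clades() == "eutheria"])
  ev_in <- data.frame(node = euth_node, site = 10, to = "W")
  sim <- simulate_alignment(sim_spec(background_rate = 0,
                                     planted_events = ev_in, seed = 2))
  r <- fitch_reconstruct(tr, sim$alignment)
  ev <- map_substitutions(r)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$site, 10)
  expect_equal(ev$child, euth_node)
  expect_equal(ev$to, "W")
  expect_false(ev$ambiguous)
})

test_that("stem classification reproduces planted 4/7/13 and is order-invariant", {
  tr <- fixture_tree()
  cl <- fixture_clades()
  sim <- simulate_alignment(sim_spec(background_rate = 0, seed = 11))
  r <- fitch_reconstruct(tr, sim$alignment)
  rep1 <- classify_stem_substitutions(map_substitutions(r), tr, cl)
  expect_equal(rep1$counts[["therian_stem"]], 4L)
  expect_equal(rep1$counts[["marsupial_stem"]], 7L)
  expect_equal(rep1$counts[["eutherian_stem"]], 13L)
  expect_equal(rep1$counts[["other"]], 0L)
  expect_equal(sum(rep1$ambiguous_counts), 0L)

  # leaf-order invariance: permute alignment rows
  perm <- sim$alignment$seqs[rev(rownames(sim$alignment$seqs)), ]
  aln_perm <- aligned_set(perm, cl)
  rep2 <- classify_stem_substitutions(
    map_substitutions(fitch_reconstruct(tr, aln_perm)), tr, cl)
  expect_identical(rep1$counts, rep2$counts)

  # no-variation alignment: all counts zero
  flat <- aligned_set(matrix("K", length(tr$tip.label), 5,
                             dimnames = list(tr$tip.label, NULL)), cl)
  rep0 <- classify_stem_substitutions(
    map_substitutions(fitch_reconstruct(tr, flat)), tr, cl)
  expect_true(all(rep0$counts == 0))
})

test_that("non-monophyletic clades are rejected with the offending leaves named", {
  tr <- fixture_tree()
  cl <- fixture_clades()
  cl[["human_SOX3"]] <- "eutheria"  # breaks eutherian monophyly
  sim <- simulate_alignment(sim_spec(background_rate = 0, seed = 1))
  ev <- map_substitutions(fitch_reconstruct(tr, sim$alignment))
  expect_error(classify_stem_substitutions(ev, tr, cl),
               "not monophyletic.*human_SOX3")
})

test_that("within-clade conservation calls report shared residues only", {
  sim <- simulate_alignment(sim_spec(background_rate = 0, seed = 3))
  aln <- sim$alignment
  # planted eutherian-specific E68K and marsupial-specific V64K
  expect_equal(conserved_within_clade(aln, "eutheria", 68), "K")
  expect_equal(conserved_within_clade(aln, "marsupialia", 64), "K")
  expect_equal(conserved_within_clade(aln, "eutheria", 55), "F")
  # site 64 is planted only in marsupials: eutherians keep the ancestral V
  expect_equal(conserved_within_clade(aln, "eutheria", 64), "V")
  # invariant site: every clade agrees
  expect_equal(conserved_within_clade(aln, "sox_outgroup", 1), "M")
  # non-conserved site returns NA
  m <- aln$seqs
  m["human_SRY", 2] <- "W"
  aln2 <- aligned_set(m, aln$clades)
  expect_true(is.na(conserved_within_clade(aln2, "eutheria", 2)))
  expect_error(conserved_within_clade(aln, "eutheria", 99), "out of range")
})
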