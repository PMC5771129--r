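test_that("amino-acid distances match closed forms and a naive oracle", {
  aln <- aln_from_strings(c(a = "AAAAAAAAAA", b = "AAAAAAAACC",
                            c = "CCCCCAAAAA", d = "AAAAAAAAAA"))
  d_p <- aa_distance_matrix(aln, "p_distance")
  expect_equal(d_p["a", "d"], 0)
  expect_equal(d_p["a", "b"], 0.2)
  d_pois <- aa_distance_matrix(aln, "poisson")
  expect_equal(d_pois["a", "b"], -log(0.8))
  # element-wise naive mismatch counting
  for (i in rownames(d_p)) for (j in rownames(d_p))
    expect_equal(d_p[i, j], mean(aln$seqs[i, ] != aln$seqs[j, ]))
  expect_true(isSymmetric(d_p))

  gapped <- aln_from_strings(c(a = "A-A", b = "AAA"))
  expect_error(aa_distance_matrix(gapped), "complete_deletion")
  sat <- aln_from_strings(c(a = "AAAA", b = "CCCC"))
  expect_error(aa_distance_matrix(sat, "poisson"), "p >= 1")
})

test_that("nei_gojobori handles degenerate and single-difference codon pairs", {
  same <- nei_gojobori("ATGAAACCC", "ATGAAACCC")
  expect_equal(same$dn, 0)
  expect_equal(same$ds, 0)
  expect_false(same$ratio_defined)
  expect_true(is.na(same$ratio))
  expect_equal(same$n_sites + same$s_sites, 9)

  # AAA (K) -> AGA (R): one nonsynonymous difference
  r <- nei_gojobori("ATGAAA", "ATGAGA")
  o <- oracle_ng("ATGAAA", "ATGAGA")
  expect_gt(r$dn, 0)
  expect_equal(r$ds, 0)
  expect_equal(r$dn, o$dn)
  expect_equal(r$s_sites, o$S)
  expect_equal(r$nd, o$Nd)

  expect_error(nei_gojobori("ATGAAA", "ATG"), "length")
  expect_error(nei_gojobori("ATGTAAAAA", "ATGTAAAAA"), "internal stop")
})

test_that("codons containing gaps or N are skipped pairwise", {
  r <- nei_gojobori("ATG---AAA", "ATGCCCAAA")
  expect_equal(r$n_codons, 2)
  r2 <- nei_gojobori("ATGNNNAAA", "ATGCCCAAA")
  expect_equal(r2$n_codons, 2)
})

test_that("nei_gojobori is symmetric and matches the pathway oracle on random pairs", {
  with_seed2(42, {
    for (k in 1:12) {
      a <- random_coding(15)
      b <- mutate_coding(a, sample(1:8, 1))
      r_ab <- nei_gojobori(a, b)
      r_ba <- nei_gojobori(b, a)
      expect_equal(r_ab$dn, r_ba$dn)
      expect_equal(r_ab$ds, r_ba$ds)
      expect_equal(r_ab$s_sites, r_ba$s_sites)
      o <- oracle_ng(a, b)
      expect_equal(r_ab$dn, o$dn, tolerance = 1e-12)
      expect_equal(r_ab$ds, o$ds, tolerance = 1e-12)
      expect_equal(r_ab$nd, o$Nd, tolerance = 1e-12)
      expect_equal(r_ab$sd, o$Sd, tolerance = 1e-12)
    }
  })
})

test_that("dn and ds are monotone as additional differences are planted", {
  # plant one nonsynonymous change per codon, each in a fresh codon, so the
  # difference set only ever grows
  root_codons <- rep(c("ATG", "CTG", "AAA", "CGT", "TGG", "CAT"), 2)
  mutants <- vapply(root_codons, function(cd) {
    for (pos in 1:3) for (n in c("A", "C", "G", "T")) {
      mut <- cd
      substr(mut, pos, pos) <- n
      if (mut != cd && oracle_translate(mut) != "*" &&
          oracle_translate(mut) != oracle_translate(cd)) return(mut)
    }
    stop("unreachable")
  }, character(1))
  root <- paste(root_codons, collapse = "")
  prev_dn <- -1
  for (k in seq_along(root_codons)) {
    derived <- paste(c(mutants[seq_len(k)], root_codons[-seq_len(k)]),
                     collapse = "")
    r <- nei_gojobori(root, derived)
    expect_gt(r$dn, prev_dn)
    prev_dn <- r$dn
  }
  # planting only synonymous changes moves ds, never dn
  sim <- simulate_codons(codon_sim_spec(
    root, data.frame(name = "s1", n_syn = 4, n_nonsyn = 0), seed = 3))
  r <- nei_gojobori(root, sim$seqs[["s1"]])
  expect_equal(r$dn, 0)
  expect_gt(r$ds, 0)
})

test_that("overall dn/ds aggregates pairs and reflects planted selection", {
  root <- paste(rep("ATGCTGAAACGTTGGCAT", 4), collapse = "")
  # strong nonsynonymous excess
  simN <- simulate_codons(codon_sim_spec(
    root, data.frame(name = c("a", "b", "c"),
                     n_syn = c(1, 0, 1), n_nonsyn = c(9, 8, 9)), seed = 5))
  oN <- overall_dnds(simN$seqs)
  expect_gt(oN$ratio, 1)
  # purely synonymous changes in disjoint codons across the three sequences,
  # so no codon ever carries two hits (two same-codon synonymous hits can
  # legitimately register fractional nonsynonymous pathway steps)
  rc <- c("GCT", "CGT", "GGA", "CTG", "ACG", "TCT", "GTA", "CCG", "AAA")
  syn_of <- c(GCT = "GCC", CGT = "CGC", GGA = "GGG", CTG = "CTA",
              ACG = "ACA", TCT = "TCC", GTA = "GTG", CCG = "CCA", AAA = "AAG")
  mk <- function(idx) paste(ifelse(seq_along(rc) %in% idx, syn_of[rc], rc),
                            collapse = "")
  seqsS <- c(a = mk(1:3), b = mk(4:6), c = mk(7:9))
  oS <- overall_dnds(seqsS)
  expect_equal(oS$ratio, 0)
  # two sequences degenerate to the single pairwise estimate
  two <- overall_dnds(simN$seqs[1:2])
  pw <- nei_gojobori(simN$seqs[[1]], simN$seqs[[2]])
  expect_equal(two$ratio, pw$dn / pw$ds)
  expect_error(overall_dnds(simN$seqs[1]), ">= 2")
})

test_that("neutral mutation drives the overall ratio toward 1", {
  with_seed2(99, {
    root <- random_coding(250)
    seqs <- c(s1 = mutate_coding(root, 45), s2 = mutate_coding(root, 45),
              s3 = mutate_coding(root, 45), s4 = mutate_coding(root, 45))
    o <- overall_dnds(seqs)
    expect_gt(o$ratio, 0.7)
    expect_lt(o$ratio, 1.35)
  })
})

test_that("terminal stop codons are trimmed, coding FASTA reads named vectors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ATGAAACCCTAA", ">b", "ATGAAACCG"), fa)
  seqs <- suppressMessages(read_codon_fasta(fa))
  expect_equal(unname(nchar(seqs[["a"]])), 9)
  expect_equal(names(seqs), c("a", "b"))
})
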