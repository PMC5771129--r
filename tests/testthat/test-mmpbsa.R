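test_that("snapshot window arithmetic", {
  expect_equal(snapshot_count(c(20, 50, 300)), 100L)
  expect_equal(snapshot_count(c(0, 1, 1000)), 1L)
  expect_equal(snapshot_count(c(20, 50, 100)), 300L)
  expect_error(snapshot_count(c(50, 20, 300)), "end > start")
  expect_error(snapshot_count(c(20, 50, 0)), "stride")
})

test_that("g_molecule sums components with the gamma*A + b nonpolar term", {
  cfg <- mmpbsa_config()
  zero <- list(e_internal = 0, e_elec = 0, e_vdw = 0, g_polar = 0,
               sasa = 0, g_nonpolar = NA)
  expect_equal(g_molecule(zero, mmpbsa_config(b = 0)), 0)
  snap <- list(e_internal = 10, e_elec = -50, e_vdw = -20, g_polar = -30,
               sasa = 1000, g_nonpolar = NA)
  expect_equal(g_molecule(snap, cfg), -83.66)
  # linearity in gamma: doubling gamma adds gamma * A
  g2 <- g_molecule(snap, mmpbsa_config(gamma = 2 * cfg$gamma))
  expect_equal(g2 - g_molecule(snap, cfg), cfg$gamma * 1000)
  # explicit g_nonpolar takes precedence over sasa
  snap$g_nonpolar <- 7
  expect_equal(g_molecule(snap, cfg), 10 - 50 - 20 - 30 + 7)
  expect_error(g_molecule(list(e_internal = 0, e_elec = 0, e_vdw = 0,
                               g_polar = 0), cfg), "sasa or g_nonpolar")
  expect_error(mmpbsa_config(include_entropy = TRUE), "entropy")
})

toy_table <- function() {
  # 3 snapshots with hand-set components (g_nonpolar given directly)
  rows <- list()
  comp <- list(
    complex     = list(c(10, -200, -40, 120, 3), c(12, -210, -38, 125, 3),
                       c(11, -205, -42, 118, 3)),
    apoprotein  = list(c(6, -80, -15, 60, 1), c(7, -85, -14, 62, 1),
                       c(6, -82, -16, 61, 1)),
    free_ligand = list(c(4, -40, -5, 30, 1), c(5, -45, -4, 32, 1),
                       c(5, -44, -6, 31, 1)))
  for (sp in names(comp))
    for (i in 1:3) {
      v <- comp[[sp]][[i]]
      rows[[length(rows) + 1]] <- data.frame(
        snapshot_id = i, species = sp, e_internal = v[1], e_elec = v[2],
        e_vdw = v[3], g_polar = v[4], sasa = NA_real_, g_nonpolar = v[5])
    }
  do.call(rbind, rows)
}

test_that("delta_g_binding matches hand arithmetic on a toy table", {
  tab <- toy_table()
  res <- delta_g_binding(tab)
  # per-snapshot hand sums
  g <- function(v) sum(v)
  dg <- c(g(c(10, -200, -40, 120, 3)) - g(c(6, -80, -15, 60, 1)) - g(c(4, -40, -5, 30, 1)),
          g(c(12, -210, -38, 125, 3)) - g(c(7, -85, -14, 62, 1)) - g(c(5, -45, -4, 32, 1)),
          g(c(11, -205, -42, 118, 3)) - g(c(6, -82, -16, 61, 1)) - g(c(5, -44, -6, 31, 1)))
  expect_equal(res$per_snapshot, dg)
  expect_equal(res$mean, mean(dg))
  expect_equal(res$sd, stats::sd(dg))
  expect_equal(res$n, 3)
  # linearity: mean dG decomposes over components
  expect_equal(sum(res$components), res$mean)
  # order invariance
  res2 <- delta_g_binding(tab[sample(nrow(tab)), ])
  expect_equal(res2$mean, res$mean)
  expect_equal(res2$sd, res$sd)
})

test_that("exact cancellation gives dG = 0 with zero spread", {
  tab <- toy_table()
  # rebuild complex rows as the exact sum of the parts, snapshot-wise
  for (i in 1:3) {
    parts <- tab[tab$snapshot_id == i & tab$species != "complex", ]
    for (col in c("e_internal", "e_elec", "e_vdw", "g_polar", "g_nonpolar"))
      tab[tab$snapshot_id == i & tab$species == "complex", col] <- sum(parts[[col]])
  }
  res <- delta_g_binding(tab)
  expect_equal(res$mean, 0)
  expect_equal(res$sd, 0)
})

test_that("missing or duplicated species rows are rejected by name", {
  tab <- toy_table()
  expect_error(delta_g_binding(tab[tab$species != "free_ligand" |
                                   tab$snapshot_id != 2, ]),
               "missing species 'free_ligand': 2")
  expect_error(delta_g_binding(rbind(tab, tab[1, ])), "duplicate")
})

test_that("generator-implied means and SDs are recovered from seeded tables", {
  cfg <- mmpbsa_config()
  for (target in c(-243.42, -208.53)) {
    means <- energy_means_for_target(target, cfg)
    expect_equal(expected_delta_g(means, cfg), target)
    sds <- default_energy_sds()
    sigma <- implied_delta_g_sd(sds, cfg)
    tab <- generate_energy_table(100, means, sds, seed = round(abs(target)))
    res <- delta_g_binding(tab, cfg)
    expect_equal(res$n, 100)
    expect_lt(abs(res$mean - target), 4 * sigma / sqrt(100))
    expect_lt(abs(res$sd - sigma), 0.5 * sigma)
  }
  # internal energy cancels in expectation under the single-trajectory preset
  means <- energy_means_for_target(-100)
  expect_equal(means$complex[["e_internal"]],
               means$apoprotein[["e_internal"]] + means$free_ligand[["e_internal"]])
})

test_that("energy tables round-trip through the tab-separated format", {
  tab <- generate_energy_table(5, energy_means_for_target(-50), seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(tab, f)
  back <- read_energy_table(f)
  expect_equal(back$e_elec, tab$e_elec)
  expect_equal(delta_g_binding(back)$mean, delta_g_binding(tab)$mean)
})

test_that("variant ranking orders by mean dG, ties and singletons handled", {
  cfg <- mmpbsa_config()
  wt <- delta_g_binding(generate_energy_table(
    50, energy_means_for_target(-243, cfg), seed = 1), cfg)
  mut <- delta_g_binding(generate_energy_table(
    50, energy_means_for_target(-200, cfg), seed = 2), cfg)
  cmp <- compare_variants(list(wild_type = wt, mutant = mut))
  expect_equal(cmp$ranking$variant, c("wild_type", "mutant"))
  expect_lt(cmp$ranking$mean[1], cmp$ranking$mean[2])
  expect_equal(nrow(cmp$pairwise), 1)
  expect_lt(cmp$pairwise$diff, 0)

  tie <- compare_variants(list(a = wt, b = wt))
  expect_equal(tie$pairwise$diff, 0)
  one <- compare_variants(list(only = wt))
  expect_equal(nrow(one$ranking), 1)
  expect_equal(nrow(one$pairwise), 0)
})
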