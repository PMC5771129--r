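# Seeded generators for every input the pipeline consumes, with exact ground
# truth: amino-acid alignments evolved on the SRY/SOX fixture topology with
# planted stem-branch substitutions, codon sets with controlled
# synonymous/nonsynonymous changes, and MM/PB-SA snapshot energy tables.

#' Bundled HMG-like root sequence (78 residues)
#'
#' A synthetic ancestral HMG-domain-like sequence used as the simulation
#' root. Positions relevant to the stem-substitution scenario carry the
#' ancestral residues I55, K59, V64 and E68, so that the canonical planted
#' events (I55F, K59Q, V64K, E68K) are well defined.
#'
#' @return Character scalar of length 78.
#' @export
fixture_root_seq <- function() {
  base <- paste0("MQDRVKRPMNAFIVWSRDQRRKMALENPRMRNSEISKQLGY",
                 "QWKMLTEAEKRPFIDEAKRLRAVHMKEHPDYKYRPRR")
  s <- strsplit(base, "")[[1]]
  stopifnot(length(s) == 78)
  s[c(55, 59, 64, 68)] <- c("I", "K", "V", "E")
  paste(s, collapse = "")
}

#' Bundled SRY/SOX fixture tree
#'
#' A rooted 16-leaf tree mirroring the canonical SRY/SOX topology: a sea
#' squirt SOXB1 outgroup at the root, SOX1, SOX2 and SOX3 clades, and a
#' monophyletic therian SRY clade sister to SOX3, split into eutherian and
#' marsupial subclades. Branch lengths are in substitutions per site, chosen
#' to reflect a strongly conserved HMG domain within therian SRY and deeper
#' divergence toward the SOX outgroups. The time span of the therian stem
#' branch (about 30 million years between the SRY/SOX3 differentiation and
#' the marsupial/eutherian split) is attached as attribute
#' `stem_duration_my`.
#'
#' @return Rooted `phylo` tree.
#' @export
fixture_tree <- function() {
  txt <- paste0(
    "(seasquirt_SOXB1:0.8,((human_SOX1:0.05,mouse_SOX1:0.05):0.3,",
    "((human_SOX2:0.05,mouse_SOX2:0.05):0.3,",
    "((human_SOX3:0.04,mouse_SOX3:0.04):0.25,",
    "(((human_SRY:0.08,horse_SRY:0.08):0.02,",
    "(mouse_SRY:0.1,(dog_SRY:0.06,cattle_SRY:0.06):0.03):0.02):0.15,",
    "((opossum_SRY:0.08,dunnart_SRY:0.08):0.03,",
    "(koala_SRY:0.05,(kangaroo_SRY:0.03,wallaby_SRY:0.03):0.02):0.04):0.12)",
    ":0.2):0.1):0.05):0.05);")
  tr <- ape::read.tree(text = txt)
  attr(tr, "stem_duration_my") <-
    c(therian_stem = 30, marsupial_stem = 79, eutherian_stem = 105)
  tr
}

#' Clade labels for the fixture tree
#' @return Named character vector usable as the `clades` argument of
#'   [aligned_set()].
#' @export
fixture_clades <- function() {
  c(seasquirt_SOXB1 = "other",
    human_SOX1 = "sox_outgroup", mouse_SOX1 = "sox_outgroup",
    human_SOX2 = "sox_outgroup", mouse_SOX2 = "sox_outgroup",
    human_SOX3 = "sox_outgroup", mouse_SOX3 = "sox_outgroup",
    human_SRY = "eutheria", horse_SRY = "eutheria", mouse_SRY = "eutheria",
    dog_SRY = "eutheria", cattle_SRY = "eutheria",
    opossum_SRY = "marsupialia", dunnart_SRY = "marsupialia",
    koala_SRY = "marsupialia", kangaroo_SRY = "marsupialia",
    wallaby_SRY = "marsupialia")
}

#' Child node of the branch subtending a leaf set
#'
#' Convenience for addressing planted events: the branch "above" a clade is
#' identified by its child node (the clade's MRCA, or the leaf itself).
#'
#' @param tree `phylo` tree.
#' @param leaves Leaf name(s).
#' @return ape node id (integer).
#' @export
branch_node <- function(tree, leaves) {
  stem_node(tree, leaves, paste(leaves, collapse = "+"))
}

# Deterministic "derived" residue: next amino acid in the canonical order.
derived_residue <- function(from) {
  i <- match(from, AA_ALPHABET)
  AA_ALPHABET[(i %% length(AA_ALPHABET)) + 1]
}

#' Canonical planted stem events for the fixture
#'
#' Four substitutions on the therian stem, seven on the marsupial stem and
#' thirteen on the eutherian stem, at 24 distinct sites. The eutherian set
#' includes I55F, K59Q and E68K and the marsupial set V64K, echoing the
#' clade-conserved residues the downstream conservation analysis looks for;
#' the remaining target residues are a deterministic function of the root
#' residue.
#'
#' @param tree The [fixture_tree()] (or a tree with the same leaf names).
#' @param root_seq Root sequence the `from` states come from.
#' @return data.frame with columns `node`, `site`, `to` suitable for
#'   [sim_spec()].
#' @export
fixture_planted_events <- function(tree = fixture_tree(),
                                   root_seq = fixture_root_seq()) {
  clades <- fixture_clades()
  euth <- names(clades)[clades == "eutheria"]
  mars <- names(clades)[clades == "marsupialia"]
  nodes <- c(therian = branch_node(tree, c(euth, mars)),
             marsupial = branch_node(tree, mars),
             eutherian = branch_node(tree, euth))
  root <- strsplit(root_seq, "")[[1]]
  sites <- list(therian = c(3, 12, 27, 41),
                marsupial = c(7, 18, 30, 44, 52, 64, 71),
                eutherian = c(5, 10, 15, 22, 25, 35, 38, 49, 55, 59, 62, 68, 74))
  special <- c("55" = "F", "59" = "Q", "64" = "K", "68" = "K")
  ev <- do.call(rbind, lapply(names(sites), function(nm) {
    s <- sites[[nm]]
    to <- ifelse(as.character(s) %in% names(special),
                 special[as.character(s)], derived_residue(root[s]))
    data.frame(node = nodes[[nm]], site = s, to = unname(to))
  }))
  stopifnot(all(ev$to != root[ev$site]))
  ev
}

#' Simulation specification for alignment evolution
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param root_seq Residue string at the root (default: the bundled
#'   78-residue HMG-like sequence).
#' @param background_rate Expected substitutions per site per branch-length
#'   unit (Poisson events per branch: `rate x branch_length x length`).
#' @param planted_events data.frame with columns `node` (branch child node),
#'   `site`, `to`; applied deterministically after the branch's random
#'   events.
#' @param clades Optional named clade vector attached to the output
#'   alignment.
#' @param seed Integer seed; identical specs and seeds give identical output.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(tree = fixture_tree(), root_seq = fixture_root_seq(),
                     background_rate = 0,
                     planted_events = fixture_planted_events(tree, root_seq),
                     clades = fixture_clades(), seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (background_rate < 0) stop("background_rate must be >= 0")
  L <- nchar(root_seq)
  if (!is.null(planted_events) && nrow(planted_events)) {
    if (any(planted_events$site < 1 | planted_events$site > L))
      stop("planted event site outside root sequence")
    if (anyDuplicated(planted_events[, c("node", "site")]))
      stop("conflicting planted events: same branch and site listed twice")
    if (any(!planted_events$node %in% seq_len(length(tree$tip.label) + tree$Nnode)))
      stop("planted event on unknown node")
  }
  structure(list(tree = tree, root_seq = toupper(root_seq),
                 background_rate = background_rate,
                 planted_events = planted_events, clades = clades,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Evolve an alignment on a tree with known ground truth
#'
#' Walks the tree from the root: on each branch, a Poisson number of random
#' substitutions (`background_rate x branch_length x sequence_length`;
#' uniform site, uniform alternative residue) is applied sequentially, then
#' any planted events for that branch are applied deterministically. Returns
#' the leaf alignment together with the exact per-branch event log.
#'
#' @param spec A [sim_spec()].
#' @return List with `alignment` (an [aligned_set] of the leaves), `events`
#'   (data.frame: `node`, `parent`, `site`, `from`, `to`, `planted`), and
#'   `tree`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- nchar(spec$root_seq)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  states <- matrix(NA_character_, nnode, L)
  states[root, ] <- strsplit(spec$root_seq, "")[[1]]
  log_rows <- list()
  with_seed(spec$seed, {
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; v <- edges[e, 2]
      cur <- states[p, ]
      n_bg <- stats::rpois(1, spec$background_rate * lens[e] * L)
      if (n_bg > 0) {
        for (k in seq_len(n_bg)) {
          site <- sample.int(L, 1)
          to <- sample(setdiff(AA_ALPHABET, cur[site]), 1)
          log_rows[[length(log_rows) + 1]] <- data.frame(
            node = v, parent = p, site = site, from = cur[site], to = to,
            planted = FALSE)
          cur[site] <- to
        }
      }
      pe <- spec$planted_events
      if (!is.null(pe) && nrow(pe)) {
        pe <- pe[pe$node == v, , drop = FALSE]
        for (k in seq_len(nrow(pe))) {
          site <- pe$site[k]
          log_rows[[length(log_rows) + 1]] <- data.frame(
            node = v, parent = p, site = site, from = cur[site],
            to = pe$to[k], planted = TRUE)
          cur[site] <- pe$to[k]
        }
      }
      states[v, ] <- cur
    }
  })
  m <- states[seq_len(ntip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  events <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(node = integer(), parent = integer(), site = integer(),
               from = character(), to = character(), planted = logical())
  list(alignment = aligned_set(m, spec$clades), events = events, tree = tree)
}

#' Net per-branch ground-truth substitutions
#'
#' Compresses a simulator event log to net changes per (branch, site): the
#' state at the start of the branch versus the state at its end, dropping
#' exact reversals.
#'
#' @param events Event log from [simulate_alignment()].
#' @return data.frame `node`, `site`, `from`, `to`.
#' @export
net_events <- function(events) {
  if (!nrow(events))
    return(data.frame(node = integer(), site = integer(),
                      from = character(), to = character()))
  key <- paste(events$node, events$site)
  out <- lapply(split(seq_len(nrow(events)), key), function(ix) {
    data.frame(node = events$node[ix[1]], site = events$site[ix[1]],
               from = events$from[ix[1]], to = events$to[ix[length(ix)]])
  })
  out <- do.call(rbind, out)
  out <- out[out$from != out$to, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$node, out$site), , drop = FALSE]
}

#' Ground-truth stem counts from a simulator log
#'
#' @param events Event log from [simulate_alignment()].
#' @param tree The simulation tree.
#' @param clades Clade labels for the tree's leaves.
#' @return Named integer vector: `therian_stem`, `marsupial_stem`,
#'   `eutherian_stem`, `other` (net events per category).
#' @export
true_stem_counts <- function(events, tree, clades) {
  net <- net_events(events)
  euth <- intersect(names(clades)[clades == "eutheria"], tree$tip.label)
  mars <- intersect(names(clades)[clades == "marsupialia"], tree$tip.label)
  nodes <- c(therian_stem = stem_node(tree, c(euth, mars), "theria"),
             marsupial_stem = stem_node(tree, mars, "marsupialia"),
             eutherian_stem = stem_node(tree, euth, "eutheria"))
  cls <- rep("other", nrow(net))
  for (nm in names(nodes)) cls[net$node == nodes[[nm]]] <- nm
  lev <- c("therian_stem", "marsupial_stem", "eutherian_stem", "other")
  v <- table(factor(cls, levels = lev))
  stats::setNames(as.integer(v), lev)
}

# --- codon simulation --------------------------------------------------------

#' Codon simulation specification
#'
#' Plants controlled numbers of synonymous and nonsynonymous changes on the
#' branches of a star phylogeny: every named sequence descends independently
#' from the same root codon string. Each planted change claims a distinct
#' codon within its sequence, so the requested counts are exactly the
#' observable single-nucleotide differences from the root.
#'
#' @param root_codons Coding nucleotide string (length divisible by 3, no
#'   internal stop).
#' @param changes data.frame with columns `name`, `n_syn`, `n_nonsyn`: the
#'   number of synonymous / nonsynonymous changes to plant on each
#'   sequence's branch.
#' @param seed Integer seed.
#' @return List of class `codon_sim_spec`.
#' @export
codon_sim_spec <- function(root_codons, changes, seed = 1) {
  root_codons <- check_coding(root_codons)
  stopifnot(all(c("name", "n_syn", "n_nonsyn") %in% names(changes)))
  if (anyDuplicated(changes$name)) stop("duplicate sequence names")
  structure(list(root_codons = toupper(root_codons), changes = changes,
                 seed = as.integer(seed)),
            class = "codon_sim_spec")
}

# Apply one random change of the requested kind (syn/nonsyn) at a codon from
# `avail`; never creates a stop codon. Each planted change claims a fresh
# codon so the requested counts are exactly observable in the output.
plant_codon_change <- function(cods, synonymous, avail) {
  nt <- c("T", "C", "A", "G")
  for (try in 1:2000) {
    ci <- if (length(avail) == 1) avail else sample(avail, 1)
    pos <- sample.int(3, 1)
    alt <- sample(setdiff(nt, substr(cods[ci], pos, pos)), 1)
    mut <- cods[ci]
    substr(mut, pos, pos) <- alt
    if (codon_table[[mut]] == "*") next
    same_aa <- codon_table[[mut]] == codon_table[[cods[ci]]]
    if (same_aa == synonymous) {
      cods[ci] <- mut
      return(list(cods = cods, used = ci))
    }
  }
  stop("could not plant a ", if (synonymous) "synonymous" else "nonsynonymous",
       " change (sequence too constrained)")
}

#' Simulate codon sequences with planted change counts
#'
#' @param spec A [codon_sim_spec()].
#' @return List with `seqs` (named character vector of coding sequences,
#'   first element the unchanged root as reference is NOT included) and
#'   `truth` (the `changes` table actually applied).
#' @export
simulate_codons <- function(spec) {
  stopifnot(inherits(spec, "codon_sim_spec"))
  n_codons <- length(split_codons(spec$root_codons))
  if (any(spec$changes$n_syn + spec$changes$n_nonsyn > n_codons))
    stop("more planted changes than codons (one change per codon)")
  with_seed(spec$seed, {
    seqs <- vapply(seq_len(nrow(spec$changes)), function(i) {
      cods <- split_codons(spec$root_codons)
      avail <- seq_along(cods)
      kinds <- c(rep(TRUE, spec$changes$n_syn[i]),
                 rep(FALSE, spec$changes$n_nonsyn[i]))
      for (syn in kinds) {
        res <- plant_codon_change(cods, syn, avail)
        cods <- res$cods
        avail <- setdiff(avail, res$used)
      }
      paste(cods, collapse = "")
    }, character(1))
    names(seqs) <- spec$changes$name
    list(seqs = seqs, truth = spec$changes)
  })
}

# --- energy-table generation -------------------------------------------------

#' Per-component means for a target binding energy
#'
#' Builds a plausible set of component means for complex, apoprotein and
#' free ligand under the single-trajectory convention (internal energies
#' cancel exactly; buried surface area of 1500 A^2 on binding) such that the
#' implied mean binding energy equals `target` under `cfg`.
#'
#' @param target Desired mean binding energy, kcal/mol.
#' @param cfg [mmpbsa_config()] used for the nonpolar term.
#' @return Named list of mean vectors (per species) with components
#'   `e_internal`, `e_elec`, `e_vdw`, `g_polar`, `sasa`.
#' @export
energy_means_for_target <- function(target, cfg = mmpbsa_config()) {
  apo <- c(e_internal = 2500, e_elec = -5500, e_vdw = -250,
           g_polar = -3800, sasa = 7000)
  lig <- c(e_internal = 800, e_elec = -3000, e_vdw = -80,
           g_polar = -4500, sasa = 4500)
  d_elec <- -2500; d_vdw <- -180; d_sasa <- -1500
  d_nonpolar <- cfg$gamma * d_sasa - cfg$b   # b enters once per molecule
  d_polar <- target - d_elec - d_vdw - d_nonpolar
  cpx <- c(e_internal = unname(apo["e_internal"] + lig["e_internal"]),
           e_elec = unname(apo["e_elec"] + lig["e_elec"] + d_elec),
           e_vdw = unname(apo["e_vdw"] + lig["e_vdw"] + d_vdw),
           g_polar = unname(apo["g_polar"] + lig["g_polar"] + d_polar),
           sasa = unname(apo["sasa"] + lig["sasa"] + d_sasa))
  list(complex = cpx, apoprotein = apo, free_ligand = lig)
}

#' Default per-component standard deviations
#'
#' One set shared by all three species; kcal/mol except `sasa` (A^2).
#' @return Named list of sd vectors per species.
#' @export
default_energy_sds <- function() {
  s <- c(e_internal = 5, e_elec = 5, e_vdw = 3, g_polar = 4, sasa = 50)
  list(complex = s, apoprotein = s, free_ligand = s)
}

#' Expected binding energy and its SD implied by generator parameters
#'
#' @param means,sds Component means/SDs as produced by
#'   [energy_means_for_target()] / [default_energy_sds()].
#' @param cfg [mmpbsa_config()].
#' @return `expected_delta_g`: numeric mean; `implied_delta_g_sd`: numeric
#'   SD of the per-snapshot binding energy under independent normal
#'   components.
#' @export
expected_delta_g <- function(means, cfg = mmpbsa_config()) {
  g <- vapply(means, function(m)
    m[["e_internal"]] + m[["e_elec"]] + m[["e_vdw"]] + m[["g_polar"]] +
      cfg$gamma * m[["sasa"]] + cfg$b, numeric(1))
  unname(g["complex"] - g["apoprotein"] - g["free_ligand"])
}

#' @rdname expected_delta_g
#' @export
implied_delta_g_sd <- function(sds, cfg = mmpbsa_config()) {
  v <- vapply(sds, function(s)
    s[["e_internal"]]^2 + s[["e_elec"]]^2 + s[["e_vdw"]]^2 + s[["g_polar"]]^2 +
      (cfg$gamma * s[["sasa"]])^2, numeric(1))
  sqrt(sum(v))
}

#' Generate a per-snapshot energy table
#'
#' Independent normal draws per component, per species, per snapshot.
#'
#' @param n Number of snapshots.
#' @param means,sds Per-species component means and SDs (see
#'   [energy_means_for_target()], [default_energy_sds()]).
#' @param seed Integer seed; identical arguments give byte-identical tables.
#' @return Energy-table data.frame accepted by [delta_g_binding()].
#' @export
generate_energy_table <- function(n, means = energy_means_for_target(-243.42),
                                  sds = default_energy_sds(), seed = 1) {
  if (n < 1) stop("need n >= 1")
  comp <- c("e_internal", "e_elec", "e_vdw", "g_polar", "sasa")
  with_seed(seed, {
    rows <- lapply(SPECIES_LEVELS, function(sp) {
      draws <- vapply(comp, function(cc)
        stats::rnorm(n, means[[sp]][[cc]], sds[[sp]][[cc]]), numeric(n))
      draws <- matrix(draws, nrow = n,
                      dimnames = list(NULL, comp))
      data.frame(snapshot_id = seq_len(n), species = sp,
                 e_internal = draws[, "e_internal"], e_elec = draws[, "e_elec"],
                 e_vdw = draws[, "e_vdw"], g_polar = draws[, "g_polar"],
                 sasa = draws[, "sasa"], g_nonpolar = NA_real_)
    })
    do.call(rbind, rows)
  })
}
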