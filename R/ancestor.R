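# Parsimony ancestral reconstruction and mapping of substitutions onto
# branches, in particular the therian / marsupial / eutherian stem branches.

#' Fitch parsimony ancestral reconstruction
#'
#' Per alignment column, computes the minimum number of unordered state
#' changes on a rooted binary tree and reconstructs ancestral residues. The
#' per-site minimum is found by dynamic programming over the observed
#' residues (equal-cost Sankoff recursion, which for unit costs is exactly
#' Fitch parsimony). Two resolutions of equally parsimonious assignments are
#' kept: delayed transformation (DELTRAN, changes pushed toward the tips;
#' the default read of the reconstruction) and accelerated transformation
#' (ACCTRAN, changes pulled toward the root). The exact set of states each
#' node can take in *some* minimal labelling (its MPR set) is retained so
#' that ambiguous placements can be flagged.
#'
#' Columns containing a gap or X in any tree leaf are skipped (complete
#' deletion convention) and reported in `skipped_sites`.
#'
#' @param tree Rooted binary `phylo` tree whose tips are all present in
#'   `aln`.
#' @param aln An [aligned_set].
#' @return Object of class `fitch_recon`: list with `tree`, `sites` (original
#'   column indices reconstructed), `score` (per-site parsimony score),
#'   `deltran` / `acctran` (node x site character matrices of resolved
#'   states, nodes in ape numbering), `mpr` (per site, list of candidate
#'   state vectors per node), and `skipped_sites`.
#' @export
fitch_reconstruct <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "aligned_set"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing <- setdiff(tree$tip.label, rownames(aln$seqs))
  if (length(missing))
    stop("leaves missing from alignment: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # children per internal node, in a postorder edge ordering
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  post_nodes <- unique(po$edge[, 1])          # internal nodes, children-first
  pre_edges <- ape::reorder.phylo(tree, "cladewise")$edge
  parent_of <- integer(nnode)
  parent_of[pre_edges[, 2]] <- pre_edges[, 1]

  M <- aln$seqs[tree$tip.label, , drop = FALSE]
  use <- which(apply(M, 2, function(col) !any(col %in% MISSING_CHARS)))
  skipped <- setdiff(seq_len(ncol(M)), use)
  if (length(skipped))
    message(length(skipped), " gapped column(s) skipped in reconstruction")
  if (!length(use)) stop("no gap-free columns to reconstruct")

  score <- integer(0)
  deltran <- matrix(NA_character_, nnode, length(use))
  acctran <- matrix(NA_character_, nnode, length(use))
  forced <- matrix(FALSE, nnode, length(use))  # keyed by edge child node
  mpr <- vector("list", length(use))

  for (si in seq_along(use)) {
    col <- M[, use[si]]
    states <- sort(unique(col))
    k <- length(states)
    leaf_idx <- match(col, states)
    # cost[v, s]: minimal changes in subtree of v given node v has state s
    cost <- matrix(Inf, nnode, k)
    cost[cbind(seq_len(ntip), leaf_idx)] <- 0
    for (v in post_nodes) {
      acc <- numeric(k)
      for (ch in kids[[as.character(v)]]) {
        cc <- cost[ch, ]
        m0 <- min(cc)
        # min over child state: cc[s'] + (s' != s)
        acc <- acc + pmin(cc, m0 + 1)
      }
      cost[v, ] <- acc
    }
    sc <- min(cost[root, ])
    score[si] <- as.integer(sc)
    # up[v, s]: minimal changes outside subtree of v given v has state s
    up <- matrix(0, nnode, k)
    nochange <- numeric(nrow(pre_edges))
    # preorder over edges (cladewise is parents before children)
    for (e in seq_len(nrow(pre_edges))) {
      p <- pre_edges[e, 1]; v <- pre_edges[e, 2]
      sibs <- setdiff(kids[[as.character(p)]], v)
      base <- up[p, ]
      for (w in sibs) {
        cw <- cost[w, ]
        base <- base + pmin(cw, min(cw) + 1)
      }
      # best total score achievable when parent and child share a state,
      # i.e. with no change on this edge; > sc means a change is forced here
      nochange[e] <- min(base + cost[v, ])
      # up[v, s] = min over parent state sp of base[sp] + (sp != s)
      b0 <- min(base)
      up[v, ] <- pmin(base, b0 + 1)
    }
    total <- cost + up
    forced[pre_edges[, 2], si] <- nochange > sc
    mpr[[si]] <- lapply(seq_len(nnode), function(v)
      states[abs(total[v, ] - sc) < 1e-9])
    # top-down resolutions; root: smallest optimal state for both
    res_d <- integer(nnode)
    res_a <- integer(nnode)
    root_opts <- which(abs(cost[root, ] - sc) < 1e-9)
    res_d[root] <- res_a[root] <- root_opts[1]
    for (e in seq_len(nrow(pre_edges))) {
      p <- pre_edges[e, 1]; v <- pre_edges[e, 2]
      pick <- function(parent_state) {
        opts <- cost[v, ] + as.numeric(seq_len(k) != parent_state)
        cand <- which(abs(opts - min(opts)) < 1e-9)
        cand
      }
      cand_d <- pick(res_d[p])
      res_d[v] <- if (res_d[p] %in% cand_d) res_d[p] else cand_d[1]
      cand_a <- pick(res_a[p])
      non_parent <- setdiff(cand_a, res_a[p])
      res_a[v] <- if (length(non_parent)) non_parent[1] else cand_a[1]
    }
    deltran[, si] <- states[res_d]
    acctran[, si] <- states[res_a]
  }
  structure(list(tree = tree, sites = use, score = score,
                 deltran = deltran, acctran = acctran, forced = forced,
                 mpr = mpr, skipped_sites = skipped),
            class = "fitch_recon")
}

#' @export
print.fitch_recon <- function(x, ...) {
  cat(sprintf("fitch_recon: %d sites reconstructed (%d skipped), total parsimony score %d\n",
              length(x$sites), length(x$skipped_sites), sum(x$score)))
  invisible(x)
}

#' Map reconstructed substitutions onto branches
#'
#' One event per (branch, site) where the resolved (DELTRAN) parent and
#' child states differ. An event is flagged `ambiguous` when an alternative
#' equally parsimonious labelling can move it off that branch: the flag is
#' exact, computed by asking whether any minimal labelling assigns the
#' parent and child the same state (in which case no change is forced on the
#' branch). An event whose branch is certain but whose from/to residues vary
#' across minimal labellings is *not* flagged.
#'
#' @param recon A [fitch_reconstruct()] result.
#' @return data.frame with columns `site` (original alignment column,
#'   1-based), `from`, `to`, `parent`, `child` (ape node ids),
#'   `child_label` (leaf name or `""`), `ambiguous` (logical).
#' @export
map_substitutions <- function(recon) {
  stopifnot(inherits(recon, "fitch_recon"))
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  out <- list()
  for (si in seq_along(recon$sites)) {
    d <- recon$deltran[, si]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      if (d[p] != d[v]) {
        amb <- !recon$forced[v, si]
        out[[length(out) + 1]] <- data.frame(
          site = recon$sites[si], from = d[p], to = d[v],
          parent = p, child = v,
          child_label = if (v <= ntip) tree$tip.label[v] else "",
          ambiguous = amb)
      }
    }
  }
  if (!length(out))
    return(data.frame(site = integer(), from = character(),
                      to = character(), parent = integer(), child = integer(),
                      child_label = character(), ambiguous = logical()))
  do.call(rbind, out)
}

# Child node of the stem edge subtending all leaves of `leaves`; the leaf
# itself for a single-member clade.
stem_node <- function(tree, leaves, clade_name) {
  if (!all(leaves %in% tree$tip.label))
    stop("clade '", clade_name, "' has leaves missing from the tree: ",
         paste(setdiff(leaves, tree$tip.label), collapse = ", "))
  if (length(leaves) == 1) return(match(leaves, tree$tip.label))
  if (!ape::is.monophyletic(tree, leaves))
    stop("clade '", clade_name, "' is not monophyletic in the tree (leaves: ",
         paste(leaves, collapse = ", "), ")")
  ape::getMRCA(tree, leaves)
}

#' Classify substitutions onto stem branches
#'
#' Assigns each substitution event to the therian, marsupial or eutherian
#' stem branch (the edge subtending all therian SRY leaves, all marsupial
#' SRY leaves, or all eutherian SRY leaves respectively), or to
#' "terminal/other". Headline counts are of unambiguous events; ambiguous
#' events are tallied separately.
#'
#' @param events Event table from [map_substitutions()].
#' @param tree The rooted tree the events were mapped on (SOX outgroup
#'   rooting assumed).
#' @param clades Named clade vector (see [aligned_set()]); therian leaves are
#'   those labelled `eutheria` or `marsupialia`.
#' @return Object of class `stem_report`: list with `counts` (named integer
#'   vector: therian_stem, marsupial_stem, eutherian_stem, other),
#'   `ambiguous_counts` (same shape), and `events` (the input table with a
#'   `classification` column).
#' @export
classify_stem_substitutions <- function(events, tree, clades) {
  stopifnot(inherits(tree, "phylo"))
  euth <- intersect(names(clades)[clades == "eutheria"], tree$tip.label)
  mars <- intersect(names(clades)[clades == "marsupialia"], tree$tip.label)
  if (!length(euth)) stop("no eutherian leaves in tree")
  if (!length(mars)) stop("no marsupial leaves in tree")
  nodes <- c(therian_stem = stem_node(tree, c(euth, mars), "theria"),
             marsupial_stem = stem_node(tree, mars, "marsupialia"),
             eutherian_stem = stem_node(tree, euth, "eutheria"))
  cls <- rep("other", nrow(events))
  for (nm in names(nodes)) cls[events$child == nodes[[nm]]] <- nm
  events$classification <- cls
  lev <- c("therian_stem", "marsupial_stem", "eutherian_stem", "other")
  count_by <- function(sub) {
    v <- table(factor(sub$classification, levels = lev))
    stats::setNames(as.integer(v), lev)
  }
  structure(list(counts = count_by(events[!events$ambiguous, , drop = FALSE]),
                 ambiguous_counts = count_by(events[events$ambiguous, , drop = FALSE]),
                 stem_nodes = nodes,
                 events = events),
            class = "stem_report")
}

#' @export
print.stem_report <- function(x, ...) {
  cat("stem substitution report (unambiguous events):\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-16s %3d   (+%d ambiguous)\n", nm, x$counts[[nm]],
                x$ambiguous_counts[[nm]]))
  invisible(x)
}

#' Residue conserved within a clade at a site
#'
#' @param aln An [aligned_set].
#' @param clade Clade label with at least one member.
#' @param site 1-based column index.
#' @return The shared residue if all clade members agree at the site (gaps
#'   and X dropped with a warning), otherwise `NA`.
#' @export
conserved_within_clade <- function(aln, clade, site) {
  stopifnot(inherits(aln, "aligned_set"))
  members <- names(aln$clades)[aln$clades == clade]
  if (!length(members)) stop("no members in clade '", clade, "'")
  if (site < 1 || site > ncol(aln$seqs)) stop("site out of range")
  res <- aln$seqs[members, site]
  gap <- res %in% MISSING_CHARS
  if (any(gap)) {
    warning(sum(gap), " member(s) with gap/X at site ", site, " excluded")
    res <- res[!gap]
  }
  if (!length(res)) return(NA_character_)
  if (length(unique(res)) == 1) unique(res) else NA_character_
}
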