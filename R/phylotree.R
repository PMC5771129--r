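# Neighbor-joining, bootstrap support and rooting. Trees are ape "phylo"
# objects throughout; newick is the interchange format.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion is joined and branch lengths follow the standard formulas.
#' Two departures from a textbook transcription make the output well behaved
#' and deterministic:
#' * a negative branch length is clamped to zero and the deficit moved to its
#'   sibling branch, so the joined pair's mutual distance is preserved;
#' * when several pairs tie on Q (within 1e-12), the lexicographically
#'   smallest label pair is joined (internal nodes carry the smallest label
#'   of their members for this purpose).
#'
#' @param d Symmetric numeric matrix (or `dist`) with >= 3 labelled taxa.
#' @return Unrooted `phylo` tree (trifurcating basal node).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square matrix or dist")
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs >= 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(!is.finite(d)))
    stop("'d' must be symmetric and finite with zero diagonal")
  fmt <- function(x) sprintf("%.12g", x)
  # active node bookkeeping: newick fragment + smallest member label
  nwk <- labs
  key <- labs
  act <- seq_len(n)            # indices into d rows still active
  D <- d
  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(D[act, act])
    # Q matrix over active nodes
    best <- NULL
    best_q <- Inf
    for (ii in 1:(m - 1)) {
      for (jj in (ii + 1):m) {
        q <- (m - 2) * D[act[ii], act[jj]] - r[ii] - r[jj]
        pair_key <- sort(c(key[act[ii]], key[act[jj]]))
        if (q < best_q - 1e-12 ||
            (abs(q - best_q) <= 1e-12 && !is.null(best) &&
             lex_less(pair_key, best$key))) {
          best_q <- min(q, best_q)
          best <- list(ii = ii, jj = jj, key = pair_key)
        }
      }
    }
    i <- act[best$ii]; j <- act[best$jj]
    vi <- D[i, j] / 2 + (r[best$ii] - r[best$jj]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0; if (vi < 0) vi <- 0 }
    # distances from new node u to remaining nodes
    others <- setdiff(act, c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    u <- i  # reuse slot i for the merged node
    D[u, others] <- newd
    D[others, u] <- newd
    D[u, u] <- 0
    nwk[u] <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":", fmt(vj), ")")
    key[u] <- min(key[i], key[j])
    act <- c(others, u)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- paste0("(", nwk[a], ":", fmt(la), ",", nwk[b], ":", fmt(lb), ",",
                nwk[c3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

lex_less <- function(a, b) {
  if (a[1] != b[1]) return(a[1] < b[1])
  a[2] < b[2]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates every internal bipartition of the
#' point-estimate tree with the percentage of replicates containing it
#' (stored in `node.label`). Reproducible under a fixed seed.
#'
#' @param aln Gap-free [aligned_set].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param model Distance model passed to [aa_distance_matrix()].
#' @return The point-estimate NJ tree with percentage supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1,
                              model = c("p_distance", "poisson")) {
  stopifnot(inherits(aln, "aligned_set"))
  model <- match.arg(model)
  if (replicates < 1) stop("'replicates' must be >= 1")
  point <- neighbor_joining(aa_distance_matrix(aln, model))
  L <- ncol(aln$seqs)
  reps <- with_seed(seed, lapply(seq_len(replicates), function(k) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- aligned_set(aln$seqs[, cols, drop = FALSE], aln$clades)
    neighbor_joining(aa_distance_matrix(sub, model))
  }))
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  supp <- round(100 * counts / replicates)
  point$node.label <- ifelse(is.na(supp), "", as.character(supp))
  point
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge leading to the outgroup (a single leaf or a
#' set of leaves forming a clade) and resolves the basal node so the result
#' is binary. Re-rooting on the same outgroup is idempotent.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Leaf name(s) present in the tree.
#' @return Rooted binary `phylo` tree.
#' @export
root_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  t2 <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ape::root(t2, outgroup = outgroup, resolve.root = TRUE)
}

#' Read / write newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]; integer
#' internal-node labels are bootstrap percentages.
#'
#' @param path File path.
#' @return `read_newick`: a `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree `phylo` tree to write.
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
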