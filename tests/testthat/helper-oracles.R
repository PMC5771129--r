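# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# reference implementations from other packages.

# --- exhaustive parsimony oracle --------------------------------------------
# Minimum number of changes over ALL labelings of internal nodes, enumerating
# the observed states only (adding unobserved states never lowers the score).
oracle_parsimony_min <- function(tree, tip_states) {
  states <- sort(unique(tip_states))
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  lab <- character(ntip + tree$Nnode)
  lab[seq_len(ntip)] <- tip_states[tree$tip.label]
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab[internal] <- unlist(grid[g, ])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# --- Fisher exact oracle -----------------------------------------------------
# Full enumeration with log-factorial arithmetic, no dhyper.
oracle_fisher <- function(a, b, c, d) {
  lfact <- function(k) lgamma(k + 1)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lconst <- lfact(r1) + lfact(r2) + lfact(c1) + lfact(c2) - lfact(n)
  ptab <- function(x) {
    # table (x, r1-x, c1-x, r2-c1+x)
    exp(lconst - lfact(x) - lfact(r1 - x) - lfact(c1 - x) - lfact(r2 - c1 + x))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, ptab, numeric(1))
  pobs <- ptab(a)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# --- Nei-Gojobori oracle -----------------------------------------------------
# Independent re-derivation: translation through seqinr directly, potential
# sites and pathway averaging written with explicit loops.
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_syn_fraction <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon)
  syn <- 0
  for (i in 1:3) {
    for (n in nts) {
      if (n == substr(codon, i, i)) next
      mut <- codon
      substr(mut, i, i) <- n
      aam <- oracle_translate(mut)
      if (aam == aa0 && aam != "*") syn <- syn + 1
    }
  }
  syn / 3
}

oracle_pathways <- function(from, to) {
  # returns matrix with one row per pathway: syn steps, nonsyn steps, blocked
  diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(diffs)) return(matrix(c(0, 0, 0), 1))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (p in perm_list(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
    res
  }
  rows <- lapply(perm_list(diffs), function(ord) {
    cur <- from; s <- 0; ns <- 0; blocked <- 0
    for (i in ord) {
      nxt <- cur
      substr(nxt, i, i) <- substr(to, i, i)
      if (oracle_translate(nxt) == "*") blocked <- 1
      if (oracle_translate(nxt) == oracle_translate(cur)) s <- s + 1
      else ns <- ns + 1
      cur <- nxt
    }
    c(s, ns, blocked)
  })
  do.call(rbind, rows)
}

oracle_ng <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- (sum(sapply(ca, oracle_syn_fraction)) +
        sum(sapply(cb, oracle_syn_fraction))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    paths <- oracle_pathways(ca[i], cb[i])
    keep <- paths[, 3] == 0
    if (!any(keep)) keep <- rep(TRUE, nrow(paths))
    Sd <- Sd + mean(paths[keep, 1])
    Nd <- Nd + mean(paths[keep, 2])
  }
  jc <- function(p) if (p == 0) 0 else -3 / 4 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ds = jc(Sd / S), dn = jc(Nd / N))
}

# random coding sequence without stop codons
random_coding <- function(n_codons) {
  nts <- c("A", "C", "G", "T")
  repeat_codon <- function() {
    repeat {
      cd <- paste(sample(nts, 3, replace = TRUE), collapse = "")
      if (oracle_translate(cd) != "*") return(cd)
    }
  }
  paste(vapply(seq_len(n_codons), function(i) repeat_codon(), character(1)),
        collapse = "")
}

# mutate a coding sequence at k random positions, rejecting stop codons
mutate_coding <- function(seq, k) {
  nts <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  done <- 0
  while (done < k) {
    i <- sample.int(length(s), 1)
    alt <- sample(setdiff(nts, s[i]), 1)
    old <- s[i]
    s[i] <- alt
    cod_start <- 3 * ((i - 1) %/% 3) + 1
    if (oracle_translate(paste(s[cod_start:(cod_start + 2)], collapse = "")) == "*")
      s[i] <- old
    else done <- done + 1
  }
  paste(s, collapse = "")
}

# --- least-squares topology oracle (5 taxa) ---------------------------------
# OLS branch-length fit of a distance matrix on a fixed topology; residual
# sum of squares. Minimised over all 15 unrooted 5-taxon topologies.
oracle_ls_rss <- function(tree, d) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- utils::combn(n, 2)
  nodes_paths <- lapply(seq_len(ncol(pairs)), function(k)
    ape::nodepath(tree, pairs[1, k], pairs[2, k]))
  edge_id <- function(a, b) {
    hit <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
                 (tree$edge[, 1] == b & tree$edge[, 2] == a))
    hit
  }
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (k in seq_len(ncol(pairs))) {
    np <- nodes_paths[[k]]
    for (s in seq_len(length(np) - 1))
      X[k, edge_id(np[s], np[s + 1])] <- 1
  }
  y <- d[cbind(tips[pairs[1, ]], tips[pairs[2, ]])]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

oracle_best_topology_5 <- function(d) {
  tops <- phangorn::allTrees(5, tip.label = rownames(d))
  rss <- vapply(tops, oracle_ls_rss, numeric(1), d = d)
  tops[[which.min(rss)]]
}

# random additive distance matrix from a random tree
random_additive <- function(n, seed) {
  tr <- with_seed2(seed, {
    t0 <- ape::rtree(n, rooted = FALSE)
    t0$edge.length <- stats::runif(nrow(t0$edge), 0.1, 1.5)
    t0
  })
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# random tip-state vector and random rooted tree for parsimony checks
random_parsimony_case <- function(seed) {
  with_seed2(seed, {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)   # rooted
    k <- sample(2:4, 1)
    st <- sample(c("A", "K", "Q", "S", "V")[1:k], n, replace = TRUE)
    names(st) <- tr$tip.label
    list(tree = tr, states = st)
  })
}

# small helper: aligned_set from named character strings
aln_from_strings <- function(strs, clades = NULL) {
  m <- do.call(rbind, lapply(strs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(strs)
  aligned_set(m, clades)
}
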