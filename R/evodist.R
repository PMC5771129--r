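# Amino-acid distances and pairwise Nei-Gojobori dN/dS.

# 64-codon translation table (standard code), built once at load via seqinr.
codon_table <- local({
  nt <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(nt, nt, nt)[, 3:1], 1, paste0, collapse = "")
  aa <- vapply(codons, function(cd)
    seqinr::translate(unlist(strsplit(tolower(cd), ""))), character(1))
  stats::setNames(aa, codons)
})

STOP_CODONS <- names(codon_table)[codon_table == "*"]

#' Amino-acid distance matrix
#'
#' Pairwise distances on a gap-free amino-acid alignment, as used for
#' neighbor-joining. `p_distance` is the proportion of mismatching columns;
#' `poisson` is the Poisson-corrected distance `-ln(1 - p)`.
#'
#' @param aln A gap-free [aligned_set] (apply [complete_deletion()] first).
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sequence
#'   name.
#' @export
aa_distance_matrix <- function(aln, model = c("p_distance", "poisson")) {
  stopifnot(inherits(aln, "aligned_set"))
  model <- match.arg(model)
  if (any(aln$seqs %in% MISSING_CHARS))
    stop("alignment contains gaps or X; apply complete_deletion() first")
  n <- nrow(aln$seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(aln$seqs), rownames(aln$seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(aln$seqs[i, ] != aln$seqs[j, ])
      if (model == "poisson") {
        if (p >= 1) stop("Poisson correction undefined: p >= 1 for pair ",
                         rownames(aln$seqs)[i], "/", rownames(aln$seqs)[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# --- codon utilities ---------------------------------------------------------

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length ", n, " not divisible by 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Read codon (coding nucleotide) sequences from FASTA
#'
#' Sequences need not be equal length unless used as an alignment. A terminal
#' stop codon is trimmed silently (with a message); an internal stop is an
#' error.
#'
#' @param path FASTA file of nucleotide coding sequences.
#' @return Named character vector of uppercase nucleotide strings.
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- ape::read.FASTA(path, type = "DNA")
  seqs <- vapply(as.character(recs), function(s) toupper(paste(s, collapse = "")),
                 character(1))
  vapply(seqs, check_coding, character(1))
}

check_coding <- function(x) {
  cods <- split_codons(x)
  known <- cods %in% names(codon_table)
  aa <- rep(NA_character_, length(cods))
  aa[known] <- codon_table[cods[known]]
  if (length(cods) > 1 && any(aa[-length(aa)] == "*", na.rm = TRUE))
    stop("internal stop codon at codon ",
         which(aa[-length(aa)] == "*")[1])
  if (!is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
    message("terminal stop codon trimmed")
    x <- substr(x, 1, nchar(x) - 3)
  }
  x
}

# Fraction of the three possible changes at each codon position that are
# synonymous; changes creating a stop codon count as nonsynonymous.
codon_syn_sites <- function(codon) {
  nt <- c("T", "C", "A", "G")
  aa0 <- codon_table[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (codon_table[[mut]] == aa0 && codon_table[[mut]] != "*")
        s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal mutational pathways. Pathways passing through a stop codon are
# excluded; if every pathway is blocked, all are used.
codon_path_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) matrix(pos, 1) else
    matrix(unlist(lapply(combinat_perms(pos), identity)), ncol = nd, byrow = TRUE)
  score_path <- function(order) {
    cur <- ca
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (codon_table[[nxt]] == "*") blocked <- TRUE
      if (codon_table[[nxt]] == codon_table[[cur]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, blocked)
  }
  res <- t(apply(perms, 1, score_path))
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(syn = mean(res[ok, 1]), nonsyn = mean(res[ok, 2]))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' The unweighted-pathway Nei-Gojobori (1986) estimator with Jukes-Cantor
#' correction. Potential synonymous sites are counted per codon position as
#' the fraction of possible changes that are synonymous, averaged over the
#' two sequences; observed synonymous/nonsynonymous differences average over
#' all minimal mutational pathways between differing codons (stop-codon
#' intermediates excluded). `d = -(3/4) ln(1 - 4p/3)` is applied to both
#' proportions.
#'
#' @param codons_a,codons_b Nucleotide strings of equal length, divisible by
#'   3, without internal stop codons. Codon pairs where either codon contains
#'   a non-ACGT symbol (gap, N) are skipped.
#' @return A list of class `dnds` with elements `dn`, `ds`, `ratio`
#'   (`NA` with `ratio_defined = FALSE` when `ds = 0`), `n_sites`, `s_sites`,
#'   `nd`, `sd` (observed differences) and `n_codons` (codons compared).
#' @export
nei_gojobori <- function(codons_a, codons_b) {
  codons_a <- check_coding(codons_a)
  codons_b <- check_coding(codons_b)
  if (nchar(codons_a) != nchar(codons_b))
    stop("sequences differ in length (", nchar(codons_a), " vs ",
         nchar(codons_b), ")")
  ca <- split_codons(codons_a)
  cb <- split_codons(codons_b)
  ok <- ca %in% names(codon_table) & cb %in% names(codon_table)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) stop("no comparable codons")
  s_a <- sum(vapply(ca, codon_syn_sites, numeric(1)))
  s_b <- sum(vapply(cb, codon_syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) codon_path_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  jc <- function(p, what) {
    if (p == 0) return(0)
    if (4 * p / 3 >= 1)
      stop("saturation: Jukes-Cantor correction undefined for p", what,
           " = ", signif(p, 4))
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ds <- jc(if (S > 0) Sd / S else 0, "S")
  dn <- jc(if (N > 0) Nd / N else 0, "N")
  ratio_defined <- ds > 0
  structure(list(dn = dn, ds = ds,
                 ratio = if (ratio_defined) dn / ds else NA_real_,
                 ratio_defined = ratio_defined,
                 n_sites = N, s_sites = S, nd = Nd, sd = Sd,
                 n_codons = length(ca)),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("dN = %.4f (N sites %.2f), dS = %.4f (S sites %.2f), dN/dS = %s\n",
              x$dn, x$n_sites, x$ds, x$s_sites,
              if (x$ratio_defined) sprintf("%.4f", x$ratio) else "undefined (dS = 0)"))
  invisible(x)
}

#' Overall dN/dS over a codon alignment
#'
#' Aggregates pairwise Nei-Gojobori estimates over all unordered sequence
#' pairs as `mean(dN) / mean(dS)` (means across pairs), which is robust to
#' individual pairs with tiny dS. Pairs whose estimate is undefined
#' (saturation) are excluded and counted.
#'
#' @param codon_seqs Named character vector of >= 2 equal-length coding
#'   sequences.
#' @return List with `ratio`, `mean_dn`, `mean_ds`, `n_pairs_used`,
#'   `n_pairs_excluded` and the per-pair table `pairs` (data.frame).
#' @export
overall_dnds <- function(codon_seqs) {
  if (length(codon_seqs) < 2) stop("need >= 2 sequences")
  nm <- names(codon_seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(codon_seqs))
  idx <- utils::combn(seq_along(codon_seqs), 2)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- tryCatch(nei_gojobori(codon_seqs[[i]], codon_seqs[[j]]),
                  error = function(e) NULL)
    rows[[k]] <- if (is.null(r))
      data.frame(seq_a = nm[i], seq_b = nm[j], dn = NA_real_, ds = NA_real_,
                 ratio = NA_real_)
    else
      data.frame(seq_a = nm[i], seq_b = nm[j], dn = r$dn, ds = r$ds,
                 ratio = r$ratio)
  }
  tab <- do.call(rbind, rows)
  used <- !is.na(tab$dn) & !is.na(tab$ds)
  if (!any(used)) stop("all pairs undefined")
  mean_dn <- mean(tab$dn[used])
  mean_ds <- mean(tab$ds[used])
  list(ratio = if (mean_ds > 0) mean_dn / mean_ds else NA_real_,
       mean_dn = mean_dn, mean_ds = mean_ds,
       n_pairs_used = sum(used), n_pairs_excluded = sum(!used),
       pairs = tab)
}
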