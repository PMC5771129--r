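# Aligned amino-acid sets: the container every downstream stage consumes.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
MISSING_CHARS <- c("-", "X")
CLADE_LABELS <- c("eutheria", "marsupialia", "monotremata_outgroup",
                  "sox_outgroup", "other")

#' Construct an aligned amino-acid set
#'
#' An `aligned_set` couples an alignment (a character matrix of single-letter
#' amino-acid codes, one row per sequence) with a clade label per sequence.
#' Clade labels drive the similarity, conservation and stem-branch analyses;
#' sequences without a known clade get `"other"`.
#'
#' @param seqs Character matrix; rows are sequences (rownames are the unique
#'   sequence identifiers), columns are alignment positions. Allowed symbols:
#'   the 20 amino acids, `"-"` (gap) and `"X"` (unknown residue).
#' @param clades Named character vector mapping sequence name to one of
#'   `"eutheria"`, `"marsupialia"`, `"monotremata_outgroup"`,
#'   `"sox_outgroup"`, `"other"`. Missing names default to `"other"`.
#' @return An object of class `aligned_set` with elements `seqs` and `clades`.
#' @export
aligned_set <- function(seqs, clades = NULL) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("'seqs' must be a character matrix")
  if (is.null(rownames(seqs)))
    stop("'seqs' must have rownames (sequence identifiers)")
  if (anyDuplicated(rownames(seqs)))
    stop("duplicate sequence names: ",
         paste(unique(rownames(seqs)[duplicated(rownames(seqs))]), collapse = ", "))
  seqs[] <- toupper(seqs)
  bad <- setdiff(unique(as.vector(seqs)), c(AA_ALPHABET, MISSING_CHARS))
  if (length(bad))
    stop("invalid alignment symbols: ", paste(bad, collapse = " "))
  cl <- rep("other", nrow(seqs))
  names(cl) <- rownames(seqs)
  if (!is.null(clades)) {
    if (is.null(names(clades))) stop("'clades' must be a named vector")
    unknown <- setdiff(clades, CLADE_LABELS)
    if (length(unknown))
      stop("unknown clade labels: ", paste(unknown, collapse = ", "))
    hit <- intersect(names(clades), rownames(seqs))
    cl[hit] <- clades[hit]
  }
  structure(list(seqs = seqs, clades = cl), class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  tab <- table(x$clades)
  cat("clades:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.aligned_set <- function(x) dim(x$seqs)

#' Read an aligned amino-acid FASTA file
#'
#' All records must have equal length (it is an alignment, not a sequence
#' collection). Clade labels can be attached from a companion two-column
#' tab-separated file (`name<TAB>clade`).
#'
#' @param path FASTA file of aligned amino-acid sequences.
#' @param clades Either the path of a tab-separated clade map, or a named
#'   character vector, or `NULL`.
#' @return An [aligned_set].
#' @export
read_aligned_fasta <- function(path, clades = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- ape::read.FASTA(path, type = "AA")
  if (length(recs) == 0) stop("no sequences in ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1)
    stop("alignment-format error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (anyDuplicated(names(recs)))
    stop("duplicate sequence names in ", path)
  m <- toupper(as.character(as.matrix(recs)))
  if (is.character(clades) && length(clades) == 1 && is.null(names(clades)))
    clades <- read_clade_map(clades)
  aligned_set(m, clades)
}

#' Write an aligned set to FASTA
#'
#' @param aln An [aligned_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_set"))
  ape::write.FASTA(ape::as.AAbin(aln$seqs), path)
  invisible(path)
}

#' Read a clade map file
#'
#' Two tab-separated columns, no header: sequence name, clade label.
#'
#' @param path File path.
#' @return Named character vector (name -> clade).
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("name", "clade"))
  stats::setNames(tab$clade, tab$name)
}

#' Write a clade map file
#' @param clades Named character vector (name -> clade).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(clades, path) {
  utils::write.table(data.frame(name = names(clades), clade = unname(clades)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a domain window from an alignment
#'
#' Used to cut the HMG-domain block (around 78 columns for SRY/SOX) out of a
#' whole-protein alignment. Columns are 1-based and inclusive; positions in
#' the extracted block are then numbered from 1, which is the numbering used
#' for substitution notation such as "I55F".
#'
#' @param aln An [aligned_set].
#' @param window Integer vector `c(start, end)`, 1-based inclusive.
#' @return An [aligned_set] restricted to the window; clade labels preserved.
#' @export
extract_domain <- function(aln, window) {
  stopifnot(inherits(aln, "aligned_set"))
  window <- as.integer(window)
  if (length(window) != 2 || anyNA(window))
    stop("'window' must be c(start, end)")
  if (window[1] < 1 || window[2] > ncol(aln$seqs) || window[1] > window[2])
    stop(sprintf("window [%d, %d] out of bounds for %d-column alignment",
                 window[1], window[2], ncol(aln$seqs)))
  aligned_set(aln$seqs[, window[1]:window[2], drop = FALSE], aln$clades)
}

#' Percent similarity between (or within) clades
#'
#' Similarity is percent identity averaged over sequence pairs: for each pair
#' the score is 100 x (identical columns) / (columns where neither sequence
#' has a gap or X). Between two clades all cross pairs are used; within one
#' clade all unordered pairs (self-pairs excluded). Pairs with no mutually
#' ungapped column are dropped with a warning.
#'
#' @param aln An [aligned_set].
#' @param clade_a,clade_b Clade labels. Equal labels give within-clade
#'   similarity and require at least two members.
#' @return Mean percent identity (numeric scalar). Attribute `n_pairs` holds
#'   the number of pairs averaged.
#' @export
clade_similarity <- function(aln, clade_a, clade_b) {
  stopifnot(inherits(aln, "aligned_set"))
  a <- names(aln$clades)[aln$clades == clade_a]
  b <- names(aln$clades)[aln$clades == clade_b]
  if (length(a) == 0) stop("no members in clade '", clade_a, "'")
  if (length(b) == 0) stop("no members in clade '", clade_b, "'")
  if (identical(clade_a, clade_b)) {
    if (length(a) < 2) stop("within-clade similarity needs >= 2 members")
    pairs <- utils::combn(a, 2)
  } else {
    pairs <- rbind(rep(a, each = length(b)), rep(b, times = length(a)))
  }
  vals <- apply(pairs, 2, function(p) pair_identity(aln$seqs[p[1], ], aln$seqs[p[2], ]))
  drop <- is.na(vals)
  if (any(drop))
    warning(sum(drop), " pair(s) with no comparable columns excluded")
  if (all(drop)) stop("all pairs have zero comparable columns")
  structure(mean(vals[!drop]), n_pairs = sum(!drop))
}

pair_identity <- function(x, y) {
  ok <- !(x %in% MISSING_CHARS) & !(y %in% MISSING_CHARS)
  if (!any(ok)) return(NA_real_)
  100 * sum(x[ok] == y[ok]) / sum(ok)
}

#' Complete deletion of gapped columns
#'
#' Removes every column in which any sequence has a gap (`-`) or unknown
#' residue (`X`), the pre-processing used before distance and tree
#' computation. The retained column count is reported via [message()].
#'
#' @param aln An [aligned_set].
#' @return An [aligned_set] with only fully resolved columns. The original
#'   column indices of retained columns are kept in attribute `"columns"`.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  keep <- apply(aln$seqs, 2, function(col) !any(col %in% MISSING_CHARS))
  if (!any(keep))
    stop("complete deletion removed every column")
  out <- aligned_set(aln$seqs[, keep, drop = FALSE], aln$clades)
  attr(out, "columns") <- which(keep)
  message("complete deletion retained ", sum(keep), " of ", length(keep), " columns")
  out
}
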