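# MM/PB-SA binding free-energy bookkeeping over per-snapshot component
# energies. Molecular dynamics and Poisson-Boltzmann solving happen
# upstream; this module aggregates their per-snapshot output:
#
#   dG_binding = G(complex) - { G(apoprotein) + G(free ligand) }
#   G(molecule) = <E_MM> + <G_solv_polar> + <G_solv_nonpolar> - TS
#   <E_MM> = <E_internal> + <E_electrostatic> + <E_vdW>
#   G_solv_nonpolar = gamma * A + b
#
# The entropy term TS is disabled by default (not computed upstream either).

SPECIES_LEVELS <- c("complex", "apoprotein", "free_ligand")
ENERGY_COMPONENTS <- c("e_internal", "e_elec", "e_vdw", "g_polar")

#' MM/PB-SA configuration
#'
#' @param gamma Surface-tension coefficient, kcal/mol/A^2 (default 0.00542,
#'   the conventional MM/PB-SA value).
#' @param b Nonpolar-solvation offset, kcal/mol (default 0.92).
#' @param include_entropy Must be `FALSE` (the entropy term is not
#'   aggregated; enabling it would require per-snapshot TS input, which this
#'   module does not model).
#' @param window Snapshot window `c(start_ns, end_ns, stride_ps)`.
#' @return List of class `mmpbsa_config`.
#' @export
mmpbsa_config <- function(gamma = 0.00542, b = 0.92, include_entropy = FALSE,
                          window = c(20, 50, 300)) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (isTRUE(include_entropy))
    stop("entropy aggregation is not supported; include_entropy must be FALSE")
  structure(list(gamma = gamma, b = b, include_entropy = FALSE,
                 window = window),
            class = "mmpbsa_config")
}

#' Number of snapshots in a trajectory window
#'
#' Sampling at `start + stride, start + 2 stride, ..., end`:
#' `floor((end - start) * 1000 / stride)` snapshots. The production setting
#' of a 20-50 ns window at 300 ps stride gives 100.
#'
#' @param window `c(start_ns, end_ns, stride_ps)`.
#' @return Integer snapshot count.
#' @export
snapshot_count <- function(window = c(20, 50, 300)) {
  if (length(window) != 3) stop("'window' must be c(start_ns, end_ns, stride_ps)")
  start <- window[1]; end <- window[2]; stride <- window[3]
  if (end <= start || stride <= 0) stop("need end > start and stride > 0")
  as.integer(floor((end - start) * 1000 / stride))
}

#' Read a per-snapshot energy-component table
#'
#' Tab-separated with header columns `snapshot_id`, `species` (one of
#' `complex`, `apoprotein`, `free_ligand`), `e_internal`, `e_elec`, `e_vdw`,
#' `g_polar`, and exactly one of `sasa` (A^2) or `g_nonpolar` (kcal/mol) per
#' row; the other may be `NA` or absent.
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_energy_table(tab)
}

validate_energy_table <- function(tab) {
  need <- c("snapshot_id", "species", ENERGY_COMPONENTS)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("energy table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"sasa" %in% names(tab)) tab$sasa <- NA_real_
  if (!"g_nonpolar" %in% names(tab)) tab$g_nonpolar <- NA_real_
  bad <- setdiff(unique(tab$species), SPECIES_LEVELS)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  both_missing <- is.na(tab$sasa) & is.na(tab$g_nonpolar)
  if (any(both_missing))
    stop("rows lacking both sasa and g_nonpolar: ",
         paste(utils::head(which(both_missing), 5), collapse = ", "))
  tab
}

#' Free energy of one molecule for one snapshot
#'
#' `E_internal + E_electrostatic + E_vdW + G_polar + G_nonpolar`, with
#' `G_nonpolar = gamma * A + b` when a surface area is supplied instead of a
#' precomputed nonpolar term. No entropy term.
#'
#' @param snap One-row data.frame or list with the energy-table fields.
#' @param cfg An [mmpbsa_config()].
#' @return kcal/mol (numeric scalar).
#' @export
g_molecule <- function(snap, cfg = mmpbsa_config()) {
  nonpolar <- if (!is.null(snap$g_nonpolar) && !is.na(snap$g_nonpolar))
    snap$g_nonpolar
  else if (!is.null(snap$sasa) && !is.na(snap$sasa))
    cfg$gamma * snap$sasa + cfg$b
  else stop("snapshot needs sasa or g_nonpolar")
  snap$e_internal + snap$e_elec + snap$e_vdw + snap$g_polar + nonpolar
}

#' Binding free energy over a snapshot table
#'
#' Per snapshot, `dG = G(complex) - G(apoprotein) - G(free_ligand)`; the
#' result is the arithmetic mean, the sample standard deviation (n - 1
#' denominator), the snapshot count, and a per-component decomposition of
#' the mean. Under a single-trajectory protocol (parts extracted from the
#' complex trajectory) the internal-energy component cancels exactly.
#'
#' @param table Energy table (see [read_energy_table()]): every snapshot_id
#'   must appear once per species.
#' @param cfg An [mmpbsa_config()].
#' @return Object of class `binding_energy`: list with `mean`, `sd`, `n`,
#'   `per_snapshot` (numeric vector) and `components` (named mean
#'   decomposition, kcal/mol).
#' @export
delta_g_binding <- function(table, cfg = mmpbsa_config()) {
  tab <- validate_energy_table(table)
  ids <- sort(unique(tab$snapshot_id))
  for (sp in SPECIES_LEVELS) {
    have <- tab$snapshot_id[tab$species == sp]
    if (anyDuplicated(have))
      stop("duplicate ", sp, " rows for snapshot(s) ",
           paste(utils::head(unique(have[duplicated(have)]), 5), collapse = ", "))
    lack <- setdiff(ids, have)
    if (length(lack))
      stop("snapshot(s) missing species '", sp, "': ",
           paste(utils::head(lack, 5), collapse = ", "))
  }
  tab$g_np <- ifelse(!is.na(tab$g_nonpolar), tab$g_nonpolar,
                     cfg$gamma * tab$sasa + cfg$b)
  tab$g <- tab$e_internal + tab$e_elec + tab$e_vdw + tab$g_polar + tab$g_np
  by_sp <- function(col) {
    m <- matrix(NA_real_, length(ids), length(SPECIES_LEVELS),
                dimnames = list(as.character(ids), SPECIES_LEVELS))
    m[cbind(match(tab$snapshot_id, ids), match(tab$species, SPECIES_LEVELS))] <-
      tab[[col]]
    m
  }
  g <- by_sp("g")
  dg <- g[, "complex"] - g[, "apoprotein"] - g[, "free_ligand"]
  comp_cols <- c(ENERGY_COMPONENTS, "g_np")
  comps <- vapply(comp_cols, function(cc) {
    m <- by_sp(cc)
    mean(m[, "complex"] - m[, "apoprotein"] - m[, "free_ligand"])
  }, numeric(1))
  structure(list(mean = mean(dg),
                 sd = if (length(dg) > 1) stats::sd(dg) else 0,
                 n = length(dg),
                 per_snapshot = unname(dg),
                 components = comps),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("dG_binding = %.2f kcal/mol (sd %.2f, n = %d snapshots)\n",
              x$mean, x$sd, x$n))
  cat("component means:",
      paste(sprintf("%s=%.2f", names(x$components), x$components),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank protein/DNA variants by binding energy
#'
#' Orders variants by mean binding energy ascending: more negative means
#' higher predicted affinity. Pairwise mean differences with pooled-SD
#' z-scores are reported descriptively (snapshots along one MD trajectory
#' are autocorrelated, so these are not formal tests).
#'
#' @param results Named list of [delta_g_binding()] results.
#' @return List with `ranking` (data.frame: variant, mean, sd, n, rank) and
#'   `pairwise` (data.frame of mean differences and z-scores; empty for a
#'   single variant).
#' @export
compare_variants <- function(results) {
  if (!length(results)) stop("no results to compare")
  if (is.null(names(results))) stop("'results' must be a named list")
  rk <- data.frame(variant = names(results),
                   mean = vapply(results, `[[`, numeric(1), "mean"),
                   sd = vapply(results, `[[`, numeric(1), "sd"),
                   n = vapply(results, `[[`, numeric(1), "n"))
  rk <- rk[order(rk$mean, rk$variant), ]
  rk$rank <- seq_len(nrow(rk))
  rownames(rk) <- NULL
  pw <- list()
  if (nrow(rk) > 1) {
    cb <- utils::combn(nrow(rk), 2)
    for (k in seq_len(ncol(cb))) {
      i <- cb[1, k]; j <- cb[2, k]
      pooled <- sqrt(rk$sd[i]^2 / rk$n[i] + rk$sd[j]^2 / rk$n[j])
      pw[[k]] <- data.frame(variant_a = rk$variant[i], variant_b = rk$variant[j],
                            diff = rk$mean[i] - rk$mean[j],
                            z = if (pooled > 0) (rk$mean[i] - rk$mean[j]) / pooled
                                else NA_real_)
    }
  }
  list(ranking = rk,
       pairwise = if (length(pw)) do.call(rbind, pw)
                  else data.frame(variant_a = character(), variant_b = character(),
                                  diff = numeric(), z = numeric()))
}

#' Write an energy table to a tab-separated file
#' @param table Energy table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
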