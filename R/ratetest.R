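# Exact 2x2 tests and the stem-branch substitution-tempo comparison.

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact p by the conventional minimum-likelihood rule: with margins fixed,
#' the p-value is the sum of hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards against floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = lineages,
#'   columns = substituted vs unsubstituted sites, or any 2x2 design).
#' @return The two-tailed p-value (numeric scalar).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("'tab' must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margins; p = 1")
    return(1)
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Tempo input for one lineage
#'
#' @param count Substitutions observed on the lineage's stem branch.
#' @param sites Number of compared sites (e.g. HMG columns analysed).
#' @param duration Optional branch duration in million years.
#' @return List of class `tempo_input`.
#' @export
tempo_input <- function(count, sites, duration = NULL) {
  if (count < 0 || sites <= 0 || count > sites)
    stop("need 0 <= count <= sites, sites > 0")
  if (!is.null(duration) && duration <= 0) stop("duration must be > 0")
  structure(list(count = count, sites = sites, duration = duration),
            class = "tempo_input")
}

#' Substitution-tempo comparison between two lineages
#'
#' Compares substitution rates on two stem branches with Fisher's exact
#' test. In `per_site` mode each lineage contributes the row
#' `(count, sites - count)`. In `per_time` mode the opportunity is scaled by
#' branch duration: each row is `(count, round(sites x duration) - count)`,
#' i.e. site-million-year exposure.
#'
#' @param x,y [tempo_input()] objects.
#' @param mode `"per_site"` (default) or `"per_time"` (requires durations).
#' @return List with `p_value`, `rate_x`, `rate_y` (count/sites or
#'   count/(sites x MY)), `table` (the 2x2 used) and `mode`.
#' @export
tempo_test <- function(x, y, mode = c("per_site", "per_time")) {
  stopifnot(inherits(x, "tempo_input"), inherits(y, "tempo_input"))
  mode <- match.arg(mode)
  if (mode == "per_site") {
    tab <- rbind(c(x$count, x$sites - x$count),
                 c(y$count, y$sites - y$count))
    rx <- x$count / x$sites
    ry <- y$count / y$sites
  } else {
    if (is.null(x$duration) || is.null(y$duration))
      stop("per_time mode requires durations for both lineages")
    ex <- round(x$sites * x$duration)
    ey <- round(y$sites * y$duration)
    tab <- rbind(c(x$count, ex - x$count),
                 c(y$count, ey - y$count))
    rx <- x$count / (x$sites * x$duration)
    ry <- y$count / (y$sites * y$duration)
  }
  dimnames(tab) <- list(c("x", "y"), c("substituted", "unsubstituted"))
  list(p_value = fisher_exact(tab), rate_x = rx, rate_y = ry,
       table = tab, mode = mode)
}
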