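#' Spatial overlap statistics and permutation significance
#'
#' Quantifies the spatial congruence between a projected relative-risk
#' surface and observed incident reports: Schoener's D and Warren's I
#' (both comparing the surfaces as discrete probability distributions over
#' cells), Spearman rank correlation over occupied cells, and a permutation
#' null obtained by reshuffling the vessel surface across cells and
#' recomputing risk and statistic each time.
#'
#' @name overlap_stats
NULL

# surfaces or numeric vectors -> aligned probability vectors over shared cells
as_prob_pair <- function(P, Q) {
  pv <- if (inherits(P, "surface")) surface_values(P) else as.numeric(P)
  qv <- if (inherits(Q, "surface")) surface_values(Q) else as.numeric(Q)
  if (length(pv) != length(qv)) stop("surfaces must share a grid")
  ok <- is.finite(pv) & is.finite(qv)
  pv <- pv[ok]; qv <- qv[ok]
  if (any(pv < 0) || any(qv < 0)) stop("negative values are not distributions")
  if (sum(pv) <= 0 || sum(qv) <= 0) stop("all-zero surface")
  list(p = pv / sum(pv), q = qv / sum(qv))
}

#' Schoener's D overlap
#'
#' `D = 1 - 0.5 * sum |p_k - q_k|` after renormalizing both surfaces to sum
#' one; 0 = disjoint, 1 = identical.
#'
#' @param P,Q non-negative [surface()]s (or numeric vectors) on a common grid.
#' @return a number in \[0, 1\].
#' @export
schoeners_d <- function(P, Q) {
  d <- as_prob_pair(P, Q)
  1 - 0.5 * sum(abs(d$p - d$q))
}

#' Warren's I overlap (Hellinger-based)
#'
#' `I = 1 - 0.5 * sum (sqrt(p_k) - sqrt(q_k))^2`; 0 = disjoint, 1 = identical.
#'
#' @inheritParams schoeners_d
#' @return a number in \[0, 1\].
#' @export
warrens_i <- function(P, Q) {
  d <- as_prob_pair(P, Q)
  1 - 0.5 * sum((sqrt(d$p) - sqrt(d$q))^2)
}

#' Spearman correlation over occupied cells
#'
#' Rank correlation (average ranks for ties) between risk and incident counts
#' over the cells passing the filter — by default cells with at least one
#' incident, matching the restriction used for the Poisson regression.
#'
#' @param E a risk [surface()].
#' @param NI an incident-count [surface()] on the same grid.
#' @param cell_filter function of the incident counts returning a logical
#'   vector of cells to keep.
#' @return Spearman's rho.
#' @export
spearman_nonzero <- function(E, NI, cell_filter = function(ni) ni >= 1) {
  ev <- surface_values(E); nv <- surface_values(NI)
  keep <- cell_filter(nv) & is.finite(ev) & is.finite(nv)
  if (sum(keep) < 5) stop("need at least 5 cells after filtering")
  if (stats::sd(ev[keep]) == 0 || stats::sd(nv[keep]) == 0)
    stop("constant values after filtering: correlation undefined")
  stats::cor(ev[keep], nv[keep], method = "spearman")
}

#' Vessel-permutation significance test for an overlap statistic
#'
#' The observed statistic compares incidents with the risk surface built from
#' the actual vessel-hours layout. For each permutation the vessel values are
#' reshuffled across study cells (sampling without replacement), the risk
#' chain B -> E -> normalized E is recomputed, and the statistic re-evaluated;
#' the observed value is significant when it falls outside the middle 95% of
#' the permuted distribution (two-sided percentile rule).
#'
#' Overlap statistics (D, I) compare sum-normalized risk against the
#' incident-count surface normalized to sum one; `rho` is the Spearman
#' correlation over occupied cells.
#'
#' @param NI incident-count [surface()].
#' @param HSV habitat-suitability [surface()] aligned with `NI`.
#' @param V vessel-hours [surface()] aligned with `NI`.
#' @param statistic `"D"`, `"I"` or `"rho"`.
#' @param n number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return an object of class `overlap_result`: `statistic`, `observed`,
#'   `lower`, `upper` (2.5/97.5 permutation percentiles), `significant`,
#'   `unstable` (TRUE when the null distribution is degenerate or `n` is too
#'   small to place 2.5% tails), `n_permutations`, `seed`, `permuted`.
#' @export
permutation_test <- function(NI, HSV, V, statistic = c("D", "I", "rho"),
                             n = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(NI, "surface"), inherits(HSV, "surface"),
            inherits(V, "surface"))
  g <- V$grid
  vv <- surface_values(V)
  W <- normalize_occupancy(HSV)
  wv <- surface_values(W)
  niv <- surface_values(NI)
  stat_for <- function(vperm) {
    e <- wv * (vperm / sum(vperm))
    if (statistic == "rho") {
      keep <- niv >= 1
      if (sum(keep) < 5 || stats::sd(e[keep]) == 0 || stats::sd(niv[keep]) == 0)
        return(NA_real_)
      stats::cor(e[keep] / sum(e), niv[keep], method = "spearman")
    } else {
      en <- e / sum(e)
      nin <- niv / sum(niv)
      if (statistic == "D") 1 - 0.5 * sum(abs(en - nin))
      else 1 - 0.5 * sum((sqrt(en) - sqrt(nin))^2)
    }
  }
  observed <- stat_for(vv)
  degenerate <- stats::sd(vv) == 0
  set.seed(as.integer(seed))
  permuted <- vapply(seq_len(n), function(i) stat_for(sample(vv)), numeric(1))
  qs <- stats::quantile(permuted, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  unstable <- degenerate || n < 40 || qs[1] == qs[2] ||
    anyNA(c(observed, permuted))
  significant <- !unstable &&
    (observed < qs[1] || observed > qs[2])
  structure(list(statistic = statistic, observed = observed,
                 lower = qs[1], upper = qs[2],
                 significant = significant, unstable = unstable,
                 n_permutations = n, seed = seed, permuted = permuted),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s = %.4f, permutation 95%% interval [%.4f, %.4f] (%d perms)%s%s\n",
              x$statistic, x$observed, x$lower, x$upper, x$n_permutations,
              if (x$significant) " *significant*" else "",
              if (x$unstable) " [UNSTABLE]" else ""))
  invisible(x)
}

#' Overlap summary table for one species
#'
#' Schoener's D, Warren's I and the Spearman correlation between projected
#' risk and observed incidents, each with its vessel-permutation significance
#' flag.
#'
#' @inheritParams permutation_test
#' @return data.frame with one row per statistic: value, lower, upper,
#'   significant.
#' @export
overlap_table <- function(NI, HSV, V, n = 1000, seed = 1) {
  rows <- lapply(c("D", "I", "rho"), function(s) {
    r <- permutation_test(NI, HSV, V, statistic = s, n = n, seed = seed)
    data.frame(statistic = s, value = r$observed, lower = r$lower,
               upper = r$upper, significant = r$significant)
  })
  do.call(rbind, rows)
}
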