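## Randomization-based significance procedures with a uniform p-value
## convention: one-tailed exceedance with the add-one correction
## p = (count + 1)/(N + 1), plus the raw-fraction bound string ("P < 1/N")
## reported alongside when no null draw reaches the observed statistic.

perm_result <- function(observed, null_values, exceed, n, seed,
                        alternative) {
  count <- sum(exceed)
  p <- (count + 1) / (n + 1)
  structure(list(observed = observed, n = n, exceedance_count = count,
                 p_value = p,
                 p_bound = if (count == 0L) sprintf("P < %g", 1 / n) else NA_character_,
                 alternative = alternative, seed = seed,
                 null_values = null_values),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed = %.6g, N = %d, exceedances = %d\n",
              x$observed, x$n, x$exceedance_count))
  cat(sprintf("  one-tailed (%s) p = %.6g%s  [seed %d]\n", x$alternative,
              x$p_value,
              if (!is.na(x$p_bound)) paste0(" (", x$p_bound, ")") else "",
              x$seed))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the standard convention).
#'
#' @param xs,ys equal-length numeric vectors, length >= 3.
#' @return rho in [-1, 1]; NA with a warning when either vector is constant.
#' @export
spearman_rho <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warning("spearman_rho undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(xs, ys, method = "spearman")
}

#' Permutation test of the similarity-cost rank correlation
#'
#' Null distribution: Spearman's rho after randomly permuting the costs
#' against the S values. One-tailed; by default (`alternative = "auto"`) the
#' tail follows the sign of the observed rho, matching the usual reporting
#' of a strong negative similarity-cost association. A fixed tail ("less" or
#' "greater") makes the test calibrated (uniform p under the null), which
#' the sign-adaptive default deliberately is not.
#'
#' @param S_values,costs paired vectors (feasible records).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param alternative "auto", "less" or "greater".
#' @return a `permutation_result`.
#' @export
perm_test_spearman <- function(S_values, costs, n_perm = 1e4, seed = 1,
                               alternative = c("auto", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  obs <- spearman_rho(S_values, costs)
  if (!is.finite(obs)) stop("observed Spearman rho undefined")
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stats::cor(S_values, sample(costs), method = "spearman"), 0)
  if (alternative == "auto") alternative <- if (obs < 0) "less" else "greater"
  if (alternative == "less")
    perm_result(obs, null, null <= obs, n_perm, seed, "rho <= observed")
  else perm_result(obs, null, null >= obs, n_perm, seed, "rho >= observed")
}

#' Resampling test of phosphoprotein enrichment
#'
#' Null distribution: the phosphoprotein fraction of random subsets of all
#' detected proteins, size-matched to the oscillating subset. One-tailed
#' for enrichment (null fraction >= observed fraction).
#'
#' @param records a `proteome_records` data frame (all detected proteins).
#' @param subset logical index marking the oscillating proteins.
#' @param n_iter resampling iterations (>= 100).
#' @param seed RNG seed.
#' @return a `permutation_result`.
#' @export
resample_test_enrichment <- function(records, subset, n_iter = 1e4, seed = 1) {
  stopifnot(n_iter >= 100)
  m <- sum(subset)
  if (m == 0L) stop("empty oscillating subset")
  obs <- phospho_fraction(records, subset)
  set.seed(seed)
  lab <- records$phospho
  null <- vapply(seq_len(n_iter), function(i) mean(sample(lab, m)), 0)
  perm_result(obs, null, null >= obs, n_iter, seed, "null fraction >= observed")
}

#' Permutation test of the cg-phosphofraction association
#'
#' Permutes the cg values across the oscillating proteins regardless of
#' phospho label, recomputes the per-bin phosphoprotein proportions, and
#' counts the event that every adjacent-bin fold change of the permuted
#' proportions is at least the observed fold change (cg bins in ascending
#' order). A small p marks an observed rise steeper than the permuted ones.
#'
#' @param records a `proteome_records` data frame with finite `cg` for the
#'   tested proteins.
#' @param bin_edges strictly increasing cg bin edges (>= 2 non-empty bins).
#' @param n_iter permutation iterations (>= 100).
#' @param seed RNG seed.
#' @return a `permutation_result` (observed = smallest adjacent fold change).
#' @export
perm_test_cg_monotonic <- function(records, bin_edges, n_iter = 1e4, seed = 1) {
  stopifnot(n_iter >= 100)
  d <- records[is.finite(records$cg), , drop = FALSE]
  obs_bins <- bin_by_cg(d, bin_edges)$bins
  ok <- is.finite(obs_bins$fraction)
  if (sum(ok) < 2L) stop("need at least 2 non-empty cg bins")
  fold <- function(fr) {
    fr <- fr[is.finite(fr)]
    fr[-1L] / pmax(fr[-length(fr)], .Machine$double.eps)
  }
  obs_fc <- fold(obs_bins$fraction)
  set.seed(seed)
  dominates <- vapply(seq_len(n_iter), function(i) {
    dp <- d
    dp$cg <- sample(d$cg)
    pb <- suppressWarnings(bin_by_cg(dp, bin_edges)$bins)
    pf <- fold(pb$fraction)
    length(pf) == length(obs_fc) && all(pf >= obs_fc)
  }, TRUE)
  perm_result(min(obs_fc), as.numeric(dominates), dominates, n_iter, seed,
              "permuted fold changes all >= observed")
}

#' Empirical test of cost proximity to the scan minimum
#'
#' Among feasible scan records, the p-value is the (add-one adjusted)
#' fraction of records whose cost lies closer to the reference minimum cost
#' than the focal record's cost does. Small p: the focal record (typically
#' the largest-S set) is nearly cost-minimal.
#'
#' @param records a `scan_records` data frame (feasible rows are used).
#' @param focal_index row index of the focal record in `records`.
#' @param reference_min_cost the reference minimum cost (defaults to the
#'   minimum feasible cost in the scan).
#' @return a `permutation_result` (seed field 0: no randomness involved).
#' @export
test_cost_proximity <- function(records, focal_index,
                                reference_min_cost = NULL) {
  ok <- records$feasible & is.finite(records$cost)
  d <- records[ok, , drop = FALSE]
  if (nrow(d) < 100L)
    warning("fewer than 100 feasible records: low p-value resolution")
  focal_cost <- records$cost[focal_index]
  if (!is.finite(focal_cost)) stop("focal record is not feasible")
  if (is.null(reference_min_cost)) reference_min_cost <- min(d$cost)
  dist <- abs(d$cost - reference_min_cost)
  focal_dist <- abs(focal_cost - reference_min_cost)
  closer <- dist < focal_dist
  perm_result(focal_cost, d$cost, closer, nrow(d), 0L,
              "cost closer to the minimum than the focal cost")
}
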