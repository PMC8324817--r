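## Proteome-level cost analysis: eligibility filtering of abundance series,
## per-protein constant-rate cost bounds cg, the aggregate cost fraction
## Fcost, phosphoprotein fractions across cg bins, and abundance-controlled
## subsetting under a truncated power law.

#' Eligibility of an abundance time series for spline-based cg
#'
#' A series qualifies when it has at least seven data points across the
#' replicates and more than two of its consecutive (time-ordered, unique)
#' points are separated by less than 6 hours.
#'
#' @param series an [empirical_series()] (or NULL).
#' @param min_points minimum total point count.
#' @param max_gap_h the gap threshold in hours.
#' @param min_close_pairs consecutive pairs closer than `max_gap_h` must
#'   exceed this count.
#' @return logical.
#' @export
series_eligible <- function(series, min_points = 7L, max_gap_h = 6,
                            min_close_pairs = 2L) {
  if (is.null(series)) return(FALSE)
  if (nrow(series) < min_points) return(FALSE)
  ut <- sort(unique(series$time_h))
  if (length(ut) < 2L) return(FALSE)
  sum(diff(ut) < max_gap_h) > min_close_pairs
}

#' Constant-rate cost bound cg of one protein
#'
#' Splines the relative abundance series (cubic, interpolating by default),
#' takes the maximum logarithmic decline rate max(-x'/x), and multiplies by
#' the protein's typical absolute abundance.
#'
#' @param series an eligible [empirical_series()] of relative abundances.
#' @param chi typical absolute abundance (copies/cell), > 0.
#' @param smoothing spline residual bound (see [fit_profile_spline()]).
#' @param period period in hours.
#' @return cg in copies/cell/h, or NA when the series is ineligible.
#' @export
protein_cg <- function(series, chi, smoothing = 0, period = 24) {
  stopifnot(chi > 0)
  if (!series_eligible(series)) return(NA_real_)
  prof <- fit_profile_spline(series, smoothing = smoothing, period = period)
  min_constant_rate(prof) * chi
}

#' Compute cg for every eligible oscillating protein in a table
#'
#' @param records a `proteome_records` data frame (see
#'   [make_synthetic_proteome()] or [read_proteome_tsv()]).
#' @param smoothing spline residual bound.
#' @return the records with a `cg` column (NA for non-oscillating or
#'   ineligible proteins).
#' @export
proteome_cg <- function(records, smoothing = 0) {
  series <- attr(records, "series")
  records$cg <- vapply(seq_len(nrow(records)), function(i) {
    if (!records$oscillating[i]) return(NA_real_)
    protein_cg(series[[i]], records$abundance[i], smoothing = smoothing)
  }, 0)
  records
}

#' Aggregate cost fraction of oscillating proteins
#'
#' With constant degradation rates, the fraction of total proteome synthesis
#' attributable to oscillating proteins is bounded below by
#' Fcost = sum_C cg / (sum_C cg + r_i sum_{A-C} chi), where C are the
#' oscillating proteins (with cg) and A all detected proteins. The
#' oscillating-abundance fraction sum_C chi / sum_A chi is reported
#' alongside.
#'
#' @param records a `proteome_records` data frame with a `cg` column, or NULL
#'   to use pre-computed aggregates directly.
#' @param ri constant degradation rate of non-oscillating proteins (1/h).
#' @param sum_cg,sum_chi_osc,sum_chi_all optional pre-computed aggregates
#'   (copies/cell/h and copies/cell) overriding `records`.
#' @param sum_deg_rest optional pre-computed degradation flux of the
#'   non-oscillating proteins (copies/cell/h); defaults to
#'   `ri * (sum_chi_all - sum_chi_osc)`. Useful when the aggregate comes from
#'   a different measurement than the abundance sums.
#' @return list with `abundance_fraction` and `Fcost`.
#' @export
fcost_aggregate <- function(records = NULL, ri = 0.01,
                            sum_cg = NULL, sum_chi_osc = NULL,
                            sum_chi_all = NULL, sum_deg_rest = NULL) {
  if (is.null(sum_cg)) {
    stopifnot(!is.null(records), "cg" %in% names(records))
    osc <- records$oscillating & is.finite(records$cg)
    sum_cg <- sum(records$cg[osc])
    sum_chi_osc <- sum(records$abundance[records$oscillating])
    sum_chi_all <- sum(records$abundance)
  }
  stopifnot(sum_chi_all > 0)
  rest <- sum_deg_rest %||% (ri * (sum_chi_all - sum_chi_osc))
  den <- sum_cg + rest
  if (den <= 0) stop("empty denominator in Fcost")
  list(abundance_fraction = sum_chi_osc / sum_chi_all,
       Fcost = sum_cg / den)
}

#' Fraction of phosphoproteins in a subset
#'
#' @param records a `proteome_records` data frame.
#' @param subset logical index into `records` (default all rows).
#' @return fraction in [0, 1].
#' @export
phospho_fraction <- function(records, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(records))
  d <- records[subset, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty subset")
  mean(d$phospho)
}

#' Phosphoprotein fractions across cg bins
#'
#' Assigns every protein with a finite cg to a half-open bin [e_i, e_{i+1})
#' and reports the per-bin phosphoprotein fraction plus a least-squares
#' trend of fraction against bin index (a visual-guide regression; empty
#' bins are excluded with a warning).
#'
#' @param records a `proteome_records` data frame with `cg`.
#' @param edges strictly increasing bin edges (length >= 2).
#' @return list with `bins` (data frame: bin, lo, hi, n, fraction), `slope`,
#'   `r_squared`.
#' @export
bin_by_cg <- function(records, edges) {
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  d <- records[is.finite(records$cg), , drop = FALSE]
  idx <- findInterval(d$cg, edges, rightmost.closed = FALSE)
  inb <- idx >= 1L & idx <= length(edges) - 1L
  d <- d[inb, , drop = FALSE]; idx <- idx[inb]
  nb <- length(edges) - 1L
  frac <- rep(NA_real_, nb); cnt <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- idx == b
    cnt[b] <- sum(sel)
    if (cnt[b] > 0L) frac[b] <- mean(d$phospho[sel])
  }
  if (any(cnt == 0L)) warning("empty cg bin(s) excluded from the trend")
  bins <- data.frame(bin = seq_len(nb), lo = edges[-length(edges)],
                     hi = edges[-1L], n = cnt, fraction = frac)
  ok <- is.finite(frac)
  slope <- r2 <- NA_real_
  if (sum(ok) >= 2L) {
    fit <- stats::lm(frac[ok] ~ bins$bin[ok])
    slope <- unname(stats::coef(fit)[2L])
    r2 <- summary(fit)$r.squared
  }
  list(bins = bins, slope = slope, r_squared = r2)
}

#' Abundance-controlled subset of a proteome table
#'
#' Inclusive filter chi_min <= chi <= chi_max; within a range where both
#' phospho- and non-phospho-proteins follow the same power law the two
#' groups have no systematic abundance bias, so cg comparisons inside the
#' window are abundance-controlled. The defaults are the mouse-liver control
#' window (3.0e4 to 5.4e5 copies/cell).
#'
#' @param records a `proteome_records` data frame.
#' @param chi_min,chi_max abundance bounds (copies/cell).
#' @export
abundance_controlled_subset <- function(records, chi_min = 3.0e4,
                                        chi_max = 5.4e5) {
  stopifnot(chi_min < chi_max)
  keep <- records$abundance >= chi_min & records$abundance <= chi_max
  if (!any(keep)) warning("abundance-controlled subset is empty")
  out <- records[keep, , drop = FALSE]
  sr <- attr(records, "series")
  if (!is.null(sr)) attr(out, "series") <- sr[keep]
  class(out) <- class(records)
  out
}

#' Maximum-likelihood exponent of a truncated power law
#'
#' Fits P(chi) ~ chi^-gamma on [chi_min, chi_max] by maximizing the
#' truncated-Pareto likelihood over gamma (profile likelihood on a bounded
#' interval; the gamma = 1 logarithmic case is handled continuously).
#'
#' @param abundances positive values; only those inside the bounds are used.
#' @param chi_min,chi_max truncation bounds.
#' @param min_n minimum usable sample size.
#' @param interval search interval for gamma.
#' @return gamma estimate.
#' @export
powerlaw_exponent <- function(abundances, chi_min, chi_max, min_n = 50L,
                              interval = c(0.05, 5)) {
  x <- abundances[abundances >= chi_min & abundances <= chi_max]
  if (length(x) < min_n)
    stop("need at least ", min_n, " values inside the truncation bounds")
  slx <- sum(log(x)); n <- length(x)
  lognorm <- function(g) {
    if (abs(g - 1) < 1e-9) log(log(chi_max / chi_min))
    else {
      e <- 1 - g
      # log of (chi_max^e - chi_min^e)/e, computed stably
      m <- max(e * log(chi_max), e * log(chi_min))
      m + log(abs(exp(e * log(chi_max) - m) - exp(e * log(chi_min) - m))) -
        log(abs(e))
    }
  }
  nll <- function(g) g * slx + n * lognorm(g)
  stats::optimize(nll, interval = interval)$minimum
}

#' Read a proteome table from TSV
#'
#' Columns: `id`, `abundance` (copies/cell), `oscillating` (0/1 or
#' TRUE/FALSE), `phospho` (idem), then optional wide time columns named
#' `t<hours>_rep<k>` carrying relative abundance time series.
#'
#' @param path file path.
#' @return a `proteome_records` data frame with per-protein series (when time
#'   columns are present) in attribute `series`.
#' @export
read_proteome_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  need <- c("id", "abundance", "oscillating", "phospho")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  tc <- grep("^t[0-9.]+_rep[0-9]+$", names(d), value = TRUE)
  rec <- data.frame(id = d$id, abundance = d$abundance,
                    oscillating = as.logical(d$oscillating),
                    phospho = as.logical(d$phospho))
  series <- vector("list", nrow(d))
  if (length(tc)) {
    tm <- as.numeric(sub("^t([0-9.]+)_rep.*$", "\\1", tc))
    rp <- as.integer(sub("^t[0-9.]+_rep([0-9]+)$", "\\1", tc))
    for (i in seq_len(nrow(d))) {
      v <- as.numeric(d[i, tc])
      ok <- is.finite(v)
      if (sum(ok) >= 2L)
        series[[i]] <- empirical_series(tm[ok], v[ok], rp[ok],
                                        kind = "abundance")
    }
  }
  class(rec) <- c("proteome_records", "data.frame")
  attr(rec, "series") <- series
  rec
}

#' Write a proteome table to TSV
#'
#' @param records a `proteome_records` data frame.
#' @param path file path.
#' @export
write_proteome_tsv <- function(records, path) {
  series <- attr(records, "series")
  base <- as.data.frame(records)[c("id", "abundance", "oscillating", "phospho")]
  wide <- NULL
  if (!is.null(series) && any(!vapply(series, is.null, TRUE))) {
    first <- series[[which(!vapply(series, is.null, TRUE))[1L]]]
    key <- paste0("t", first$time_h, "_rep", first$replicate)
    wide <- matrix(NA_real_, nrow(base), length(key),
                   dimnames = list(NULL, key))
    for (i in seq_len(nrow(base))) {
      s <- series[[i]]
      if (is.null(s)) next
      kk <- paste0("t", s$time_h, "_rep", s$replicate)
      wide[i, match(kk, key)] <- s$value
    }
  }
  out <- if (is.null(wide)) base else cbind(base, as.data.frame(wide))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
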