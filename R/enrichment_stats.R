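#' @title Breakpoint enrichment and permutation statistics
#' @description Length-normalized breakpoint enrichment (expected
#'   counts under a length-proportional null, chi-square goodness of
#'   fit, per-kb densities) and the length-weighted permutation test of
#'   breakpoint/feature co-localization (`T = sum(F_i * B_i)` against a
#'   multinomial length-proportional null).
#' @name enrichment_stats
NULL

#' Expected breakpoint counts under the length-proportional null
#'
#' `E_i = N * L_i / sum(L)`: under the null hypothesis that breakpoints
#' fall at random with probability proportional to region length.
#'
#' @param lengths positive region lengths (bp).
#' @param n total number of observed breakpoints `N`.
#' @return numeric vector summing to `n`.
#' @export
expected_counts <- function(lengths, n) {
  if (!length(lengths)) stop("empty length vector")
  if (any(lengths < 1)) stop("all lengths must be >= 1")
  if (n < 0) stop("n must be >= 0")
  n * lengths / sum(lengths)
}

#' Chi-square goodness-of-fit test
#'
#' `X^2 = sum((O_i - E_i)^2 / E_i)` with `df = k - 1`, upper-tail p from
#' the chi-square distribution. Observed and expected totals must agree
#' (a mismatch means a misconstructed null).
#'
#' @param observed integer counts per category.
#' @param expected positive expected counts, same length.
#' @return `ChiSquareResult` list: `observed`, `expected`, `statistic`,
#'   `df`, `p_value`.
#' @export
chisq_gof <- function(observed, expected) {
  k <- length(observed)
  if (k < 2 || length(expected) != k)
    stop("observed and expected must have the same length >= 2")
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (abs(sum(observed) - sum(expected)) >
      1e-6 * max(1, sum(observed)))
    stop("sum(observed) != sum(expected): misconstructed null")
  stat <- sum((observed - expected)^2 / expected)
  structure(list(observed = observed, expected = expected,
                 statistic = stat, df = k - 1L,
                 p_value = pchisq(stat, df = k - 1, lower.tail = FALSE)),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("chi-square GoF: X2(%d, N = %g) = %.2f, p = %.3g\n",
              x$df, sum(x$observed), x$statistic, x$p_value))
  invisible(x)
}

#' Breakpoints per kilobase
#' @param b breakpoint counts per region.
#' @param lengths region lengths (bp, >= 1).
#' @return `d_i = 1000 * B_i / L_i`.
#' @export
breakpoint_density <- function(b, lengths) {
  if (any(lengths < 1)) stop("all lengths must be >= 1")
  1000 * b / lengths
}

#' Region feature table for the permutation framework
#'
#' One row per analysis region carrying its length `L_i`, observed
#' breakpoint count `B_i`, and feature value `F_i` (e.g. per-region
#' max |dDeltaG| in kcal/mol, or a motif density per kb).
#'
#' @param region region names.
#' @param length region lengths in bp (>= 1).
#' @param breakpoints observed breakpoint counts (non-negative integers).
#' @param feature feature values, fully populated.
#' @return `RegionFeatureTable` data.frame.
#' @export
region_feature_table <- function(region, length, breakpoints, feature) {
  stopifnot(length(region) == length(length),
            length(region) == length(breakpoints),
            length(region) == length(feature))
  if (any(length < 1)) stop("all lengths must be >= 1")
  if (any(breakpoints < 0) || any(breakpoints != round(breakpoints)))
    stop("breakpoint counts must be non-negative integers")
  if (anyNA(feature)) stop("feature column must be fully populated")
  out <- data.frame(region = normalize_region_name(region),
                    length = as.numeric(length),
                    breakpoints = as.integer(breakpoints),
                    feature = as.numeric(feature),
                    stringsAsFactors = FALSE)
  class(out) <- c("RegionFeatureTable", "data.frame")
  out
}

#' Breakpoint-weighted feature sum `T = sum(F_i * B_i)`
#' @param table a [region_feature_table()].
#' @return the observed statistic `T_obs`.
#' @export
weighted_statistic <- function(table) {
  sum(table$feature * table$breakpoints)
}

#' Length-weighted permutation test of breakpoint/feature association
#'
#' Tests whether breakpoints preferentially fall in regions with high
#' feature values. Each permutation redistributes the `N = sum(B_i)`
#' breakpoints independently over the regions with probability
#' proportional to region length (a multinomial draw, per the stated
#' null), recomputes `T_perm = sum(F_i * B*_i)`, and the one-sided
#' p-value is `#(T_perm >= T_obs) / n_perm`. Ties count toward the
#' numerator; the optional `(r + 1)/(n + 1)` correction is off by
#' default to follow the printed estimator exactly.
#'
#' @param table a [region_feature_table()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the draw order is fixed, so results are
#'   reproducible bit-for-bit per seed. The caller's RNG state is
#'   restored afterwards.
#' @param plus_one use the add-one p-value estimator `(r + 1)/(n + 1)`.
#' @return `PermutationResult` list: `t_obs`, `n_perm`, `seed`,
#'   `null_sample`, `p_value`.
#' @export
permutation_test <- function(table, n_perm = 10000, seed = NULL,
                             plus_one = FALSE) {
  stopifnot(n_perm >= 1)
  N <- sum(table$breakpoints)
  if (N <= 0) stop("the table carries no breakpoints (sum B_i = 0)")
  if (nrow(table) < 2) {
    warning("degenerate table with a single region; p = 1")
    return(structure(list(t_obs = weighted_statistic(table),
                          n_perm = as.integer(n_perm), seed = seed,
                          null_sample = rep(weighted_statistic(table), n_perm),
                          p_value = 1), class = "PermutationResult"))
  }
  t_obs <- weighted_statistic(table)
  p_len <- table$length / sum(table$length)
  null_sample <- with_seed(seed, {
    counts <- rmultinom(n_perm, size = N, prob = p_len)
    as.vector(crossprod(counts, table$feature))
  })
  r <- sum(null_sample >= t_obs)
  p <- if (plus_one) (r + 1) / (n_perm + 1) else r / n_perm
  structure(list(t_obs = t_obs, n_perm = as.integer(n_perm),
                 seed = seed, null_sample = null_sample, p_value = p),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "permutation test: T_obs = %.4g, n_perm = %d, one-sided p = %.4f\n",
    x$t_obs, x$n_perm, x$p_value))
  invisible(x)
}

#' Read / write a region feature table (Table-4-style TSV)
#'
#' The TSV mirrors the per-region feature summary: columns `region`,
#' `length`, `breakpoints`, then one column per feature. `feature`
#' selects which feature column becomes `F_i`.
#'
#' @param path TSV path.
#' @param feature name of the feature column to use.
#' @param regions optional subset (and order) of region names; defaults
#'   to all rows in file order.
#' @return a [region_feature_table()].
#' @export
load_feature_table <- function(path, feature, regions = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  tb$region <- normalize_region_name(tb$region)
  need <- c("region", "length", "breakpoints", feature)
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.null(regions)) {
    regions <- normalize_region_name(regions)
    miss <- setdiff(regions, tb$region)
    if (length(miss))
      stop("region(s) not in table: ", paste(miss, collapse = ", "))
    tb <- tb[match(regions, tb$region), ]
  }
  region_feature_table(tb$region, tb$length, tb$breakpoints, tb[[feature]])
}
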