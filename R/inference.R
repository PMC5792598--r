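#' Pairwise rank-sum tests between treatments within a year
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests for every pair of
#' treatment groups; the design is unpaired (different trees per treatment).
#' Pairs with an empty (or singleton) group are skipped with a note.
#'
#' @param values numeric response (e.g. branch-year needle length).
#' @param treatment factor/character of treatment labels, same length.
#' @param alpha significance level recorded alongside the result.
#' @return data frame, one row per comparable pair: `group1`, `group2`,
#'   `n1`, `n2`, `statistic` (W), `p_value`, `significant`.
#' @export
ranksum_pairs <- function(values, treatment, alpha = 0.05) {
  treatment <- as.character(treatment)
  groups <- unique(treatment)
  if (length(groups) < 2L) stop("need at least two treatment groups")
  combs <- utils::combn(sort(groups), 2, simplify = FALSE)
  rows <- lapply(combs, function(pr) {
    x <- values[treatment == pr[1]]
    y <- values[treatment == pr[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      message("skipping pair ", pr[1], "/", pr[2], ": fewer than 2 observations in a group")
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               significant = wt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    message("no comparable treatment pairs")
    out <- data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), statistic = numeric(),
                      p_value = numeric(), significant = logical())
  }
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov test of one year against the pooled years
#'
#' Two-sample KS test of whether a single year's distribution differs from
#' the distribution pooled over all years of the experiment (the long-term
#' within-treatment benchmark).
#'
#' @param values_year the year's observations.
#' @param values_pooled the pooled observations (all years).
#' @param alpha significance level recorded alongside the result.
#' @return data frame with `statistic` (D), `p_value`, `n_year`, `n_pooled`,
#'   `significant`.
#' @export
ks_year_vs_pooled <- function(values_year, values_pooled, alpha = 0.05) {
  values_year <- values_year[!is.na(values_year)]
  values_pooled <- values_pooled[!is.na(values_pooled)]
  if (!length(values_year) || !length(values_pooled)) stop("both samples must be nonempty")
  if (length(values_year) < 3L || length(values_pooled) < 3L) {
    warning("fewer than 3 observations in a sample; KS p-value is unreliable")
  }
  kt <- suppressWarnings(stats::ks.test(values_year, values_pooled))
  data.frame(statistic = unname(kt$statistic), p_value = kt$p.value,
             n_year = length(values_year), n_pooled = length(values_pooled),
             significant = kt$p.value < alpha)
}

#' Least-squares slope through the origin
#'
#' Zero-intercept regression of `y` on `x`; the closed form is
#' `sum(x*y) / sum(x^2)`. Used for the SA-on-LA relationships, where a branch
#' with no leaf area cannot add sapwood.
#'
#' @param x predictor (e.g. LA values).
#' @param y response (e.g. SA values).
#' @return the slope (scalar).
#' @export
zero_intercept_slope <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least two complete (x, y) pairs")
  sx2 <- sum(x^2)
  if (sx2 == 0) stop("all x are zero; slope undefined")
  sum(x * y) / sx2
}

#' Fit a zero-intercept slope with a bootstrap summary
#'
#' @inheritParams zero_intercept_slope
#' @param b number of bootstrap resamples of the (x, y) pairs.
#' @param seed optional RNG seed for reproducibility.
#' @param conf confidence level of the percentile interval.
#' @return object of class `slope_fit`: list with `slope`, `n`, `b`,
#'   `ci_lower`, `ci_upper`, `boot_slopes`.
#' @export
fit_zero_intercept_slope <- function(x, y, b = 1000L, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  slope <- zero_intercept_slope(x, y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  bs <- vapply(seq_len(b), function(i) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(x[idx]^2) > 0) return(sum(x[idx] * y[idx]) / sum(x[idx]^2))
    }
  }, numeric(1))
  qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(slope = slope, n = n, b = b,
                 ci_lower = qs[1], ci_upper = qs[2], boot_slopes = bs),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("zero-intercept slope = %.4g (n = %d; %d-resample percentile CI [%.4g, %.4g])\n",
              x$slope, x$n, x$b, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Bootstrap comparison of two zero-intercept slopes
#'
#' Resamples the (x, y) pairs with replacement within each group, refits the
#' zero-intercept slopes, and forms the bootstrap distribution of their
#' difference (group1 minus group2). The two-sided p-value is the percentile
#' position of zero in that distribution; the difference is significant at
#' `1 - conf` when the percentile interval excludes zero. Degenerate
#' resamples (all x zero) are redrawn and counted.
#'
#' @param x1,y1 pairs of the first group.
#' @param x2,y2 pairs of the second group.
#' @param b number of bootstrap replicates (default 10000).
#' @param seed RNG seed; required for reproducibility of reported p-values.
#' @param conf confidence level of the percentile interval.
#' @return data frame with the two slopes, `diff`, `ci_lower`, `ci_upper`,
#'   `p_value`, `significant`, `n_redrawn`.
#' @export
bootstrap_slope_difference <- function(x1, y1, x2, y2, b = 10000L,
                                       seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  keep <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    list(x = x[ok], y = y[ok])
  }
  g1 <- keep(x1, y1); g2 <- keep(x2, y2)
  if (length(g1$x) < 3L || length(g2$x) < 3L) stop("each group needs at least 3 pairs")
  n_redrawn <- 0L
  boot_group <- function(g) {
    n <- length(g$x)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), n, b)
    num <- colSums(matrix(g$x[idx] * g$y[idx], n, b))
    den <- colSums(matrix(g$x[idx]^2, n, b))
    s <- num / den
    while (any(bad <- den == 0)) {      # degenerate resample: redraw, counted
      n_redrawn <<- n_redrawn + sum(bad)
      for (j in which(bad)) {
        i2 <- sample.int(n, n, replace = TRUE)
        den[j] <- sum(g$x[i2]^2)
        s[j] <- sum(g$x[i2] * g$y[i2]) / den[j]
      }
    }
    s
  }
  diffs <- boot_group(g1) - boot_group(g2)
  qs <- stats::quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  # two-sided percentile position of zero, with the +1 continuity adjustment
  p <- 2 * min((sum(diffs <= 0) + 1) / (b + 1), (sum(diffs >= 0) + 1) / (b + 1))
  p <- min(p, 1)
  data.frame(slope1 = zero_intercept_slope(g1$x, g1$y),
             slope2 = zero_intercept_slope(g2$x, g2$y),
             diff = zero_intercept_slope(g1$x, g1$y) - zero_intercept_slope(g2$x, g2$y),
             ci_lower = qs[1], ci_upper = qs[2], p_value = p,
             significant = qs[1] > 0 | qs[2] < 0,
             n_redrawn = n_redrawn)
}
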