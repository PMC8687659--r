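#' Theil-Sen robust trend estimate
#'
#' Slope as the median of all pairwise slopes (y_j - y_i)/(x_j - x_i) over
#' x_j != x_i; intercept as median(y - slope * x); two-sided p-value from
#' the associated Kendall rank-correlation test. Robust to up to ~29% gross
#' outliers, which makes it the appropriate trend estimate for noisy
#' per-generation summaries.
#'
#' @param x,y Numeric vectors (>= 3 finite pairs; x not all equal).
#' @return A list of class `infoflow_trend`: `slope`, `intercept`,
#'   `p_value`, `n`.
#' @export
theil_sen <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite pairs")
  if (length(unique(x)) < 2L) stop("x values are all equal")
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  sl <- dy[dx != 0] / dx[dx != 0]
  slope <- stats::median(sl)
  kt <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  structure(list(slope = slope, intercept = stats::median(y - slope * x),
                 p_value = kt$p.value, n = n), class = "infoflow_trend")
}

#' @export
print.infoflow_trend <- function(x, ...) {
  cat(sprintf("<Theil-Sen trend> slope %.4g, intercept %.4g, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$p_value, x$n))
  invisible(x)
}

#' Rank tests with a uniform report format
#'
#' Thin wrapper around the standard Mann-Whitney-Wilcoxon (unpaired) and
#' Wilcoxon signed-rank (paired) tests, returning the statistic name, its
#' value, the two-sided p-value and per-arm sizes in one flat list. Ties use
#' mid-ranks; the normal approximation is used above 50 observations per
#' arm, exact distributions below (the `stats` defaults).
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Logical.
#' @return A list: `test`, `statistic` (`"U"` or `"V"`), `value`, `p`,
#'   `n_a`, `n_b`. Degenerate paired input (all differences zero) reports
#'   `p = NA` as a no-difference outcome; arms with < 3 observations are
#'   skipped with a warning (`value = NA`).
#' @export
rank_tests <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  nm <- if (paired) "wilcoxon_signed_rank" else "mann_whitney_wilcoxon"
  stat <- if (paired) "V" else "U"
  if (length(a) < 3L || length(b) < 3L || (paired && length(a) != length(b))) {
    warning("insufficient observations for ", nm, "; skipped")
    return(list(test = nm, statistic = stat, value = NA_real_, p = NA_real_,
                n_a = length(a), n_b = length(b)))
  }
  if (paired && all(a - b == 0))
    return(list(test = nm, statistic = stat, value = 0, p = NA_real_,
                n_a = length(a), n_b = length(b)))
  exact <- max(length(a), length(b)) <= 50
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired, exact = exact))
  list(test = nm, statistic = stat, value = unname(wt$statistic),
       p = wt$p.value, n_a = length(a), n_b = length(b))
}
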