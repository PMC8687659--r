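## Plug-in information dynamics on binary rotation series.
## All probabilities are empirical frequencies estimated separately for each
## flight; transitions that touch a masked (NA) symbol are dropped from the
## counts, never imputed.

# Encode k-step histories as integers 0..2^k-1 and gather the per-transition
# (history, next, source) triplets used by every estimator below.
# Returns NULL-free vectors plus the symbol index of each counted transition.
te_transitions <- function(src, tgt, k) {
  if (length(src) != length(tgt)) stop("source and target series differ in length")
  n <- length(tgt)
  if (n <= k + 1L) stop("series too short for history length k = ", k)
  if (k < 1L) stop("history length k must be >= 1")
  H <- stats::embed(tgt[-n], k)          # row i: tgt[i+k-1] ... tgt[i]
  hist_code <- as.vector(H %*% 2^(0:(k - 1)))
  i_present <- k:(n - 1L)                # symbol index of the "present"
  nxt <- tgt[i_present + 1L]
  e <- src[i_present]
  ok <- !is.na(hist_code) & !is.na(nxt) & !is.na(e)
  list(hist = hist_code[ok], nxt = nxt[ok], src = e[ok],
       idx = i_present[ok], n = sum(ok))
}

sym_vec <- function(s) if (inherits(s, "infoflow_rotation")) s$symbols else as.integer(s)

#' Marginal entropy of a rotation series
#'
#' Plug-in Shannon entropy `-sum p log2 p` of the empirical symbol
#' frequencies of one flight: 1 bit for maximally uncertain turning, 0 bits
#' for fully deterministic rotation.
#'
#' @param s An `infoflow_rotation` or a 0/1 vector (`NA` = masked).
#' @return Entropy in bits.
#' @export
marginal_entropy <- function(s) {
  x <- sym_vec(s); x <- x[!is.na(x)]
  if (!length(x)) stop("empty series")
  p <- tabulate(x + 1L, 2L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy of the next symbol given its k-step past
#'
#' Plug-in `H(S_{i+1} | S_i^{(k)})` from joint counts of (k-history, next
#' symbol). This is the residual uncertainty about the next rotation after
#' accounting for the series' own autocorrelation, and the denominator of
#' predictive power. Transitions overlapping masked samples are dropped.
#'
#' @param s An `infoflow_rotation` or a 0/1 vector.
#' @param k History length in samples (>= 1).
#' @return Entropy in bits.
#' @export
conditional_entropy <- function(s, k) {
  x <- sym_vec(s)
  tr <- te_transitions(x, x, k)  # src unused; same masking rules
  if (tr$n == 0L) stop("no countable transitions")
  cond_H(tr$hist, tr$nxt, tr$n)
}

# H(next | ctx) from paired integer code vectors
cond_H <- function(ctx, nxt, m) {
  j <- ctx * 2L + nxt
  c_j <- table(j); c_c <- table(ctx)
  pj <- as.numeric(c_j) / m
  pc_for_j <- as.numeric(c_c[match(as.integer(names(c_j)) %/% 2L,
                                   as.integer(names(c_c)))]) / m
  -sum(pj * log2(pj / pc_for_j))
}

#' Transfer entropy between two rotation series
#'
#' Plug-in transfer entropy from `source` to `target`:
#' `TE = H(T_{i+1} | T^{(k)}) - H(T_{i+1} | T^{(k)}, S_i)`, the reduction in
#' uncertainty about the target's next rotation contributed by the source's
#' present rotation beyond the target's own k-step past. Probabilities are
#' estimated from this flight's counts only. Also reports the conditional
#' entropy and the predictive power, i.e. TE as a percentage of the
#' uncertainty it reduces.
#'
#' @param source,target `infoflow_rotation` objects (or 0/1 vectors) on the
#'   same time grid and of equal length.
#' @param k History length in samples.
#' @param pp_denominator `"conditional"` (default) divides TE by
#'   `H(T_{i+1}|T^{(k)})`; `"marginal"` divides by `H(T_{i+1})`.
#' @return A list of class `infoflow_te`: `te_bits`, `h_cond_bits`,
#'   `predictive_power_pct`, `k`, `period`, `n_transitions`, `direction`.
#' @export
transfer_entropy <- function(source, target, k = 10L,
                             pp_denominator = c("conditional", "marginal")) {
  pp_denominator <- match.arg(pp_denominator)
  s <- sym_vec(source); t <- sym_vec(target)
  tr <- te_transitions(s, t, k)
  if (tr$n == 0L) stop("no countable transitions")
  h_cond <- cond_H(tr$hist, tr$nxt, tr$n)
  h_cond2 <- cond_H(tr$hist * 2L + tr$src, tr$nxt, tr$n)
  te <- max(h_cond - h_cond2, 0)
  denom <- if (pp_denominator == "conditional") h_cond else {
    p1 <- mean(tr$nxt); p <- c(1 - p1, p1); p <- p[p > 0]
    -sum(p * log2(p))
  }
  structure(list(
    direction = c(source = attr_or(source, "bird_id", "source"),
                  target = attr_or(target, "bird_id", "target")),
    te_bits = te, h_cond_bits = h_cond,
    predictive_power_pct = if (denom > 0) 100 * te / denom else 0,
    k = as.integer(k),
    period = attr_or(source, "period", NA_real_),
    n_transitions = tr$n), class = "infoflow_te")
}

attr_or <- function(x, field, default) {
  if (is.list(x) && !is.null(x[[field]])) x[[field]] else default
}

#' @export
print.infoflow_te <- function(x, ...) {
  cat(sprintf("<transfer entropy> %s -> %s | k=%d | TE=%.4f bits (H_cond=%.4f, PP=%.1f%%, n=%d)\n",
              x$direction[["source"]], x$direction[["target"]], x$k,
              x$te_bits, x$h_cond_bits, x$predictive_power_pct, x$n_transitions))
  invisible(x)
}

#' Local (pointwise) transfer entropy
#'
#' The per-transition log-ratio
#' `log2 p(t_{i+1} | t^{(k)}, s_i) / p(t_{i+1} | t^{(k)})` whose average over
#' counted transitions is exactly the flight's transfer entropy. Positive
#' values mark informative interactions at that moment, negative values
#' misinformative ones. Uses the same per-flight plug-in probabilities as
#' [transfer_entropy()].
#'
#' @inheritParams transfer_entropy
#' @return A list of class `infoflow_lte`: `values` (bits per transition),
#'   `idx` (symbol index of each transition's present), `te_bits`.
#' @export
local_transfer_entropy <- function(source, target, k = 10L) {
  s <- sym_vec(source); t <- sym_vec(target)
  tr <- te_transitions(s, t, k)
  if (tr$n == 0L) stop("no countable transitions")
  m <- tr$n
  j_hn <- tr$hist * 2L + tr$nxt
  j_he <- tr$hist * 2L + tr$src
  j_hne <- j_he * 2L + tr$nxt
  f <- function(code) { tb <- table(code); as.numeric(tb[match(code, as.integer(names(tb)))]) }
  p_cond_src <- f(j_hne) / f(j_he)
  p_cond <- f(j_hn) / f(tr$hist)
  vals <- log2(p_cond_src / p_cond)
  structure(list(values = vals, idx = tr$idx, te_bits = mean(vals),
                 k = as.integer(k), n_transitions = m), class = "infoflow_lte")
}

#' Net predictive power of a pair
#'
#' Predictive power of the experienced-to-naive direction minus that of the
#' naive-to-experienced direction for one flight: positive values mean the
#' experienced bird carries more predictive information about its partner's
#' future turning than vice versa.
#'
#' @param te_en,te_ne `infoflow_te` results for the two directions of the
#'   same flight at identical settings.
#' @return Signed percentage points.
#' @export
net_predictive_power <- function(te_en, te_ne) {
  if (te_en$k != te_ne$k || !identical(te_en$period, te_ne$period))
    stop("the two directions were computed with different settings")
  te_en$predictive_power_pct - te_ne$predictive_power_pct
}

#' Per-flight transfer entropy in both directions
#'
#' Convenience wrapper: encodes both birds of each pair at `period`,
#' estimates TE experienced->naive and naive->experienced, and returns one
#' tidy row per flight and direction.
#'
#' @param pairs List of [pair_flight()] objects.
#' @param period Sampling period in seconds.
#' @param k History length in samples.
#' @return A data.frame with flight keys, `direction` (`"EN"`/`"NE"`),
#'   `te_bits`, `h_cond_bits`, `predictive_power_pct`, `n_transitions`.
#' @export
pair_te <- function(pairs, period = 0.2, k = 10L) {
  rows <- lapply(seq_along(pairs), function(i) {
    pf <- pairs[[i]]
    re <- rotation_series(pf$experienced, period)
    rn <- rotation_series(pf$naive, period)
    en <- transfer_entropy(re, rn, k)
    ne <- transfer_entropy(rn, re, k)
    data.frame(flight = i, chain = pf$chain_id, generation = pf$generation,
               release = pf$release, is_surrogate = pf$is_surrogate,
               direction = c("EN", "NE"),
               te_bits = c(en$te_bits, ne$te_bits),
               h_cond_bits = c(en$h_cond_bits, ne$h_cond_bits),
               predictive_power_pct = c(en$predictive_power_pct,
                                        ne$predictive_power_pct),
               n_transitions = c(en$n_transitions, ne$n_transitions))
  })
  do.call(rbind, rows)
}

#' Scan sampling period and history length
#'
#' For each (period, k) combination, estimates the mean over flights of the
#' total transfer of information within the pair, TE(E->N) + TE(N->E), and
#' reports the configuration that maximises it. This is the standard way to
#' select the estimator's prediction interval and history length.
#'
#' @param pairs List of [pair_flight()] objects.
#' @param periods Numeric seconds, multiples of 0.2 in [0.2, 4].
#' @param ks Integer history lengths.
#' @return A list with `grid` (data.frame period, k, mean_total_te) and
#'   `best` (the argmax row).
#' @export
parameter_scan <- function(pairs, periods = c(0.2, 0.4, 1, 2, 4), ks = c(1, 5, 10)) {
  if (!length(pairs)) stop("no pairs supplied")
  grid <- expand.grid(period = periods, k = ks)
  grid$mean_total_te <- vapply(seq_len(nrow(grid)), function(i) {
    d <- pair_te(pairs, grid$period[i], grid$k[i])
    mean(tapply(d$te_bits, d$flight, sum))
  }, 0)
  list(grid = grid, best = grid[which.max(grid$mean_total_te), ])
}

#' Local transfer entropy binned by relative position
#'
#' Pools local TE values of both directions across flights and bins them by
#' the signed projected inter-bird distance d_EN at the transition's present
#' sample. Reports per-bin means with flight-level bootstrap 95% CIs, and a
#' front-bird dominance statistic per bin: mean local TE of the
#' front-to-back direction minus the back-to-front one (front = experienced
#' where d_EN > 0, naive where d_EN < 0).
#'
#' @param pairs List of [pair_flight()] objects.
#' @param k History length in samples.
#' @param period Sampling period in seconds.
#' @param bins Bin edges in metres for d_EN.
#' @param n_boot Bootstrap resamples (flights resampled with replacement).
#' @param conf Confidence level for the bootstrap interval.
#' @return A list with `by_bin` (bin, direction, mean, ci_lo, ci_hi, n) and
#'   `dominance` (bin, front_minus_back, n). Empty bins are absent, not zero.
#' @export
local_te_by_distance <- function(pairs, k = 10L, period = 0.2,
                                 bins = seq(-50, 50, by = 5),
                                 n_boot = 1000L, conf = 0.95) {
  per_flight <- lapply(seq_along(pairs), function(i) {
    pf <- pairs[[i]]
    Es <- subsample(pf$experienced, period)
    Ns <- subsample(pf$naive, period)
    d <- projected_distance(pair_flight(Es, Ns))$d_en
    re <- rotation_series(pf$experienced, period)
    rn <- rotation_series(pf$naive, period)
    en <- local_transfer_entropy(re, rn, k)
    ne <- local_transfer_entropy(rn, re, k)
    # symbol index j sits at trajectory position j + 1 (cross product centre)
    rbind(
      data.frame(flight = i, direction = "EN", lte = en$values,
                 d_en = d[en$idx + 1L]),
      data.frame(flight = i, direction = "NE", lte = ne$values,
                 d_en = d[ne$idx + 1L]))
  })
  all <- do.call(rbind, per_flight)
  all <- all[!is.na(all$d_en), , drop = FALSE]
  all$bin <- cut(all$d_en, bins, include.lowest = TRUE)
  all <- all[!is.na(all$bin), , drop = FALSE]
  agg <- stats::aggregate(lte ~ bin + direction, all, mean)
  cnt <- stats::aggregate(lte ~ bin + direction, all, length)
  names(agg)[3] <- "mean"; names(cnt)[3] <- "n"
  by_bin <- merge(agg, cnt)
  # flight-level bootstrap
  flights <- unique(all$flight)
  if (n_boot > 0 && length(flights) > 1) {
    key <- interaction(by_bin$bin, by_bin$direction, drop = FALSE)
    boot <- matrix(NA_real_, n_boot, nrow(by_bin))
    split_fl <- split(all, all$flight)
    for (b in seq_len(n_boot)) {
      take <- sample(length(split_fl), replace = TRUE)
      res <- do.call(rbind, split_fl[take])
      m <- tapply(res$lte, interaction(res$bin, res$direction, drop = FALSE), mean)
      boot[b, ] <- m[match(as.character(key), names(m))]
    }
    a <- (1 - conf) / 2
    by_bin$ci_lo <- apply(boot, 2, stats::quantile, a, na.rm = TRUE)
    by_bin$ci_hi <- apply(boot, 2, stats::quantile, 1 - a, na.rm = TRUE)
  } else {
    by_bin$ci_lo <- NA_real_; by_bin$ci_hi <- NA_real_
  }
  # dominance: front bird's direction minus back bird's, per bin
  mid <- (bins[-length(bins)] + bins[-1]) / 2
  lev <- levels(all$bin)
  dom <- do.call(rbind, lapply(seq_along(lev), function(j) {
    sub <- by_bin[by_bin$bin == lev[j], ]
    if (nrow(sub) < 2) return(NULL)
    en <- sub$mean[sub$direction == "EN"]; ne <- sub$mean[sub$direction == "NE"]
    fmb <- if (mid[j] > 0) en - ne else ne - en
    data.frame(bin = lev[j], bin_mid = mid[j], front_minus_back = fmb,
               n = sum(sub$n))
  }))
  list(by_bin = by_bin, dominance = dom)
}
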