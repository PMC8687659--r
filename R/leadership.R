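#' Extract front/back leadership segments from d_EN
#'
#' Splits a flight into maximal runs of constant sign of the projected
#' inter-bird distance: the experienced bird leads (is in front) while
#' d_EN > 0, the naive bird while d_EN < 0. Exact zeros and masked samples
#' extend the current run — a leader change requires an actual sign flip,
#' which keeps the segmentation robust to the ~1.69 m front/back GPS error
#' near zero. An optional hysteresis band treats |d_EN| below `hysteresis`
#' as retaining the incumbent leader.
#'
#' @param d An `infoflow_den` from [projected_distance()] (or a plain
#'   numeric d_EN vector).
#' @param period Sampling period in seconds (segment durations = samples x
#'   period).
#' @param hysteresis Metres; values with |d_EN| below it keep the incumbent
#'   leader. Default 0 (off).
#' @return A data.frame with one row per segment: `leader` (`"E"`/`"N"`),
#'   `start_s`, `duration_s`, `n_samples`. Empty for an all-masked series.
#' @export
leadership_segments <- function(d, period = 0.2, hysteresis = 0) {
  den <- if (inherits(d, "infoflow_den")) d$d_en else as.numeric(d)
  tt <- if (inherits(d, "infoflow_den")) d$t else (seq_along(den) - 1) * period
  sgn <- sign(den)
  if (hysteresis > 0) sgn[!is.na(den) & abs(den) < hysteresis] <- 0
  # zeros and NAs extend the current run; leading zeros take the first sign
  lead <- rep(NA_integer_, length(sgn))
  cur <- 0L
  for (i in seq_along(sgn)) {
    s <- sgn[i]
    if (!is.na(s) && s != 0) cur <- as.integer(s)
    lead[i] <- cur
  }
  first <- lead[lead != 0L]
  if (!length(first)) return(data.frame(leader = character(0), start_s = numeric(0),
                                        duration_s = numeric(0), n_samples = integer(0)))
  lead[lead == 0L] <- first[1]  # samples before the first defined sign
  r <- rle(lead)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(leader = ifelse(r$values > 0, "E", "N"),
             start_s = tt[starts],
             duration_s = r$lengths * period,
             n_samples = r$lengths)
}

#' Proportion of flight time led by each role
#'
#' Per-flight share of time each bird spent at the front, with a paired
#' Wilcoxon signed-rank test of the experienced against the naive shares
#' across flights (overall or per generation).
#'
#' @param segments A data.frame of [leadership_segments()] rows bearing
#'   `flight` and (optionally) `generation` columns.
#' @param by `"flight"` (no test, per-flight shares only) or `"generation"`
#'   (adds "overall" and per-generation tests).
#' @return A list with `shares` (flight, share_E, share_N) and, for grouped
#'   output, `tests` (group, V, p, mean_share_E, mean_share_N, n). Groups
#'   with <3 flights are skipped; all-zero difference groups report p = NA
#'   as a degenerate no-difference outcome.
#' @export
leadership_proportions <- function(segments, by = c("flight", "generation")) {
  by <- match.arg(by)
  stopifnot("flight" %in% names(segments))
  sh <- do.call(rbind, lapply(split(segments, segments$flight), function(s) {
    tot <- sum(s$duration_s)
    data.frame(flight = s$flight[1],
               generation = if ("generation" %in% names(s)) s$generation[1] else NA,
               share_E = sum(s$duration_s[s$leader == "E"]) / tot,
               share_N = sum(s$duration_s[s$leader == "N"]) / tot)
  }))
  rownames(sh) <- NULL
  if (by == "flight") return(list(shares = sh))
  groups <- c(list(overall = sh), split(sh, sh$generation))
  tests <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3L) {
      warning("group ", g, ": fewer than 3 flights, test skipped"); return(NULL)
    }
    diffs <- d$share_E - d$share_N
    if (all(diffs == 0)) {
      return(data.frame(group = g, V = NA_real_, p = NA_real_,
                        mean_share_E = mean(d$share_E),
                        mean_share_N = mean(d$share_N), n = nrow(d)))
    }
    wt <- stats::wilcox.test(d$share_E, d$share_N, paired = TRUE, exact = FALSE)
    data.frame(group = g, V = unname(wt$statistic), p = wt$p.value,
               mean_share_E = mean(d$share_E), mean_share_N = mean(d$share_N),
               n = nrow(d))
  }))
  list(shares = sh, tests = tests)
}

#' Fit candidate distributions to leadership durations
#'
#' Maximum-likelihood log-normal and exponential fits to the consecutive
#' time each bird spends at the front, compared by AIC and
#' Kolmogorov-Smirnov distance. Optionally contrasts the experienced and
#' naive duration distributions with a Mann-Whitney-Wilcoxon test.
#'
#' @param durations Positive durations in seconds (>= 30 values).
#' @param durations_other Optional second sample (the other role) for the
#'   MWW comparison.
#' @return A list: `lnorm` (`meanlog`, `sdlog`, `aic`, `ks`), `exp`
#'   (`rate`, `aic`, `ks`), `preferred` (`"lnorm"`/`"exp"` by AIC), and
#'   `mww` (`W`, `p`) when a second sample is given.
#' @export
duration_distribution_fit <- function(durations, durations_other = NULL) {
  if (any(durations <= 0)) stop("durations must be positive")
  if (length(durations) < 30L) stop("need at least 30 durations")
  f_ln <- fitdistrplus::fitdist(durations, "lnorm")
  f_ex <- fitdistrplus::fitdist(durations, "exp")
  ks_ln <- suppressWarnings(stats::ks.test(durations, "plnorm",
                                           f_ln$estimate[["meanlog"]],
                                           f_ln$estimate[["sdlog"]])$statistic)
  ks_ex <- suppressWarnings(stats::ks.test(durations, "pexp",
                                           f_ex$estimate[["rate"]])$statistic)
  out <- list(
    lnorm = list(meanlog = unname(f_ln$estimate[["meanlog"]]),
                 sdlog = unname(f_ln$estimate[["sdlog"]]),
                 aic = f_ln$aic, ks = unname(ks_ln)),
    exp = list(rate = unname(f_ex$estimate[["rate"]]),
               aic = f_ex$aic, ks = unname(ks_ex)),
    preferred = if (f_ln$aic < f_ex$aic) "lnorm" else "exp")
  if (!is.null(durations_other)) {
    wt <- stats::wilcox.test(durations, durations_other, exact = FALSE)
    out$mww <- list(W = unname(wt$statistic), p = wt$p.value)
  }
  out
}
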