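#' Point-to-point distance from a focal to a baseline trajectory
#'
#' For each focal sample, the minimum Euclidean distance to any vertex of
#' the baseline trajectory (exact nearest-vertex search, not index-matched).
#' At 5 Hz and ~20 m/s the baseline vertex spacing (~4 m) is far below the
#' 300 m labelling threshold, so vertex resolution is adequate.
#'
#' @param focal,baseline [trajectory()] objects (baseline non-empty).
#' @return Numeric metres per focal sample (`NA` where the focal sample is
#'   masked).
#' @export
distance_to_baseline <- function(focal, baseline) {
  bx <- baseline$x[!is.na(baseline$x)]
  by <- baseline$y[!is.na(baseline$y)]
  if (!length(bx)) stop("empty baseline")
  n <- length(focal$x)
  out <- rep(NA_real_, n)
  b2 <- bx^2 + by^2
  # chunked to bound the n_focal x n_baseline distance matrix
  chunk <- max(1L, floor(4e6 / length(bx)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fx <- focal$x[idx]; fy <- focal$y[idx]
    d2 <- outer(fx^2 + fy^2, b2, "+") - 2 * (cbind(fx, fy) %*% rbind(bx, by))
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Map each flight to its baseline route
#'
#' Chooses, for every flight of a transmission chain, the earlier route
#' against which exploration is defined. Model `"previous_release"`:
#' release r > 1 is compared with release r - 1 of the same chain, and the
#' first release of a generation with the last release of the previous
#' generation; the very first flight of the chain has no baseline and is
#' excluded. Model `"last_of_previous_generation"`: every release of
#' generation g > 1 is compared with the last release of generation g - 1
#' (what the experienced bird knew at the start of the generation);
#' generation 1 falls back to the previous-release rule.
#'
#' @param meta A data.frame with columns `chain`, `generation`, `release`
#'   (one row per flight).
#' @param model `"previous_release"` or `"last_of_previous_generation"`.
#' @return `meta` with added `baseline_generation`, `baseline_release`
#'   (`NA` where no baseline exists).
#' @export
select_baseline <- function(meta, model = c("previous_release",
                                            "last_of_previous_generation")) {
  model <- match.arg(model)
  out <- meta
  out$baseline_generation <- NA_integer_
  out$baseline_release <- NA_integer_
  for (i in seq_len(nrow(meta))) {
    ch <- meta$chain[i]; g <- meta$generation[i]; r <- meta$release[i]
    last_of <- function(gen) {
      rel <- meta$release[meta$chain == ch & meta$generation == gen]
      if (length(rel)) max(rel) else NA_integer_
    }
    bg <- br <- NA_integer_
    if (model == "previous_release" || g == 1L) {
      if (r > 1L) { bg <- g; br <- r - 1L }
      else if (g > 1L) { bg <- g - 1L; br <- last_of(g - 1L) }
    } else {
      bg <- g - 1L; br <- last_of(g - 1L)
    }
    out$baseline_generation[i] <- bg
    out$baseline_release[i] <- br
  }
  out
}

#' Label samples as exploration or exploitation
#'
#' A sample explores when its point-to-point distance to the baseline route
#' exceeds the threshold (strictly; a bird exactly at 300 m still counts as
#' remaining within its route), and exploits otherwise. Contiguous runs of
#' one label form phases.
#'
#' @param dist Metres per sample from [distance_to_baseline()].
#' @param threshold Metres (default 300).
#' @return A data.frame of class `infoflow_labels`: `dist_m`, `label`
#'   (`"exploitation"`/`"exploration"`, `NA` where dist is masked), and
#'   `phase` (integer id of each contiguous labelled run).
#' @export
label_segments <- function(dist, threshold = 300) {
  lab <- ifelse(is.na(dist), NA_character_,
                ifelse(dist > threshold, "exploration", "exploitation"))
  # phase ids over non-masked runs
  change <- c(TRUE, lab[-1] != lab[-length(lab)])
  change[is.na(change)] <- TRUE
  phase <- cumsum(change)
  phase[is.na(lab)] <- NA_integer_
  structure(data.frame(dist_m = dist, label = lab, phase = phase),
            class = c("infoflow_labels", "data.frame"))
}

#' Proportion of a flight spent exploring
#'
#' @param labels An `infoflow_labels` data.frame.
#' @return Fraction of valid samples labelled exploration.
#' @export
exploration_proportion <- function(labels) {
  mean(labels$label == "exploration", na.rm = TRUE)
}

#' Leadership shares within exploration and exploitation phases
#'
#' Within the samples of each phase type, the fraction led by the
#' experienced bird (d_EN > 0) versus the naive one (d_EN < 0); zeros and
#' masked samples are ignored. A phase type absent from the flight yields
#' `NA` shares, not zero.
#'
#' @param labels An `infoflow_labels` data.frame.
#' @param d An `infoflow_den` (or numeric d_EN) on the same sample grid.
#' @return A data.frame with one row per phase type: `label`, `share_E`,
#'   `share_N`, `n` (valid samples counted).
#' @export
phase_leadership_share <- function(labels, d) {
  den <- if (inherits(d, "infoflow_den")) d$d_en else as.numeric(d)
  stopifnot(length(den) == nrow(labels))
  do.call(rbind, lapply(c("exploration", "exploitation"), function(ph) {
    sel <- !is.na(labels$label) & labels$label == ph & !is.na(den) & den != 0
    n <- sum(sel)
    data.frame(label = ph,
               share_E = if (n) mean(den[sel] > 0) else NA_real_,
               share_N = if (n) mean(den[sel] < 0) else NA_real_,
               n = n)
  }))
}

#' Attribute phase transitions to the bird that initiated them
#'
#' A transition happens where the label switches between exploitation and
#' exploration; its initiator is the bird at the front of the pair (the
#' sign of d_EN) at the first sample of the new phase. If d_EN is masked or
#' exactly zero there, the front role of the nearest preceding valid sample
#' is used.
#'
#' @param labels An `infoflow_labels` data.frame.
#' @param d An `infoflow_den` (or numeric d_EN) on the same grid.
#' @param direction `"exploit_to_explore"` or `"explore_to_exploit"`.
#' @return A data.frame with one row per transition: `index` (first sample
#'   of the new phase) and `initiator` (`"E"`/`"N"`, `NA` if no valid d_EN
#'   exists at or before the transition).
#' @export
transition_initiators <- function(labels, d,
                                  direction = c("exploit_to_explore",
                                                "explore_to_exploit")) {
  direction <- match.arg(direction)
  from <- if (direction == "exploit_to_explore") "exploitation" else "exploration"
  to <- if (direction == "exploit_to_explore") "exploration" else "exploitation"
  den <- if (inherits(d, "infoflow_den")) d$d_en else as.numeric(d)
  ok <- !is.na(labels$phase)
  ph_start <- tapply(which(ok), labels$phase[ok], min)
  ph_lab <- tapply(labels$label[ok], labels$phase[ok], function(v) v[1])
  ord <- order(ph_start)
  ph_start <- ph_start[ord]; ph_lab <- ph_lab[ord]
  is_hit <- seq_along(ph_lab) > 1 & ph_lab == to &
    c(NA, ph_lab[-length(ph_lab)]) == from
  hits <- as.integer(ph_start[which(is_hit)])
  if (!length(hits))
    return(data.frame(index = integer(0), initiator = character(0)))
  initiator <- vapply(hits, function(i) {
    j <- i
    while (j >= 1L && (is.na(den[j]) || den[j] == 0)) j <- j - 1L
    if (j < 1L) NA_character_ else if (den[j] > 0) "E" else "N"
  }, "")
  data.frame(index = hits, initiator = initiator)
}

#' Exact binomial test of who initiates transitions
#'
#' Two-sided exact binomial test of the number of naive-initiated
#' transitions against an equal-likelihood null of 0.5.
#'
#' @param initiators Character vector of `"E"`/`"N"` (NAs dropped).
#' @return A list: `n`, `n_naive`, `prop_naive`, `p`.
#' @export
initiation_test <- function(initiators) {
  x <- initiators[!is.na(initiators)]
  n <- length(x)
  if (!n) return(list(n = 0L, n_naive = 0L, prop_naive = NA_real_, p = NA_real_))
  k <- sum(x == "N")
  list(n = n, n_naive = k, prop_naive = k / n,
       p = stats::binom.test(k, n, 0.5)$p.value)
}
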