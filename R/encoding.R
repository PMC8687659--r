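#' Construct a rotation symbol series
#'
#' @param symbols Integer vector over {0 = clockwise, 1 = counterclockwise},
#'   `NA` where masked.
#' @param period Sampling period in seconds.
#' @param tie_mask Logical vector marking symbols produced by a zero cross
#'   product (carried forward rather than observed).
#' @param bird_id,chain_id,generation,release Flight metadata.
#' @return An object of class `infoflow_rotation`.
#' @export
rotation_series_obj <- function(symbols, period, tie_mask = NULL,
                                bird_id = "bird", chain_id = "chain",
                                generation = 1L, release = 1L) {
  symbols <- as.integer(symbols)
  if (any(!symbols %in% c(0L, 1L) & !is.na(symbols)))
    stop("rotation symbols must be 0, 1 or NA")
  if (is.null(tie_mask)) tie_mask <- rep(FALSE, length(symbols))
  structure(list(symbols = symbols, period = period, tie_mask = tie_mask,
                 bird_id = bird_id, chain_id = chain_id,
                 generation = as.integer(generation),
                 release = as.integer(release)),
            class = "infoflow_rotation")
}

#' @export
print.infoflow_rotation <- function(x, ...) {
  cat(sprintf("<rotation series> bird %s | period %.1f s | %d symbols (%.1f%% ties, %.1f%% masked)\n",
              x$bird_id, x$period, length(x$symbols),
              100 * mean(x$tie_mask), 100 * mean(is.na(x$symbols))))
  invisible(x)
}

#' @export
length.infoflow_rotation <- function(x) length(x$symbols)

#' Subsample a trajectory to a coarser period
#'
#' Keeps every (period / 0.2)-th position starting at the first sample.
#' Larger periods make the downstream rotation encoding measure coarser
#' turning, which is how the prediction interval of the transfer-entropy
#' estimator is scanned.
#'
#' @param traj A [trajectory()] sampled at 0.2 s.
#' @param period Target period in seconds; must be a multiple of the native
#'   0.2 s spacing, in [0.2, 4].
#' @param native Native sampling period in seconds.
#' @return The subsampled [trajectory()].
#' @export
subsample <- function(traj, period, native = 0.2) {
  step <- period / native
  if (abs(step - round(step)) > 1e-8 || period < native - 1e-9 || period > 4 + 1e-9)
    stop("period must be a multiple of ", native, " s in [", native, ", 4]")
  step <- as.integer(round(step))
  if (step == 1L) return(traj)
  idx <- seq(1L, length(traj$t), by = step)
  trajectory(traj$t[idx], traj$x[idx], traj$y[idx], traj$bird_id,
             traj$chain_id, traj$generation, traj$release)
}

#' Encode a trajectory as binary rotations
#'
#' The direction of rotation at step i is the sign of the planar cross
#' product between the motion vector from position i-1 to i and that from i
#' to i+1: counterclockwise (symbol 1) when positive, clockwise (symbol 0)
#' when negative. Exact zeros (collinear motion) carry the previous symbol
#' forward — a run of zeros at the start of a series defaults to 0 — and are
#' flagged in `tie_mask` so the tie fraction can be audited per flight.
#' Subsampling to `period` happens before the cross products are taken.
#'
#' @param traj A [trajectory()].
#' @param period Sampling period in seconds (multiple of the native 0.2 s).
#' @return An `infoflow_rotation` of length `n_positions - 2`; positions with
#'   masked coordinates yield `NA` symbols.
#' @export
rotation_series <- function(traj, period = 0.2) {
  traj <- subsample(traj, period)
  n <- length(traj$t)
  if (n < 3L) stop("need at least 3 positions after subsampling")
  vx <- diff(traj$x); vy <- diff(traj$y)
  cr <- vx[-length(vx)] * vy[-1] - vy[-length(vy)] * vx[-1]
  sym <- rep(NA_integer_, length(cr))
  sym[which(cr > 0)] <- 1L
  sym[which(cr < 0)] <- 0L
  tie <- !is.na(cr) & cr == 0
  # carry the previous symbol across ties without disturbing masked samples
  last <- 0L
  for (i in seq_along(sym)) {
    if (tie[i]) sym[i] <- last
    else if (!is.na(sym[i])) last <- sym[i]
  }
  rotation_series_obj(sym, period, tie, traj$bird_id, traj$chain_id,
                      traj$generation, traj$release)
}

#' Signed projected inter-bird distance
#'
#' The distance of the experienced bird from the naive one projected on the
#' pair's current direction of motion: `u_hat(i)` is the normalised sum of
#' the two birds' unit velocity vectors and
#' `d_EN(i) = (x_E(i) - x_N(i)) . u_hat(i)`. Positive values mean the
#' experienced bird flies ahead of the naive one, negative behind. Samples
#' where the pair direction is undefined (a masked fix, a stationary bird,
#' or exactly opposed equal-speed headings) are `NA`.
#'
#' @param pf An aligned [pair_flight()].
#' @return A list of class `infoflow_den` with fields `t`, `d_en` (signed
#'   metres), and `u_hat` (two-column matrix of unit pair directions).
#' @export
projected_distance <- function(pf) {
  E <- pf$experienced; N <- pf$naive
  n <- length(E$t)
  vel <- function(tr) {
    vx <- c(diff(tr$x), NA); vy <- c(diff(tr$y), NA)
    # final sample inherits the last step's velocity
    vx[n] <- vx[n - 1L]; vy[n] <- vy[n - 1L]
    sp <- sqrt(vx^2 + vy^2)
    cbind(vx / sp, vy / sp)  # zero speed -> NaN -> masked
  }
  uE <- vel(E); uN <- vel(N)
  sx <- uE[, 1] + uN[, 1]; sy <- uE[, 2] + uN[, 2]
  nrm <- sqrt(sx^2 + sy^2)
  bad <- !is.finite(nrm) | nrm < 1e-12
  ux <- sx / nrm; uy <- sy / nrm
  d <- (E$x - N$x) * ux + (E$y - N$y) * uy
  d[bad] <- NA_real_
  structure(list(t = E$t, d_en = d, u_hat = cbind(ux, uy)),
            class = "infoflow_den")
}
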