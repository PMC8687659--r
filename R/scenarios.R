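#' Standard synthetic study conditions
#'
#' Scenario builders shared by the analysis scripts, the test suite and the
#' acceptance checks, so every consumer measures the same simulated
#' conditions.
#'
#' `scenario_coupled_colony()` simulates flights of coupled pairs under the
#' default flight model (delayed heading coupling `w_couple = 0.6`,
#' `tau = 1` step, cohesion attraction, alternating Markov leadership).
#'
#' `scenario_uncoupled_colony()` pairs two independently simulated solo
#' flights per release: the two birds share release site, home and flight
#' duration but exchange no information — the ground-truth null for
#' surrogate calibration.
#'
#' `scenario_chain_colony()` simulates transmission chains with exploration
#' bouts enabled (waypoint amplitude 400-1000 m) and elevated naive-bird
#' exploration drive early in each generation.
#'
#' @param n_flights,n_pairs,n_chains Number of flights/pairs/chains.
#' @param n_steps Steps per flight.
#' @param seed Integer seed; per-flight seeds are drawn from it.
#' @param ... Overrides passed to [sim_config()].
#' @return A list of [pair_flight()] objects (colonies) or a list of chain
#'   record lists (`scenario_chain_colony`), with ground truths attached as
#'   attribute `"truths"` for the colonies.
#' @name scenarios
NULL

scenario_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @rdname scenarios
#' @export
scenario_coupled_colony <- function(n_flights = 20L, n_steps = 6000L,
                                    seed = 1L, ...) {
  seeds <- scenario_seeds(seed, n_flights)
  sims <- lapply(seq_len(n_flights), function(i) {
    simulate_pair_flight(
      sim_config(n_steps = n_steps, seed = seeds[i], ...),
      bird_ids = paste0(c("E", "N"), i), chain_id = "coupled",
      generation = 2L, release = i)
  })
  out <- lapply(sims, `[[`, "pair")
  attr(out, "truths") <- lapply(sims, `[[`, "truth")
  out
}

#' @rdname scenarios
#' @export
scenario_uncoupled_colony <- function(n_pairs = 6L, n_steps = 3000L,
                                      seed = 1L, ...) {
  seeds <- matrix(scenario_seeds(seed, 2L * n_pairs), ncol = 2L)
  out <- lapply(seq_len(n_pairs), function(i) {
    mk <- function(j, id) {
      cfg <- sim_config(n_steps = n_steps, seed = seeds[i, j], ...)
      simulate_solo_flight(cfg, bird_id = id, chain_id = "uncoupled",
                           generation = 2L, release = i)$trajectory
    }
    pair_flight(mk(1L, paste0("E", i)), mk(2L, paste0("N", i)))
  })
  out
}

#' @rdname scenarios
#' @param n_generations,n_releases Chain design.
#' @export
scenario_chain_colony <- function(n_chains = 6L, n_generations = 2L,
                                  n_releases = 12L, n_steps = 2600L,
                                  seed = 1L, ...) {
  seeds <- scenario_seeds(seed, n_chains)
  lapply(seq_len(n_chains), function(i) {
    cfg <- sim_config(n_steps = n_steps, p_explore = 0.0008,
                      explore_band = c(400, 1000), seed = seeds[i], ...)
    simulate_transmission_chain(cfg, n_generations, n_releases,
                                chain_id = paste0("C", i))
  })
}

#' Write a simulated chain to track and ground-truth CSV files
#'
#' Tracks go to the same CSV dialect [read_flights()] accepts (planar
#' coordinates); per-step ground truth (latent leader, exploration state)
#' goes to a sidecar CSV keyed by flight and step.
#'
#' @param chain A chain record list from [simulate_transmission_chain()].
#' @param tracks_path,truth_path Output CSV paths.
#' @export
write_chain_csv <- function(chain, tracks_path, truth_path) {
  tracks <- list(); truths <- list()
  for (rec in chain) {
    trajs <- if (rec$kind == "solo") list(rec$trajectory)
             else list(rec$pair$experienced, rec$pair$naive)
    for (tr in trajs) tracks[[length(tracks) + 1L]] <- as.data.frame(tr)
    tru <- rec$truth
    truths[[length(truths) + 1L]] <- data.frame(
      chain = rec$chain, generation = rec$generation, release = rec$release,
      step = seq_along(tru$explore_state),
      leader_state = if (is.null(tru$leader_state)) NA_character_
                     else tru$leader_state,
      explore_state = tru$explore_state)
  }
  utils::write.csv(do.call(rbind, tracks), tracks_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, truths), truth_path, row.names = FALSE)
  invisible(c(tracks_path, truth_path))
}

#' Event-level agreement between labelled phases and true bouts
#'
#' Matches contiguous labelled exploration phases against ground-truth
#' exploration bouts by temporal overlap and returns the event Jaccard
#' index: matched bouts divided by the union of true bouts and labelled
#' phases. Measures whether the labelling recovers the bouts the generator
#' actually produced.
#'
#' @param truth_state Logical per-sample ground-truth bout indicator.
#' @param labels An `infoflow_labels` data.frame on the same grid.
#' @return A list: `jaccard`, `n_true`, `n_labelled`, `n_matched_true`
#'   (true bouts with an overlapping labelled phase), `n_matched_labelled`
#'   (labelled phases with an overlapping true bout).
#' @export
bout_detection_jaccard <- function(truth_state, labels) {
  lab_ex <- !is.na(labels$label) & labels$label == "exploration"
  runs <- function(v) {
    r <- rle(v); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    cbind(s, e)[r$values, , drop = FALSE]
  }
  R1 <- runs(truth_state); R2 <- runs(as.logical(lab_ex))
  overlap <- function(a, R) any(R[, 1] <= a[2] & R[, 2] >= a[1])
  m1 <- if (nrow(R1) && nrow(R2)) sum(apply(R1, 1, overlap, R2)) else 0L
  m2 <- if (nrow(R1) && nrow(R2)) sum(apply(R2, 1, overlap, R1)) else 0L
  denom <- nrow(R1) + nrow(R2) - m2
  list(jaccard = if (denom > 0) m1 / denom else NA_real_,
       n_true = nrow(R1), n_labelled = nrow(R2),
       n_matched_true = m1, n_matched_labelled = m2)
}
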