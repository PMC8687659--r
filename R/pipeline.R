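#' Default analysis configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout: 0.2 s sampling period and history length 10 for the transfer
#' entropy estimator (the configuration that maximises total information
#' transfer), the 250 m pair-exclusion threshold, the 300 m exploration
#' threshold, and 5 m bins over [-50, 50] m for local TE against relative
#' position.
#'
#' @param period Sampling period in seconds (multiple of 0.2 in [0.2, 4]).
#' @param k History length in samples.
#' @param exclusion_m Mean-separation pair-exclusion threshold in metres.
#' @param threshold_m Exploration labelling threshold in metres.
#' @param baseline_model `"previous_release"` or
#'   `"last_of_previous_generation"`.
#' @param bins d_EN bin edges in metres for [local_te_by_distance()].
#' @param n_boot Bootstrap resamples for binned local TE CIs.
#' @param surrogate_within_release Restrict surrogate pairings to the same
#'   release index.
#' @return A validated list of class `infoflow_config`.
#' @export
analysis_config <- function(period = 0.2, k = 10L, exclusion_m = 250,
                            threshold_m = 300,
                            baseline_model = "previous_release",
                            bins = seq(-50, 50, 5), n_boot = 200L,
                            surrogate_within_release = TRUE) {
  step <- period / 0.2
  if (abs(step - round(step)) > 1e-8 || period < 0.2 - 1e-9 || period > 4 + 1e-9)
    stop("period must be a multiple of 0.2 s in [0.2, 4]")
  if (k < 1L) stop("k must be >= 1")
  structure(list(period = period, k = as.integer(k),
                 exclusion_m = exclusion_m, threshold_m = threshold_m,
                 baseline_model = baseline_model, bins = bins,
                 n_boot = as.integer(n_boot),
                 surrogate_within_release = surrogate_within_release),
            class = "infoflow_config")
}

#' Run the full analysis over a collection of chain flights
#'
#' Composes every stage of the analysis in order: pair filtering (mean
#' separation), per-flight transfer entropy in both directions, the
#' surrogate-pairing significance test, front/back leadership segmentation
#' with duration fits, exploration-exploitation labelling against baseline
#' routes, transition-initiation attribution, and Theil-Sen trends of net
#' predictive power over generations.
#'
#' @param chains A list of chains, each a list of flight records as
#'   produced by [simulate_transmission_chain()] (fields `kind`, `chain`,
#'   `generation`, `release`, `trajectory`/`pair`, `route`).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, tidy CSV/JSON outputs and
#'   a run manifest are written under it.
#' @return A list with `te` (per-flight TE rows), `surrogate_test`,
#'   `leadership` (shares + duration fits), `explore` (per-flight
#'   proportions, phase shares, initiation tests), `trends`, and `manifest`.
#' @export
run_full_analysis <- function(chains, config = analysis_config(),
                              out_dir = NULL) {
  records <- do.call(c, chains)
  is_pair <- vapply(records, function(r) r$kind == "pair", TRUE)
  pairs_all <- lapply(records[is_pair], function(r) r$pair)
  pairs <- filter_pairs(pairs_all, config$exclusion_m)

  te <- pair_te(pairs, config$period, config$k)
  surr <- build_surrogate_pairs(pairs, config$surrogate_within_release)
  surrogate_test <- if (length(surr) >= 3L) {
    te_surr <- pair_te(surr, config$period, config$k)
    compare_real_vs_surrogate(te, te_surr, "overall")
  } else NULL

  # leadership from d_EN
  seg_rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pf <- pairs[[i]]
    segs <- leadership_segments(projected_distance(pf), config$period)
    if (!nrow(segs)) return(NULL)
    cbind(flight = i, generation = pf$generation, release = pf$release, segs)
  }))
  props <- leadership_proportions(seg_rows, "generation")
  dur_E <- seg_rows$duration_s[seg_rows$leader == "E"]
  dur_N <- seg_rows$duration_s[seg_rows$leader == "N"]
  dur_fit <- if (length(c(dur_E, dur_N)) >= 30L)
    duration_distribution_fit(c(dur_E, dur_N),
                              durations_other = NULL) else NULL

  # exploration-exploitation per chain
  explore_rows <- list(); init_rows <- list()
  for (ch in chains) {
    meta <- data.frame(
      chain = vapply(ch, function(r) r$chain, ""),
      generation = vapply(ch, function(r) r$generation, 0L),
      release = vapply(ch, function(r) r$release, 0L))
    map <- select_baseline(meta, config$baseline_model)
    for (i in seq_along(ch)) {
      if (is.na(map$baseline_release[i])) next
      j <- which(meta$generation == map$baseline_generation[i] &
                   meta$release == map$baseline_release[i])
      if (!length(j)) next
      focal <- ch[[i]]$route; base <- ch[[j[1]]]$route
      dist <- distance_to_baseline(focal, base)
      labs <- label_segments(dist, config$threshold_m)
      prop <- exploration_proportion(labs)
      explore_rows[[length(explore_rows) + 1L]] <- data.frame(
        chain = meta$chain[i], generation = meta$generation[i],
        release = meta$release[i], kind = ch[[i]]$kind,
        exploration_prop = prop)
      if (ch[[i]]$kind == "pair") {
        den <- projected_distance(ch[[i]]$pair)
        ti <- transition_initiators(labs, den, "exploit_to_explore")
        if (nrow(ti))
          init_rows[[length(init_rows) + 1L]] <- cbind(
            chain = meta$chain[i], generation = meta$generation[i],
            release = meta$release[i], ti)
      }
    }
  }
  explore_df <- do.call(rbind, explore_rows)
  init_df <- do.call(rbind, init_rows)
  init_overall <- if (!is.null(init_df)) initiation_test(init_df$initiator) else NULL
  init_release1 <- if (!is.null(init_df))
    initiation_test(init_df$initiator[init_df$release == 1L]) else NULL

  # net predictive power trend over generations
  wide <- merge(te[te$direction == "EN", c("flight", "generation",
                                           "predictive_power_pct")],
                te[te$direction == "NE", c("flight", "predictive_power_pct")],
                by = "flight", suffixes = c("_EN", "_NE"))
  wide$net_pp <- wide$predictive_power_pct_EN - wide$predictive_power_pct_NE
  trend <- if (length(unique(wide$generation)) >= 3L)
    theil_sen(wide$generation, wide$net_pp) else NULL

  manifest <- list(
    n_flights = length(records), n_pairs_in = length(pairs_all),
    n_pairs_kept = length(pairs), n_surrogates = length(surr),
    config = unclass(config))

  out <- list(te = te, net_pp = wide, surrogate_test = surrogate_test,
              leadership = list(segments = seg_rows, proportions = props,
                                duration_fit = dur_fit),
              explore = list(per_flight = explore_df, initiations = init_df,
                             initiation_overall = init_overall,
                             initiation_release1 = init_release1),
              trend_net_pp = trend, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(te, file.path(out_dir, "te_per_flight.csv"), row.names = FALSE)
    if (!is.null(seg_rows))
      utils::write.csv(seg_rows, file.path(out_dir, "leadership_segments.csv"),
                       row.names = FALSE)
    if (!is.null(explore_df))
      utils::write.csv(explore_df, file.path(out_dir, "exploration_per_flight.csv"),
                       row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
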