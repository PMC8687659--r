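test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "infoflow_simconfig")
  expect_error(sim_config(w_couple = 0.6, alpha_attract = 0.3, beta_home = 0.2),
               "sum")
  expect_error(sim_config(tau = 0), "tau")
  expect_error(sim_config(n_steps = 5, tau = 10), "n_steps")
  expect_error(sim_config(dt = 0), "positive")
  expect_error(sim_config(q_switch = 1.2), "q_switch")
})

test_that("noise-free uncoupled birds fly straight at constant step length", {
  cfg <- sim_config(n_steps = 200, w_couple = 0, alpha_attract = 0,
                    beta_home = 0, sigma_heading = 0, q_switch = 0, seed = 1)
  sim <- simulate_pair_flight(cfg)
  for (tr in list(sim$pair$experienced, sim$pair$naive)) {
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_equal(steps, rep(20 * 0.2, 199), tolerance = 1e-9)
    # straight line: all motion collinear with the first step
    vx <- diff(tr$x); vy <- diff(tr$y)
    expect_lt(max(abs(vx[1] * vy - vy[1] * vx)), 1e-9)
  }
  # separation changes linearly (here: constant, parallel headings)
  sep <- pair_distance(sim$pair)
  expect_lt(max(abs(diff(sep, differences = 2))), 1e-9)
})

test_that("step length is speed*dt under noise and coupling too", {
  sim <- simulate_pair_flight(sim_config(n_steps = 500, seed = 8))
  for (tr in list(sim$pair$experienced, sim$pair$naive)) {
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_lt(max(abs(steps - 4)), 1e-9)
  }
})

test_that("leader run lengths are geometric with mean 1/q_switch", {
  cfg <- sim_config(n_steps = 50000, q_switch = 0.01, seed = 21)
  sim <- simulate_pair_flight(cfg)
  runs <- rle(sim$truth$leader_state)$lengths
  expect_lt(abs(mean(runs) - 100) / 100, 0.1)
  # run lengths are consistent with a geometric sample of the same size
  set.seed(1)
  ref <- rgeom(length(runs), 0.01) + 1
  expect_gt(suppressWarnings(ks.test(runs, ref)$p.value), 1e-3)
  expect_length(sim$truth$leader_state, 50000)
})

test_that("log-normal leadership mode produces log-normal run lengths", {
  cfg <- sim_config(n_steps = 60000, leader_mode = "lognormal",
                    leader_lognorm = c(meanlog = 4, sdlog = 1), seed = 5)
  sim <- simulate_pair_flight(cfg)
  runs <- rle(sim$truth$leader_state)$lengths * 0.2
  fit <- duration_distribution_fit(runs)
  expect_equal(fit$preferred, "lnorm")
  expect_lt(fit$lnorm$aic, fit$exp$aic)
})

test_that("coupling direction is recoverable by the TE estimator", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_pair_flight(sim_config(n_steps = 20000, w_couple = 0.9,
                                           tau = 1, alpha_attract = 0,
                                           beta_home = 0.05, q_switch = 0,
                                           seed = s))
    rA <- rotation_series(sim$pair$experienced)
    rB <- rotation_series(sim$pair$naive)
    transfer_entropy(rA, rB, 10)$te_bits > transfer_entropy(rB, rA, 10)$te_bits
  }, TRUE)
  expect_true(all(hits))
})

test_that("analytic channel matches its closed-form transfer entropy", {
  ch <- generate_binary_channel(1e5, 0, seed = 1)
  expect_lt(abs(transfer_entropy(ch$source, ch$target, 1)$te_bits - 1), 0.01)
  expect_error(generate_binary_channel(100, 0.7), "p_flip")
  # determinism: same seed, same symbols
  a <- generate_binary_channel(100, 0.2, seed = 9)
  b <- generate_binary_channel(100, 0.2, seed = 9)
  expect_identical(a$source$symbols, b$source$symbols)
  expect_identical(a$target$symbols, b$target$symbols)
})

test_that("transmission chain has the 12-release multi-generation structure", {
  cfg <- sim_config(n_steps = 60, seed = 2)
  ch <- simulate_transmission_chain(cfg, n_generations = 5, n_releases = 12)
  expect_length(ch, 60)  # 12 solo + 4 x 12 paired
  kinds <- vapply(ch, `[[`, "", "kind")
  gens <- vapply(ch, `[[`, 0L, "generation")
  expect_true(all(kinds[gens == 1L] == "solo"))
  expect_true(all(kinds[gens > 1L] == "pair"))
  expect_equal(as.integer(table(gens)), rep(12L, 5))
  # the experienced bird of generation g is the naive bird of g-1
  for (g in 2:5) {
    rec <- ch[[which(gens == g)[1]]]
    prev <- ch[[which(gens == g - 1L)[1]]]
    expect_equal(rec$experienced_id, prev$naive_id)
    expect_equal(rec$pair$experienced$bird_id, rec$experienced_id)
  }
  ch1 <- simulate_transmission_chain(cfg, n_generations = 1, n_releases = 12)
  expect_length(ch1, 12)
  expect_true(all(vapply(ch1, `[[`, "", "kind") == "solo"))
})

test_that("chain tracks round-trip through the CSV track format", {
  cfg <- sim_config(n_steps = 80, seed = 4)
  ch <- simulate_transmission_chain(cfg, n_generations = 2, n_releases = 2)
  tracks <- withr::local_tempfile(fileext = ".csv")
  truth <- withr::local_tempfile(fileext = ".csv")
  write_chain_csv(ch, tracks, truth)
  back <- read_flights(tracks)
  expect_length(back, 2 + 2 * 2)  # 2 solo + 2 paired flights x 2 birds
  orig <- ch[[1]]$trajectory
  match <- Filter(function(tr) tr$bird_id == orig$bird_id & tr$release == 1 &
                    tr$generation == 1, back)[[1]]
  expect_equal(match$x, orig$x, tolerance = 1e-9)
  tru <- utils::read.csv(truth)
  expect_true(all(c("leader_state", "explore_state", "step") %in% names(tru)))
})

test_that("naive birds explore more in early releases of a generation", {
  p16 <- c(); p712 <- c()
  for (sd in 1:3) {
    chain <- scenario_chain_colony(n_chains = 1, n_generations = 2,
                                   n_releases = 12, n_steps = 2000,
                                   seed = 100 + sd)[[1]]
    meta <- data.frame(
      chain = vapply(chain, `[[`, "", "chain"),
      generation = vapply(chain, `[[`, 0L, "generation"),
      release = vapply(chain, `[[`, 0L, "release"))
    map <- select_baseline(meta, "previous_release")
    for (i in seq_along(chain)) {
      if (is.na(map$baseline_release[i]) || meta$generation[i] < 2) next
      j <- which(meta$generation == map$baseline_generation[i] &
                   meta$release == map$baseline_release[i])
      labs <- label_segments(distance_to_baseline(chain[[i]]$route,
                                                  chain[[j]]$route))
      pr <- exploration_proportion(labs)
      if (meta$release[i] <= 6) p16 <- c(p16, pr) else p712 <- c(p712, pr)
    }
  }
  expect_gt(mean(p16), mean(p712))
})
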