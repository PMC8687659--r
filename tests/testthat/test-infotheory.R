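binary_entropy <- function(p) {
  p <- c(p, 1 - p); p <- p[p > 0]
  -sum(p * log2(p))
}

test_that("marginal entropy matches closed forms", {
  expect_equal(marginal_entropy(rep(0L, 50)), 0)
  expect_equal(marginal_entropy(rep(c(0L, 1L), 25)), 1)
  expect_equal(marginal_entropy(c(rep(0L, 25), rep(1L, 75))),
               binary_entropy(0.25), tolerance = 1e-12)
  expect_error(marginal_entropy(rep(NA_integer_, 5)), "empty")
})

test_that("conditional entropy vanishes for deterministic series and is ~1 for iid", {
  expect_equal(conditional_entropy(rep(c(0L, 1L), 100), k = 1), 0)
  # period-4 series 0011 repeated with k = 2: all four contexts deterministic
  expect_equal(conditional_entropy(rep(c(0L, 0L, 1L, 1L), 50), k = 2), 0)
  set.seed(9)
  s <- rbinom(50000, 1, 0.5)
  expect_lt(abs(conditional_entropy(s, 1) - 1), 1e-3)
  expect_error(conditional_entropy(rep(c(0L, 1L), 100), k = 0), "k")
})

test_that("transfer entropy recovers analytic channel values", {
  for (p in c(0, 0.1)) {
    ch <- generate_binary_channel(1e5, p, seed = 17)
    te <- transfer_entropy(ch$source, ch$target, k = 1)
    expect_lt(abs(te$te_bits - (1 - binary_entropy(p))), 0.01)
    # no information flows against the channel direction
    expect_lt(transfer_entropy(ch$target, ch$source, k = 1)$te_bits, 0.005)
  }
  ch <- generate_binary_channel(1e5, 0.5, seed = 17)
  expect_lt(transfer_entropy(ch$source, ch$target, k = 1)$te_bits, 0.001)
  expect_error(transfer_entropy(rep(0:1, 10), rep(0:1, 11), k = 1), "length")
})

test_that("TE respects its information-theoretic bounds and relabelling invariance", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 4000
    s <- rbinom(n, 1, 0.5)
    t <- as.integer(xor(c(0L, s[-n]), rbinom(n, 1, 0.3)))
    te <- transfer_entropy(s, t, k = 2)
    expect_gte(te$te_bits, 0)
    expect_lte(te$te_bits, te$h_cond_bits + 1e-12)
    expect_lte(te$h_cond_bits, 1 + 1e-12)
    expect_lte(te$te_bits, marginal_entropy(s) + 1e-12)
    # global 0<->1 relabelling of both series leaves TE unchanged
    te_flip <- transfer_entropy(1L - s, 1L - t, k = 2)
    expect_equal(te_flip$te_bits, te$te_bits, tolerance = 1e-12)
    expect_true(te$predictive_power_pct >= 0 && te$predictive_power_pct <= 100)
  }
})

test_that("local TE averages exactly to TE and is 1 bit on a perfect copy", {
  inputs <- list(
    generate_binary_channel(5000, 0.1, seed = 2),
    generate_binary_channel(5000, 0.4, seed = 3))
  for (ch in inputs) {
    for (k in c(1, 3)) {
      te <- transfer_entropy(ch$source, ch$target, k)
      lte <- local_transfer_entropy(ch$source, ch$target, k)
      expect_equal(mean(lte$values), te$te_bits, tolerance = 1e-9)
      expect_length(lte$values, te$n_transitions)
    }
  }
  # perfect copy: every counted value is 1 bit up to the plug-in estimate of
  # the 50/50 context frequencies
  copy <- generate_binary_channel(5000, 0, seed = 4)
  lte <- local_transfer_entropy(copy$source, copy$target, 1)
  expect_true(all(abs(lte$values - 1) < 0.05))
  expect_equal(mean(lte$values),
               transfer_entropy(copy$source, copy$target, 1)$te_bits,
               tolerance = 1e-12)
  # independent series: values near zero on average, both signs present
  set.seed(5)
  lte0 <- local_transfer_entropy(rbinom(5000, 1, 0.5), rbinom(5000, 1, 0.5), 1)
  expect_lt(abs(mean(lte0$values)), 0.01)
  expect_true(any(lte0$values > 0) && any(lte0$values < 0))
})

test_that("net predictive power is antisymmetric and zero for identical directions", {
  ch <- generate_binary_channel(20000, 0.2, seed = 6)
  en <- transfer_entropy(ch$source, ch$target, 1)
  ne <- transfer_entropy(ch$target, ch$source, 1)
  expect_equal(net_predictive_power(en, en), 0)
  expect_equal(net_predictive_power(en, ne), -net_predictive_power(ne, en))
  expect_gt(net_predictive_power(en, ne), 0)
  en2 <- transfer_entropy(ch$source, ch$target, 2)
  expect_error(net_predictive_power(en, en2), "settings")
})

test_that("parameter scan identifies the generating timescale", {
  pairs <- lapply(1:4, function(s)
    simulate_pair_flight(sim_config(n_steps = 4000, w_couple = 0.8, tau = 1,
                                    alpha_attract = 0, beta_home = 0.05,
                                    q_switch = 0, seed = s))$pair)
  sc <- parameter_scan(pairs, periods = c(0.2, 1, 2, 4), ks = c(2, 10))
  expect_equal(nrow(sc$grid), 8)
  expect_equal(sc$best$period, 0.2)
  expect_equal(sc$best$k, 10)
  # total TE decays towards zero as the period grows past the coupling lag
  g <- sc$grid[sc$grid$k == 10, ]
  expect_true(all(diff(g$mean_total_te[order(g$period)]) < 0))
  expect_lt(g$mean_total_te[g$period == 4], 0.1)
  sc1 <- parameter_scan(pairs[1], periods = c(0.2, 0.4), ks = 1)
  expect_equal(nrow(sc1$grid), 2)
  expect_error(parameter_scan(list()), "no pairs")
})

test_that("local TE by distance attributes information to the front bird", {
  pairs <- lapply(1:6, function(s)
    simulate_pair_flight(sim_config(n_steps = 4000, seed = s))$pair)
  res <- local_te_by_distance(pairs, k = 5, period = 0.2,
                              bins = seq(-40, 40, 10), n_boot = 30)
  expect_true(all(c("mean", "ci_lo", "ci_hi", "n") %in% names(res$by_bin)))
  expect_true(all(res$by_bin$ci_lo <= res$by_bin$mean + 1e-9))
  expect_true(all(res$by_bin$n > 0))
  # central bins populated in both directions, and dominance mostly positive
  dom <- res$dominance[abs(res$dominance$bin_mid) <= 20, ]
  expect_gt(nrow(dom), 0)
  expect_gt(mean(dom$front_minus_back > 0), 0.5)
  # one bin spanning everything reproduces the global mean local TE
  one <- local_te_by_distance(pairs[1], k = 5, bins = c(-1e6, 1e6), n_boot = 0)
  pf <- pairs[[1]]
  lte <- local_transfer_entropy(rotation_series(pf$experienced),
                                rotation_series(pf$naive), 5)
  d <- projected_distance(pf)$d_en
  manual <- mean(lte$values[!is.na(d[lte$idx + 1L])])
  expect_equal(one$by_bin$mean[one$by_bin$direction == "EN"], manual,
               tolerance = 1e-12)
})
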