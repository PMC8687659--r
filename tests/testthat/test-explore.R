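test_that("distance to baseline is the exact nearest-vertex distance", {
  f <- straight_traj(50)
  expect_equal(distance_to_baseline(f, f), rep(0, 50))
  # parallel track offset by 400 m
  f2 <- straight_traj(50, from = c(400, 0))
  expect_equal(distance_to_baseline(f2, f), rep(400, 50))
  # point equidistant from two baseline vertices: the common distance
  base <- trajectory(c(0, 1, 2), c(-10, 0, 10), c(0, 0, 0))
  focal <- trajectory(c(0, 1, 2), c(-5, -5, -5), c(3, 3, 3))
  expect_equal(distance_to_baseline(focal, base),
               rep(sqrt(5^2 + 3^2), 3))
  expect_error(distance_to_baseline(f, trajectory(1:3, rep(NA_real_, 3),
                                                  rep(NA_real_, 3))), "empty")
})

test_that("baseline mapping follows the previous-release and last-of-generation rules", {
  meta <- expand.grid(release = 1:12, generation = 1:5)
  meta$chain <- "C1"
  a <- select_baseline(meta, "previous_release")
  # within a generation: previous release
  r5 <- a[a$generation == 2 & a$release == 5, ]
  expect_equal(c(r5$baseline_generation, r5$baseline_release), c(2L, 4L))
  # generation boundary: last release of the previous generation
  g3r1 <- a[a$generation == 3 & a$release == 1, ]
  expect_equal(c(g3r1$baseline_generation, g3r1$baseline_release), c(2L, 12L))
  # the chain's very first flight has no baseline
  g1r1 <- a[a$generation == 1 & a$release == 1, ]
  expect_true(is.na(g1r1$baseline_release))

  b <- select_baseline(meta, "last_of_previous_generation")
  g3r7 <- b[b$generation == 3 & b$release == 7, ]
  expect_equal(c(g3r7$baseline_generation, g3r7$baseline_release), c(2L, 12L))
  # generation 1 falls back to the previous-release rule
  g1r4 <- b[b$generation == 1 & b$release == 4, ]
  expect_equal(c(g1r4$baseline_generation, g1r4$baseline_release), c(1L, 3L))
  # full-grid agreement with a literal restatement of the rules
  for (i in seq_len(nrow(meta))) {
    g <- meta$generation[i]; r <- meta$release[i]
    exp_a <- if (r > 1) c(g, r - 1) else if (g > 1) c(g - 1, 12) else c(NA, NA)
    exp_b <- if (g > 1) c(g - 1, 12) else exp_a
    expect_equal(c(a$baseline_generation[i], a$baseline_release[i]),
                 as.integer(exp_a))
    expect_equal(c(b$baseline_generation[i], b$baseline_release[i]),
                 as.integer(exp_b))
  }
})

test_that("labelling splits at the 300 m threshold with equality as exploitation", {
  labs <- label_segments(c(100, 350, 350, 100))
  expect_equal(labs$label, c("exploitation", "exploration", "exploration",
                             "exploitation"))
  expect_equal(length(unique(labs$phase)), 3)
  expect_equal(label_segments(c(250, 300, 301))$label,
               c("exploitation", "exploitation", "exploration"))
  expect_equal(exploration_proportion(label_segments(rep(0, 100))), 0)
  expect_equal(exploration_proportion(label_segments(rep(400, 100))), 1)
  expect_equal(exploration_proportion(label_segments(c(rep(400, 30), rep(0, 70)))),
               0.3)
  expect_equal(exploration_proportion(label_segments(rep(400, 10), Inf)), 0)
})

test_that("exploration proportion is monotone non-increasing in the threshold", {
  set.seed(31)
  for (rep in 1:5) {
    dist <- abs(cumsum(rnorm(500, 0, 30)))
    props <- vapply(c(50, 100, 200, 300, 500),
                    function(th) exploration_proportion(label_segments(dist, th)), 0)
    expect_true(all(diff(props) <= 0))
  }
})

test_that("labels are invariant under rigid motions applied to focal and baseline", {
  f <- rw_traj(120, seed = 4); b <- rw_traj(120, seed = 5)
  rot <- function(tr, th, dx, dy) {
    trajectory(tr$t, cos(th) * tr$x - sin(th) * tr$y + dx,
               sin(th) * tr$x + cos(th) * tr$y + dy)
  }
  l0 <- label_segments(distance_to_baseline(f, b), 150)
  l1 <- label_segments(distance_to_baseline(rot(f, 0.7, 500, -200),
                                            rot(b, 0.7, 500, -200)), 150)
  expect_equal(l0$label, l1$label)
})

test_that("phase leadership shares are conditional on the phase type", {
  labs <- label_segments(c(rep(0, 50), rep(400, 50)))
  d <- c(rep(2, 50), rep(-2, 25), rep(2, 25))
  sh <- phase_leadership_share(labs, d)
  expl <- sh[sh$label == "exploration", ]
  expt <- sh[sh$label == "exploitation", ]
  expect_equal(expt$share_E, 1)
  expect_equal(expl$share_E, 0.5)
  expect_equal(sh$share_E + sh$share_N, rep(1, 2))
  # a phase type absent from the flight yields NA shares, not zero
  sh2 <- phase_leadership_share(label_segments(rep(0, 100)), rep(2, 100))
  expect_true(is.na(sh2$share_E[sh2$label == "exploration"]))
})

test_that("transition initiators are the front bird at phase onset", {
  # one exploit->explore transition with E in front at onset
  labs <- label_segments(c(rep(0, 10), rep(400, 10)))
  ti <- transition_initiators(labs, c(rep(-1, 10), rep(3, 10)),
                              "exploit_to_explore")
  expect_equal(nrow(ti), 1)
  expect_equal(ti$initiator, "E")
  expect_equal(ti$index, 11)
  # masked/zero d_EN at onset falls back to the nearest preceding valid sample
  ti2 <- transition_initiators(labs, c(rep(-1, 10), 0, NA, rep(3, 8)),
                               "exploit_to_explore")
  expect_equal(ti2$initiator, "N")
  # the reverse direction finds nothing here
  expect_equal(nrow(transition_initiators(labs, rep(1, 20),
                                          "explore_to_exploit")), 0)
  # explore->exploit on the mirrored series
  labs2 <- label_segments(c(rep(400, 10), rep(0, 10)))
  ti3 <- transition_initiators(labs2, rep(1, 20), "explore_to_exploit")
  expect_equal(ti3$initiator, "E")
})

test_that("the exact binomial initiation test matches its closed form", {
  expect_equal(initiation_test(c(rep("N", 10), rep("E", 10)))$p, 1)
  # 31 of 44 naive-initiated transitions: significantly asymmetric
  res <- initiation_test(c(rep("N", 31), rep("E", 13)))
  expect_equal(res$n, 44L)
  expect_equal(res$prop_naive, 31 / 44)
  expect_equal(res$p, stats::binom.test(31, 44, 0.5)$p.value)
  expect_lt(res$p, 0.01)
  expect_equal(initiation_test(character(0))$n, 0L)
})

test_that("labelled phases recover ground-truth bouts on a synthetic chain", {
  chain <- scenario_chain_colony(n_chains = 1, n_generations = 2,
                                 n_releases = 6, n_steps = 2000, seed = 77)[[1]]
  meta <- data.frame(
    chain = vapply(chain, `[[`, "", "chain"),
    generation = vapply(chain, `[[`, 0L, "generation"),
    release = vapply(chain, `[[`, 0L, "release"))
  map <- select_baseline(meta, "previous_release")
  agg <- c(n_true = 0, n_lab = 0, m_true = 0, m_lab = 0)
  for (i in seq_along(chain)) {
    if (is.na(map$baseline_release[i])) next
    j <- which(meta$generation == map$baseline_generation[i] &
                 meta$release == map$baseline_release[i])
    labs <- label_segments(distance_to_baseline(chain[[i]]$route,
                                                chain[[j]]$route))
    jc <- bout_detection_jaccard(chain[[i]]$truth$explore_state, labs)
    agg <- agg + c(jc$n_true, jc$n_labelled, jc$n_matched_true,
                   jc$n_matched_labelled)
  }
  expect_gt(agg[["n_true"]], 5)
  jac <- agg[["m_true"]] / (agg[["n_true"]] + agg[["n_lab"]] - agg[["m_lab"]])
  expect_gt(jac, 0.7)
})
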