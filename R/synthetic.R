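#' Configuration for the paired-flight simulator
#'
#' Builds and validates the parameter set of the correlated-random-walk
#' generator. Two birds fly at constant speed on a plane; at every step each
#' bird's new heading is a convex blend of unit vectors — its previous
#' heading, a steering target (home, a preferred corridor, or an exploration
#' waypoint), the partner's heading `tau` steps earlier, and the bearing to
#' the partner when separation exceeds the cohesion radius — normalised and
#' then perturbed by wrapped-Gaussian noise. A latent leader steers towards
#' the goal; the follower couples to the leader. Leadership alternates.
#'
#' Defaults emulate the field conditions of a homing release: 5 Hz sampling
#' (`dt = 0.2`), a conventional pigeon ground speed of 20 m/s, ~8.7 min
#' flights (`n_steps = 2600`), and a ~9 km beeline from release to home.
#'
#' @param dt Seconds per step.
#' @param speed Ground speed in metres/second.
#' @param n_steps Number of positions per flight.
#' @param w_couple Weight in [0,1] on the partner's lagged heading
#'   (the information channel the TE estimator should detect).
#' @param tau Coupling delay in steps (>= 1).
#' @param alpha_attract Weight in [0,1] on the bearing to the partner,
#'   active when separation exceeds `r_coh`.
#' @param r_coh Cohesion radius in metres.
#' @param beta_home Weight in [0,1] on the bearing to the steering target.
#' @param sigma_heading Heading noise SD in radians per step.
#' @param q_switch Per-step probability that leadership flips
#'   (Markov switching; geometric run lengths with mean `1/q_switch`).
#' @param leader_mode `"markov"` (default) or `"lognormal"`, which draws
#'   leadership run lengths from a log-normal distribution instead.
#' @param leader_lognorm `c(meanlog, sdlog)` of run lengths in steps for
#'   `leader_mode = "lognormal"`.
#' @param p_explore Per-step probability that the current leader starts an
#'   exploration bout (when not already in one).
#' @param explore_len Mean dwell time in steps spent near the waypoint once
#'   reached (geometric); a bout flies out to its waypoint, dwells, then
#'   resumes goal-directed flight.
#' @param beta_explore Steering weight towards the waypoint during a bout
#'   (replaces `beta_home`); stronger than the home bias so bouts actually
#'   depart from the corridor.
#' @param explore_band `c(min, max)` lateral offset in metres of exploration
#'   waypoints from the release-home beeline; the default 300-1000 m band
#'   guarantees bouts cross the 300 m exploration-labelling threshold.
#' @param home,release Planar `c(x, y)` coordinates in metres.
#' @param start_sep Initial separation of the two birds in metres.
#' @param corridor Optional two-column matrix of route points the leader
#'   follows in place of the direct home bearing (an inherited idiosyncratic
#'   route); the bearing target is the first corridor point further than the
#'   lookahead distance ahead of the bird, falling back to home past the end.
#' @param seed Integer seed; every stochastic draw of one flight flows from
#'   this single per-flight generator.
#' @return A validated list of class `infoflow_simconfig`.
#' @export
sim_config <- function(dt = 0.2, speed = 20, n_steps = 2600,
                       w_couple = 0.6, tau = 1L, alpha_attract = 0.2,
                       r_coh = 10, beta_home = 0.1, sigma_heading = 0.3,
                       q_switch = 0.005, leader_mode = c("markov", "lognormal"),
                       leader_lognorm = c(meanlog = 4, sdlog = 1),
                       p_explore = 0, explore_len = 150, beta_explore = 0.35,
                       explore_band = c(300, 1000),
                       home = c(0, 9000), release = c(0, 0),
                       start_sep = 4, corridor = NULL, seed = 1L) {
  leader_mode <- match.arg(leader_mode)
  cfg <- list(dt = dt, speed = speed, n_steps = as.integer(n_steps),
              w_couple = w_couple, tau = as.integer(tau),
              alpha_attract = alpha_attract, r_coh = r_coh,
              beta_home = beta_home, sigma_heading = sigma_heading,
              q_switch = q_switch, leader_mode = leader_mode,
              leader_lognorm = leader_lognorm, p_explore = p_explore,
              explore_len = explore_len, beta_explore = beta_explore,
              explore_band = explore_band,
              home = home, release = release, start_sep = start_sep,
              corridor = corridor, seed = as.integer(seed))
  if (dt <= 0 || speed <= 0) stop("dt and speed must be positive")
  if (cfg$tau < 1L) stop("tau must be >= 1")
  if (cfg$n_steps <= cfg$tau) stop("n_steps must exceed tau")
  w <- c(w_couple, alpha_attract, beta_home)
  if (any(w < 0) || any(w > 1) || sum(w) > 1 + 1e-12)
    stop("w_couple, alpha_attract and beta_home must be in [0,1] and sum to at most 1")
  if (q_switch < 0 || q_switch > 1) stop("q_switch must be in [0,1]")
  class(cfg) <- "infoflow_simconfig"
  cfg
}

unit <- function(v) {
  n <- sqrt(v[1]^2 + v[2]^2)
  if (n < 1e-12) c(1, 0) else v / n
}

# Latent leadership symbol stream: geometric (Markov) or log-normal runs.
draw_leader_state <- function(cfg) {
  n <- cfg$n_steps
  if (cfg$leader_mode == "markov") {
    flips <- stats::runif(n) < cfg$q_switch
    flips[1] <- FALSE
    ifelse(cumsum(flips) %% 2L == 0L, "A", "B")
  } else {
    out <- character(0); who <- "A"
    while (length(out) < n) {
      len <- max(1L, round(stats::rlnorm(1, cfg$leader_lognorm[[1]],
                                         cfg$leader_lognorm[[2]])))
      out <- c(out, rep(who, len))
      who <- if (who == "A") "B" else "A"
    }
    out[seq_len(n)]
  }
}

# Waypoint on a lateral band off the release-home beeline, placed slightly
# ahead of the bird's current beeline progress. When a corridor (the route
# the labelling baseline will be) is inherited, draws are rejected until the
# waypoint also lies at least the band minimum from every corridor vertex,
# so a completed bout is guaranteed to depart from the baseline route, not
# merely from the beeline.
draw_waypoint <- function(cfg, pos, corr = NULL) {
  along_hat <- unit(cfg$home - cfg$release)
  perp_hat <- c(-along_hat[2], along_hat[1])
  L <- sqrt(sum((cfg$home - cfg$release)^2))
  prog <- sum((pos - cfg$release) * along_hat)
  for (try in 1:20) {
    a <- min(prog + stats::runif(1, 200, 800), 0.95 * L)
    o <- stats::runif(1, cfg$explore_band[1], cfg$explore_band[2]) *
      sample(c(-1, 1), 1)
    wp <- cfg$release + a * along_hat + o * perp_hat
    if (is.null(corr)) return(wp)
    gap <- min(sqrt((corr[, 1] - wp[1])^2 + (corr[, 2] - wp[2])^2))
    if (gap >= cfg$explore_band[1]) return(wp)
  }
  wp
}

# Exploration bout state machine: fly out to the waypoint, dwell near it for
# a geometric number of steps, then resume goal-directed flight. A hard age
# cap guards against unreachable waypoints.
bout_begin <- function(cfg, pos, corr = NULL) {
  list(waypoint = draw_waypoint(cfg, pos, corr), phase = "out",
       dwell = 1L + stats::rgeom(1L, 1 / cfg$explore_len), age = 0L)
}

# Bouts only start before most of the beeline has been covered: flights
# converge on the loft, where departures are neither realistic nor
# completable before arrival.
bout_can_start <- function(cfg, pos) {
  along_hat <- unit(cfg$home - cfg$release)
  L <- sqrt(sum((cfg$home - cfg$release)^2))
  sum((pos - cfg$release) * along_hat) < 0.85 * L
}
bout_advance <- function(bout, pos) {
  bout$age <- bout$age + 1L
  if (bout$phase == "out" && sum((bout$waypoint - pos)^2) < 75^2)
    bout$phase <- "dwell"
  if (bout$phase == "dwell") bout$dwell <- bout$dwell - 1L
  if ((bout$phase == "dwell" && bout$dwell <= 0L) || bout$age > 1500L)
    return(NULL)
  bout
}

# Follow an inherited route: keep a monotone pointer at the nearest corridor
# vertex and steer at a fixed lookahead beyond it; past the end, steer home.
corridor_target <- function(corr, cptr, p, ahead_pts, home) {
  n <- nrow(corr)
  while (cptr < n &&
         sum((corr[cptr + 1L, ] - p)^2) <= sum((corr[cptr, ] - p)^2))
    cptr <- cptr + 1L
  target <- if (cptr + ahead_pts > n) home else corr[cptr + ahead_pts, ]
  list(target = target, cptr = cptr)
}

#' Simulate one paired flight with known ground truth
#'
#' Runs the correlated-random-walk model of [sim_config()] and returns the
#' pair of trajectories together with the latent per-step leader identity
#' and exploration state, so downstream estimators can be validated against
#' a known coupling structure. Bird A takes the experienced role, bird B the
#' naive one.
#'
#' @param cfg A [sim_config()].
#' @param bird_ids Character ids for birds A (experienced role) and B.
#' @param chain_id,generation,release Metadata stamped on the trajectories.
#' @param p_explore_by_leader Optional named vector `c(A = , B = )` of
#'   per-step bout-start probabilities overriding `cfg$p_explore` depending
#'   on which bird currently leads (used to give naive birds elevated
#'   exploration drive).
#' @return A list with `pair` (an aligned [pair_flight()]) and `truth`
#'   (`leader_state`, `explore_state`, `w_couple`, `tau`).
#' @export
simulate_pair_flight <- function(cfg, bird_ids = c("A", "B"),
                                 chain_id = "sim", generation = 2L,
                                 release = 1L, p_explore_by_leader = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_steps; tau <- cfg$tau
  leader <- draw_leader_state(cfg)
  noise <- matrix(stats::rnorm(2L * n, 0, cfg$sigma_heading), n, 2L)
  u_start <- stats::runif(n)  # bout-start draws
  pex <- if (is.null(p_explore_by_leader))
    c(A = cfg$p_explore, B = cfg$p_explore) else p_explore_by_leader

  h0 <- unit(cfg$home - cfg$release)
  perp <- c(-h0[2], h0[1])
  pos <- array(NA_real_, c(n, 2L, 2L))  # step x (x,y) x bird(A,B)
  pos[1, , 1L] <- cfg$release - perp * cfg$start_sep / 2
  pos[1, , 2L] <- cfg$release + perp * cfg$start_sep / 2
  hx <- matrix(NA_real_, n, 2L); hy <- matrix(NA_real_, n, 2L)
  hx[1, ] <- h0[1]; hy[1, ] <- h0[2]

  corr <- cfg$corridor; cptr <- 1L
  step_len <- cfg$speed * cfg$dt
  ahead_pts <- as.integer(ceiling(150 / step_len))
  bout <- NULL
  explore <- logical(n)
  w_prev_f <- 1 - cfg$w_couple - cfg$alpha_attract

  for (i in 2:n) {
    ld <- if (leader[i] == "A") 1L else 2L
    fw <- 3L - ld
    p_ld <- pos[i - 1L, , ld]; p_fw <- pos[i - 1L, , fw]

    # exploration bout bookkeeping (leader-driven)
    if (is.null(bout) && u_start[i] < pex[[leader[i]]] &&
        bout_can_start(cfg, p_ld))
      bout <- bout_begin(cfg, p_ld, corr)
    if (!is.null(bout)) {
      explore[i] <- TRUE
      bout <- bout_advance(bout, p_ld)
    }

    # leader steering target: waypoint > corridor > home
    if (!is.null(bout)) {
      target <- bout$waypoint; beta <- cfg$beta_explore
    } else {
      beta <- cfg$beta_home
      if (!is.null(corr)) {
        ct <- corridor_target(corr, cptr, p_ld, ahead_pts, cfg$home)
        target <- ct$target; cptr <- ct$cptr
      } else target <- cfg$home
    }

    u_prev_ld <- c(hx[i - 1L, ld], hy[i - 1L, ld])
    v <- (1 - beta) * u_prev_ld + beta * unit(target - p_ld)
    u <- unit(v); th <- noise[i, ld]
    cs <- cos(th); sn <- sin(th)
    u_ld <- c(u[1] * cs - u[2] * sn, u[1] * sn + u[2] * cs)

    j <- max(i - tau, 1L)
    u_lag <- c(hx[j, ld], hy[j, ld])  # partner-of-follower = leader, lagged
    sep2 <- sum((p_ld - p_fw)^2)
    u_prev_fw <- c(hx[i - 1L, fw], hy[i - 1L, fw])
    if (sep2 > cfg$r_coh^2) {
      v <- w_prev_f * u_prev_fw + cfg$w_couple * u_lag +
        cfg$alpha_attract * unit(p_ld - p_fw)
    } else {
      v <- (w_prev_f + cfg$alpha_attract) * u_prev_fw + cfg$w_couple * u_lag
    }
    u <- unit(v); th <- noise[i, fw]
    cs <- cos(th); sn <- sin(th)
    u_fw <- c(u[1] * cs - u[2] * sn, u[1] * sn + u[2] * cs)

    hx[i, ld] <- u_ld[1]; hy[i, ld] <- u_ld[2]
    hx[i, fw] <- u_fw[1]; hy[i, fw] <- u_fw[2]
    pos[i, , ld] <- p_ld + step_len * u_ld
    pos[i, , fw] <- p_fw + step_len * u_fw
  }

  tgrid <- (seq_len(n) - 1) * cfg$dt
  trA <- trajectory(tgrid, pos[, 1L, 1L], pos[, 2L, 1L], bird_ids[1],
                    chain_id, generation, release)
  trB <- trajectory(tgrid, pos[, 1L, 2L], pos[, 2L, 2L], bird_ids[2],
                    chain_id, generation, release)
  list(pair = pair_flight(trA, trB),
       truth = list(leader_state = leader, explore_state = explore,
                    w_couple = cfg$w_couple, tau = cfg$tau))
}

#' Simulate one solo flight
#'
#' A single bird following the leader dynamics of [simulate_pair_flight()]
#' (previous heading, steering target, noise) with no partner terms. Used
#' for generation-1 training flights of a transmission chain.
#'
#' @inheritParams simulate_pair_flight
#' @param bird_id Bird identifier.
#' @param p_explore_override Optional per-step bout-start probability.
#' @return A list with `trajectory` and `truth` (`explore_state`).
#' @export
simulate_solo_flight <- function(cfg, bird_id = "A", chain_id = "sim",
                                 generation = 1L, release = 1L,
                                 p_explore_override = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_steps
  noise <- stats::rnorm(n, 0, cfg$sigma_heading)
  u_start <- stats::runif(n)
  pex <- if (is.null(p_explore_override)) cfg$p_explore else p_explore_override
  pos <- matrix(NA_real_, n, 2L)
  pos[1, ] <- cfg$release
  h <- unit(cfg$home - cfg$release)
  corr <- cfg$corridor; cptr <- 1L
  step_len <- cfg$speed * cfg$dt
  ahead_pts <- as.integer(ceiling(150 / step_len))
  bout <- NULL
  explore <- logical(n)
  for (i in 2:n) {
    p <- pos[i - 1L, ]
    if (is.null(bout) && u_start[i] < pex && bout_can_start(cfg, p))
      bout <- bout_begin(cfg, p, corr)
    if (!is.null(bout)) {
      explore[i] <- TRUE
      bout <- bout_advance(bout, p)
    }
    if (!is.null(bout)) {
      target <- bout$waypoint; beta <- cfg$beta_explore
    } else {
      beta <- cfg$beta_home
      if (!is.null(corr)) {
        ct <- corridor_target(corr, cptr, p, ahead_pts, cfg$home)
        target <- ct$target; cptr <- ct$cptr
      } else target <- cfg$home
    }
    v <- (1 - beta) * h + beta * unit(target - p)
    u <- unit(v); th <- noise[i]
    h <- c(u[1] * cos(th) - u[2] * sin(th), u[1] * sin(th) + u[2] * cos(th))
    pos[i, ] <- p + step_len * h
  }
  tr <- trajectory((seq_len(n) - 1) * cfg$dt, pos[, 1], pos[, 2], bird_id,
                   chain_id, generation, release)
  list(trajectory = tr, truth = list(explore_state = explore))
}

#' Simulate a full transmission-chain experiment
#'
#' Emulates the multi-generation release design: generation 1 is 12 solo
#' training flights of the founding bird; each later generation pairs the
#' previous generation's naive bird (now experienced, inheriting its last
#' route as a preferred corridor) with a newly introduced naive bird. Naive
#' birds carry an elevated exploration drive that decays over the releases
#' of their first generation, so early releases of each paired generation
#' explore more than late ones.
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the whole chain, each
#'   flight drawing its own sub-seed from it.
#' @param n_generations Number of generations (>= 1).
#' @param n_releases Releases per generation (>= 2).
#' @param chain_id Chain identifier.
#' @param explore_boost,explore_decay Naive bird's bout-start probability is
#'   `p_explore * (1 + explore_boost * exp(-(release - 1) / explore_decay))`.
#' @return A list of flight records; each has `kind` (`"solo"`/`"pair"`),
#'   `generation`, `release`, `chain`, the flight (`trajectory` or `pair`),
#'   `truth`, and the route actually flown (`route`, the solo track or pair
#'   mean) used as the next flight's corridor.
#' @export
simulate_transmission_chain <- function(cfg, n_generations = 5L,
                                        n_releases = 12L, chain_id = "C1",
                                        explore_boost = 8, explore_decay = 2) {
  stopifnot(n_generations >= 1L, n_releases >= 2L)
  set.seed(cfg$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_generations * n_releases),
                  n_generations, n_releases)
  birds <- paste0(chain_id, "_G", seq_len(n_generations))
  out <- vector("list", 0L)
  corridor <- NULL
  for (g in seq_len(n_generations)) {
    for (r in seq_len(n_releases)) {
      p_naive <- cfg$p_explore * (1 + explore_boost * exp(-(r - 1) / explore_decay))
      fcfg <- cfg
      fcfg$seed <- seeds[g, r]
      fcfg$corridor <- corridor
      class(fcfg) <- "infoflow_simconfig"
      if (g == 1L) {
        fl <- simulate_solo_flight(fcfg, birds[1L], chain_id, 1L, r,
                                   p_explore_override = p_naive)
        route <- fl$trajectory
        rec <- list(kind = "solo", chain = chain_id, generation = 1L,
                    release = r, naive_id = birds[1L], experienced_id = NA,
                    trajectory = fl$trajectory, truth = fl$truth,
                    route = route)
      } else {
        fl <- simulate_pair_flight(
          fcfg, bird_ids = c(birds[g - 1L], birds[g]), chain_id = chain_id,
          generation = g, release = r,
          p_explore_by_leader = c(A = cfg$p_explore, B = p_naive))
        route <- mean_pair_trajectory(fl$pair)
        rec <- list(kind = "pair", chain = chain_id, generation = g,
                    release = r, naive_id = birds[g],
                    experienced_id = birds[g - 1L],
                    pair = fl$pair, truth = fl$truth, route = route)
      }
      out[[length(out) + 1L]] <- rec
      corridor <- cbind(route$x, route$y)
    }
  }
  out
}

#' Analytic binary channel with known transfer entropy
#'
#' Source symbols are i.i.d. fair coin flips; the target copies the source
#' with one step of delay, flipping each copied symbol with probability
#' `p_flip`. The true transfer entropy source->target at history length 1 is
#' `1 + p log2 p + (1-p) log2(1-p)` bits (1 bit for a perfect copy, 0 at
#' p = 0.5); target->source is 0. Used to validate the plug-in estimator
#' against closed forms.
#'
#' @param n Series length.
#' @param p_flip Flip probability in [0, 0.5].
#' @param seed Integer seed.
#' @return A list with `source` and `target` rotation series.
#' @export
generate_binary_channel <- function(n, p_flip, seed = 1L) {
  if (p_flip < 0 || p_flip > 0.5) stop("p_flip must lie in [0, 0.5]")
  set.seed(seed)
  src <- stats::rbinom(n, 1L, 0.5)
  flip <- stats::rbinom(n, 1L, p_flip)
  tgt <- c(stats::rbinom(1L, 1L, 0.5),
           (src[-n] + flip[-1L]) %% 2L)
  list(source = rotation_series_obj(src, 0.2, bird_id = "source"),
       target = rotation_series_obj(tgt, 0.2, bird_id = "target"))
}
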