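# Small geometric fixtures built in code.

# trajectory along a straight line from `from` towards unit direction `dir`
straight_traj <- function(n = 10, from = c(0, 0), dir = c(0, 1),
                          step = 4, dt = 0.2, ...) {
  s <- (seq_len(n) - 1) * step
  trajectory((seq_len(n) - 1) * dt, from[1] + s * dir[1], from[2] + s * dir[2], ...)
}

# trajectory on a circle; ccw = TRUE runs counterclockwise
circle_traj <- function(n = 20, r = 100, ccw = TRUE, dt = 0.2, ...) {
  th <- (seq_len(n) - 1) * 0.1 * (if (ccw) 1 else -1)
  trajectory((seq_len(n) - 1) * dt, r * cos(th), r * sin(th), ...)
}

# aligned pair moving along +x with E at a fixed lead over N
offset_pair <- function(n = 10, lead = 1, dir = c(1, 0), step = 4) {
  tgrid <- (seq_len(n) - 1) * 0.2
  s <- (seq_len(n) - 1) * step
  E <- trajectory(tgrid, lead * dir[1] + s * dir[1], lead * dir[2] + s * dir[2],
                  bird_id = "E1")
  N <- trajectory(tgrid, s * dir[1], s * dir[2], bird_id = "N1")
  pair_flight(E, N)
}

# random-walk trajectory for property tests
rw_traj <- function(n = 200, seed = 1, dt = 0.2) {
  set.seed(seed)
  th <- cumsum(rnorm(n, 0, 0.4))
  trajectory((seq_len(n) - 1) * dt, cumsum(cos(th)) * 4, cumsum(sin(th)) * 4)
}
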