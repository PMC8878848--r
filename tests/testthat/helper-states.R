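# shared constructors for small synthetic states used across tests

# single-particle-copy snapshot with copies at given positions (site at origin)
snap_with_copies <- function(copy_positions, site = c(0, 0, 0)) {
  pos <- rbind(matrix(site, 1, 3), as.matrix(copy_positions))
  n <- nrow(pos)
  snapshot(system_state(pos, matrix(0, n, 3), rep(1, n),
                        copy_id = 0:(n - 1L)))
}

# a random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_motion <- function(coords, R = random_rotation(), t = stats::rnorm(3)) {
  sweep(coords %*% t(R), 2, t, `+`)
}

# exhaustive transition enumeration: independent oracle for count_transitions
count_oracle <- function(segments, n_states, lag) {
  C <- matrix(0, n_states, n_states)
  for (s in segments) {
    if (length(s) <= lag) next
    for (t in seq_len(length(s) - lag))
      C[s[t], s[t + lag]] <- C[s[t], s[t + lag]] + 1
  }
  C
}
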