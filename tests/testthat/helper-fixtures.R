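# Build a trajectory object from explicit event data, for hand-computed
# burst/dwell/occupancy fixtures.
make_traj <- function(times, states, counts, kinds, t_end,
                      initial_state = 0L, initial_count = 0L, seed = NA) {
  telegraph:::new_trajectory(
    list(times = times, states = as.integer(states),
         counts = as.integer(counts),
         kinds = match(kinds, c("synthesis", "removal", "switch"))),
    seed = seed, t_end = t_end,
    initial_state = initial_state, initial_count = initial_count,
    params = NULL)
}

# Direct sparse solve of the truncated stationary master equation for
# the state-resolved probabilities (alpha_n, beta_n); the independent
# oracle for the exact pmf.  Synthesis out of the top count state is
# dropped (reflecting truncation), so the solve is exact for the
# truncated chain.
solve_master_equation <- function(rates, n_max) {
  k <- rates$k; f <- rates$f; h <- rates$h; rho <- rates$rho
  nn <- n_max + 1
  idx <- function(state, n) state * nn + n + 1   # state 0 = OFF, 1 = ON
  triplets <- list()
  add <- function(i, j, v) triplets[[length(triplets) + 1]] <<- c(i, j, v)
  for (n in 0:n_max) {
    for (state in 0:1) {
      i <- idx(state, n)
      out <- rho * n + (if (state == 1) h else f) +
        (if (state == 1 && n < n_max) k else 0)
      add(i, i, -out)
      if (n > 0 && state == 1) add(idx(1, n), idx(1, n - 1), k)
      if (n < n_max) add(idx(state, n), idx(state, n + 1), rho * (n + 1))
      add(idx(state, n), idx(1 - state, n), if (state == 1) f else h)
    }
  }
  tr <- do.call(rbind, triplets)
  A <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(2 * nn, 2 * nn))
  # replace the last balance row with the normalization constraint
  A[2 * nn, ] <- 1
  b <- c(numeric(2 * nn - 1), 1)
  x <- as.numeric(Matrix::solve(A, b))
  list(beta = x[1:nn], alpha = x[(nn + 1):(2 * nn)])
}
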