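# Shared fixtures built in code.

# A propagator that replays a fixed table of progress coordinates: the
# state holds a row index that advances by one per iteration, so scripted
# trajectories exercise the real engine bookkeeping (labels, arrivals,
# lineage) without stochastic dynamics.
replay_propagator <- function(table) {
  table <- as.matrix(table)
  we_propagator(
    step = function(states, n_steps, seed, ids, iteration) {
      matrix(pmin(states[, 1] + 1, nrow(table)), ncol = 1)
    },
    pcoord = function(states) table[states[, 1], , drop = FALSE],
    dim = 1L, pdim = ncol(table), name = "replay")
}

# run a scripted single-walker (or few-walker) trajectory through run_we;
# rows of `table` are pcoords, row 1 is the initial configuration
run_scripted <- function(table, n_walkers = 1L, defs = state_defs(),
                         tau = 1) {
  prop <- replay_propagator(table)
  one_bin <- bin_scheme_1d(c(0), stage = "script")
  init <- matrix(rep(1, n_walkers), ncol = 1)
  run_we(prop, init, n_iter = nrow(table) - 1L, tau_steps = 1L, tau = tau,
         scheme = one_bin,
         policy = we_policy("per_bin_target", target = n_walkers),
         defs = defs, seed = 1)
}

# small deterministic point cloud for clustering tests
cloud2d <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(2 * n), ncol = 2)
}
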