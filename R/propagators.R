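#' Propagator objects for the WE engine
#'
#' A propagator bundles a stochastic dynamics kernel with its progress
#' coordinate.  The engine is agnostic to the dynamics: it only requires
#' `step(states, n_steps, seed, ids, iteration)` returning a state matrix
#' and `pcoord(states)` returning a numeric matrix (one row per walker).
#' Propagation must be stochastic and reproducible from the stream key; the
#' engine never relies on walker order.
#'
#' @param step function `(states, n_steps, seed, ids, iteration) -> states`.
#' @param pcoord function `states -> matrix` of progress coordinates.
#' @param dim state dimension (columns of the state matrix).
#' @param pdim progress-coordinate dimension.
#' @param name descriptive label.
#' @return An object of class `we_propagator`.
#' @export
we_propagator <- function(step, pcoord, dim, pdim, name = "custom") {
  stopifnot(is.function(step), is.function(pcoord))
  structure(list(step = step, pcoord = pcoord, dim = dim, pdim = pdim,
                 name = name),
            class = "we_propagator")
}

#' @export
print.we_propagator <- function(x, ...) {
  cat(sprintf("WE propagator '%s': state dim %d, pcoord dim %d\n",
              x$name, x$dim, x$pdim))
  invisible(x)
}

#' Toy association-model propagator
#'
#' Wraps [toy_propagate()] and [toy_pcoord()] for use in [run_we()].
#'
#' @param params a [toy_params()] object.
#' @return A `we_propagator`.
#' @export
toy_propagator <- function(params) {
  force(params)
  we_propagator(
    step = function(states, n_steps, seed, ids, iteration) {
      cpp_toy_propagate(states, as.integer(n_steps), unclass(params),
                        as.numeric(seed), as.integer(ids),
                        as.integer(iteration))
    },
    pcoord = function(states) {
      out <- cpp_toy_pcoord(states, unclass(params))
      colnames(out) <- c("min_sep", "binding_rmsd")
      out
    },
    dim = 7L, pdim = 2L, name = "toy_binding")
}

#' One-dimensional double-well propagator
#'
#' Overdamped Langevin dynamics on \eqn{U(x) = h (x^2 - 1)^2}; the standard
#' fixture for checking that WE resampling leaves equilibrium bin
#' probabilities unbiased.  The progress coordinate is `x` itself.
#'
#' @param h barrier scale in kT (barrier height at x = 0 is `h`).
#' @param D diffusion coefficient.
#' @param dt integrator time step.
#' @param kT thermal energy.
#' @return A `we_propagator` with 1-D states.
#' @export
double_well_propagator <- function(h = 3, D = 1, dt = 0.005, kT = 1) {
  we_propagator(
    step = function(states, n_steps, seed, ids, iteration) {
      out <- cpp_dw_propagate(states[, 1], as.integer(n_steps), h, D, dt, kT,
                              as.numeric(seed), as.integer(ids),
                              as.integer(iteration))
      matrix(out, ncol = 1)
    },
    pcoord = function(states) matrix(states[, 1], ncol = 1,
                                     dimnames = list(NULL, "x")),
    dim = 1L, pdim = 1L, name = "double_well")
}

#' Identity propagator (testing aid)
#'
#' Leaves states untouched; the progress coordinate is the state itself.
#' Useful for scripted resampling scenarios.
#'
#' @param pdim number of state columns interpreted as progress coordinate.
#' @return A `we_propagator`.
#' @export
identity_propagator <- function(pdim = 1L) {
  we_propagator(
    step = function(states, n_steps, seed, ids, iteration) states,
    pcoord = function(states) states[, seq_len(pdim), drop = FALSE],
    dim = pdim, pdim = pdim, name = "identity")
}
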