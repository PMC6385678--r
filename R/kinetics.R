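#' State definitions on the progress coordinate
#'
#' Default thresholds: unbound = minimum separation >= 20; encounter =
#' binding RMSD in \[4, 20\] and separation <= 3; bound = binding RMSD
#' <= 3.5 and separation <= 3.  Coordinates in none of the regions are
#' labelled `none` (this includes the deliberate gap between the bound
#' RMSD threshold 3.5 and the encounter lower threshold 4).  State
#' definitions are applied post hoc, so they may be chosen after an
#' equilibrium WE run has completed.
#'
#' @param unbound_min_sep separation threshold of the unbound state.
#' @param enc_rmsd length-2 RMSD range of the encounter complex.
#' @param enc_max_sep separation threshold of the encounter complex.
#' @param bound_rmsd RMSD threshold of the bound state.
#' @param bound_max_sep separation threshold of the bound state.
#' @return An object of class `state_defs`.
#' @export
state_defs <- function(unbound_min_sep = 20, enc_rmsd = c(4, 20),
                       enc_max_sep = 3, bound_rmsd = 3.5, bound_max_sep = 3) {
  if (bound_rmsd >= enc_rmsd[1])
    stop("overlapping regions: bound RMSD threshold must lie below the encounter range")
  if (max(enc_max_sep, bound_max_sep) >= unbound_min_sep)
    stop("overlapping regions: contact separation thresholds must lie below unbound_min_sep")
  structure(list(unbound_min_sep = unbound_min_sep, enc_rmsd = enc_rmsd,
                 enc_max_sep = enc_max_sep, bound_rmsd = bound_rmsd,
                 bound_max_sep = bound_max_sep),
            class = "state_defs")
}

.STATE_NAMES <- c("none", "unbound", "encounter", "bound")

# integer codes: 0 none, 1 unbound, 2 encounter, 3 bound
.assign_code <- function(pcoord, defs) {
  if (!is.matrix(pcoord)) pcoord <- matrix(pcoord, nrow = 1)
  sep <- pcoord[, 1]
  rmsd <- pcoord[, 2]
  code <- integer(length(sep))
  code[sep >= defs$unbound_min_sep] <- 1L
  enc <- sep <= defs$enc_max_sep & rmsd >= defs$enc_rmsd[1] &
    rmsd <= defs$enc_rmsd[2]
  code[enc] <- 2L
  bnd <- sep <= defs$bound_max_sep & rmsd <= defs$bound_rmsd
  code[bnd] <- 3L
  code
}

#' Assign a progress coordinate to a named state
#'
#' @param pcoord numeric length-2 vector `(min_sep, binding_rmsd)` or a
#'   matrix with those two columns.
#' @param defs a [state_defs()] object.
#' @return Character vector in `c("none", "unbound", "encounter", "bound")`.
#' @export
assign_state <- function(pcoord, defs = state_defs()) {
  if (!is.matrix(pcoord)) pcoord <- matrix(pcoord, nrow = 1)
  if (any(!is.finite(pcoord))) stop("non-finite progress coordinate")
  .STATE_NAMES[.assign_code(pcoord, defs) + 1L]
}

#' Update trajectory history labels
#'
#' Implements the steady-state decomposition label: a trajectory is labelled
#' `"U"` while it was more recently in the unbound state than the bound
#' state and `"B"` otherwise.  Entering the unbound state sets the label to
#' `"U"`, entering the bound state sets it to `"B"`; the encounter complex
#' and unassigned regions never relabel.
#'
#' @param label character vector of current labels (`"U"`/`"B"`).
#' @param state character vector of current state assignments (from
#'   [assign_state()]).
#' @return Updated label vector.
#' @export
update_history <- function(label, state) {
  label[state == "unbound"] <- "U"
  label[state == "bound"] <- "B"
  label
}

# window helper: "last:100" or explicit integer vector, against n iterations
.resolve_window <- function(window, n) {
  if (is.character(window)) {
    m <- regmatches(window, regexec("^last:([0-9]+)$", window))[[1]]
    if (length(m) != 2) stop("window must be 'last:<k>' or an integer vector")
    k <- as.integer(m[2])
    w <- seq.int(max(1L, n - k + 1L), n)
  } else {
    w <- as.integer(window)
  }
  if (length(w) < 1) stop("empty window")
  if (any(w < 1 | w > n)) stop("window outside the run")
  w
}

#' Conditional probability flux between states
#'
#' Per-iteration conditional flux carried by trajectories of the relevant
#' history label into `to`: the summed statistical weight of walkers that
#' enter `to` during an iteration, divided by tau.  For binding-direction
#' fluxes (into the encounter or bound state) the label is `"U"` ("more
#' recently unbound than bound"); for flux into the unbound state it is
#' `"B"`.  State entries are detected at tau resolution, so re-entries
#' within one tau count once.
#'
#' @param run a `we_run` from [run_we()].
#' @param from,to state names (`"unbound"`, `"encounter"`, `"bound"`).
#'   `from` documents the transition and selects the normalizing population
#'   in the rate equations; the label side follows the direction.
#' @param window iteration window: `"last:<k>"` or an integer vector.
#' @return An object of class `flux_series`: list with `values`
#'   (probability / time), `tau`, `window`, `from`, `to`.
#' @export
conditional_flux <- function(run, from, to, window = "last:100") {
  stopifnot(inherits(run, "we_run"))
  w <- .resolve_window(window, length(run$records))
  side <- if (to == "unbound") "B" else "U"
  tocode <- match(to, .STATE_NAMES) - 1L
  if (is.na(tocode) || tocode == 0L) stop("unknown state: ", to)
  vals <- vapply(run$records[w],
                 function(r) r$arrive[side, tocode] / run$tau, 0)
  structure(list(values = vals, tau = run$tau, window = w, from = from,
                 to = to),
            class = "flux_series")
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("Conditional flux %s -> %s over %d iterations: mean %.4g / time unit\n",
              x$from, x$to, length(x$values), mean(x$values)))
  invisible(x)
}

#' Labelled state population
#'
#' Time-average over the window of the summed weight of walkers currently
#' in `state` and carrying history label `label` (the steady-state
#' population of that state for the chosen direction).
#'
#' @inheritParams conditional_flux
#' @param state state name.
#' @param label history label, `"U"` or `"B"`.
#' @return Mean probability.
#' @export
labeled_population <- function(run, state, label = "U", window = "last:100") {
  stopifnot(inherits(run, "we_run"))
  w <- .resolve_window(window, length(run$records))
  code <- match(state, .STATE_NAMES) - 1L
  if (is.na(code)) stop("unknown state: ", state)
  mean(vapply(run$records[w],
              function(r) sum(r$weight[r$scode == code & r$label == label]),
              0))
}

#' Effective concentration maintained by the simulation volume
#'
#' \eqn{C_0 = 1/(N_A V)}: the concentration corresponding to one ligand in
#' the simulation volume.  The volume is taken in nm^3 and the result
#' returned in mol/L (1 nm^3 = 1e-24 L).
#'
#' @param V_nm3 simulation volume in nm^3.
#' @return Concentration in mol/L.
#' @examples
#' effective_concentration(956)  # ~1.7e-3 M = 1.7 mM
#' @export
effective_concentration <- function(V_nm3) {
  if (!is.finite(V_nm3) || V_nm3 <= 0) stop("V must be > 0")
  1 / (6.02214076e23 * V_nm3 * 1e-24)
}

#' Bimolecular rate constant from conditional flux
#'
#' \eqn{k = \mathrm{flux}/(p\,C_0)} where `flux_mean` is the mean
#' conditional flux into the product state (probability per time unit), `pop`
#' the steady-state population of the reactant state for the relevant
#' direction, and `C0` the effective concentration.  The result is in
#' 1/(M x time unit of the flux); multiply by 1e12 to convert a per-ps rate
#' to M^-1 s^-1.
#'
#' @param flux_mean mean conditional flux (1/time).
#' @param pop reactant-state labelled population (> 0).
#' @param C0 effective concentration (mol/L, > 0).
#' @return Rate constant, 1/(M x time).
#' @export
rate_bimolecular <- function(flux_mean, pop, C0) {
  if (!is.finite(pop) || pop <= 0)
    stop("state never populated in window (pop = 0)")
  if (!is.finite(C0) || C0 <= 0) stop("C0 must be > 0")
  flux_mean / (pop * C0)
}

#' Unimolecular rate constant from conditional flux
#'
#' \eqn{k_2 = \mathrm{flux}/p}: no concentration factor.
#'
#' @inheritParams rate_bimolecular
#' @return Rate constant, 1/time.
#' @export
rate_unimolecular <- function(flux_mean, pop) {
  if (!is.finite(pop) || pop <= 0)
    stop("state never populated in window (pop = 0)")
  flux_mean / pop
}

#' Percentage of productive collisions
#'
#' `100 * flux(unbound -> bound) / flux(unbound -> encounter)`: the fraction
#' of diffusional collisions (encounter-complex formations) that eventually
#' rearrange to the bound state.
#'
#' @param flux_UB mean conditional flux into the bound state.
#' @param flux_UE mean conditional flux into the encounter state (> 0).
#' @return Percentage.
#' @export
productive_percentage <- function(flux_UB, flux_UE) {
  if (!is.finite(flux_UE) || flux_UE <= 0)
    stop("zero encounter flux: percentage undefined")
  100 * flux_UB / flux_UE
}
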