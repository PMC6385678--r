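#' Parameters of the toy association model
#'
#' Configures a Brownian-dynamics model of bimolecular association: a mobile
#' "ligand" sphere carrying an orientational patch and two anchor points
#' diffuses around a fixed "receptor" sphere (patch axis +z) inside a
#' reflecting spherical shell.  The interaction
#' \deqn{U = U_{rep}(r) - \epsilon f(r)\,[g(\cos\theta_r)^{p_{rec}}
#'       g(\cos\theta_l)^{p_{lig}} + w_{enc} h(\cos\theta_r,\cos\theta_l)]}
#' with \eqn{g(x)=\max(x,0)} and \eqn{h = g(\cos\theta_r)^2(1-\cos^2\theta_l)}
#' produces the three-basin topology the analysis assumes: a free unbound
#' region, a shallow metastable encounter basin (ligand at the receptor patch
#' but misoriented, depth \eqn{w_{enc}\epsilon}), and a deep bound basin
#' (both patches aligned, depth \eqn{\epsilon}).  \eqn{f} is a C1 switch
#' equal to 1 at contact and 0 at `r_cut`; \eqn{U_{rep}} is a soft quadratic
#' core below contact.
#'
#' Reduced units throughout: `kT = 1`, lengths in Angstrom-like units, times
#' in ps-like units.  A mapping to physical units is a documentation
#' convention only and is not enforced.
#'
#' @param R_rec,R_lig receptor and ligand contact radii (length units).
#' @param eps well depth of the aligned (bound) minimum, in kT.
#' @param p_rec,p_lig patch sharpness exponents for the receptor and ligand
#'   alignment factors.
#' @param w_enc encounter-shoulder weight: depth of the misoriented contact
#'   minimum relative to `eps`.
#' @param D_t translational diffusion coefficient (length^2 / time).
#' @param D_r rotational diffusion coefficient (rad^2 / time).
#' @param dt integrator time step.
#' @param kT thermal energy (reduced units; keep at 1).
#' @param R_out radius of the reflecting confining shell for the ligand
#'   centre; must exceed `R_rec + R_lig + 20` so that an unbound state
#'   (minimum separation >= 20) exists.
#' @param r_cut interaction cutoff on the centre-centre distance; `U = 0`
#'   exactly beyond it.
#' @param k_rep soft-core repulsion strength (kT) at full overlap.
#' @param anchor_points 2 x 3 matrix of anchor coordinates in the ligand body
#'   frame; defaults to the two patch-axis poles `(0,0,+/-R_lig)`.  They play
#'   the role of the ligand anchor residues in the binding RMSD coordinate.
#' @param absorb_radius optional absorbing boundary on the centre-centre
#'   distance (0 disables it): once the ligand centre reaches this radius
#'   the walker stays put, implementing true per-step absorption for
#'   first-passage fixtures.
#' @return An object of class `toy_params` (a named list).
#' @examples
#' p <- toy_params()
#' s <- toy_state(c(0, 0, p$R_rec + p$R_lig))
#' toy_energy(s, p)  # aligned contact: -eps
#' @export
toy_params <- function(R_rec = 12, R_lig = 8, eps = 10, p_rec = 4, p_lig = 4,
                       w_enc = 0.4, D_t = 0.5, D_r = 0.02, dt = 0.05, kT = 1,
                       R_out = 48, r_cut = 30, k_rep = 100,
                       anchor_points = NULL, absorb_radius = 0) {
  if (is.null(anchor_points))
    anchor_points <- rbind(c(0, 0, R_lig), c(0, 0, -R_lig))
  anchor_points <- matrix(as.numeric(anchor_points), nrow = 2)
  stopifnot(ncol(anchor_points) == 3)
  p <- list(R_rec = R_rec, R_lig = R_lig, eps = eps, p_rec = p_rec,
            p_lig = p_lig, w_enc = w_enc, D_t = D_t, D_r = D_r, dt = dt,
            kT = kT, R_out = R_out, r_cut = r_cut, k_rep = k_rep,
            anchor_points = anchor_points, absorb_radius = absorb_radius)
  if (!all(vapply(p[c("R_rec", "R_lig", "D_t", "D_r", "dt", "kT")],
                  function(x) is.finite(x) && x >= 0, TRUE)))
    stop("R_rec, R_lig, D_t, D_r, dt, kT must be finite and non-negative")
  if (dt <= 0) stop("dt must be > 0")
  if (R_out <= R_rec + R_lig + 20)
    stop("R_out must exceed R_rec + R_lig + 20 (no unbound region otherwise)")
  if (r_cut <= R_rec + R_lig) stop("r_cut must exceed the contact distance")
  # Euler-Maruyama stability: drift per step far below the receptor size
  if (D_t * dt * 2 * k_rep / (kT * (R_rec + R_lig)) > 0.5 * R_rec)
    stop("dt too large for the soft-core stiffness: reduce dt or k_rep")
  structure(p, class = "toy_params")
}

#' @export
print.toy_params <- function(x, ...) {
  cat("Toy association model parameters (reduced units)\n")
  cat(sprintf("  radii: R_rec = %g, R_lig = %g (contact %g), shell R_out = %g\n",
              x$R_rec, x$R_lig, x$R_rec + x$R_lig, x$R_out))
  cat(sprintf("  well: eps = %g kT, w_enc = %g, patches p_rec = %g / p_lig = %g, r_cut = %g\n",
              x$eps, x$w_enc, x$p_rec, x$p_lig, x$r_cut))
  cat(sprintf("  dynamics: D_t = %g, D_r = %g, dt = %g, kT = %g\n",
              x$D_t, x$D_r, x$dt, x$kT))
  invisible(x)
}

#' Construct a toy-model state
#'
#' A state is the ligand centre position plus a unit quaternion for the
#' ligand orientation; the receptor is fixed at the origin with its patch
#' axis along +z.  States are stored as length-7 numeric vectors
#' `(x, y, z, qw, qx, qy, qz)`; ensembles as n x 7 matrices.
#'
#' @param position length-3 numeric, ligand centre.
#' @param orientation length-4 unit quaternion (w, x, y, z); identity by
#'   default.
#' @return A length-7 numeric vector of class `toy_state`.
#' @export
toy_state <- function(position, orientation = c(1, 0, 0, 0)) {
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  if (length(position) != 3 || !all(is.finite(position)))
    stop("position must be a finite 3-vector")
  if (length(orientation) != 4 || !all(is.finite(orientation)))
    stop("orientation must be a finite 4-vector")
  n <- sqrt(sum(orientation^2))
  if (abs(n - 1) > 1e-9) stop("orientation quaternion must have norm 1 (+/- 1e-9)")
  structure(c(position, orientation / n), class = "toy_state")
}

.as_state_matrix <- function(state) {
  if (is.matrix(state)) {
    stopifnot(ncol(state) == 7)
    state
  } else {
    matrix(as.numeric(state), nrow = 1)
  }
}

#' Rotate a vector by a unit quaternion
#'
#' @param q length-4 unit quaternion (w, x, y, z).
#' @param v length-3 vector.
#' @return The rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  u <- q[2:4]
  w <- q[1]
  t <- .cross3(u, v) + w * v
  v + 2 * .cross3(u, t)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Interaction energy of a toy-model state
#'
#' @param state a `toy_state` (length-7 vector).
#' @param params a [toy_params()] object.
#' @return Energy in kT.  Exactly 0 beyond `r_cut`; `-eps` at perfectly
#'   aligned contact.
#' @export
toy_energy <- function(state, params) {
  state <- as.numeric(state)
  if (length(state) != 7 || !all(is.finite(state)))
    stop("state must be a finite length-7 vector")
  cpp_toy_energy(state, unclass(params))
}

#' Propagate toy-model states by overdamped Langevin dynamics
#'
#' Euler-Maruyama translation
#' \eqn{\Delta x = -(D_t/kT)\nabla U\, dt + \sqrt{2 D_t dt}\,\xi} with a
#' reflecting shell at `R_out`, plus rotational diffusion of variance
#' \eqn{2 D_r dt} with torque drift.  All randomness derives from
#' `(seed, stream id, iteration)`, so identical arguments give bitwise
#' identical trajectories regardless of call order or R's RNG state.
#'
#' @param state a single state (length-7) or an n x 7 matrix of states.
#' @param params a [toy_params()] object.
#' @param n_steps number of integrator steps (>= 1).
#' @param seed integer global seed.
#' @param stream_id per-walker stream id(s); recycled walkers and split
#'   children should carry distinct ids.
#' @param iteration iteration index mixed into the stream key.
#' @return Propagated state(s), same shape as the input.
#' @export
toy_propagate <- function(state, params, n_steps, seed = 1L, stream_id = 1L,
                          iteration = 1L) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  m <- .as_state_matrix(state)
  if (!all(is.finite(m))) stop("non-finite coordinates in state")
  ids <- as.integer(rep_len(stream_id, nrow(m)))
  out <- cpp_toy_propagate(m, as.integer(n_steps), unclass(params),
                           as.numeric(seed), ids, as.integer(iteration))
  if (is.matrix(state)) out else structure(as.numeric(out), class = "toy_state")
}

#' Progress coordinate of toy-model states
#'
#' Returns the two-dimensional progress coordinate used for binning: the
#' minimum surface-to-surface separation (centre distance minus the radii
#' sum, clamped at 0) and the binding RMSD of the two ligand anchor points
#' against the bound reference pose (the receptor frame is the laboratory
#' frame, so no superposition is needed for the analytic toy geometry; the
#' general Kabsch route in [binding_rmsd()] gives identical values).
#'
#' @inheritParams toy_propagate
#' @return An n x 2 matrix with columns `min_sep` and `binding_rmsd`.
#' @export
toy_pcoord <- function(state, params) {
  m <- .as_state_matrix(state)
  out <- cpp_toy_pcoord(m, unclass(params))
  colnames(out) <- c("min_sep", "binding_rmsd")
  out
}

#' Reference coordinate frame of the toy model
#'
#' Point-set representation of the bound pose used by the generic
#' coordinate operations: receptor points (centre, patch pole, two
#' equatorial points for a non-degenerate superposition) followed by ligand
#' points (centre, the two anchors).
#'
#' @param params a [toy_params()] object.
#' @param state optionally, a toy state; if supplied the ligand points are
#'   placed at that state instead of the bound pose.
#' @return A list with `coords` (7 x 3 matrix), `receptor` (fit indices),
#'   `ligand`, and `anchors` (row indices of the anchor points).
#' @export
toy_frame <- function(params, state = NULL) {
  Rc <- params$R_rec + params$R_lig
  rec <- rbind(c(0, 0, 0), c(0, 0, params$R_rec),
               c(params$R_rec, 0, 0), c(0, params$R_rec, 0))
  if (is.null(state)) {
    p <- c(0, 0, Rc)
    q <- c(0, 1, 0, 0)  # 180 degrees about x: patch axis points back
  } else {
    state <- as.numeric(state)
    p <- state[1:3]
    q <- state[4:7]
  }
  anch <- t(apply(params$anchor_points, 1, function(a) p + quat_rotate(q, a)))
  lig <- rbind(p, anch)
  coords <- rbind(rec, lig)
  rownames(coords) <- c("rec_centre", "rec_patch", "rec_eq1", "rec_eq2",
                        "lig_centre", "anchor1", "anchor2")
  list(coords = coords, receptor = 1:4, ligand = 5:7, anchors = 6:7)
}

#' Generate an initial unbound ensemble
#'
#' Draws `n_pairs` states with surface-to-surface separation at least
#' `min_sep` (uniform over the accessible shell volume between
#' `R_rec + R_lig + min_sep` and `R_out`, or at fixed radius `r0` if given)
#' and ligand orientations uniform on the rotation group.
#'
#' @param n_pairs number of states.
#' @param params a [toy_params()] object.
#' @param min_sep minimum surface separation (default 20).
#' @param seed integer seed.
#' @param r0 optional fixed centre-centre radius (overrides the volume
#'   draw; used by the absorbing-shell fixtures where the analytic
#'   first-passage time needs a fixed start radius).
#' @return An `n_pairs` x 7 matrix of states.
#' @export
make_initial_ensemble <- function(n_pairs, params, min_sep = 20, seed = 1L,
                                  r0 = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (min_sep < 0) stop("min_sep must be >= 0")
  r_lo <- params$R_rec + params$R_lig + min_sep
  if (r_lo >= params$R_out && is.null(r0))
    stop("infeasible geometry: R_out leaves no room for min_sep")
  if (!is.null(r0) && (r0 < r_lo || r0 > params$R_out))
    stop("r0 outside the feasible shell")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.substream(seed, 0L, salt = 101L))
  n <- n_pairs
  r <- if (is.null(r0)) {
    (runif(n) * (params$R_out^3 - r_lo^3) + r_lo^3)^(1 / 3)
  } else rep(r0, n)
  # uniform direction
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * r
  # uniform rotation: normalized 4-variate gaussian quaternion
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  out <- cbind(pos, q)
  colnames(out) <- c("x", "y", "z", "qw", "qx", "qy", "qz")
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Brute-force mean first passage time
#'
#' Direct unbiased simulation from the initial ensemble until first entry
#' into the target region; the independent oracle against which WE rate
#' estimates are validated.
#'
#' @param params a [toy_params()] object.
#' @param stop stopping condition: `list(type = "radius", b = <r>)` absorbs
#'   at centre distance `<= b`; `list(type = "bound", rmsd = 3.5, sep = 3)`
#'   absorbs at the bound state.
#' @param n_replicas number of independent replicas (>= 10).
#' @param seed integer seed.
#' @param max_steps step cap per replica; replicas exceeding it are counted
#'   in `n_capped` and excluded from the mean, never silently dropped.
#' @param initial optional matrix of start states; defaults to
#'   [make_initial_ensemble()] draws.
#' @param check_every detection stride in steps (1 = per-step detection).
#' @param min_sep,r0 passed to [make_initial_ensemble()] when `initial` is
#'   not supplied.
#' @return A list with `mfpt`, `se`, `times` (in time units), `n_events`,
#'   and `n_capped`.
#' @export
brute_force_mfpt <- function(params, stop, n_replicas = 100, seed = 1L,
                             max_steps = 1e7, initial = NULL, check_every = 1L,
                             min_sep = 20, r0 = NULL) {
  if (n_replicas < 10) base::stop("n_replicas must be >= 10")
  if (is.null(initial))
    initial <- make_initial_ensemble(n_replicas, params, min_sep = min_sep,
                                     seed = seed, r0 = r0)
  if (nrow(initial) < n_replicas)
    initial <- initial[rep_len(seq_len(nrow(initial)), n_replicas), , drop = FALSE]
  sr <- if (identical(stop$type, "radius")) -1 else stop$rmsd
  ss <- if (identical(stop$type, "radius")) -1 else stop$sep
  sb <- if (identical(stop$type, "radius")) stop$b else -1
  times <- numeric(0)
  n_capped <- 0L
  for (i in seq_len(n_replicas)) {
    res <- cpp_toy_fpt(initial[i, ], unclass(params), as.numeric(seed),
                       as.integer(i), 0L, max_steps, as.integer(check_every),
                       sr, ss, sb)
    if (res$hit) times <- c(times, res$n_steps * params$dt)
    else n_capped <- n_capped + 1L
  }
  list(mfpt = mean(times), se = sd(times) / sqrt(length(times)),
       times = times, n_events = length(times), n_capped = n_capped)
}

#' Analytic mean first passage time in a spherical shell
#'
#' Free 3-D diffusion with an absorbing sphere at radius `b` and a
#' reflecting shell at radius `R`:
#' \deqn{T(r_0) = \frac{1}{D}\left[\frac{R^3}{3}\left(\frac{1}{b} -
#'   \frac{1}{r_0}\right) - \frac{r_0^2 - b^2}{6}\right].}
#' Serves as the closed-form oracle for the Hill-relation check (steady
#' state arrival flux = 1 / MFPT).
#'
#' @param b absorbing radius.
#' @param R reflecting outer radius.
#' @param r0 start radius, `b <= r0 <= R`.
#' @param D diffusion coefficient.
#' @return Mean first passage time.
#' @export
shell_mfpt_analytic <- function(b, R, r0, D) {
  if (!(b > 0 && b <= r0 && r0 <= R && D > 0))
    stop("require 0 < b <= r0 <= R and D > 0")
  (R^3 / 3 * (1 / b - 1 / r0) - (r0^2 - b^2) / 6) / D
}
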