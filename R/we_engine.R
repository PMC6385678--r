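#' Resampling policy for the WE engine
#'
#' Two allocation modes: `per_bin_target` maintains `target` walkers in
#' every occupied bin (the classic scheme); `fixed_total` keeps the global
#' walker count at `total` at all times, distributing slots as
#' `max(1, floor(total / occupied bins))` per occupied bin with the leftover
#' slots given one-by-one to occupied bins in descending bin weight.
#'
#' @param mode `"per_bin_target"` or `"fixed_total"`.
#' @param target per-bin target count (per_bin_target mode).
#' @param total global walker count (fixed_total mode).
#' @param recycle logical: steady-state mode.  Walkers that enter the
#'   target state are recorded as arrivals and restarted from fresh initial
#'   states with unchanged weights; equilibrium mode (the default) never
#'   recycles, which permits refining state definitions after the run.
#' @param target_state name of the recycling target state (default
#'   `"bound"`).
#' @return An object of class `we_policy`.
#' @export
we_policy <- function(mode = c("per_bin_target", "fixed_total"), target = 12L,
                      total = NULL, recycle = FALSE, target_state = "bound") {
  mode <- match.arg(mode)
  if (mode == "fixed_total") {
    if (is.null(total) || total < 1) stop("fixed_total mode needs total >= 1")
  } else if (target < 1) stop("target must be >= 1")
  structure(list(mode = mode, target = as.integer(target),
                 total = if (is.null(total)) NULL else as.integer(total),
                 recycle = isTRUE(recycle), target_state = target_state),
            class = "we_policy")
}

#' Initialize a walker ensemble
#'
#' Creates `nrow(states) * copies_per_state` walkers, each with weight
#' `1 / (n_states * copies)`, history label `"U"`, and a root-lineage index
#' recording which initial state it descends from.
#'
#' @param states matrix of initial dynamic states (rows = states).
#' @param copies_per_state independent trajectories started per state.
#' @return An object of class `we_walkers`: a column-oriented list with
#'   `state`, `weight`, `id`, `root`, `label`, `parent`.
#' @export
initialize_walkers <- function(states, copies_per_state = 1L) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  n0 <- nrow(states)
  if (n0 < 1 || copies_per_state < 1) stop("need >= 1 state and >= 1 copy")
  idx <- rep(seq_len(n0), each = copies_per_state)
  n <- length(idx)
  structure(list(state = states[idx, , drop = FALSE],
                 weight = rep(1 / n, n),
                 id = seq_len(n),
                 root = idx,
                 label = rep("U", n),
                 parent = rep(NA_integer_, n)),
            class = "we_walkers")
}

#' @export
print.we_walkers <- function(x, ...) {
  cat(sprintf("WE walker ensemble: %d walkers, total weight %.15f\n",
              length(x$weight), sum(x$weight)))
  invisible(x)
}

#' Split a walker into k children
#'
#' Children share the parent's dynamic state, progress coordinate and
#' history label; the parent weight is divided evenly.
#'
#' @param walker a list with at least `weight` (plus any other fields, which
#'   are copied).
#' @param k number of children (>= 1).
#' @param next_id first id to assign to the children.
#' @return List of `k` walker lists with `weight = walker$weight / k`,
#'   fresh `id`s, and `parent` set to the parent's id.
#' @export
split_walker <- function(walker, k, next_id = 1L) {
  if (k < 1) stop("k must be >= 1")
  lapply(seq_len(k), function(i) {
    ch <- walker
    ch$weight <- walker$weight / k
    ch$parent <- walker$id
    ch$id <- next_id + i - 1L
    ch
  })
}

#' Merge two walkers in the same bin
#'
#' The survivor's dynamic state is chosen with probability proportional to
#' weight, preserving expectations; the survivor carries the summed weight
#' and the loser's lineage terminates.
#'
#' @param w1,w2 walker lists with `weight` (> 0) and matching `bin`.
#' @return The surviving walker with `weight = w1$weight + w2$weight`.
#' @export
merge_pair <- function(w1, w2) {
  if (!is.null(w1$bin) && !is.null(w2$bin) && !identical(w1$bin, w2$bin))
    stop("cannot merge walkers from different bins")
  if (w1$weight <= 0 || w2$weight <= 0)
    stop("merge requires strictly positive weights")
  tot <- w1$weight + w2$weight
  surv <- if (runif(1) < w1$weight / tot) w1 else w2
  surv$weight <- tot
  surv
}

# core resampler on the column-oriented walker set; returns new walkers plus
# the origin index (input row each output walker descends from)
.resample_core <- function(w, bins, policy, next_id) {
  occ <- sort(unique(bins))
  no <- length(occ)
  if (policy$mode == "fixed_total") {
    total <- policy$total
    if (total < no)
      stop(sprintf("fixed_total = %d is smaller than the %d occupied bins (bins: %s)",
                   total, no, paste(utils::head(occ, 20), collapse = ",")))
    base <- max(1L, total %/% no)
    tgt <- rep(base, no)
    left <- total - base * no
    if (left > 0) {
      bw <- vapply(occ, function(b) sum(w$weight[bins == b]), 0)
      ord <- order(-bw, occ)
      tgt[ord[seq_len(left)]] <- base + 1L
    }
  } else {
    tgt <- rep(policy$target, no)
  }
  out_origin <- integer(0)
  out_weight <- numeric(0)
  n_merge <- 0L
  n_split <- 0L
  for (bi in seq_len(no)) {
    idx <- which(bins == occ[bi])
    wt <- w$weight[idx]
    ids <- w$id[idx]
    while (length(idx) > tgt[bi]) {
      o <- order(wt, ids)
      i1 <- o[1]; i2 <- o[2]
      tot <- wt[i1] + wt[i2]
      surv <- if (runif(1) < wt[i1] / tot) i1 else i2
      lose <- if (surv == i1) i2 else i1
      wt[surv] <- tot
      idx <- idx[-lose]; wt <- wt[-lose]; ids <- ids[-lose]
      n_merge <- n_merge + 1L
    }
    while (length(idx) < tgt[bi]) {
      o <- order(-wt, ids)
      i1 <- o[1]
      half <- wt[i1] / 2       # exact in binary floating point
      wt[i1] <- half
      idx <- c(idx, idx[i1]); wt <- c(wt, half); ids <- c(ids, ids[i1])
      n_split <- n_split + 1L
    }
    out_origin <- c(out_origin, idx)
    out_weight <- c(out_weight, wt)
  }
  n_out <- length(out_origin)
  nw <- structure(list(state = w$state[out_origin, , drop = FALSE],
                       weight = out_weight,
                       id = seq.int(next_id, length.out = n_out),
                       root = w$root[out_origin],
                       label = w$label[out_origin],
                       parent = out_origin),
                  class = "we_walkers")
  nw$scode <- w$scode[out_origin]
  list(walkers = nw, origin = out_origin, n_merge = n_merge,
       n_split = n_split)
}

#' Resample a walker ensemble on a bin scheme
#'
#' Brings every occupied bin to its target count by splitting the
#' highest-weight walkers (ties broken by id) and merging the two
#' lowest-weight walkers repeatedly (survivor drawn proportionally to
#' weight).  Total weight is conserved exactly; splits preserve every
#' weighted observable exactly and merges preserve it in expectation.
#'
#' @param walkers a `we_walkers` ensemble.
#' @param scheme a `bin_scheme` used to bin the walkers' progress
#'   coordinates.
#' @param policy a [we_policy()].
#' @param pcoord optional pre-computed progress-coordinate matrix; defaults
#'   to `walkers$pcoord`.
#' @param next_id first id for the resampled walkers.
#' @return A list with `walkers` (the resampled ensemble), `origin` (input
#'   row of each output walker), `n_merge`, `n_split`.
#' @export
resample <- function(walkers, scheme, policy, pcoord = NULL, next_id = 1L) {
  if (is.null(pcoord)) pcoord <- walkers$pcoord
  if (is.null(pcoord)) stop("walkers carry no progress coordinates")
  bins <- assign_bin(pcoord, scheme)
  res <- .resample_core(walkers, bins, policy, next_id)
  res$walkers$pcoord <- pcoord[res$origin, , drop = FALSE]
  res
}

#' Reassign bins after a scheme switch
#'
#' Trajectory weights are independent of the bins, so switching schemes
#' mid-run changes only the bin assignments; weights, dynamic states and
#' walker count are untouched.  The next resampling adapts the counts to
#' the new partition.
#'
#' @param walkers a `we_walkers` ensemble carrying `pcoord`.
#' @param new_scheme the replacement `bin_scheme`.
#' @return The ensemble with `bin` recomputed under `new_scheme`.
#' @export
switch_scheme <- function(walkers, new_scheme) {
  if (is.null(walkers$pcoord)) stop("walkers carry no progress coordinates")
  walkers$bin <- assign_bin(walkers$pcoord, new_scheme)
  walkers
}

#' Run one WE iteration
#'
#' Propagates all walkers for `tau_steps` dynamics steps, recomputes
#' progress coordinates, state assignments and history labels, records
#' per-state arrival weights (each entering walker contributes its full
#' weight exactly once), optionally recycles walkers that reached the
#' target state, and resamples.
#'
#' @param walkers a `we_walkers` ensemble with `scode` initialized (see
#'   [run_we()], which manages this).
#' @param prop a `we_propagator`.
#' @param tau_steps integration steps per iteration.
#' @param scheme a `bin_scheme`.
#' @param policy a [we_policy()].
#' @param defs a [state_defs()] or `NULL` (no state bookkeeping).
#' @param seed run seed.
#' @param iteration iteration index (mixed into the propagation streams).
#' @param init_sampler function `(n, seed, iteration) -> state matrix`
#'   supplying fresh initial states when recycling.
#' @param next_id first id for post-resampling walkers.
#' @param store_states keep the propagated dynamic states in the record.
#' @return A list with `walkers` (post-resampling) and `record` (the
#'   pre-resampling iteration record: `weight`, `pcoord`, `bin`, `label`,
#'   `scode`, `parent`, `entry`, `arrive`, `recycled`, `root`).
#' @export
run_iteration <- function(walkers, prop, tau_steps, scheme, policy,
                          defs = NULL, seed = 1L, iteration = 1L,
                          init_sampler = NULL, next_id = 1L,
                          store_states = FALSE) {
  w <- walkers
  n <- length(w$weight)
  st <- prop$step(w$state, tau_steps, seed, w$id, iteration)
  pc <- prop$pcoord(st)
  arrive <- matrix(0, 2, 3, dimnames = list(c("U", "B"),
                                            c("unbound", "encounter", "bound")))
  entry <- integer(n)
  recycled <- 0
  code <- NULL
  if (!is.null(defs)) {
    code <- .assign_code(pc, defs)
    prev <- w$scode
    for (s in 1:3) {
      ent <- code == s & prev != s
      entry[ent] <- s
      arrive["U", s] <- sum(w$weight[ent & w$label == "U"])
      arrive["B", s] <- sum(w$weight[ent & w$label == "B"])
    }
    w$label[code == 1L] <- "U"
    w$label[code == 3L] <- "B"
  }
  # pre-resampling record holds the arrival-frame coordinates
  record <- list(weight = w$weight, pcoord = pc,
                 label = w$label, scode = code, parent = w$parent,
                 entry = entry, arrive = arrive, root = w$root)
  if (store_states) record$state <- st
  w$state <- st
  w$scode <- code
  if (!is.null(defs) && policy$recycle) {
    tcode <- match(policy$target_state, .STATE_NAMES) - 1L
    hit <- which(code == tcode)
    if (length(hit) > 0) {
      if (is.null(init_sampler))
        stop("recycling mode requires an init_sampler")
      recycled <- sum(w$weight[hit])
      fresh <- init_sampler(length(hit), seed, iteration)
      w$state[hit, ] <- fresh
      pc[hit, ] <- prop$pcoord(fresh)
      w$scode[hit] <- .assign_code(pc[hit, , drop = FALSE], defs)
      w$label[hit] <- "U"
    }
  }
  record$recycled <- recycled
  bins <- assign_bin(pc, scheme)
  record$bin <- bins
  res <- .resample_core(w, bins, policy, next_id)
  res$walkers$pcoord <- pc[res$origin, , drop = FALSE]
  record$n_merge <- res$n_merge
  record$n_split <- res$n_split
  list(walkers = res$walkers, record = record)
}

#' Run a weighted-ensemble simulation
#'
#' The full WE loop: propagate all walkers for tau, apply state and
#' history-label bookkeeping, optionally recycle target-state arrivals
#' (steady-state mode), then split/merge within bins to the policy's
#' targets.  Supports a two-stage bin scheme with a fixed or automatic
#' switch: the automatic trigger fires once every initial-state lineage
#' either has a descendant that visited the encounter state or has no live
#' descendants (subject to `switch_window`).
#'
#' @param prop a `we_propagator`.
#' @param initial matrix of initial dynamic states.
#' @param n_iter number of WE iterations.
#' @param tau_steps dynamics steps per iteration.
#' @param tau physical duration of one iteration (in the propagator's time
#'   units); used to convert arrival weights to fluxes.
#' @param scheme a `bin_scheme`, or the stage-1 scheme when `scheme2` is
#'   given.
#' @param policy a [we_policy()].
#' @param defs a [state_defs()] or `NULL` to skip state bookkeeping.
#' @param copies_per_state independent trajectories per initial state.
#' @param seed integer run seed; all propagation streams and resampling
#'   draws derive from it.
#' @param scheme2 optional stage-2 scheme.
#' @param switch_at iteration at which to switch to `scheme2`, or `"auto"`.
#' @param switch_window length-2 integer vector `(min, max)` bracketing the
#'   automatic switch.
#' @param init_sampler function `(n, seed, iteration)` returning fresh
#'   initial states (required in recycling mode).
#' @param store_states keep dynamic states in every iteration record
#'   (needed for entry-point maps and contact analyses).
#' @return An object of class `we_run`: list with `records` (one
#'   pre-resampling record per iteration), `tau`, `tau_steps`, `defs`,
#'   `policy`, `stage` (per-iteration scheme stage), `switch_iter`,
#'   `weight_err` (per-iteration |1 - total weight|), `final` walkers,
#'   `n_initial`, `seed`.
#' @export
run_we <- function(prop, initial, n_iter, tau_steps, tau, scheme, policy,
                   defs = NULL, copies_per_state = 1L, seed = 1L,
                   scheme2 = NULL, switch_at = NULL,
                   switch_window = c(1L, n_iter), init_sampler = NULL,
                   store_states = FALSE) {
  w <- initialize_walkers(initial, copies_per_state)
  pc <- prop$pcoord(w$state)
  w$pcoord <- pc
  w$scode <- if (is.null(defs)) rep(0L, length(w$weight)) else .assign_code(pc, defs)
  next_id <- max(w$id) + 1L
  records <- vector("list", n_iter)
  stage <- integer(n_iter)
  weight_err <- numeric(n_iter)
  cur_scheme <- scheme
  cur_stage <- 1L
  switch_iter <- NA_integer_
  roots_all <- unique(w$root)
  roots_enc <- integer(0)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (it in seq_len(n_iter)) {
    set.seed(.substream(seed, it, salt = 7L))
    step <- run_iteration(w, prop, tau_steps, cur_scheme, policy, defs,
                          seed = seed, iteration = it,
                          init_sampler = init_sampler, next_id = next_id,
                          store_states = store_states)
    w <- step$walkers
    next_id <- max(w$id) + 1L
    records[[it]] <- step$record
    stage[it] <- cur_stage
    weight_err[it] <- abs(1 - sum(w$weight))
    # stage switching
    if (!is.null(scheme2) && cur_stage == 1L) {
      do_switch <- FALSE
      if (identical(switch_at, "auto")) {
        if (!is.null(defs)) {
          roots_enc <- union(roots_enc,
                             unique(step$record$root[step$record$scode == 2L]))
          alive <- unique(w$root)
          resolved <- all(alive %in% roots_enc)
          do_switch <- (it >= switch_window[1] && resolved) ||
            it >= switch_window[2]
        } else do_switch <- it >= switch_window[2]
      } else if (!is.null(switch_at)) {
        do_switch <- it >= switch_at
      }
      if (do_switch) {
        cur_scheme <- scheme2
        cur_stage <- 2L
        switch_iter <- it + 1L
        w <- switch_scheme(w, cur_scheme)
      }
    }
  }
  structure(list(records = records, tau = tau, tau_steps = tau_steps,
                 defs = defs, policy = policy, stage = stage,
                 switch_iter = switch_iter, weight_err = weight_err,
                 final = w, n_initial = nrow(.as_matrix_rows(initial)),
                 seed = seed),
            class = "we_run")
}

.as_matrix_rows <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' @export
print.we_run <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf("WE run: %d iterations, tau = %g, %d final walkers\n",
              n, x$tau, length(x$final$weight)))
  cat(sprintf("  max |1 - total weight| = %.3g\n", max(x$weight_err)))
  if (!is.na(x$switch_iter))
    cat(sprintf("  scheme switched to stage 2 at iteration %d\n",
                x$switch_iter))
  arr <- sum(vapply(x$records, function(r) sum(r$arrive["U", "bound"]), 0))
  if (!is.null(x$defs))
    cat(sprintf("  cumulative binding-direction arrival weight at bound: %.3g\n",
                arr))
  invisible(x)
}
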