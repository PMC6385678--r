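#' Extract the transition path ensemble from a WE run
#'
#' For every binding-direction arrival at the bound state, walks the walker
#' lineage backwards through the parent links to the most recent frame
#' assigned to the unbound state.  The returned path spans the frames after
#' that last unbound exit up to and including the first bound frame, and
#' carries the arriving walker's weight.  Paths from distinct initial-state
#' lineages (roots) are statistically independent.
#'
#' @param run a `we_run` with state bookkeeping (`defs` was supplied).
#' @param min_len drop paths shorter than this many frames (default 1 =
#'   keep all).
#' @return An object of class `tpe`: a list of paths, each a list with
#'   `frames` (matrix with columns `iteration`, `index`, `min_sep`,
#'   `binding_rmsd`, `encounter` flag), `weight`, `duration`
#'   (`n frames x tau`), `root`.  Empty list when no arrivals occurred.
#' @export
extract_tpe <- function(run, min_len = 1L) {
  stopifnot(inherits(run, "we_run"))
  if (is.null(run$defs)) stop("run has no state assignments")
  paths <- list()
  recs <- run$records
  for (it in seq_along(recs)) {
    r <- recs[[it]]
    hits <- which(r$entry == 3L)
    for (jj in hits) {
      # binding-direction arrivals only: the walker must have been more
      # recently unbound than bound before this entry (pre-entry label U)
      prelab <- if (it == 1L) "U" else {
        par <- r$parent[jj]
        if (is.na(par)) "U" else recs[[it - 1L]]$label[par]
      }
      if (prelab != "U") next
      frames <- NULL
      k <- it
      idx <- jj
      repeat {
        rk <- recs[[k]]
        if (rk$scode[idx] == 1L) break   # most recent unbound frame: stop
        frames <- rbind(c(k, idx, rk$pcoord[idx, 1], rk$pcoord[idx, 2],
                          as.integer(rk$scode[idx] == 2L)), frames)
        par <- rk$parent[idx]
        if (k == 1L || is.na(par)) break
        k <- k - 1L
        idx <- par
      }
      if (is.null(frames) || nrow(frames) < min_len) next
      colnames(frames) <- c("iteration", "index", "min_sep", "binding_rmsd",
                            "encounter")
      paths[[length(paths) + 1L]] <-
        list(frames = frames, weight = r$weight[jj],
             duration = nrow(frames) * run$tau, root = r$root[jj])
    }
  }
  structure(paths, class = "tpe")
}

#' @export
print.tpe <- function(x, ...) {
  cat(sprintf("Transition path ensemble: %d paths, total weight %.3g, %d independent lineages\n",
              length(x), sum(vapply(x, `[[`, 0, "weight")),
              length(unique(vapply(x, `[[`, 0, "root")))))
  invisible(x)
}

#' Weighted event-duration distribution of a TPE
#'
#' Durations (barrier-crossing times) of the transition paths, histogrammed
#' with the path weights; the modal value is the centre of the
#' highest-mass cell.
#'
#' @param tpe a `tpe` from [extract_tpe()].
#' @param bin_width histogram bin width in time units; defaults to the
#'   run's tau (one frame).
#' @return A list with `durations`, `weights`, `breaks`, `mass` (histogram
#'   mass per cell, summing to the total TPE weight), `mode`, `bin_width`.
#' @export
event_durations <- function(tpe, bin_width = NULL) {
  if (length(tpe) < 1) stop("empty transition path ensemble")
  dur <- vapply(tpe, `[[`, 0, "duration")
  wt <- vapply(tpe, `[[`, 0, "weight")
  if (is.null(bin_width)) bin_width <- min(dur)
  breaks <- seq(0, max(dur) + bin_width, by = bin_width)
  cell <- pmin(findInterval(dur, breaks), length(breaks) - 1L)
  mass <- vapply(seq_len(length(breaks) - 1L),
                 function(i) sum(wt[cell == i]), 0)
  mode_cell <- which.max(mass)
  list(durations = dur, weights = wt, breaks = breaks, mass = mass,
       mode = (breaks[mode_cell] + breaks[mode_cell + 1L]) / 2,
       bin_width = bin_width)
}

#' Weighted contact probabilities over TPE frames
#'
#' Probability of each pairwise contact in the transition path ensemble:
#' the summed weight of frames whose pair distance is within the cutoff,
#' divided by the total frame weight.
#'
#' @param distances n_frames x n_pairs matrix of pair distances.
#' @param weights frame weights.
#' @param cutoff contact distance cutoff (default 4.5).
#' @return Named numeric vector of contact probabilities per pair.
#' @export
weighted_contact_probabilities <- function(distances, weights, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  distances <- as.matrix(distances)
  if (nrow(distances) != length(weights))
    stop("weights length must match the number of frames")
  tw <- sum(weights)
  if (tw <= 0) stop("total weight must be positive")
  colSums((distances <= cutoff) * weights) / tw
}

#' Pair distances of toy-model frames
#'
#' Distances between the receptor reference points (centre, patch pole) and
#' the ligand points (centre, two anchors) for each state — the toy-model
#' stand-in for intermolecular residue pairs in contact maps.
#'
#' @inheritParams toy_pcoord
#' @return n x 6 matrix of distances, one column per (receptor point,
#'   ligand point) pair.
#' @export
toy_pair_distances <- function(state, params) {
  m <- .as_state_matrix(state)
  rec <- rbind(c(0, 0, 0), c(0, 0, params$R_rec))
  out <- matrix(NA_real_, nrow(m), 6)
  for (i in seq_len(nrow(m))) {
    p <- m[i, 1:3]
    q <- m[i, 4:7]
    lig <- rbind(p,
                 p + quat_rotate(q, params$anchor_points[1, ]),
                 p + quat_rotate(q, params$anchor_points[2, ]))
    d <- sqrt(outer(rowSums(rec^2), rowSums(lig^2), "+") - 2 * rec %*% t(lig))
    out[i, ] <- as.numeric(t(d))
  }
  colnames(out) <- c("centre-centre", "centre-anchor1", "centre-anchor2",
                     "patch-centre", "patch-anchor1", "patch-anchor2")
  out
}

#' Weighted histogram entropy
#'
#' \eqn{S = -\sum_i p_i \ln p_i} over the weighted histogram of the
#' samples, in units of the gas constant R; empty cells contribute zero.
#' Multi-column samples are histogrammed on the joint grid (`n_bins` per
#' dimension).  Degenerate all-identical samples occupy a single cell and
#' give S = 0.
#'
#' @param samples numeric vector or matrix (rows = observations) of angles
#'   or scalars.
#' @param weights observation weights (default uniform).
#' @param n_bins cells per dimension (>= 2); qualitative stability should
#'   be checked across 15..35 bins.
#' @return Entropy in units of R (dimensionless multiple).
#' @export
histogram_entropy <- function(samples, weights = NULL, n_bins = 25) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n <- nrow(m)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  if (sum(weights) <= 0) stop("total weight must be positive")
  cell <- rep(1L, n)
  mult <- 1L
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    lo <- min(x); hi <- max(x)
    cj <- if (hi == lo) rep(1L, n) else {
      br <- seq(lo, hi, length.out = n_bins + 1)
      pmin(pmax(findInterval(x, br), 1L), n_bins)
    }
    cell <- cell + (cj - 1L) * mult
    mult <- mult * n_bins
  }
  p <- vapply(split(weights, cell), sum, 0) / sum(weights)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Canberra distance
#'
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / (|u_i| + |v_i|)} with 0/0 terms
#' defined as 0.
#'
#' @param u,v numeric vectors of equal length.
#' @return The Canberra distance.
#' @export
canberra <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  num <- abs(u - v)
  den <- abs(u) + abs(v)
  sum(ifelse(den == 0, 0, num / den))
}

#' Greedy k-centers clustering
#'
#' Farthest-point traversal: starting from `seed_index`, repeatedly add the
#' point farthest from the current centers, then assign every point to its
#' nearest center.  Deterministic given `seed_index` and guaranteed within
#' a factor 2 of the optimal covering radius.
#'
#' @param features n x d matrix of feature vectors.
#' @param k number of clusters (<= n).
#' @param metric `"euclidean"` or `"canberra"`.
#' @param seed_index index of the first center.
#' @return A list with `centers` (row indices), `assignment` (length n),
#'   `radius` (covering radius).
#' @export
kcenters <- function(features, k, metric = c("euclidean", "canberra"),
                     seed_index = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop("k must not exceed the number of points")
  metric <- match.arg(metric)
  distfun <- function(ci) {
    cvec <- features[ci, ]
    if (metric == "euclidean") {
      sqrt(rowSums(sweep(features, 2, cvec)^2))
    } else {
      num <- abs(sweep(features, 2, cvec))
      den <- sweep(abs(features), 2, abs(cvec), "+")
      rowSums(ifelse(den == 0, 0, num / den))
    }
  }
  centers <- integer(k)
  centers[1] <- as.integer(seed_index)
  dmin <- distfun(centers[1])
  assignment <- rep(1L, n)
  if (k > 1) {
    for (j in 2:k) {
      centers[j] <- which.max(dmin)
      dj <- distfun(centers[j])
      upd <- dj < dmin
      dmin[upd] <- dj[upd]
      assignment[upd] <- j
    }
  }
  list(centers = centers, assignment = assignment, radius = max(dmin))
}

#' Build a conformation space network
#'
#' Nodes are cluster centers carrying the total statistical weight and the
#' weighted average of a property over the member frames; directed edges
#' record observed transitions between clusters along each trajectory
#' (consecutive frames in different clusters), weighted by the transitioning
#' frame's weight.
#'
#' @param assignment integer cluster labels per frame.
#' @param weights frame weights.
#' @param traj trajectory id per frame; transitions are only counted within
#'   a trajectory.  Default: one single trajectory.
#' @param property optional numeric property per frame to average per node.
#' @return An object of class `csn`: list with `nodes` (data.frame
#'   `cluster`, `weight`, `property`) and `edges` (data.frame `from`, `to`,
#'   `weight`, `count`).
#' @export
build_csn <- function(assignment, weights, traj = NULL, property = NULL) {
  n <- length(assignment)
  if (length(weights) != n) stop("weights length mismatch")
  if (!is.null(property) && length(property) != n)
    stop("property length mismatch")
  if (is.null(traj)) traj <- rep(1L, n)
  levs <- sort(unique(assignment))
  af <- factor(assignment, levels = levs)
  nodes <- data.frame(
    cluster = levs,
    weight = as.numeric(vapply(split(weights, af), sum, 0)))
  if (!is.null(property)) {
    wp <- vapply(split(seq_len(n), af),
                 function(ix) sum(weights[ix] * property[ix]) / sum(weights[ix]),
                 0)
    nodes$property <- as.numeric(wp)
  }
  i <- seq_len(n - 1)
  ok <- traj[i] == traj[i + 1] & assignment[i] != assignment[i + 1]
  edges <- data.frame(from = assignment[i][ok], to = assignment[i + 1][ok],
                      weight = weights[i + 1][ok])
  if (nrow(edges) > 0) {
    key <- paste(edges$from, edges$to, sep = "->")
    agg <- lapply(split(edges, key), function(d)
      data.frame(from = d$from[1], to = d$to[1], weight = sum(d$weight),
                 count = nrow(d)))
    edges <- do.call(rbind, agg)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0), count = integer(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "csn")
}

#' @export
print.csn <- function(x, ...) {
  cat(sprintf("Conformation space network: %d nodes (total weight %.3g), %d directed edges\n",
              nrow(x$nodes), sum(x$nodes$weight), nrow(x$edges)))
  invisible(x)
}

#' Spherical map of ligand entry points
#'
#' Projects weighted entry directions onto a unit sphere around the
#' receptor and histograms them on an equal-area grid: `n_bins` latitude
#' bands of equal area (uniform in cos theta), each subdivided in
#' longitude into near-square cells.  The receptor patch axis is +z (the
#' analog of rotating the receptor so a reference residue aligns with the
#' z-axis).
#'
#' @param directions n x 3 matrix of entry vectors (normalized internally;
#'   zero vectors are an error).
#' @param weights entry weights (default uniform).
#' @param n_bins number of latitude bands (default 30).
#' @return A data.frame with one row per cell: `band`, `sector`, `z_lo`,
#'   `z_hi`, `solid_angle`, `prob`; cell probabilities sum to 1.
#' @export
spherical_entry_map <- function(directions, weights = NULL, n_bins = 30) {
  directions <- as.matrix(directions)
  n <- nrow(directions)
  if (is.null(weights)) weights <- rep(1, n)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop("zero entry vector")
  u <- directions / nrm
  z_edges <- seq(1, -1, length.out = n_bins + 1)
  band <- pmin(pmax(findInterval(-u[, 3], sort(-z_edges),
                                 rightmost.closed = TRUE), 1L), n_bins)
  # near-square cells: sectors per band proportional to the band's
  # circumference over its polar height
  cells <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    th_lo <- acos(z_edges[b]); th_hi <- acos(z_edges[b + 1])
    th_mid <- (th_lo + th_hi) / 2
    m <- max(1L, round(2 * pi * sin(th_mid) / (th_hi - th_lo)))
    data.frame(band = b, sector = seq_len(m), z_lo = z_edges[b + 1],
               z_hi = z_edges[b],
               solid_angle = 2 * pi * (z_edges[b] - z_edges[b + 1]) / m)
  }))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  m_of_band <- vapply(seq_len(n_bins),
                      function(b) max(cells$sector[cells$band == b]), 0)
  sector <- pmin(floor(phi / (2 * pi) * m_of_band[band]) + 1L,
                 m_of_band[band])
  key_obs <- paste(band, sector)
  mass <- vapply(split(weights, key_obs), sum, 0)
  key_cell <- paste(cells$band, cells$sector)
  cells$prob <- as.numeric(mass[key_cell]) / sum(weights)
  cells$prob[is.na(cells$prob)] <- 0
  cells
}

#' Collision entry directions from a WE run
#'
#' The entry point of a diffusional collision is the receptor-to-ligand
#' unit vector at the first frame of a walker lineage with minimum
#' separation below the threshold.  Requires a run with
#' `store_states = TRUE`.
#'
#' @param run a `we_run` over toy-model states with stored states.
#' @param threshold separation threshold defining a collision (default 5).
#' @return A list with `directions` (m x 3) and `weights`.
#' @export
collision_entries <- function(run, threshold = 5) {
  stopifnot(inherits(run, "we_run"))
  if (is.null(run$records[[1]]$state))
    stop("run was not stored with store_states = TRUE")
  dirs <- NULL
  wts <- numeric(0)
  for (it in seq_along(run$records)) {
    r <- run$records[[it]]
    inside <- r$pcoord[, 1] < threshold
    if (it == 1L) {
      newly <- inside
    } else {
      prev <- run$records[[it - 1L]]
      newly <- inside & prev$pcoord[r$parent, 1] >= threshold
    }
    for (j in which(newly)) {
      p <- r$state[j, 1:3]
      dirs <- rbind(dirs, p / sqrt(sum(p^2)))
      wts <- c(wts, r$weight[j])
    }
  }
  list(directions = dirs, weights = wts)
}
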