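#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1) and translation that
#' superpose `mobile` onto `reference` in the least-squares sense over
#' `fit_subset`, and applies the transform to all mobile points.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates.
#' @param fit_subset indices of the rows used for the fit (default: all);
#'   at least 3 non-collinear points are required.
#' @return A list with `rotation` (3 x 3, maps column vectors), `translation`
#'   (length 3), `transformed` (all mobile points after the transform), and
#'   `rmsd_fit` (post-fit root-mean-square deviation over `fit_subset`).
#' @export
kabsch_superpose <- function(mobile, reference, fit_subset = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinates must be n x 3 matrices")
  if (is.null(fit_subset)) fit_subset <- seq_len(nrow(mobile))
  if (length(fit_subset) < 3) stop("need >= 3 fit points")
  m <- mobile[fit_subset, , drop = FALSE]
  r <- reference[fit_subset, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("fit subsets must have equal point counts")
  cm <- colMeans(m)
  cr <- colMeans(r)
  m0 <- sweep(m, 2, cm)
  r0 <- sweep(r, 2, cr)
  s <- svd(t(m0) %*% r0)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300) || s$d[1] < 1e-12)
    stop("degenerate fit set (collinear or coincident points)")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
  dev <- transformed[fit_subset, , drop = FALSE] - r
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       transformed = transformed,
       rmsd_fit = sqrt(mean(rowSums(dev^2))))
}

#' Binding RMSD of ligand anchor points
#'
#' Superposes the frame onto the bound reference using the receptor points
#' only, then reports the root-mean-square deviation over the ligand anchor
#' points.  At large separations this acts as a distance metric; near
#' contact it measures both position and relative orientation against the
#' bound pose.
#'
#' @param frame n x 3 coordinates of the current configuration
#'   (receptor + ligand points, same row layout as `reference`).
#' @param reference n x 3 coordinates of the bound pose.
#' @param anchors row indices of the ligand anchor points.
#' @param fit_subset row indices of the receptor points used for the
#'   superposition.
#' @return The anchor RMSD (length units).
#' @export
binding_rmsd <- function(frame, reference, anchors, fit_subset) {
  if (length(anchors) < 1) stop("anchors must be nonempty")
  fit <- kabsch_superpose(frame, reference, fit_subset)
  dev <- fit$transformed[anchors, , drop = FALSE] -
    as.matrix(reference)[anchors, , drop = FALSE]
  sqrt(mean(rowSums(dev^2)))
}

#' Minimum separation between two point sets
#'
#' The minimum over all inter-set point-pair distances.  For the analytic
#' sphere geometry of the toy model use [toy_min_separation()].
#'
#' @param a,b non-empty n x 3 coordinate matrices.
#' @return The minimum pairwise distance.
#' @export
min_separation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 1 || nrow(b) < 1) stop("point sets must be nonempty")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

#' Analytic minimum separation for the toy model
#'
#' Centre-centre distance minus the sum of the contact radii, clamped at 0.
#'
#' @inheritParams toy_pcoord
#' @return Numeric vector of separations.
#' @export
toy_min_separation <- function(state, params) {
  m <- .as_state_matrix(state)
  r <- sqrt(rowSums(m[, 1:3, drop = FALSE]^2))
  pmax(r - (params$R_rec + params$R_lig), 0)
}

#' Read reference coordinates from a whitespace-delimited xyz table
#'
#' Plain-text point tables: one point per line, three whitespace-separated
#' columns (x, y, z), optionally preceded by a point label in a first
#' column; lines starting with `#` are comments.  This is the exchange
#' format for reference structures used by the RMSD operations; a bound
#' reference pose of the toy model ships in
#' `system.file("extdata", "toy_bound_reference.xyz", package = "wepath")`.
#'
#' @param file path to the table.
#' @return An n x 3 numeric matrix, with row names when labels are present.
#' @export
read_xyz <- function(file) {
  tab <- utils::read.table(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 4) {
    m <- as.matrix(tab[, 2:4])
    rownames(m) <- tab[, 1]
  } else if (ncol(tab) == 3) {
    m <- as.matrix(tab)
  } else stop("xyz table must have 3 coordinate columns (plus optional label)")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  if (any(!is.finite(m))) stop("non-numeric coordinates in xyz table")
  m
}

#' Write an xyz coordinate table
#'
#' @param coords n x 3 numeric matrix; row names become point labels.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(coords, file) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  df <- data.frame(format(coords[, 1], digits = 12),
                   format(coords[, 2], digits = 12),
                   format(coords[, 3], digits = 12))
  if (!is.null(rownames(coords))) df <- cbind(rownames(coords), df)
  utils::write.table(df, file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

# ---- bin schemes ----------------------------------------------------------

new_bin_scheme <- function(kind, stage, ...) {
  structure(c(list(kind = kind, stage = stage), list(...)),
            class = "bin_scheme")
}

#' One-dimensional bin scheme from explicit edges
#'
#' Cells are half-open `[lo, hi)`; a value exactly on an edge belongs to the
#' upper cell; the final cell `[last edge, Inf)` is open-ended.  Values
#' below the first edge are clamped into the first cell (progress
#' coordinates are non-negative in this package; the clamp only matters for
#' generic 1-D fixtures).
#'
#' @param edges strictly increasing numeric vector; `length(edges)` cells.
#' @param stage stage tag.
#' @return A `bin_scheme`.
#' @export
bin_scheme_1d <- function(edges, stage = "preparatory") {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  new_bin_scheme("grid1d", stage, edges = edges)
}

#' The 45-bin preparatory scheme
#'
#' One-dimensional RMSD scheme used to sample unbound-state conformations:
#' bins every 0.1 from 0 to 3.0, every 0.5 from 3.0 to 10, and a single
#' open-ended bin for values >= 10 — 45 cells in total.
#'
#' @return A `bin_scheme` with 45 cells.
#' @export
preparatory_scheme <- function() {
  bin_scheme_1d(c(seq(0, 3, by = 0.1), seq(3.5, 10, by = 0.5)),
                stage = "preparatory")
}

#' Two-dimensional binding bin scheme
#'
#' The separation dimension splits configurations in van der Waals contact
#' (`min_sep < 5`) from those not in contact (`>= 5`).  Within the contact
#' cell the binding RMSD is divided into fine 0.5-unit cells on \[0, 10),
#' coarse 1-unit cells on \[10, 60), and one open-ended cell — 71 RMSD
#' cells.  Stage 1 applies the same RMSD subdivision on the non-contact
#' side (142 cells total); stage 2 merges the non-contact side into a
#' single cell (72 cells total), shifting sampling effort onto
#' rearrangements of contact configurations.
#'
#' @param stage 1 or 2.
#' @return A `bin_scheme`.
#' @export
binding_scheme <- function(stage) {
  if (!stage %in% c(1, 2)) stop("stage must be 1 or 2")
  new_bin_scheme("binding", stage = as.integer(stage), sep_split = 5,
                 rmsd_edges = c(seq(0, 9.5, by = 0.5), seq(10, 60, by = 1)))
}

#' Number of cells of a bin scheme
#'
#' @param scheme a `bin_scheme`.
#' @return Integer cell count.
#' @export
n_bins <- function(scheme) {
  switch(scheme$kind,
         grid1d = length(scheme$edges),
         binding = {
           nr <- length(scheme$rmsd_edges)  # 70 finite cells + overflow = 71
           if (scheme$stage == 1L) 2L * nr else nr + 1L
         },
         stop("unknown scheme kind"))
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("Bin scheme '%s' (stage %s): %d cells\n", x$kind,
              as.character(x$stage), n_bins(x)))
  invisible(x)
}

#' Assign progress coordinates to bin cells
#'
#' Deterministic half-open assignment: a coordinate exactly on an edge goes
#' to the upper cell; the final cell along each dimension is open-ended.
#' Cells partition the coordinate space, so every finite coordinate maps to
#' exactly one cell.
#'
#' @param pcoord numeric vector (one coordinate) or matrix (rows =
#'   walkers); 2 columns `(min_sep, binding_rmsd)` for the binding scheme.
#' @param scheme a `bin_scheme`.
#' @return Integer vector of 1-based cell indices.
#' @export
assign_bin <- function(pcoord, scheme) {
  if (!is.matrix(pcoord)) pcoord <- matrix(pcoord, nrow = 1)
  if (any(!is.finite(pcoord))) stop("NaN or non-finite progress coordinate")
  switch(scheme$kind,
         grid1d = {
           idx <- findInterval(pcoord[, 1], scheme$edges)
           pmax(idx, 1L)
         },
         binding = {
           sep <- pcoord[, 1]
           rmsd <- pcoord[, 2]
           rj <- pmax(findInterval(rmsd, scheme$rmsd_edges), 1L)
           nr <- length(scheme$rmsd_edges)
           contact <- sep < scheme$sep_split
           if (scheme$stage == 1L) {
             ifelse(contact, rj, nr + rj)
           } else {
             ifelse(contact, rj, nr + 1L)
           }
         },
         stop("unknown scheme kind"))
}
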