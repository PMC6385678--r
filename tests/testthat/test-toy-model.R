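test_that("energy reproduces the designed basin topology", {
  p <- toy_params()
  Rc <- p$R_rec + p$R_lig
  # aligned patches at the radial minimum (contact): U = -eps, U_rep = 0
  aligned <- toy_state(c(0, 0, Rc), c(0, 1, 0, 0))
  expect_equal(toy_energy(aligned, p), -p$eps)
  # beyond the cutoff the potential vanishes exactly
  expect_identical(toy_energy(toy_state(c(0, 0, p$r_cut)), p), 0)
  expect_identical(toy_energy(toy_state(c(0, 0, p$r_cut + 50)), p), 0)
  # both alignment cosines <= 0 and w_enc = 0: only the soft core remains
  p0 <- toy_params(w_enc = 0)
  anti <- toy_state(c(0, 0, -Rc + 1), c(1, 0, 0, 0))  # ligand below receptor
  r <- Rc - 1
  expect_equal(toy_energy(anti, p0), p0$k_rep * (1 - r / Rc)^2)
  # encounter shoulder: ligand at the patch, axis perpendicular
  perp <- toy_state(c(0, 0, Rc), c(cos(pi / 4), 0, sin(pi / 4), 0))
  expect_equal(toy_energy(perp, p), -p$w_enc * p$eps)
  expect_error(toy_energy(c(NA, 0, 0, 1, 0, 0, 0), p), "finite")
})

test_that("state and parameter validation enforce the invariants", {
  expect_error(toy_state(c(0, 0, 30), c(1, 0.1, 0, 0)), "norm 1")
  expect_error(toy_params(R_out = 30), "R_out")
  expect_error(toy_params(dt = -1), "dt|non-negative")
  p <- toy_params()
  expect_identical(nrow(p$anchor_points), 2L)
})

test_that("propagation is deterministic given the stream and inert at zero noise", {
  p <- toy_params(eps = 0, D_t = 0, D_r = 0)
  s <- toy_state(c(0, 0, 40))
  out <- toy_propagate(s, p, 500, seed = 3)
  expect_equal(as.numeric(out), as.numeric(s))
  p2 <- toy_params()
  st <- make_initial_ensemble(10, p2, seed = 4)
  a <- toy_propagate(st, p2, 200, seed = 9, stream_id = 1:10)
  b <- toy_propagate(st, p2, 200, seed = 9, stream_id = 1:10)
  expect_identical(a, b)
  d <- toy_propagate(st, p2, 200, seed = 10, stream_id = 1:10)
  expect_false(identical(a, d))
})

test_that("free diffusion reproduces the Einstein mean-square displacement", {
  p <- toy_params(eps = 0)
  n <- 10000
  st <- matrix(rep(c(0, 0, 40, 1, 0, 0, 0), each = n), nrow = n)
  n_steps <- 40
  out <- toy_propagate(st, p, n_steps, seed = 21, stream_id = seq_len(n))
  disp2 <- rowSums((out[, 1:3] - st[, 1:3])^2)
  expected <- 6 * p$D_t * n_steps * p$dt
  se <- sd(disp2) / sqrt(n)
  expect_lt(abs(mean(disp2) - expected), 3 * se)
})

test_that("initial ensembles satisfy the separation and orientation contracts", {
  p <- toy_params()
  ens <- make_initial_ensemble(200, p, min_sep = 20, seed = 5)
  expect_true(all(toy_min_separation(ens, p) >= 20 - 1e-12))
  expect_true(all(sqrt(rowSums(ens[, 1:3]^2)) <= p$R_out + 1e-12))
  expect_identical(make_initial_ensemble(100, p, seed = 8),
                   make_initial_ensemble(100, p, seed = 8))
  # uniform orientations: the mean rotated patch vector vanishes
  big <- make_initial_ensemble(10000, p, seed = 6)
  patch <- t(apply(big, 1, function(s) quat_rotate(s[4:7], c(0, 0, 1))))
  se <- apply(patch, 2, sd) / sqrt(nrow(patch))
  expect_true(all(abs(colMeans(patch)) < 3 * se))
  expect_error(make_initial_ensemble(5, toy_params(), min_sep = 1000),
               "infeasible")
})

test_that("shell MFPT closed form behaves as derived", {
  expect_equal(shell_mfpt_analytic(1, 5, 1, 2), 0)
  expect_equal(shell_mfpt_analytic(1, 2, 2, 1), 5 / 6)
  expect_equal(shell_mfpt_analytic(3, 30, 10, 2),
               shell_mfpt_analytic(3, 30, 10, 1) / 2)
  expect_error(shell_mfpt_analytic(5, 4, 4.5, 1), "require")
})

test_that("brute-force MFPT matches the analytic oracle and honours caps", {
  p <- toy_params(eps = 0)
  # target state already contains the start: MFPT exactly 0
  z <- brute_force_mfpt(p, list(type = "radius", b = 45), n_replicas = 10,
                        seed = 2, r0 = 41)
  expect_equal(z$mfpt, 0)
  bf <- brute_force_mfpt(p, list(type = "radius", b = 25), n_replicas = 200,
                         seed = 3, r0 = 40)
  Tan <- shell_mfpt_analytic(25, p$R_out, 40, p$D_t)
  expect_lt(abs(bf$mfpt - Tan), 3 * bf$se)
  expect_identical(bf$n_capped, 0L)
  capped <- brute_force_mfpt(p, list(type = "radius", b = 25),
                             n_replicas = 10, seed = 3, r0 = 40,
                             max_steps = 10)
  expect_identical(capped$n_events + capped$n_capped, 10L)
})

test_that("long unbiased runs sample the Boltzmann radial distribution", {
  # radial marginal: p(r) ~ r^2 < exp(-U) > over both alignment cosines
  p <- toy_params(eps = 3, D_r = 0.1)
  res <- wepath:::cpp_toy_path(c(0, 0, 35, 1, 0, 0, 0), unclass(p),
                               111, 1L, 1L, 2e6, 20L, -1, -1, -1)
  r <- res$records[, 3]
  edges <- seq(21, p$R_out, length.out = 7)
  cr <- seq(-0.9975, 0.9975, length.out = 200)
  cl <- cr
  pr_of_r <- function(rr) {
    f <- if (rr <= p$R_rec + p$R_lig) 1
    else if (rr >= p$r_cut) 0
    else {
      s <- (rr - p$R_rec - p$R_lig) / (p$r_cut - p$R_rec - p$R_lig)
      1 - s^2 * (3 - 2 * s)
    }
    g <- outer(pmax(cr, 0)^p$p_rec, pmax(cl, 0)^p$p_lig) +
      p$w_enc * outer(pmax(cr, 0)^2, 1 - cl^2)
    rr^2 * mean(exp(p$eps * f * g))
  }
  grid <- seq(edges[1], edges[7] - 1e-9, length.out = 400)
  dens <- vapply(grid, pr_of_r, 0)
  cell <- pmin(findInterval(grid, edges), 6L)
  pred <- vapply(1:6, function(b) sum(dens[cell == b]), 0)
  pred <- pred / sum(pred)
  keep <- r >= edges[1] & r < edges[7]
  obs_cell <- pmin(findInterval(r[keep], edges), 6L)
  obs <- tabulate(obs_cell, 6) / length(obs_cell)
  # blocked standard errors (samples are serially correlated)
  blk <- 500
  nb <- floor(length(obs_cell) / blk)
  se <- vapply(1:6, function(b) {
    ind <- as.numeric(obs_cell == b)[seq_len(nb * blk)]
    bm <- colMeans(matrix(ind, nrow = blk))
    sd(bm) / sqrt(nb)
  }, 0)
  expect_true(all(abs(obs - pred) < 4 * pmax(se, 1e-4)))
})

test_that("chained propagation is Markovian in distribution", {
  p <- toy_params(eps = 5)
  n <- 3000
  st <- make_initial_ensemble(n, p, seed = 12)
  one <- toy_propagate(st, p, 400, seed = 31, stream_id = seq_len(n),
                       iteration = 1)
  half <- toy_propagate(st, p, 200, seed = 32, stream_id = seq_len(n),
                        iteration = 1)
  two <- toy_propagate(half, p, 200, seed = 32, stream_id = seq_len(n),
                       iteration = 2)
  r1 <- sqrt(rowSums(one[, 1:3]^2))
  r2 <- sqrt(rowSums(two[, 1:3]^2))
  se <- sqrt(sd(r1)^2 / n + sd(r2)^2 / n)
  expect_lt(abs(mean(r1) - mean(r2)), 3 * se)
})
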