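test_that("initialization distributes weight uniformly across copies", {
  states <- matrix(rnorm(100 * 3), ncol = 3)
  w <- initialize_walkers(states, 16)
  expect_identical(length(w$weight), 1600L)
  expect_true(all(w$weight == 1 / 1600))
  expect_lt(abs(sum(w$weight) - 1), 1e-15)
  one <- initialize_walkers(matrix(0, 1, 3), 1)
  expect_identical(one$weight, 1)
  expect_error(initialize_walkers(matrix(0, 1, 3), 0), ">= 1")
})

test_that("splitting divides weight evenly and links lineage", {
  w <- list(weight = 0.3, id = 7L, state = c(1, 2), label = "U")
  kids <- split_walker(w, 3, next_id = 10L)
  expect_identical(length(kids), 3L)
  expect_equal(vapply(kids, `[[`, 0, "weight"), rep(0.1, 3))
  expect_equal(sum(vapply(kids, `[[`, 0, "weight")), 0.3)
  expect_identical(vapply(kids, `[[`, 0L, "parent"), rep(7L, 3))
  expect_identical(vapply(kids, `[[`, 0L, "id"), 10:12)
  same <- split_walker(w, 1)
  expect_identical(same[[1]]$weight, 0.3)
  expect_error(split_walker(w, 0), ">= 1")
})

test_that("merging conserves weight and selects survivors proportionally", {
  w1 <- list(weight = 0.2, id = 1L, bin = 3L)
  w2 <- list(weight = 0.3, id = 2L, bin = 3L)
  set.seed(1)
  m <- merge_pair(w1, w2)
  expect_equal(m$weight, 0.5)
  expect_error(merge_pair(w1, list(weight = 0.3, bin = 4L)), "different bins")
  expect_error(merge_pair(w1, list(weight = 0, bin = 3L)), "positive")
  set.seed(42)
  surv1 <- vapply(seq_len(10000), function(i)
    merge_pair(w1, w2)$id == 1L, TRUE)
  expect_lt(abs(mean(surv1) - 0.4), 0.015)
})

test_that("resampling reaches targets with exact weight conservation", {
  set.seed(2)
  mk <- function(n, pcoords) {
    w <- initialize_walkers(matrix(rnorm(n), ncol = 1), 1)
    w$pcoord <- matrix(pcoords, ncol = 1)
    w
  }
  sch <- bin_scheme_1d(c(0, 1, 2))
  pol <- we_policy("per_bin_target", target = 12L)
  # one walker in one bin: split up to 12
  w <- mk(1, 0.5)
  r <- resample(w, sch, pol)
  expect_identical(length(r$walkers$weight), 12L)
  expect_equal(sum(r$walkers$weight), 1)
  expect_identical(r$n_split, 11L)
  # 20 walkers in one bin: 8 pairwise merges down to 12
  w <- mk(20, rep(0.5, 20))
  r <- resample(w, sch, pol)
  expect_identical(length(r$walkers$weight), 12L)
  expect_identical(r$n_merge, 8L)
  expect_equal(sum(r$walkers$weight), 1)
  # fixed_total: global count met exactly, error when unreachable
  w <- mk(9, c(rep(0.5, 3), rep(1.5, 6)))
  rt <- resample(w, sch, we_policy("fixed_total", total = 10L))
  expect_identical(length(rt$walkers$weight), 10L)
  expect_error(resample(w, sch, we_policy("fixed_total", total = 1L)),
               "occupied")
})

test_that("resampling preserves weighted observables (exactly under splits, in expectation under merges)", {
  sch <- bin_scheme_1d(c(0))
  pol <- we_policy("per_bin_target", target = 4L)
  set.seed(3)
  w <- initialize_walkers(matrix(rnorm(10), ncol = 1), 1)
  w$weight <- w$weight * c(3, 2, 1, 1, 0.5, 0.5, 1, 0.5, 0.25, 0.25) / 1
  w$weight <- w$weight / sum(w$weight)
  w$pcoord <- matrix(rep(0.5, 10), ncol = 1)
  truth <- sum(w$weight * w$state[, 1])
  est <- replicate(10000, {
    r <- resample(w, sch, pol)
    sum(r$walkers$weight * r$walkers$state[, 1])
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
  # splitting alone is exact: a single-walker bin only splits
  w1 <- initialize_walkers(matrix(2.5, 1, 1), 1)
  w1$pcoord <- matrix(0.5, 1, 1)
  r1 <- resample(w1, sch, pol)
  expect_equal(sum(r1$walkers$weight * r1$walkers$state[, 1]), 2.5)
})

test_that("run_iteration with an identity propagator enforces targets and conserves weight", {
  prop <- identity_propagator(pdim = 2L)
  init <- cbind(runif(5, 21, 25), runif(5, 30, 40))
  w <- initialize_walkers(init, 1)
  w$pcoord <- prop$pcoord(w$state)
  w$scode <- wepath:::.assign_code(w$pcoord, state_defs())
  set.seed(9)
  out <- run_iteration(w, prop, 1L, binding_scheme(1),
                       we_policy("per_bin_target", target = 3L),
                       defs = state_defs(), next_id = 6L)
  expect_equal(out$record$pcoord, w$pcoord)      # identity dynamics
  expect_identical(sum(out$record$entry != 0L), 0L)
  expect_equal(sum(out$record$arrive), 0)
  expect_equal(sum(out$walkers$weight), 1, tolerance = 1e-12)
  # every occupied bin reached its target of 3
  expect_true(all(table(assign_bin(out$walkers$pcoord,
                                   binding_scheme(1))) == 3))
})

test_that("arrivals are recorded exactly once per crossing", {
  # scripted walker: U -> encounter -> bound -> bound
  tab <- rbind(c(25, 40), c(2, 10), c(2, 3), c(2, 3))
  run <- run_scripted(tab)
  arrB <- vapply(run$records, function(r) r$arrive["U", "bound"], 0)
  expect_equal(arrB, c(0, 1, 0))
  arrE <- vapply(run$records, function(r) r$arrive["U", "encounter"], 0)
  expect_equal(arrE, c(1, 0, 0))
  # two simultaneous arrivals sum linearly
  run2 <- run_scripted(tab, n_walkers = 2L)
  arrB2 <- vapply(run2$records, function(r) r$arrive["U", "bound"], 0)
  expect_equal(arrB2, c(0, 1, 0))
})

test_that("weight is conserved to 1e-12 across hundreds of iterations", {
  p <- toy_params()
  run <- run_we(toy_propagator(p), make_initial_ensemble(8, p, seed = 4),
                n_iter = 120, tau_steps = 20, tau = 1,
                scheme = binding_scheme(1),
                policy = we_policy("fixed_total", total = 50),
                defs = state_defs(), copies_per_state = 4, seed = 4)
  expect_lt(max(run$weight_err), 1e-12)
  expect_identical(length(run$final$weight), 50L)
})

test_that("scheme switching changes only bin assignments", {
  p <- toy_params()
  prop <- toy_propagator(p)
  w <- initialize_walkers(make_initial_ensemble(30, p, seed = 6), 1)
  w$pcoord <- prop$pcoord(w$state)
  before <- w$weight
  sw <- switch_scheme(w, binding_scheme(2))
  expect_identical(sw$weight, before)
  expect_identical(length(sw$weight), length(before))
  expect_identical(sw$bin, assign_bin(w$pcoord, binding_scheme(2)))
})

test_that("stage switch shifts sampling effort toward the contact region", {
  # 4 contact walkers in distinct RMSD cells, 16 non-contact walkers in
  # distinct cells; fixed total 20
  pc <- rbind(cbind(rep(1, 4), c(0.2, 1.2, 2.2, 3.2)),
              cbind(rep(9, 16), seq(21, 51, by = 2)))
  w <- initialize_walkers(matrix(seq_len(20), ncol = 1), 1)
  w$pcoord <- pc
  pol <- we_policy("fixed_total", total = 20L)
  set.seed(10)
  r1 <- resample(w, binding_scheme(1), pol)
  n_contact_1 <- sum(r1$walkers$pcoord[, 1] < 5)
  r2 <- resample(w, binding_scheme(2), pol)
  n_contact_2 <- sum(r2$walkers$pcoord[, 1] < 5)
  expect_gt(n_contact_2, n_contact_1)
  expect_identical(length(r2$walkers$weight), 20L)
})

test_that("lineages trace back to initial walkers", {
  p <- toy_params()
  run <- run_we(toy_propagator(p), make_initial_ensemble(6, p, seed = 7),
                n_iter = 40, tau_steps = 20, tau = 1,
                scheme = binding_scheme(1),
                policy = we_policy("per_bin_target", target = 3L),
                defs = state_defs(), copies_per_state = 2, seed = 7)
  # walk a final walker's ancestry back through every record
  n_rec <- length(run$records)
  idx <- seq_along(run$records[[n_rec]]$weight)
  for (j in idx) {
    k <- n_rec
    i <- j
    while (k > 1) {
      i <- run$records[[k]]$parent[i]
      expect_false(is.na(i))
      k <- k - 1
    }
    expect_true(run$records[[1]]$root[i] %in% 1:6)
  }
})
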