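test_that("transition paths span last unbound exit to first bound entry", {
  # U -> E -> B: path is the encounter frame plus the first bound frame
  run <- run_scripted(rbind(c(25, 40), c(2, 10), c(2, 3)))
  tpe <- extract_tpe(run)
  expect_identical(length(tpe), 1L)
  expect_identical(nrow(tpe[[1]]$frames), 2L)
  expect_equal(tpe[[1]]$frames[, "binding_rmsd"], c(10, 3))
  expect_equal(tpe[[1]]$weight, 1)
  expect_equal(tpe[[1]]$duration, 2 * run$tau)
  expect_equal(tpe[[1]]$frames[, "encounter"], c(1, 0))
  # U -> E -> U -> E -> B: the path starts after the *last* unbound exit
  run2 <- run_scripted(rbind(c(25, 40), c(2, 10), c(25, 40), c(2, 10),
                             c(2, 3)))
  tpe2 <- extract_tpe(run2)
  expect_identical(length(tpe2), 1L)
  expect_identical(nrow(tpe2[[1]]$frames), 2L)
  expect_equal(tpe2[[1]]$frames[, "iteration"], c(3, 4))
  # a lineage that never binds contributes nothing
  run3 <- run_scripted(rbind(c(25, 40), c(2, 10), c(25, 40)))
  expect_identical(length(extract_tpe(run3)), 0L)
})

test_that("TPE weight never exceeds the total bound-arrival weight", {
  p <- toy_params()
  run <- run_we(toy_propagator(p), make_initial_ensemble(10, p, seed = 3),
                n_iter = 150, tau_steps = 100, tau = 5,
                scheme = binding_scheme(1),
                policy = we_policy("fixed_total", total = 60),
                defs = state_defs(), copies_per_state = 4, seed = 3)
  arr <- sum(vapply(run$records, function(r) r$arrive["U", "bound"], 0))
  tpe <- extract_tpe(run)
  expect_gt(length(tpe), 0L)
  expect_lte(sum(vapply(tpe, `[[`, 0, "weight")), arr + 1e-12)
})

test_that("event durations histogram conserves mass and finds the mode", {
  paths <- structure(lapply(list(c(5, 0.2), c(5, 0.5), c(2, 0.3)),
                            function(dw) list(frames = matrix(0, dw[1], 5),
                                              duration = dw[1] * 20,
                                              weight = dw[2], root = 1)),
                     class = "tpe")
  ed <- event_durations(paths, bin_width = 20)
  expect_equal(sum(ed$mass), 1.0)
  expect_equal(ed$mode, 110)  # cell [100, 120) holds weight 0.7
  expect_equal(ed$durations, c(100, 100, 40))
  expect_error(event_durations(structure(list(), class = "tpe")), "empty")
})

test_that("contact probabilities are weighted frame fractions", {
  d <- rbind(c(3, 6), c(4, 4), c(5, 2))
  w <- c(0.2, 0.3, 0.5)
  pr <- weighted_contact_probabilities(d, w, cutoff = 4.5)
  expect_equal(as.numeric(pr), c(0.5, 0.8))
  expect_equal(as.numeric(weighted_contact_probabilities(d, w, cutoff = 10)),
               c(1, 1))
  expect_equal(as.numeric(weighted_contact_probabilities(d, w, cutoff = 1)),
               c(0, 0))
  expect_error(weighted_contact_probabilities(d, w, cutoff = 0), "> 0")
})

test_that("histogram entropy has the closed-form values", {
  expect_equal(histogram_entropy(rep(1.7, 50), n_bins = 20), 0)
  # uniform over k cells: exactly R ln k
  k <- 16
  x <- rep(seq_len(k), each = 10) + 0.0001
  expect_equal(histogram_entropy(x, n_bins = k), log(k), tolerance = 1e-12)
  two <- histogram_entropy(c(0.1, 0.9), weights = c(0.25, 0.75), n_bins = 2)
  expect_equal(two, 0.5623, tolerance = 1e-4)
  # invariant under sample permutation and uniform weight rescaling
  set.seed(2)
  y <- rnorm(500)
  w <- runif(500)
  s1 <- histogram_entropy(y, w, n_bins = 25)
  prm <- sample(500)
  expect_equal(histogram_entropy(y[prm], w[prm], n_bins = 25), s1)
  expect_equal(histogram_entropy(y, 7 * w, n_bins = 25), s1)
  # joint multi-dimensional histogram
  m <- cbind(rep(1:3, 4) + 0.001, rep(1:4, 3) + 0.001)
  expect_gt(histogram_entropy(m, n_bins = 4), histogram_entropy(m[, 1],
                                                                n_bins = 4))
})

test_that("Canberra distance follows the defining sum", {
  expect_equal(canberra(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(canberra(c(1, 0), c(0, 1)), 2)
  expect_equal(canberra(c(0, 0), c(0, 0)), 0)  # 0/0 terms are 0
  set.seed(6)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(canberra(u, v), canberra(v, u))
  expect_equal(canberra(u, v), sum(abs(u - v) / (abs(u) + abs(v))))
  expect_error(canberra(1:3, 1:4), "equal length")
})

test_that("k-centers is deterministic, exact in the limits, and 2-approximate", {
  X <- cloud2d(30, seed = 4)
  all_c <- kcenters(X, 30, seed_index = 3)
  expect_equal(all_c$radius, 0)
  one <- kcenters(X, 1, seed_index = 5)
  expect_identical(one$centers, 5L)
  expect_equal(one$radius,
               max(sqrt(rowSums(sweep(X, 2, X[5, ])^2))))
  expect_error(kcenters(X, 31), "exceed")
  expect_identical(kcenters(X, 6, seed_index = 2)$centers,
                   kcenters(X, 6, seed_index = 2)$centers)
  # Canberra metric variant is self-consistent with the scalar function
  kc <- kcenters(abs(X) + 0.1, 4, metric = "canberra", seed_index = 1)
  i <- 17
  dists <- vapply(kc$centers, function(cc)
    canberra(abs(X[i, ]) + 0.1, abs(X[cc, ]) + 0.1), 0)
  expect_identical(kc$assignment[i], which.min(dists))
})

test_that("conformation space networks aggregate weights and transitions", {
  asg <- c(1, 1, 2, 3, 2, 2)
  wt <- c(0.1, 0.1, 0.2, 0.2, 0.2, 0.2)
  prop <- c(0, 1, 2, 3, 4, 5)
  g <- build_csn(asg, wt, property = prop)
  expect_equal(sum(g$nodes$weight), sum(wt))
  expect_equal(g$nodes$weight[g$nodes$cluster == 2], 0.6)
  expect_equal(g$nodes$property[g$nodes$cluster == 1], 0.5)
  # hand-enumerated edges: 1->2, 2->3, 3->2 (2->2 is not an edge)
  key <- paste(g$edges$from, g$edges$to)
  expect_setequal(key, c("1 2", "2 3", "3 2"))
  expect_equal(g$edges$weight[key == "1 2"], 0.2)
  single <- build_csn(rep(1, 4), rep(0.25, 4))
  expect_identical(nrow(single$edges), 0L)
  # transitions never cross trajectory boundaries: the 2 -> 1 step between
  # frames 2 and 3 spans two trajectories and is not an edge
  g2 <- build_csn(c(1, 2, 1, 2), rep(0.25, 4), traj = c(1, 1, 2, 2))
  expect_identical(nrow(g2$edges), 1L)
  expect_identical(g2$edges$count, 2L)
  expect_identical(c(g2$edges$from, g2$edges$to), c(1, 2))
})

test_that("spherical entry maps normalize and respect solid angles", {
  pole <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
  m <- spherical_entry_map(pole, n_bins = 30)
  expect_equal(sum(m$prob), 1)
  expect_identical(sum(m$prob > 0), 1L)
  expect_equal(sum(m$solid_angle), 4 * pi, tolerance = 1e-9)
  expect_error(spherical_entry_map(rbind(c(0, 0, 0))), "zero")
  # uniform directions: cell mass proportional to solid angle within 3 sigma
  set.seed(9)
  n <- 100000
  u <- matrix(rnorm(3 * n), ncol = 3)
  mu <- spherical_entry_map(u, n_bins = 30)
  p0 <- mu$solid_angle / (4 * pi)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(mu$prob - p0) < 4 * se))
})
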