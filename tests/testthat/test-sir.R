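test_that("degenerate transmission probabilities behave exactly", {
  cs <- contact_sequence(c("a", "b"), c("b", "c"), c(1, 2))
  # lambda = 0: nobody but the seed
  expect_equal(run_outbreak(cs, "a", 0, 100), 1)
  eo <- expected_outbreak(cs, "a", 0, 100, n_runs = 50)
  expect_equal(eo$mean, 1)
  expect_equal(eo$se, 0)
  # lambda = 1, delta > T: the full chain is reached
  expect_equal(run_outbreak(cs, "a", 1, 100), 3)
  # the chain only runs forward in time
  expect_equal(run_outbreak(cs, "c", 1, 100), 2)
  expect_error(run_outbreak(cs, "zz", 1, 100), "unknown vertex")
})

test_that("the seed's own first contact can transmit", {
  cs <- contact_sequence("a", "b", 5)
  expect_equal(run_outbreak(cs, "a", 1, 10), 2)
  expect_equal(run_outbreak(cs, "b", 1, 10), 2)
})

test_that("recovery boundary is half-open: contact at t0 + delta misses", {
  cs <- contact_sequence(c("a", "a"), c("b", "c"), c(0, 4))
  expect_equal(run_outbreak(cs, "a", 1, delta = 4), 2)    # t = 4 not < 0 + 4
  expect_equal(run_outbreak(cs, "a", 1, delta = 4.5), 3)
})

test_that("deterministic SIR equals temporal reachability on random fixtures", {
  set.seed(31)
  for (rep in 1:100) {
    cs <- random_cs(n_vertices = sample(5:50, 1),
                    n_contacts = sample(10:80, 1),
                    distinct_times = TRUE)
    seed_v <- sample(vertex_labels(cs), 1)
    got <- run_outbreak(cs, seed_v, 1, sampling_time(cs) + 1)
    expect_equal(got, oracle_reach_size(cs, seed_v))
  }
})

test_that("Monte-Carlo mean matches exact enumeration on tiny fixtures", {
  set.seed(32)
  # the hand-checkable chain: 1 + lambda + lambda^2 at lambda = 1/2
  chain <- contact_sequence(c("a", "b"), c("b", "c"), c(1, 2))
  expect_equal(oracle_expected_size(chain, "a", 0.5, 100), 1.75)
  eo <- expected_outbreak(chain, "a", 0.5, 100, n_runs = 4000)
  expect_lt(abs(eo$mean - 1.75), 3 * eo$se + 1e-9)

  # random tiny fixtures, including simultaneous contacts
  for (rep in 1:12) {
    cs <- random_cs(n_vertices = 5, n_contacts = 6, t_max = 4)
    seed_v <- sample(vertex_labels(cs), 1)
    lam <- runif(1, 0.2, 0.9)
    delta <- runif(1, 1, sampling_time(cs) + 2)
    exact <- oracle_expected_size(cs, seed_v, lam, delta)
    eo <- expected_outbreak(cs, seed_v, lam, delta, n_runs = 3000)
    expect_lt(abs(eo$mean - exact), 3 * eo$se + 0.02)
  }
})

test_that("importance table covers all seeds and is reproducible", {
  set.seed(33)
  cs <- random_cs(n_vertices = 12, n_contacts = 120, t_max = 80)
  imp1 <- importance_table(cs, 0.4, sampling_time(cs) / 3, n_runs = 50,
                           rng_seed = 99)
  imp2 <- importance_table(cs, 0.4, sampling_time(cs) / 3, n_runs = 50,
                           rng_seed = 99)
  expect_identical(imp1, imp2)
  expect_setequal(imp1$vertex, vertex_labels(cs))
  expect_true(all(imp1$sigma >= 1 & imp1$sigma <= n_vertices(cs)))
  # lambda = 0: every seed scores exactly 1
  imp0 <- importance_table(cs, 0, 10, n_runs = 5)
  expect_true(all(imp0$sigma == 1))
})

test_that("star-in-time fixture ranks the center first", {
  # center c meets each leaf once, in time order; lambda = 1, delta > T
  leaves <- paste0("l", 1:6)
  cs <- contact_sequence(rep("c", 6), leaves, 1:6)
  imp <- importance_table(cs, 1, 100, n_runs = 3)
  expect_equal(imp$sigma[imp$vertex == "c"], 7)
  expect_equal(imp$sigma[imp$vertex == "l6"], 2)   # last leaf: itself + center
  expect_equal(imp$sigma[imp$vertex == "l1"], 7)   # first leaf infects all
})

test_that("permuting vertex labels permutes the importance table", {
  set.seed(34)
  rows <- random_rows(n_vertices = 8, n_contacts = 60, t_max = 40)
  cs <- contact_sequence(rows$i, rows$j, rows$t)
  cs2 <- contact_sequence(paste0("x", rows$i), paste0("x", rows$j), rows$t)
  imp1 <- importance_table(cs, 0.5, 20, n_runs = 400, rng_seed = 5)
  imp2 <- importance_table(cs2, 0.5, 20, n_runs = 400, rng_seed = 5)
  m <- match(paste0("x", imp1$vertex), imp2$vertex)
  expect_equal(imp1$sigma, imp2$sigma[m], tolerance = 0.15)
})

test_that("mean outbreak size is monotone in lambda and delta", {
  set.seed(35)
  cs <- random_cs(n_vertices = 20, n_contacts = 300, t_max = 150)
  ms <- function(lam, del) {
    imp <- importance_table(cs, lam, del, n_runs = 200, rng_seed = 77)
    mean(imp$sigma)
  }
  T_ <- sampling_time(cs)
  expect_lte(ms(0.2, T_ / 4), ms(0.6, T_ / 4))
  expect_lte(ms(0.6, T_ / 4), ms(1.0, T_ / 4))
  expect_lte(ms(0.5, T_ / 8), ms(0.5, T_ / 2))
})

test_that("lambda calibration hits its target and trivial fixed point", {
  set.seed(36)
  cs <- random_cs(n_vertices = 25, n_contacts = 400, t_max = 200)
  # target_fraction = 1 is attained at lambda = 1
  expect_equal(as.numeric(calibrate_lambda(cs, target_fraction = 1,
                                           n_runs = 20, rng_seed = 1)), 1)
  lam <- calibrate_lambda(cs, target_fraction = 0.4, n_runs = 150,
                          rng_seed = 2)
  expect_lt(abs(attr(lam, "achieved") - 0.4), 0.011)
  # recomputing at the returned lambda reproduces the target
  delta <- sampling_time(cs) / 5
  imp <- importance_table(cs, as.numeric(lam), delta, n_runs = 300,
                          rng_seed = 3)
  expect_lt(abs(mean(imp$sigma) / attr(lam, "reference") - 0.4), 0.05)
})

test_that("calibration on a closed-form toy inverts exactly", {
  # two vertices, one contact: mean size over both seeds is 1 + lambda,
  # reference (lambda = 1) is 2, so fraction f needs lambda = 2 f - 1
  cs <- contact_sequence("a", "b", 0)
  lam <- calibrate_lambda(cs, delta = 100, target_fraction = 0.75,
                          n_runs = 4000, tol = 0.01, rng_seed = 4)
  expect_lt(abs(as.numeric(lam) - 0.5), 0.06)
  # unreachable target: mean size cannot drop below 1 (half the reference)
  expect_error(calibrate_lambda(cs, delta = 100, target_fraction = 0.2,
                                n_runs = 100, rng_seed = 5),
               "calibration failure")
})
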