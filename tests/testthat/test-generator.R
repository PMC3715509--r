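test_that("degree sampling: support, degenerate case, and mean vs pmf", {
  set.seed(51)
  expect_true(all(sample_degrees(100, 2.2, 3, 3) == 3))
  d <- sample_degrees(20000, 2.2, 1, 4999)
  expect_true(all(d >= 1 & d <= 4999))
  # pmf normalizes and its mean matches the empirical mean within 3 se
  k <- 1:4999
  p <- degree_pmf(k, 2.2, 1, 4999)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  mu <- sum(k * p)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 3 * se)
  expect_error(sample_degrees(10, 2.2, 5, 2), "support")
})

test_that("stub matching: trivial pairing and realized <= requested", {
  set.seed(52)
  g <- configuration_model(c(1, 1, 0, 0))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(attr(g, "leftover_stubs"), 0)

  deg <- sample_degrees(2000, 2.2, 1, 1999)
  g <- configuration_model(deg)
  expect_true(igraph::is_simple(g))
  realized <- unname(net_degree(g)[as.character(seq_along(deg))])
  expect_true(all(realized <= deg))
  # the bulk of stubs is matched; the heavy-tailed hubs shed the rest
  # (a vertex drawing a near-maximal degree cannot place all its stubs
  # without multi-edges, so a few percent of stubs typically die)
  expect_lt(attr(g, "leftover_stubs") / sum(deg), 0.2)
  expect_equal(sum(deg) - attr(g, "leftover_stubs"),
               2 * igraph::ecount(g))
})

test_that("activity intervals: duration, confinement, uniform starts", {
  set.seed(53)
  iv <- assign_intervals(10, 1, 1000)
  expect_true(all(iv$start == 0 & iv$end == 1000))
  iv <- assign_intervals(10000, 0.25, 1000)
  expect_equal(iv$end - iv$start, rep(250, 10000))
  expect_true(all(iv$start >= 0 & iv$end <= 1000))
  # starts uniform on [0, 750]: coarse chi-square on deciles
  h <- table(cut(iv$start, seq(0, 750, length.out = 11)))
  expect_gt(stats::chisq.test(h)$p.value, 1e-4)
})

test_that("interevent draws respect support and the tail exponent", {
  set.seed(54)
  expect_true(all(sample_interevents(50, 2, 7, 7) == 7))
  x <- sample_interevents(2e5, 2, 1, 10000)
  expect_true(all(x >= 1 & x <= 10000))
  # log-log slope of the pmf over the first decades is about -beta
  cnt <- table(x[x <= 100])
  kk <- as.numeric(names(cnt))
  fit <- stats::lm(log(as.numeric(cnt)) ~ log(kk))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 2), 0.3)
})

test_that("generated sequences honor the contact budget and intervals", {
  set.seed(55)
  cfg <- synthetic_config(N = 150, k_max = 149, mu = 0.4, T_total = 20000)
  cs <- generate_contacts(cfg, rng_seed = 10)
  expect_equal(n_contacts(cs) / n_pairs(cs), cfg$contacts_per_edge)
  expect_lte(sampling_time(cs), cfg$T_total)
  # accumulated degrees equal the realized configuration-model degrees
  g <- attr(cs, "graph")
  acc <- accumulated(cs)
  nz <- names(which(net_degree(g) > 0))
  expect_setequal(igraph::V(acc)$name, nz)
  expect_equal(net_degree(acc)[nz], net_degree(g)[nz])
})

test_that("contacts are confined to their edge's activity interval", {
  # with interval duration mu * T, no pair's contacts can span more than
  # that (plus rounding), and nothing can fall outside [0, T]
  set.seed(56)
  cfg <- synthetic_config(N = 60, k_max = 59, mu = 0.3, T_total = 5000)
  cs <- generate_contacts(cfg, rng_seed = 20)
  df <- contacts(cs)
  expect_true(all(df$t >= 0 & df$t <= cfg$T_total))
  key <- paste(df$i, df$j)
  span <- tapply(df$t, key, function(tt) diff(range(tt)))
  expect_true(all(span <= cfg$mu * cfg$T_total + 1))
})

test_that("generation is deterministic given its seed", {
  cfg <- synthetic_config(N = 80, k_max = 79, mu = 0.6, T_total = 8000)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_contacts(generate_contacts(cfg, rng_seed = 77), f1)
  write_contacts(generate_contacts(cfg, rng_seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mu = 1 with many contacts per edge merges ongoing and time-slice", {
  # generous settings: many contacts per edge and a small maximal gap, so
  # no interior window can fall inside a single interevent gap
  set.seed(58)
  cfg <- synthetic_config(N = 60, k_max = 59, mu = 1,
                          contacts_per_edge = 100,
                          delta_max = 20, T_total = 20000)
  cs <- generate_contacts(cfg, rng_seed = 30)
  T_ <- sampling_time(cs)
  ts <- edge_key(time_slice(cs, 0.4 * T_, 0.6 * T_))
  on <- edge_key(ongoing(cs, 0.4 * T_, 0.6 * T_))
  acc <- edge_key(accumulated(cs))
  # both collapse onto the accumulated edge set for interior windows
  expect_identical(ts, acc)
  expect_identical(on, acc)
})

test_that("larger mu means more overlap between activity intervals", {
  set.seed(59)
  mean_overlap <- function(mu) {
    iv <- assign_intervals(400, mu, 10000)
    idx <- cbind(sample.int(400, 2000, TRUE), sample.int(400, 2000, TRUE))
    ov <- pmax(0, pmin(iv$end[idx[, 1]], iv$end[idx[, 2]]) -
                    pmax(iv$start[idx[, 1]], iv$start[idx[, 2]]))
    mean(ov)
  }
  o <- vapply(c(0.2, 0.5, 1.0), mean_overlap, numeric(1))
  expect_true(all(diff(o) > 0))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(gamma = 1), "exceed 1")
  expect_error(synthetic_config(mu = 0), "mu")
  expect_error(synthetic_config(k_min = 0), "k_min")
  expect_error(synthetic_config(N = 100, k_max = 100), "k_min")
})
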