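test_that("dynamic generation is seed-deterministic and slot-independent", {
  co <- sample_latent(s1_params(60, 0.5, 0.5, seed = 1))
  tn1 <- generate_dynamic_s1(co, rep(0.5, 50), seed = 2)
  tn2 <- generate_dynamic_s1(co, rep(0.5, 50), seed = 2)
  expect_identical(tn1$edges_by_slot, tn2$edges_by_slot)
  # tau = 1 reduces to a single snapshot
  tn3 <- generate_dynamic_s1(co, 0.5, seed = 3)
  expect_equal(tn3$n_slots, 1L)
  expect_error(generate_dynamic_s1(co, numeric(0)), "nonempty")
})

test_that("heterogeneous per-slot degrees track their prescription", {
  co <- sample_latent(s1_params(300, 1, 0.5, seed = 4))
  kt <- rep(c(0.2, 2), each = 100)
  tn <- generate_dynamic_s1(co, kt, seed = 5)
  realized <- vapply(tn$edges_by_slot, nrow, 0L) * 2 / 300
  expect_equal(mean(realized[1:100]), 0.2, tolerance = 0.15)
  expect_equal(mean(realized[101:200]), 2, tolerance = 0.1)
})

test_that("aggregation is the union over the window and idempotent in density", {
  tn <- fix_toy3()
  g <- aggregate_network(tn)
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(2L, 3L)))
  g1 <- aggregate_network(tn, 1L)
  expect_equal(unname(g1$edges), cbind(1L, 2L))
  # disjoint windows union to the full aggregate
  ga <- aggregate_network(tn, 1:2); gb <- aggregate_network(tn, 3L)
  expect_setequal(hyperprox:::pair_key(g$edges[, 1], g$edges[, 2], 3),
                  union(hyperprox:::pair_key(ga$edges[, 1], ga$edges[, 2], 3),
                        hyperprox:::pair_key(gb$edges[, 1], gb$edges[, 2], 3)))
  expect_error(aggregate_network(tn, integer(0)), "empty")
  # density is non-decreasing in the window length
  ft <- fix_temporal()
  dens <- vapply(c(50, 200, 600), function(tau)
    graph_density(aggregate_network(ft$tn, seq_len(tau))), 0)
  expect_true(all(diff(dens) >= 0))
})

test_that("density matches 2L / N(N-1)", {
  g4 <- aggregated_graph(t(utils::combn(4, 2)), 4)
  expect_equal(graph_density(g4), 1)
  expect_equal(graph_density(aggregated_graph(matrix(0L, 0, 2), 5)), 0)
  expect_equal(2 * 2000 / (242 * 241), 0.0685847, tolerance = 1e-6)
  expect_error(graph_density(aggregated_graph(matrix(0L, 0, 2), 1)), "2 nodes")
})

test_that("aggregated probabilities: exact, limiting, and alpha", {
  expect_equal(aggregated_probability_exact(2, 0.4, 1),
               connection_probability(2, 0.4))
  expect_equal(aggregated_probability_exact(1, 0.5, 2), 0.75)
  expect_equal(aggregated_probability_exact(0, 0.5, 17), 1)
  for (T in c(0.2, 0.5, 0.8))
    expect_equal(aggregated_probability_theory(gamma(1 + T), T), 1 - exp(-1))
  expect_equal(aggregated_probability_theory(1e-9, 0.5), 1)
  # large-distance power-law form
  T <- 0.5; C <- gamma(1 + T)^(1 / T)
  expect_lt(abs(aggregated_probability_theory(10, T) - C / 100) / (C / 100),
            0.05)
  expect_equal(alpha_factor(10000, 0.5), 112.8379, tolerance = 1e-4)
  expect_true(all(diff(alpha_factor(c(10, 100, 1000), 0.3)) > 0))
  # Gamma(1+T) bounds keep alpha within (tau^T, tau^T / 0.88)
  Ts <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(gamma(1 + Ts) > 0.88 & gamma(1 + Ts) < 1))
  expect_error(aggregated_probability_exact(1, 0.5, 0), "tau")
  expect_error(aggregated_probability_theory(0, 0.5), "positive")
})

test_that("contact and intercontact durations follow the run/gap definitions", {
  # pair connected in slots {1,2,3} of 5: one contact of duration 3
  tn <- temporal_network(list(cbind(1L, 2L), cbind(1L, 2L), cbind(1L, 2L),
                              NULL, NULL), 2L)
  expect_equal(contact_durations(tn), 3L)
  expect_equal(intercontact_durations(tn), integer(0))
  # pair connected in slots {1, 4}: gap of 2 (slots 2-3)
  tn2 <- temporal_network(list(cbind(1L, 2L), NULL, NULL, cbind(1L, 2L)), 2L)
  expect_equal(contact_durations(tn2), c(1L, 1L))
  expect_equal(intercontact_durations(tn2), 2L)
  # censored boundary gaps are excluded
  tn3 <- temporal_network(list(NULL, cbind(1L, 2L), NULL), 2L)
  expect_equal(intercontact_durations(tn3), integer(0))
  # conservation: contact durations sum to the total connected-slot count
  ft <- fix_temporal()
  expect_equal(sum(contact_durations(ft$tn)),
               sum(vapply(ft$tn$edges_by_slot, nrow, 0L)))
})

test_that("the per-pair fast path matches the slot-by-slot law", {
  # same coordinates, constant degree: aggregate degree and contact counts
  # from both code paths agree in distribution (compare means)
  co <- sample_latent(s1_params(150, 1, 0.5, seed = 6))
  tn_fast <- generate_dynamic_s1(co, rep(1, 300), seed = 7)
  tn_slow <- generate_dynamic_s1(co, rep(1, 300) + rep(c(0, 1e-12), 150),
                                 seed = 7)  # distinct values force slot path
  m1 <- mean(aggregated_degrees(aggregate_network(tn_fast)))
  m2 <- mean(aggregated_degrees(aggregate_network(tn_slow)))
  expect_equal(m1, m2, tolerance = 0.08)
  c1 <- sum(vapply(tn_fast$edges_by_slot, nrow, 0L))
  c2 <- sum(vapply(tn_slow$edges_by_slot, nrow, 0L))
  expect_equal(c1, c2, tolerance = 0.05)
})

test_that("discrete power-law MLE recovers known exponents", {
  n <- 2e4
  for (a in c(1.5, 2.5)) {
    # exact inverse-CDF sampling from the zeta distribution (truncated far
    # into the tail; the cut mass is < 0.1% for both exponents)
    kmax <- 1e6
    pmf <- (1:kmax)^(-a)
    cdf <- cumsum(pmf / sum(pmf))
    x <- with_seed(8, findInterval(runif(n), cdf) + 1L)
    expect_equal(fit_powerlaw_discrete(x), a, tolerance = 0.1)
  }
  expect_error(fit_powerlaw_discrete(1:5), "too few")
})

test_that("counterpart construction extracts per-node activity", {
  tn <- temporal_network(rep(list(rbind(c(1L, 2L), c(1L, 3L))), 10), 4L)
  spec <- build_counterpart(tn)
  expect_equal(spec$kappa, c(2, 1, 1, 0))
  expect_equal(spec$zero_activity, 4L)
  expect_equal(spec$mean_degrees, rep(1, 10))
})

test_that("temperature calibration recovers the generating temperature", {
  co <- sample_latent(s1_params(200, 0.4, 0.6, seed = 9))
  tn <- generate_dynamic_s1(co, rep(0.4, 800), seed = 10)
  spec <- build_counterpart(tn)
  target <- mean(aggregated_degrees(aggregate_network(tn)))
  Tcal <- calibrate_temperature(spec, target)
  expect_lt(abs(Tcal - 0.6), 0.05)
  expect_error(calibrate_temperature(spec, 199.5), "N-1")
})
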