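test_that("angular distance is the modular circle distance", {
  expect_equal(angular_distance(0.7, 0.7), 0)
  expect_equal(angular_distance(0, pi), pi)
  expect_equal(angular_distance(0.5, 2 * pi - 0.5), 1.0)
  # symmetric, bounded, accepts unreduced input
  a <- c(-5, 0.3, 12.6, 2 * pi); b <- c(1.1, 6.9, -0.4, pi)
  expect_equal(angular_distance(a, b), angular_distance(b, a))
  expect_true(all(angular_distance(a, b) >= 0 &
                  angular_distance(a, b) <= pi))
  expect_error(angular_distance(NaN, 1), "finite")
})

test_that("mu calibration follows the closed form and is linear in k-bar", {
  expect_equal(compute_mu(10, 10, 0.5), 0.031831, tolerance = 1e-4)
  expect_equal(compute_mu(1, 1, 0.5), 1 / pi)
  expect_equal(compute_mu(4, 3, 0.7), 2 * compute_mu(2, 3, 0.7))
  expect_error(compute_mu(1, 1, 1.2), "temperature")
})

test_that("effective distance combines angle and hidden degrees", {
  co <- latent_coords(rep(10, 100), rep(0, 100), 10, 0.5)
  co$theta[2] <- pi
  expect_equal(effective_distance(1, 2, co), 15.708, tolerance = 1e-4)
  expect_equal(effective_distance(1, 2, co), effective_distance(2, 1, co))
  expect_equal(effective_distance(1, 3, co), 0)  # coincident angles
  expect_error(effective_distance(1, 1, co), "self-distance")
})

test_that("connection probability is Fermi-Dirac with half-point at chi = 1", {
  expect_equal(connection_probability(0, 0.4), 1)
  for (T in c(0.1, 0.5, 0.9)) expect_equal(connection_probability(1, T), 0.5)
  expect_equal(connection_probability(4, 0.5), 1 / 17)
  chi <- sort(runif(50, 0, 10))
  expect_true(all(diff(connection_probability(chi, 0.3)) <= 0))
  expect_error(connection_probability(-1, 0.5), "nonnegative")
})

test_that("latent sampling respects the kappa law and the seed", {
  p <- s1_params(50, 2, 0.5, kappa_law = kappa_delta(2), seed = 7)
  co <- sample_latent(p)
  expect_true(all(co$kappa == 2))
  expect_true(all(co$theta >= 0 & co$theta < 2 * pi))
  expect_identical(co, sample_latent(p))
  # Pareto mean (gamma-1)/(gamma-2)*kappa0 = 3
  pl <- s1_params(1e5, 3, 0.5, kappa_law = kappa_powerlaw(2.5, 1), seed = 8)
  expect_equal(mean(sample_latent(pl)$kappa), 3, tolerance = 0.1)
  expect_equal(sample_latent(p)$mu,
               compute_mu(2, 2, 0.5))
})

test_that("snapshot generation hits the target mean degree", {
  co <- sample_latent(s1_params(500, 10, 0.5, seed = 9))
  md <- with_seed(10, replicate(25, 2 * nrow(generate_s1_snapshot(co)) / 500))
  # conditional on these coordinates the expected mean degree is sum(p)
  p <- hyperprox:::s1_edge_probs(co, co$mu, 0.5)
  cond <- 2 * sum(p) / 500
  se <- stats::sd(md) / sqrt(length(md))
  expect_lt(abs(mean(md) - cond), 3 * se)
  # and the ensemble calibration puts that expectation near the target
  expect_lt(abs(cond - 10) / 10, 0.05)
  # two nodes at identical angles with large kappas are connected a.s.
  co2 <- latent_coords(c(100, 100, rep(1, 48)), c(0.3, 0.3, runif(48, 0, 2 * pi)),
                       5, 0.5)
  hits <- with_seed(11, replicate(20, {
    e <- generate_s1_snapshot(co2)
    any(e[, 1] == 1 & e[, 2] == 2)
  }))
  expect_true(all(hits))
})

test_that("snapshot connection frequency follows the Fermi-Dirac curve", {
  co <- sample_latent(s1_params(400, 8, 0.5, seed = 12))
  e <- with_seed(13, generate_s1_snapshot(co))
  g <- aggregated_graph(e, 400)
  pr <- hyperprox:::pair_indices(400)
  chi <- effective_distance(pr[, 1], pr[, 2], co)
  cur <- empirical_connection_curve(g, chi, pr, n_bins = 25)
  p <- connection_probability(cur$mid, 0.5)
  se <- sqrt(pmax(p * (1 - p), 1e-12) / cur$n)
  expect_gte(mean(abs(cur$freq - p) <= 3 * se), 0.9)
})

test_that("delta-law snapshot degrees are near-Poisson with mean k-bar", {
  # ensemble over fresh coordinate draws; the Poisson form is exact only in
  # the thermodynamic limit, so closeness (dispersion and total variation)
  # is asserted rather than an exact goodness-of-fit at huge sample size
  degs <- unlist(lapply(1:30, function(i) {
    co <- sample_latent(s1_params(1000, 5, 0.5, seed = 6000 + i))
    e <- with_seed(7000 + i, generate_s1_snapshot(co))
    tabulate(c(e[, 1], e[, 2]), 1000)
  }))
  expect_equal(mean(degs), 5, tolerance = 0.05)
  expect_equal(stats::var(degs) / mean(degs), 1, tolerance = 0.1)
  emp <- tabulate(degs + 1L, 20) / length(degs)
  thp <- stats::dpois(0:19, mean(degs))
  expect_lt(0.5 * sum(abs(emp - thp)), 0.02)
})

test_that("radial map reproduces effective distances exactly", {
  co <- sample_latent(s1_params(200, 8, 0.6, seed = 3))
  h <- to_hyperbolic(co)
  expect_equal(h$r[which.min(co$kappa)], h$disk_radius)
  # kappa = e * kappa0 lands exactly 2 units inside the rim
  co2 <- latent_coords(c(1, exp(1), 2, 5), runif(4), 2, 0.5)
  h2 <- to_hyperbolic(co2)
  expect_equal(h2$r[2], h2$disk_radius - 2)
  pr <- hyperprox:::pair_indices(200)
  dth <- angular_distance(co$theta[pr[, 1]], co$theta[pr[, 2]])
  chi_h <- exp((h$r[pr[, 1]] + h$r[pr[, 2]] + 2 * log(dth / 2) -
                h$disk_radius) / 2)
  chi <- effective_distance(pr[, 1], pr[, 2], co)
  expect_lt(max(abs(chi_h - chi) / chi), 1e-9)
})
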