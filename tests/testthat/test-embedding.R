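test_that("latent-degree inference matches observed degrees in expectation", {
  fs <- fix_static()
  kap <- infer_latent_degrees(fs$g, 0.5)
  # parameter recovery: delta law with kappa = 10
  expect_lt(abs(mean(kap) - 10) / 10, 0.1)
  # regular graph: all inferred degrees equal
  cyc <- aggregated_graph(cbind(1:12, c(2:12, 1)), 12)
  expect_equal(diff(range(infer_latent_degrees(cyc, 0.5))), 0)
  # star: hub strictly above leaves (looser tolerance: the hub's expected
  # degree approaches N-1 only asymptotically in kappa)
  star <- aggregated_graph(cbind(rep(1L, 5), 2:6), 6)
  ks <- infer_latent_degrees(star, 0.5, tol = 0.01)
  expect_gt(ks[1], max(ks[-1]))
  expect_error(infer_latent_degrees(aggregated_graph(cbind(1L, 2L), 3), 0.5),
               "zero-degree")
})

test_that("temperature inference recovers generating temperatures", {
  for (Ttrue in c(0.3, 0.7)) {
    co <- sample_latent(s1_params(500, 10, Ttrue, seed = 71))
    g <- aggregated_graph(with_seed(72, generate_s1_snapshot(co)), 500)
    That <- infer_temperature(g, seed = 73)
    expect_gte(That, Ttrue - 0.1)
    expect_lte(That, Ttrue + 0.1)
  }
})

test_that("Laplacian Eigenmaps initialization recovers circular structure", {
  # cycle graph: eigenvector angles are exactly equally spaced
  n <- 40
  cyc <- aggregated_graph(cbind(1:n, c(2:n, 1)), n)
  th <- initial_angles_le(cyc, rep(2, n))
  expect_lt(d_theta(th, 2 * pi * (0:(n - 1)) / n), 1e-8)
  # permutation equivariance
  perm <- with_seed(20, sample(n))
  e2 <- cbind(perm[cyc$edges[, 1]], perm[cyc$edges[, 2]])
  th2 <- initial_angles_le(aggregated_graph(e2, n), rep(2, n))
  expect_lt(d_theta(th2[perm], th), 1e-6)
  # S1 recovery beats random angles
  fs <- fix_static()
  kap <- infer_latent_degrees(fs$g, 0.5)
  th_le <- initial_angles_le(fs$g, kap)
  th_rnd <- with_seed(21, runif(150, 0, 2 * pi))
  expect_lt(d_theta(th_le, fs$coords$theta), d_theta(th_rnd, fs$coords$theta))
  # disconnected input is rejected
  disc <- aggregated_graph(rbind(c(1L, 2L), c(3L, 4L)), 4)
  expect_error(initial_angles_le(disc, rep(1, 4)), "connected")
})

test_that("likelihood refinement is monotone and reaches the toy optimum", {
  g5 <- aggregated_graph(matrix(c(1L,2L, 2L,3L, 3L,4L, 4L,5L, 1L,3L),
                                ncol = 2, byrow = TRUE), 5)
  kap5 <- rep(2, 5)
  deg <- aggregated_degrees(g5)
  mu5 <- compute_mu(mean(deg), mean(deg), 0.5)
  adj5 <- hyperprox:::adjacency_logical(g5)
  cmat5 <- (5 / (2 * pi)) / (mu5 * outer(kap5, kap5))
  probfn <- hyperprox:::conn_prob_fn(0.5, "fermi_dirac")
  # independent oracle: exhaustive search over an 18-point angular grid per
  # node, rotation gauge fixed by pinning node 1 at angle zero
  grid <- 2 * pi * (0:17) / 18
  cfg <- as.matrix(expand.grid(grid, grid, grid, grid))
  pairs <- hyperprox:::pair_indices(5)
  ll_grid <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    thi <- if (i == 1) 0 else cfg[, i - 1]
    thj <- cfg[, j - 1]
    P <- probfn(cmat5[i, j] * hyperprox:::circ_dist(thi, thj))
    P <- pmin(pmax(P, 1e-15), 1 - 1e-15)
    ll_grid <- ll_grid + if (adj5[i, j]) log(P) else log1p(-P)
  }
  opt_grid <- max(ll_grid)
  init <- with_seed(9, runif(5, 0, 2 * pi))
  ref <- refine_angles_mle(g5, kap5, init, 0.5, max_sweeps = 10, seed = 11)
  ll_init <- hyperprox:::loglik_total(adj5, init, cmat5, probfn)
  expect_gte(ref$log_likelihood, ll_init)            # hill-climbing contract
  expect_true(all(diff(ref$trace) >= 0))             # monotone sweeps
  expect_gte(ref$log_likelihood, opt_grid - 0.01 * abs(opt_grid))
  # termination contract: final sweep gains less than the tolerance unless
  # the sweep cap was hit
  tr <- ref$trace
  expect_true(length(tr) == 11L || diff(utils::tail(tr, 2)) < 1e-3)
})

test_that("likelihood is invariant under rotation and reflection", {
  fs <- fix_static()
  kap <- infer_latent_degrees(fs$g, 0.5)
  deg <- aggregated_degrees(fs$g)
  mu <- compute_mu(mean(deg), mean(deg), 0.5)
  adj <- hyperprox:::adjacency_logical(fs$g)
  cmat <- (150 / (2 * pi)) / (mu * outer(kap, kap))
  probfn <- hyperprox:::conn_prob_fn(0.5, "fermi_dirac")
  th <- fs$coords$theta
  l0 <- hyperprox:::loglik_total(adj, th, cmat, probfn)
  expect_equal(hyperprox:::loglik_total(adj, (th + 1.234) %% (2 * pi), cmat,
                                        probfn), l0)
  expect_equal(hyperprox:::loglik_total(adj, (-th) %% (2 * pi), cmat, probfn),
               l0)
})

test_that("aggregated mode with tau = 1 equals the plain mode", {
  chi <- c(1e-4, 0.1, 1, 5, 80)
  for (T in c(0.2, 0.6)) {
    f1 <- hyperprox:::conn_prob_fn(T, "aggregated", 1)
    f2 <- hyperprox:::conn_prob_fn(T, "fermi_dirac")
    # alpha(1, T) = 1/Gamma(1+T) rescales distances; undo it for comparison
    expect_equal(f1(chi / alpha_factor(1, T)), f2(chi), tolerance = 1e-12)
  }
})

test_that("full embedding recovers static S1 coordinates and is reproducible", {
  fs <- fix_static()
  emb <- embed_graph(fs$g, temperature = 0.5, seed = 31)
  expect_s3_class(emb, "embedding")
  ids <- emb$node_ids
  expect_lt(d_theta(emb$theta, fs$coords$theta[ids]), 0.2)
  expect_lt(abs(mean(emb$kappa_agg) - 10) / 10, 0.1)
  emb2 <- embed_graph(fs$g, temperature = 0.5, seed = 31)
  expect_identical(emb$theta, emb2$theta)
  # connection frequency vs inferred chi follows the Fermi-Dirac curve
  pr <- hyperprox:::pair_indices(length(ids))
  chi <- embedding_chi(emb, ids[pr[, 1]], ids[pr[, 2]])
  sub <- aggregated_graph(
    cbind(match(fs$g$edges[, 1], ids), match(fs$g$edges[, 2], ids)),
    length(ids))
  cur <- empirical_connection_curve(sub, chi, pr, n_bins = 20)
  p <- connection_probability(cur$mid, emb$temperature_hat)
  inband <- abs(cur$freq - p) <= 3 * sqrt(pmax(p * (1 - p), 1e-12) / cur$n) +
    0.05
  expect_gte(mean(inband), 0.8)
  expect_error(embed_graph(aggregated_graph(cbind(1L, 2L), 4)), "fewer than 3")
})

test_that("per-slot kappa rescales by alpha", {
  expect_equal(per_slot_kappa(56.6, 2584, 0.72), 0.1804, tolerance = 1e-3)
  expect_equal(per_slot_kappa(3, 1, 0.4), 3 * gamma(1.4))
  expect_equal(per_slot_kappa(c(2, 4), 100, 0.5),
               2 * per_slot_kappa(c(1, 2), 100, 0.5))
})
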