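test_that("greedy routing follows and delivers along decreasing distances", {
  fc <- fix_chain()
  # destination is a slot-1 neighbor
  out <- greedy_route(fc$tn, fc$emb, 1, 2)
  expect_true(out$success)
  expect_equal(out$hops, 1L)
  expect_equal(out$delivery_slot, 1L)
  # chain 1->4 over slots 1..3: three hops, distances decrease 3 -> 2 -> 1
  out <- greedy_route(fc$tn, fc$emb, 1, 4)
  expect_true(out$success)
  expect_equal(out$path, 1:4)
  expect_equal(out$hops, 3L)
  expect_equal(out$delivery_slot, 3L)
  d <- embedding_chi(fc$emb, out$path[-length(out$path)],
                     rep(4, out$hops))
  expect_true(all(diff(d) < 0))
  expect_error(greedy_route(fc$tn, fc$emb, 2, 2), "source equals")
})

test_that("random routing delivers when forced and never revisits", {
  # line 1-2 (slot 1), 2-3 (slot 2): only one trajectory exists
  tn <- temporal_network(list(cbind(1L, 2L), cbind(2L, 3L)), 3L)
  out <- random_route(tn, 1, 3, seed = 5)
  expect_true(out$success)
  expect_equal(out$path, 1:3)
  expect_setequal(out$visited, 1:3)
  # isolated destination: failure at window end
  tn2 <- temporal_network(list(cbind(1L, 2L)), 4L)
  out2 <- random_route(tn2, 1, 4, seed = 6)
  expect_false(out2$success)
})

test_that("shortest time-respecting paths respect slot order", {
  fc <- fix_chain()
  expect_equal(shortest_time_respecting_path(fc$tn, 1, 2), 1L)
  expect_equal(shortest_time_respecting_path(fc$tn, 1, 4), 3L)
  # (1,2) at slot 2 only, (2,3) at slot 1 only: 1 -> 3 is unreachable
  tn <- temporal_network(list(cbind(2L, 3L), cbind(1L, 2L)), 3L)
  expect_true(is.na(shortest_time_respecting_path(tn, 1, 3)))
  # but multiple hops within one slot are allowed
  tn2 <- temporal_network(list(rbind(c(1L, 2L), c(2L, 3L))), 3L)
  expect_equal(shortest_time_respecting_path(tn2, 1, 3), 2L)
})

test_that("routing summaries obey loop-freedom, stretch >= 1, and the
           greedy-over-random ordering", {
  ft <- fix_temporal()
  emb <- embedding_from_truth(ft$coords, 600)
  act <- intersect(active_nodes(ft$tn), emb$node_ids)
  pairs <- with_seed(83, {
    src <- sample(act, 150, replace = TRUE)
    cbind(src, vapply(src, function(s) sample(setdiff(act, s), 1L), 0L))
  })
  gr <- evaluate_routing(ft$tn, emb, pairs, strategy = "greedy")
  rr <- evaluate_routing(ft$tn, NULL, pairs, strategy = "random", seed = 84)
  expect_gt(gr$p_s, rr$p_s)
  expect_lt(gr$mean_stretch, rr$mean_stretch)
  expect_true(all(gr$per_pair$stretch >= 1, na.rm = TRUE))
  expect_true(all(rr$per_pair$stretch >= 1, na.rm = TRUE))
  # loop freedom, directly on outcomes
  for (k in 1:20) {
    o <- greedy_route(ft$tn, emb, pairs[k, 1], pairs[k, 2])
    expect_false(anyDuplicated(o$path) > 0)
    o2 <- random_route(ft$tn, pairs[k, 1], pairs[k, 2], seed = 90 + k)
    expect_false(anyDuplicated(o2$path) > 0)
  }
  # greedy is deterministic
  gr2 <- evaluate_routing(ft$tn, emb, pairs, strategy = "greedy")
  expect_identical(gr$per_pair, gr2$per_pair)
  # random depends only on the seed
  rr2 <- evaluate_routing(ft$tn, NULL, pairs, strategy = "random", seed = 84)
  expect_identical(rr$per_pair, rr2$per_pair)
})

test_that("greedy success decays with source-destination distance", {
  ft <- fix_temporal()
  emb <- embedding_from_truth(ft$coords, 600)
  act <- intersect(active_nodes(ft$tn), emb$node_ids)
  pairs <- with_seed(85, {
    src <- sample(act, 300, replace = TRUE)
    cbind(src, vapply(src, function(s) sample(setdiff(act, s), 1L), 0L))
  })
  gr <- evaluate_routing(ft$tn, emb, pairs, strategy = "greedy")
  chi <- embedding_chi(emb, pairs[, 1], pairs[, 2])
  bin <- cut(rank(chi), 5, labels = FALSE)
  ps_bin <- tapply(gr$per_pair$success, bin, mean)
  expect_lt(cor(seq_along(ps_bin), as.vector(ps_bin), method = "spearman"), 0)
})

test_that("similarity-only routing is a supported variant", {
  fc <- fix_chain()
  out <- greedy_route(fc$tn, fc$emb, 1, 4, distance = "similarity")
  expect_true(out$success)
  expect_equal(out$path, 1:4)
})
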