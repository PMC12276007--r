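test_that("maximal enumeration reproduces the derived configuration counts", {
  # 12 repeats: the single possible fold
  cfgs12 <- enumerate_configurations(12, maximal_only = TRUE)
  expect_length(cfgs12, 1)
  expect_equal(cfgs12[[1]]$starts, 1L)

  # 29 repeats: 6 maximal singles (starts 7..12) + 21 doubles
  cfgs29 <- enumerate_configurations(29, maximal_only = TRUE)
  expect_length(cfgs29, 27)
  singles <- Filter(function(cf) cf$n_folds == 1, cfgs29)
  expect_equal(sort(vapply(singles, function(cf) cf$starts, integer(1))),
               7:12)
  expect_equal(sum(vapply(cfgs29, function(cf) cf$n_folds == 2, logical(1))),
               21)

  # 24 repeats: 11 maximal singles (starts 2..12) + 1 adjacent double
  cfgs24 <- enumerate_configurations(24, maximal_only = TRUE)
  expect_length(cfgs24, 12)
  dbl <- Filter(function(cf) cf$n_folds == 2, cfgs24)
  expect_length(dbl, 1)
  expect_equal(dbl[[1]]$starts, c(1L, 13L))
  expect_equal(dbl[[1]]$n_adjacent_pairs, 1L)

  # below fold size: nothing
  expect_length(enumerate_configurations(11), 0)
})

test_that("enumeration agrees with the brute-force subset oracle", {
  for (n in c(0, 5, 12, 13, 23, 24, 25, 29, 35, 36, 40)) {
    expect_identical(config_keys(enumerate_configurations(n)),
                     brute_force_placements(n), label = paste("n =", n))
    expect_identical(
      config_keys(enumerate_configurations(n, maximal_only = TRUE)),
      brute_force_placements(n, maximal_only = TRUE),
      label = paste("maximal n =", n))
  }
  # and for a non-default fold size
  expect_identical(config_keys(enumerate_configurations(13, fold_repeats = 4)),
                   brute_force_placements(13, fold_repeats = 4))
})

test_that("number of maximal configurations is non-decreasing in chain length", {
  counts <- vapply(12:40, function(n) {
    length(enumerate_configurations(n, maximal_only = TRUE))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("adjacency statistics match hand-derived ensembles", {
  st29 <- adjacency_stats(enumerate_configurations(29, maximal_only = TRUE))
  expect_equal(st29$n_configs, 27)
  expect_equal(st29$n_adjacent_double, 6)
  expect_equal(st29$fraction_adjacent, 6 / 27)
  expect_equal(st29$n_single + st29$n_double + st29$n_triple_plus,
               st29$n_configs)

  st24 <- adjacency_stats(enumerate_configurations(24, maximal_only = TRUE))
  expect_equal(st24$fraction_adjacent, 1 / 12)

  # chains too short for two folds can never show adjacency
  st18 <- adjacency_stats(enumerate_configurations(18, maximal_only = TRUE))
  expect_equal(st18$fraction_adjacent, 0)

  expect_error(adjacency_stats(list()), "non-empty")
})

test_that("sequential simulation is seed-deterministic and trivially correct at n = 12", {
  ens <- simulate_sequential_folding(12, 50, seed = 1)
  expect_true(all(vapply(ens, function(cf) identical(cf$starts, 1L),
                         logical(1))))
  ens_a <- simulate_sequential_folding(29, 200, seed = 99)
  ens_b <- simulate_sequential_folding(29, 200, seed = 99)
  expect_identical(ens_a, ens_b)
  expect_true(all(vapply(ens_a, function(cf) cf$is_maximal, logical(1))))
})

test_that("sequential simulation converges to the exhaustive-recursion distribution", {
  dist29 <- sequential_placement_dist(29)
  expect_equal(sum(dist29$prob), 1, tolerance = 1e-12)
  mean_folds_exact <- sum(dist29$prob * dist29$n_folds)
  p_adj_exact <- sum(dist29$prob[dist29$has_adjacent])
  expect_equal(mean_folds_exact, 30 / 18, tolerance = 1e-12)
  expect_equal(p_adj_exact,
               (1 / 18) * 2 * sum(1 / (1:6)), tolerance = 1e-12)

  n_mol <- 40000
  st <- adjacency_stats(simulate_sequential_folding(29, n_mol, seed = 7))
  se_adj <- sqrt(p_adj_exact * (1 - p_adj_exact) / n_mol)
  expect_lt(abs(st$fraction_adjacent - p_adj_exact), 4 * se_adj)
  expect_lt(abs(st$mean_folds - mean_folds_exact), 0.01)

  # per-configuration frequencies match the exact distribution
  keys <- vapply(simulate_sequential_folding(29, 20000, seed = 13),
                 function(cf) paste(cf$starts, collapse = ","), character(1))
  freq <- table(keys) / length(keys)
  for (k in dist29$key) {
    p <- dist29$prob[dist29$key == k]
    obs <- if (k %in% names(freq)) as.numeric(freq[[k]]) else 0
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / 20000) + 1e-4)
  }
})

test_that("T1 fragment prediction merges adjacent folds and assigns termini", {
  # single 5'-terminal fold on (GU)29, PPP transcript
  f1 <- predict_t1_fragments(fold_configuration(29, 1), "PPP")
  expect_equal(nrow(f1), 1)
  expect_equal(f1$five_prime, "PPP")
  expect_equal(f1$three_prime, "cyclicP")
  expect_equal(f1$length_nt, 24)

  # adjacent double (starts 3, 15) survives as one 24-repeat block
  f2 <- predict_t1_fragments(fold_configuration(29, c(3, 15)), "PPP")
  expect_equal(nrow(f2), 1)
  expect_equal(f2$end_repeat - f2$start_repeat + 1, 24)
  expect_equal(f2$five_prime, "HO")
  expect_equal(f2$three_prime, "cyclicP")

  # separated folds are cut apart; the 3'-terminal one keeps its OH end
  f3 <- predict_t1_fragments(fold_configuration(29, c(1, 18)), "HO")
  expect_equal(nrow(f3), 2)
  expect_equal(f3$five_prime, c("HO", "HO"))
  expect_equal(f3$three_prime, c("cyclicP", "OH"))

  expect_error(predict_t1_fragments(fold_configuration(29, integer(0))),
               "no fold")
})

test_that("fragments conserve folds and repeats over random configurations", {
  set.seed(17)
  all_cfgs <- enumerate_configurations(40)
  for (cf in sample(all_cfgs, 50)) {
    fr <- predict_t1_fragments(cf, "PPP")
    expect_equal(sum(fr$n_folds), cf$n_folds)
    expect_equal(sum(fr$end_repeat - fr$start_repeat + 1),
                 12 * cf$n_folds)
    # protected blocks never overlap
    if (nrow(fr) > 1) {
      expect_true(all(fr$start_repeat[-1] > fr$end_repeat[-nrow(fr)]))
    }
  }
})
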