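test_that("proposal distributions match their definitions", {
  te <- experiment_task
  fl <- proposal_distribution(te, "flat")
  expect_equal(fl$probs, rep(1 / 7, 7))

  gv <- proposal_distribution(te, "general_value")
  v_unsafe <- (1 + 5 * (-0.18)) / 6
  expect_equal(gv$probs[7], 0.2 / (0.2 + 6 * v_unsafe))
  expect_equal(sum(gv$probs), 1)

  # oracle at tiny beta concentrates on the safety action
  orc <- proposal_distribution(te, "oracle", beta = 0.1)
  expect_gt(orc$probs[7], 0.99)
  expect_error(proposal_distribution(te, "oracle"), "beta")

  # negative general values: shifted proposal is a valid distribution
  # preserving the ranking
  neg <- bandit_task(c(0.5, 0.5), rbind(c(-2, -1, 3), c(-2, -1, 3)))
  gp <- proposal_distribution(neg, "general_value")
  expect_true(all(gp$probs >= 0))
  expect_equal(sum(gp$probs), 1)
  expect_equal(order(gp$probs), order(general_values(neg)))
})

test_that("action sampling respects regime, support and seed", {
  te <- experiment_task
  fl <- proposal_distribution(te, "flat")
  s <- sample_actions(fl, 7, with_replacement = FALSE, rng_seed = 1)
  expect_setequal(s$unique_actions, 1:7)
  expect_error(sample_actions(fl, 8, FALSE, 1), "distinct")

  # ~point mass; the collapse at tiny beta is slow, so allow more sweeps
  pm <- proposal_distribution(te, "oracle", beta = 0.01, max_iter = 100000L)
  s2 <- sample_actions(pm, 20, TRUE, 2)
  expect_true(all(s2$draws == 7))

  expect_identical(sample_actions(fl, 5, TRUE, 9)$draws,
                   sample_actions(fl, 5, TRUE, 9)$draws)

  # empirical frequencies converge to the proposal (chi-square, n = 1e5)
  gv <- proposal_distribution(te, "general_value")
  draws <- sample_actions(gv, 1e5, TRUE, 42)$draws
  obs <- tabulate(draws, 7)
  pval <- stats::chisq.test(obs, p = gv$probs)$p.value
  expect_gt(pval, 0.001)

  # single-draw safety frequency matches the proposal probability
  firsts <- sapply(1:2000, function(s)
    sample_actions(gv, 1, TRUE, s)$draws)
  phat <- mean(firsts == 7)
  se <- sqrt(gv$probs[7] * (1 - gv$probs[7]) / 2000)
  expect_lt(abs(phat - gv$probs[7]), 3 * se)
})

test_that("task restriction slices columns and remaps the safety marker", {
  te <- experiment_task
  full <- restrict_task(te, 1:7)
  expect_equal(full$rewards, te$rewards)
  expect_equal(full$safety_index, 7L)

  safe_only <- restrict_task(te, 7)
  expect_equal(n_actions(safe_only), 1L)
  expect_equal(safe_only$safety_index, 1L)
  fr <- trace_frontier(safe_only)
  expect_true(all(abs(fr$points$reward - 0.2) < 1e-12))
  expect_true(all(fr$points$complexity_bits < 1e-9))

  dropped <- restrict_task(te, 1:3)
  expect_null(dropped$safety_index)
  expect_error(restrict_task(te, integer(0)), "non-empty")
  expect_error(restrict_task(te, 9), "invalid")

  # restriction then BA equals BA on a manually sliced task
  rt <- restrict_task(te, c(2, 5, 7))
  manual <- bandit_task(te$state_probs, te$rewards[, c(2, 5, 7)])
  expect_equal(unclass(blahut_arimoto(rt, 3)),
               unclass(blahut_arimoto(manual, 3)), ignore_attr = TRUE)
})

test_that("BA on a symmetric-task restriction attains its analytic optimum", {
  t6 <- make_symmetric_task(6, 1, 0)
  rt <- restrict_task(t6, 1:3)
  pol <- blahut_arimoto(rt, 100)
  expect_equal(trial_averaged_reward(rt, pol), 0.5, tolerance = 1e-9)
  # matched states map deterministically; unmatched rows equal the
  # marginal (1/3 each), so I = (1/2) log2 3
  expect_equal(policy_complexity(rt$state_probs, pol), log2(3) / 2,
               tolerance = 1e-6)
  expect_lte(policy_complexity(rt$state_probs, pol),
             max_complexity_bound(3, 6) + 1e-9)
})

test_that("expand_policy embeds restricted policies with zeros elsewhere", {
  te <- experiment_task
  rt <- restrict_task(te, c(2, 7))
  pol <- blahut_arimoto(rt, 5)
  full <- expand_policy(pol, attr(rt, "parent_actions"), 7)
  expect_equal(full[, c(2, 7)], unclass(pol), ignore_attr = TRUE)
  expect_true(all(full[, -c(2, 7)] == 0))
  expect_equal(rowSums(full), rep(1, 6))
})

test_that("the complexity ceiling is min(log2 set size, log2 n states)", {
  expect_equal(max_complexity_bound(2, 6), 1.0)
  expect_equal(max_complexity_bound(7, 6), log2(6))
  expect_equal(max_complexity_bound(1, 6), 0)
  expect_error(max_complexity_bound(0, 6), "positive")
})

test_that("subset enumeration honours the safety rule and symmetry", {
  te <- experiment_task
  grid <- default_beta_grid(10L, 0.1, 30)

  all7 <- enumerate_subset_frontiers(te, 7, "ignore", grid)
  expect_length(all7, 1L)
  expect_equal(all7[[1]]$actions, 1:7)

  inc1 <- enumerate_subset_frontiers(te, 1, "include", grid)
  expect_length(inc1, 1L)
  expect_equal(inc1[[1]]$frontier$points$reward,
               rep(0.2, nrow(inc1[[1]]$frontier$points)))

  inc2 <- enumerate_subset_frontiers(te, 2, "include", grid)
  expect_length(inc2, 6L)
  expect_true(all(vapply(inc2, `[[`, logical(1), "safety_included")))
  # exchangeable unsafe actions: all safety+one-unsafe frontiers coincide
  rewards <- sapply(inc2, function(s) s$frontier$points$reward)
  expect_lt(max(abs(rewards - rewards[, 1])), 1e-9)

  exc2 <- enumerate_subset_frontiers(te, 2, "exclude", grid)
  expect_length(exc2, choose(6, 2))
  expect_false(any(vapply(exc2, `[[`, logical(1), "safety_included")))

  expect_error(enumerate_subset_frontiers(te, 7, "exclude", grid),
               "non-safety")
  expect_error(enumerate_subset_frontiers(make_random_task(3, 20, 1), 10,
                                          "ignore", grid),
               "refusing")
})

test_that("set-size-specific frontiers take the safety/no-safety upper envelope", {
  te <- experiment_task
  grid <- default_beta_grid(15L, 0.1, 40)

  f7 <- na_specific_frontier(te, 7, beta_grid = grid)
  full <- trace_frontier(te, grid)
  qs <- f7$points$complexity_bits
  expect_equal(frontier_reward_at(f7, qs), frontier_reward_at(full, qs),
               tolerance = 1e-9)

  f1 <- na_specific_frontier(te, 1, beta_grid = grid)
  expect_true(all(abs(f1$points$reward - 0.2) < 1e-9))
  expect_lt(max(f1$points$complexity_bits), 1e-9)

  # Na = 4: the safety-including branch extends further in complexity at
  # lower reward (the "downward kink" geometry), but the combined
  # envelope stays non-decreasing
  f4 <- na_specific_frontier(te, 4, beta_grid = grid)
  br <- attr(f4, "branches")
  expect_gt(max(br$include$points$complexity_bits),
            max(br$exclude$points$complexity_bits))
  expect_lt(max(br$include$points$reward), max(br$exclude$points$reward))
  expect_gte(min(diff(f4$points$reward)), -1e-9)

  # symmetry shortcut agrees with full enumeration
  f4full <- na_specific_frontier(te, 4, beta_grid = grid,
                                 use_symmetry = FALSE)
  expect_equal(f4$points$reward, f4full$points$reward, tolerance = 1e-8)

  expect_error(na_specific_frontier(make_symmetric_task(4), 2), "safety")
})

test_that("subset frontier bundles export a consistent JSON index", {
  te <- experiment_task
  dir <- withr::local_tempdir()
  bundle <- enumerate_subset_frontiers(te, 2, "include",
                                       default_beta_grid(5L, 0.5, 20))
  idx_path <- write_subset_bundle(bundle, dir)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  expect_equal(nrow(idx), length(bundle))
  expect_true(all(file.exists(file.path(dir, idx$file))))
  expect_true(all(idx$safety_included))
  # 0-based indices in the file
  expect_true(all(vapply(idx$subset, function(s) 6 %in% s, logical(1))))
})
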