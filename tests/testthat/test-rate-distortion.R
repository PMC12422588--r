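test_that("policy complexity matches hand-computed mutual information", {
  # state-independent policy carries no state information
  p_flat <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  expect_equal(policy_complexity(rep(0.25, 4), p_flat), 0)

  # deterministic bijection attains the state entropy
  expect_equal(policy_complexity(rep(1 / 6, 6), diag(6)), log2(6))

  # 2-state binary channel: I = 1 - H2(0.9)
  pol <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  h2 <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(policy_complexity(c(0.5, 0.5), pol), 1 - h2)

  expect_error(policy_complexity(c(0.5, 0.5), diag(3)), "dimensions")
})

test_that("trial-averaged reward is the P(s)-weighted policy-reward bilinear form", {
  te <- experiment_task
  expect_equal(trial_averaged_reward(te, point_mass_policy(te, 7)), 0.2)
  expect_equal(trial_averaged_reward(te, optimal_policy()), 1.0)
  expect_equal(trial_averaged_reward(te, uniform_policy(te)),
               mean(general_values(te)))
  expect_error(trial_averaged_reward(te, diag(6)), "dimensions")
})

test_that("Blahut-Arimoto hits its analytic limits and stationarity", {
  te <- experiment_task
  p0 <- blahut_arimoto(te, 0)
  expect_equal(policy_complexity(te$state_probs, p0), 0, tolerance = 1e-9)
  expect_true(all(abs(sweep(p0, 2, p0[1, ])) < 1e-9))

  p50 <- blahut_arimoto(te, 50)
  expect_equal(unclass(p50), optimal_policy(), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(trial_averaged_reward(te, p50), 1.0, tolerance = 1e-9)

  # determinism from the default uniform init
  expect_identical(unclass(blahut_arimoto(te, 2.5)),
                   unclass(blahut_arimoto(te, 2.5)))

  # converged iterate satisfies the fixed-point condition: one more
  # update moves the policy by less than 10x the tolerance
  pol <- blahut_arimoto(te, 2.5, tol = 1e-10)
  once <- blahut_arimoto(te, 2.5, max_iter = 1L, init = unclass(pol),
                         tol = 0) |> suppressWarnings()
  expect_lt(max(abs(unclass(once) - unclass(pol))), 1e-9)
})

test_that("oracle equivalence: 2x2 tasks reach the per-state argmax at large beta", {
  for (seed in 1:5) {
    tk <- make_random_task(2, 2, rng_seed = seed)
    pol <- blahut_arimoto(tk, 200)
    expect_equal(unclass(pol), greedy_policy(tk), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the zero-complexity endpoint is a point mass on the best general value", {
  te <- experiment_task
  ep <- zero_complexity_endpoint(te)
  expect_equal(ep$reward, 0.2)
  expect_equal(attr(ep, "action"), 7)
  expect_equal(zero_complexity_endpoint(make_symmetric_task(6, 1, 0))$reward,
               1 / 6)
  # ties break to the lowest action index
  expect_equal(attr(zero_complexity_endpoint(
    bandit_task(c(0.5, 0.5), matrix(2, 2, 3))), "action"), 1)
})

test_that("traced frontiers are monotone, concave, capacity-bounded and obey the beta-slope relation", {
  for (fr in list(experiment_frontier, random_frontier())) {
    p <- fr$points
    expect_gte(min(diff(p$complexity_bits)), -1e-9)
    expect_gte(min(diff(p$reward)), -1e-9)
    task_dims <- if (identical(fr, experiment_frontier)) c(6, 7) else c(16, 32)
    expect_lte(max(p$complexity_bits), log2(min(task_dims)) + 1e-9)

    # concavity: chord slopes non-increasing in complexity
    keep <- c(TRUE, diff(p$complexity_bits) > 1e-9)
    q <- p[keep, ]
    slopes <- diff(q$reward) / diff(q$complexity_bits)
    expect_lte(max(diff(slopes)), 1e-6)

    # the frontier slope (in nats) between adjacent points brackets the
    # reciprocal of the intermediate Lagrange multiplier
    pb <- p[p$beta > 0, ]
    dV <- diff(pb$reward)
    dI <- diff(pb$complexity_bits) * log(2)
    ok <- dI > 1e-8
    slope <- dV[ok] / dI[ok]
    lo <- pb$beta[-nrow(pb)][ok]
    hi <- pb$beta[-1][ok]
    expect_true(all(slope <= 1.05 / lo & slope >= 0.95 / hi))
  }
})

test_that("frontier endpoints and degenerate tasks behave", {
  p <- experiment_frontier$points
  expect_equal(p$reward[1], 0.2)
  expect_equal(p$complexity_bits[1], 0)
  expect_lte(max(p$reward), 1.0 + 1e-12)
  expect_lte(max(p$complexity_bits), log2(6) + 1e-9)

  one <- bandit_task(rep(0.25, 4), matrix(0.3, 4, 1))
  fr1 <- trace_frontier(one)
  expect_true(all(abs(fr1$points$complexity_bits) < 1e-9))
  expect_true(all(abs(fr1$points$reward - 0.3) < 1e-12))
})

test_that("frontier interpolation and reward loss behave at and between knots", {
  fr <- experiment_frontier
  p <- fr$points
  i <- which(p$complexity_bits > 0.5)[1]
  expect_equal(frontier_reward_at(fr, p$complexity_bits[i]), p$reward[i],
               tolerance = 1e-12)
  expect_equal(frontier_reward_at(fr, 0), 0.2)
  expect_equal(frontier_reward_at(fr, 100), max(p$reward))

  # synthetic two-point frontier: midpoint query is the mean
  toy <- structure(list(points = data.frame(beta = c(0, 1),
                                            complexity_bits = c(0, 1),
                                            reward = c(0.2, 0.8))),
                   class = "rc_frontier")
  expect_equal(frontier_reward_at(toy, 0.5), 0.5)

  te <- experiment_task
  # a policy taken from the frontier itself has ~zero loss
  pol <- fr$policies[[30]]
  expect_lt(abs(reward_loss(te, unclass(pol), fr)), 1e-6)
  expect_equal(reward_loss(te, point_mass_policy(te, 7), fr), 0,
               tolerance = 1e-9)
  # a restricted-set policy at high beta sits strictly below the frontier
  rt <- restrict_task(te, c(1, 7))
  sub <- blahut_arimoto(rt, 50)
  full <- expand_policy(sub, attr(rt, "parent_actions"), 7)
  expect_lt(reward_loss(te, full, fr), -0.01)
  # fingerprint guard
  expect_error(reward_loss(make_symmetric_task(6), uniform_policy(te)[, 1:6],
                           fr), "different task")
})

test_that("frontier and policy files round trip", {
  fr <- experiment_frontier
  f <- withr::local_tempfile(fileext = ".csv")
  write_frontier_csv(fr, f)
  back <- read_frontier_csv(f)
  expect_equal(back$points$reward, fr$points$reward)
  pf <- withr::local_tempfile(fileext = ".csv")
  write_policy_csv(optimal_policy(), pf, experiment_task$action_labels)
  expect_equal(read_policy_csv(pf), optimal_policy(), ignore_attr = TRUE)
})
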