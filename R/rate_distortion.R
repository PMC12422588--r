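#' Policies and their information cost
#'
#' A policy is a plain numeric matrix of conditional probabilities
#' `pi(a | s)` with one row per state and one column per action; every row
#' must sum to 1. `validate_policy()` checks these invariants and returns
#' the matrix.
#'
#' @param policy numeric matrix of conditional action probabilities.
#' @return the validated policy matrix.
#' @export
validate_policy <- function(policy) {
  policy <- as.matrix(policy)
  if (!is.numeric(policy) || anyNA(policy) || any(policy < -1e-12)) {
    stop("policy must be a non-negative numeric matrix", call. = FALSE)
  }
  if (any(abs(rowSums(policy) - 1) > 1e-10)) {
    stop("every policy row must sum to 1 (within 1e-10)", call. = FALSE)
  }
  policy
}

#' @rdname validate_policy
#' @param task a `bandit_task`.
#' @return `uniform_policy()` spreads each row evenly over all actions;
#'   `greedy_policy()` puts all mass on each state's highest-reward action
#'   (ties broken toward the lowest action index).
#' @export
uniform_policy <- function(task) {
  matrix(1 / n_actions(task), n_states(task), n_actions(task))
}

#' @rdname validate_policy
#' @export
greedy_policy <- function(task) {
  pol <- matrix(0, n_states(task), n_actions(task))
  best <- apply(task$rewards, 1, which.max)  # which.max takes the first tie
  pol[cbind(seq_len(nrow(pol)), best)] <- 1
  pol
}

#' Marginal action distribution of a policy
#'
#' `P(a) = sum_s P(s) pi(a | s)`.
#'
#' @param state_probs state distribution.
#' @param policy policy matrix.
#' @return numeric vector over actions.
#' @export
marginal_action_dist <- function(state_probs, policy) {
  policy <- validate_policy(policy)
  if (length(state_probs) != nrow(policy)) {
    stop("state_probs and policy dimensions disagree", call. = FALSE)
  }
  as.numeric(crossprod(state_probs, policy))
}

#' Policy complexity (mutual information) in bits
#'
#' The mutual information `I(S; A) = sum_s P(s) sum_a pi(a|s)
#' log[pi(a|s) / P(a)]` between states and policy-assigned actions — the
#' framework's cognitive cost. Computed in natural log internally and
#' returned in bits; zero-probability terms contribute 0 and round-off is
#' clipped at 0.
#'
#' @param state_probs state distribution.
#' @param policy policy matrix (rows = states).
#' @return non-negative scalar, in bits.
#' @export
policy_complexity <- function(state_probs, policy) {
  policy <- validate_policy(policy)
  if (length(state_probs) != nrow(policy)) {
    stop("state_probs and policy dimensions disagree", call. = FALSE)
  }
  pa <- as.numeric(crossprod(state_probs, policy))
  lr <- log(policy) - rep(log(pa), each = nrow(policy))
  terms <- policy * lr
  terms[policy <= 0] <- 0  # 0 log 0 := 0
  max(sum(state_probs * rowSums(terms)) / log(2), 0)
}

#' Trial-averaged reward of a policy
#'
#' `V = sum_s P(s) sum_a pi(a|s) Q(s, a)`: the expected per-trial reward of
#' running `policy` on `task`.
#'
#' @param task a `bandit_task`.
#' @param policy policy matrix over the task's actions.
#' @return scalar reward.
#' @export
trial_averaged_reward <- function(task, policy) {
  policy <- validate_policy(policy)
  if (nrow(policy) != n_states(task) || ncol(policy) != n_actions(task)) {
    stop("policy and task dimensions disagree", call. = FALSE)
  }
  sum(task$state_probs * rowSums(policy * task$rewards))
}

#' Blahut-Arimoto optimal capacity-limited policy
#'
#' Iterates the self-consistent update `pi(a|s) proportional to
#' P(a) exp(beta Q(s, a))` with `P(a)` the current marginal, the alternating
#' fixed point that solves the reward-maximization problem under a mutual-
#' information constraint. `beta` is the Lagrange multiplier (defined
#' against natural log): small `beta` yields state-independent,
#' low-complexity policies; large `beta` approaches the per-state argmax.
#'
#' The objective is convex, so the converged value is independent of the
#' starting point; the default uniform initialization makes runs
#' reproducible. Convergence is declared when the largest absolute policy
#' change falls below `tol`; hitting `max_iter` first raises a warning and
#' returns the current iterate (attribute `converged` set accordingly).
#'
#' @param task a `bandit_task`.
#' @param beta non-negative inverse-temperature / Lagrange multiplier.
#' @param tol convergence tolerance on the policy entries.
#' @param max_iter iteration cap.
#' @param init optional starting policy (defaults to uniform).
#' @return policy matrix with attributes `converged` (logical) and
#'   `iterations` (integer).
#' @export
blahut_arimoto <- function(task, beta, tol = 1e-10, max_iter = 10000L,
                           init = NULL) {
  validate_task(task)
  if (!is.finite(beta) || beta < 0) {
    stop("beta must be non-negative", call. = FALSE)
  }
  pol <- if (is.null(init)) uniform_policy(task) else validate_policy(init)
  if (nrow(pol) != n_states(task) || ncol(pol) != n_actions(task)) {
    stop("init policy and task dimensions disagree", call. = FALSE)
  }
  ps <- task$state_probs
  bq <- beta * task$rewards
  ns <- n_states(task)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pa <- as.numeric(crossprod(ps, pol))
    lp <- bq + rep(log(pa), each = ns)   # log P(a) = -Inf drops the action
    lp <- lp - row_logsumexp(lp)
    new <- exp(lp)
    delta <- max(abs(new - pol))
    pol <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("Blahut-Arimoto did not converge in %d iterations (beta = %g)",
                    max_iter, beta), call. = FALSE)
  }
  structure(pol, converged = converged, iterations = iter)
}

#' Analytic zero-complexity endpoint of the frontier
#'
#' At zero policy complexity the policy must be state-independent, and the
#' best such policy is a point mass on the action with the highest general
#' value `V(a)` (ties broken toward the lowest index). Returned as the
#' `beta = 0` frontier point.
#'
#' @param task a `bandit_task`.
#' @return a one-row data frame with columns `beta`, `complexity_bits`,
#'   `reward`, plus attribute `action` (the argmax action index).
#' @export
zero_complexity_endpoint <- function(task) {
  v <- general_values(task)
  a <- which.max(v)
  structure(data.frame(beta = 0, complexity_bits = 0,
                       reward = unname(v[a])),
            action = unname(a))
}

#' Default geometric beta grid
#'
#' 60 geometrically spaced Lagrange-multiplier values spanning the
#' low-complexity to near-deterministic regimes; the analytic `beta = 0`
#' endpoint is added separately by [trace_frontier()].
#'
#' @param n number of grid points.
#' @param beta_min,beta_max grid range.
#' @return increasing numeric vector.
#' @export
default_beta_grid <- function(n = 60L, beta_min = 0.05, beta_max = 50) {
  exp(seq(log(beta_min), log(beta_max), length.out = n))
}

#' Trace a reward-complexity frontier
#'
#' Runs Blahut-Arimoto at every `beta` in the grid and assembles the
#' resulting (complexity, reward) pairs, prepending the analytic
#' zero-complexity endpoint. Along the frontier both complexity and reward
#' are non-decreasing in `beta`, and reward is a concave function of
#' complexity; the reciprocal of `beta` is the frontier's local slope in
#' natural-log units.
#'
#' Each grid point is solved by warm-starting from the previous `beta`'s
#' policy (the first from uniform): the objective is convex so the solution
#' is unchanged, but convergence near phase transitions is much faster and
#' the traced curve is numerically monotone. The tracing tolerance is
#' tighter than the single-solve default so that adjacent points resolve
#' cleanly.
#'
#' @param task a `bandit_task`.
#' @param beta_grid increasing vector of positive `beta` values.
#' @param tol,max_iter passed to [blahut_arimoto()].
#' @return an `rc_frontier`: list with `points` (data frame `beta`,
#'   `complexity_bits`, `reward`), `task_fingerprint`, and the per-beta
#'   `policies`.
#' @export
trace_frontier <- function(task, beta_grid = default_beta_grid(),
                           tol = 1e-12, max_iter = 100000L) {
  validate_task(task)
  beta_grid <- as.numeric(beta_grid)
  if (length(beta_grid) == 0 || is.unsorted(beta_grid) ||
      any(beta_grid < 0)) {
    stop("beta_grid must be non-empty, non-negative and ascending",
         call. = FALSE)
  }
  beta_grid <- beta_grid[beta_grid > 0]
  ep <- zero_complexity_endpoint(task)
  policies <- vector("list", length(beta_grid))
  pts <- vector("list", length(beta_grid))
  init <- NULL
  u <- uniform_policy(task)
  for (i in seq_along(beta_grid)) {
    pol <- blahut_arimoto(task, beta_grid[i], tol = tol,
                          max_iter = max_iter, init = init)
    # keep full support in the next warm start: actions squeezed to exactly
    # zero at a small beta could otherwise never re-enter at a larger one
    init <- (1 - 1e-8) * pol + 1e-8 * u
    policies[[i]] <- pol
    pts[[i]] <- data.frame(
      beta = beta_grid[i],
      complexity_bits = policy_complexity(task$state_probs, pol),
      reward = trial_averaged_reward(task, pol))
  }
  points <- rbind(ep[, c("beta", "complexity_bits", "reward")],
                  do.call(rbind, pts))
  rownames(points) <- NULL
  structure(list(points = points,
                 task_fingerprint = task_fingerprint(task),
                 policies = policies),
            class = "rc_frontier")
}

#' @export
print.rc_frontier <- function(x, ...) {
  p <- x$points
  cat(sprintf("<rc_frontier> %d points, complexity 0 to %.4g bits, reward %.4g to %.4g\n",
              nrow(p), max(p$complexity_bits), p$reward[1], max(p$reward)))
  invisible(x)
}

#' Interpolate a frontier's reward at a given complexity
#'
#' Piecewise-linear interpolation of reward over complexity. Queries below
#' the first knot return the endpoint reward; queries beyond the last knot
#' clamp to the final reward.
#'
#' @param frontier an `rc_frontier` (or anything with a `points` data
#'   frame).
#' @param complexity_bits non-negative query point(s), in bits.
#' @return interpolated reward(s).
#' @export
frontier_reward_at <- function(frontier, complexity_bits) {
  pts <- frontier$points
  if (is.null(pts) || nrow(pts) == 0) {
    stop("frontier has no points", call. = FALSE)
  }
  if (any(complexity_bits < 0)) {
    stop("complexity_bits must be non-negative", call. = FALSE)
  }
  if (nrow(pts) == 1L) {
    return(rep(pts$reward, length(complexity_bits)))
  }
  # collapse numerically duplicated complexities to their best reward
  o <- order(pts$complexity_bits, pts$reward)
  x <- pts$complexity_bits[o]
  y <- pts$reward[o]
  keep <- c(diff(x) > 1e-12, TRUE)  # for ties keep the last (max reward)
  x <- x[keep]
  y <- y[keep]
  if (length(x) == 1L) {
    return(rep(y, length(complexity_bits)))
  }
  out <- stats::approx(x, y, xout = complexity_bits, rule = 2)$y
  # at/below the first stored point (the analytic endpoint for traced
  # frontiers) return its reward exactly, untouched by solver round-off
  # in near-duplicate knots
  first <- pts[1, ]
  out[complexity_bits <= first$complexity_bits] <- first$reward
  out
}

#' Supporting-line upper bound on a frontier's reward
#'
#' The reward-complexity frontier is concave, and at the point traced with
#' Lagrange multiplier `beta` its slope is `1 / beta` in natural-log units.
#' Each traced point therefore defines a tangent line that the whole
#' frontier lies below, and the minimum over those tangents upper-bounds
#' the true frontier at any complexity. Unlike the chord interpolation of
#' [frontier_reward_at()], which under-estimates between knots, this bound
#' never dips below the true curve — making it the right-hand side for
#' dominance checks of the form "this policy is at or below the frontier".
#'
#' @param frontier an `rc_frontier` with positive-`beta` points.
#' @param complexity_bits non-negative query point(s), in bits.
#' @return upper bound on the frontier reward at each query.
#' @export
frontier_reward_bound <- function(frontier, complexity_bits) {
  pts <- frontier$points
  pts <- pts[!is.na(pts$beta) & pts$beta > 0, ]
  if (nrow(pts) == 0) {
    stop("frontier has no positive-beta points", call. = FALSE)
  }
  vapply(complexity_bits, function(c0) {
    min(pts$reward + (c0 - pts$complexity_bits) * log(2) / pts$beta)
  }, numeric(1))
}

#' Reward loss of a policy relative to a frontier
#'
#' The achieved trial-averaged reward minus the frontier's reward at the
#' policy's own complexity: how far below the achievable optimum the
#' policy sits (non-positive up to interpolation error when the frontier
#' is the task's full-action-space frontier).
#'
#' @param task the (full) `bandit_task` the policy is evaluated on.
#' @param policy policy matrix over the full action set.
#' @param full_frontier frontier traced on `task` (fingerprints must
#'   match).
#' @return scalar loss (reward units).
#' @export
reward_loss <- function(task, policy, full_frontier) {
  if (!is.null(full_frontier$task_fingerprint) &&
      !identical(full_frontier$task_fingerprint, task_fingerprint(task))) {
    stop("frontier was traced on a different task", call. = FALSE)
  }
  cb <- policy_complexity(task$state_probs, policy)
  trial_averaged_reward(task, policy) - frontier_reward_at(full_frontier, cb)
}

#' Export frontiers and policies
#'
#' Frontiers are written as CSV with columns `beta`, `complexity_bits`,
#' `reward` (with a JSON mirror); policies as a CSV matrix with one row per
#' state and an action-label header.
#'
#' @param frontier an `rc_frontier`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frontier_csv <- function(frontier, path) {
  utils::write.csv(frontier$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frontier_csv
#' @export
write_frontier_json <- function(frontier, path) {
  jsonlite::write_json(
    list(points = frontier$points,
         task_fingerprint = frontier$task_fingerprint),
    path, auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  invisible(path)
}

#' @rdname write_frontier_csv
#' @export
read_frontier_csv <- function(path) {
  structure(list(points = utils::read.csv(path), task_fingerprint = NULL,
                 policies = NULL),
            class = "rc_frontier")
}

#' @rdname write_frontier_csv
#' @param policy policy matrix.
#' @param action_labels optional header labels.
#' @export
write_policy_csv <- function(policy, path, action_labels = NULL) {
  policy <- validate_policy(policy)
  df <- as.data.frame(policy)
  names(df) <- if (is.null(action_labels))
    paste0("a", seq_len(ncol(policy))) else action_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frontier_csv
#' @export
read_policy_csv <- function(path) {
  validate_policy(as.matrix(utils::read.csv(path, check.names = FALSE)))
}
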