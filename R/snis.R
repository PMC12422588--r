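#' Self-normalized importance-sampling policy estimator
#'
#' Estimates the full-action-space optimal policy at a given `beta` from a
#' with-replacement action sample, correcting for bias in the proposal
#' distribution. For each state the unnormalized optimal policy
#' `eta(a|s) = exp(beta Q(s, a)) P(a)` is estimated by the self-normalized
#' ratio estimator over the draws, with importance weights
#' `count(a) / P0(a)` on each sampled action; because the optimal marginal
#' `P(a)` is unknown to the agent it is replaced by the current estimate's
#' own marginal and the update iterated to a fixed point, mirroring the
#' Blahut-Arimoto alternation but confined to the sampled support and
#' weighted by the draws.
#'
#' The estimator is asymptotically unbiased for the optimal policy as the
#' number of draws grows. When every action is drawn exactly once from a
#' flat proposal the counts and proposal cancel and the fixed point
#' coincides with Blahut-Arimoto on the full task.
#'
#' All row normalizations run in log space (log-sum-exp), so large
#' negative `beta * Q` values cannot underflow an entire state row.
#'
#' @param task a `bandit_task`.
#' @param sample an `action_sample` drawn **with replacement** from a
#'   proposal with positive mass on every sampled action.
#' @param beta non-negative Lagrange multiplier.
#' @param tol convergence tolerance on the policy entries.
#' @param max_iter iteration cap.
#' @return a `snis_estimate`: list with `policy` (full-width matrix, zero
#'   outside the sampled support), `beta`, `converged`, `iterations`, and
#'   the generating `sample`.
#' @export
snis_policy <- function(task, sample, beta, tol = 1e-10, max_iter = 10000L) {
  validate_task(task)
  stopifnot(inherits(sample, "action_sample"))
  if (!isTRUE(sample$with_replacement)) {
    stop("SNIS requires a with-replacement action sample", call. = FALSE)
  }
  if (!is.finite(beta) || beta < 0) {
    stop("beta must be non-negative", call. = FALSE)
  }
  support <- sample$unique_actions
  if (any(support < 1 | support > n_actions(task))) {
    stop("sample indexes actions outside the task", call. = FALSE)
  }
  p0 <- sample$proposal$probs[support]
  if (any(p0 <= 0)) {
    stop("proposal must have positive mass on every sampled action",
         call. = FALSE)
  }
  counts <- tabulate(sample$draws, nbins = n_actions(task))[support]
  k <- length(support)
  ns <- n_states(task)
  ps <- task$state_probs
  # fixed-point iteration over the sampled support, in log space
  logw <- log(counts) - log(p0)
  bq <- beta * task$rewards[, support, drop = FALSE]
  pol <- matrix(1 / k, ns, k)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pa <- as.numeric(crossprod(ps, pol))
    lp <- bq + rep(log(pa) + logw, each = ns)
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
    warning(sprintf("SNIS fixed point did not converge in %d iterations (beta = %g)",
                    max_iter, beta), call. = FALSE)
  }
  structure(list(policy = expand_policy(pol, support, n_actions(task)),
                 beta = beta, converged = converged, iterations = iter,
                 sample = sample),
            class = "snis_estimate")
}

#' @export
print.snis_estimate <- function(x, ...) {
  cat(sprintf("<snis_estimate> beta = %g, %d draws over %d distinct actions, %s in %d iterations\n",
              x$beta, length(x$sample$draws),
              length(x$sample$unique_actions),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Evaluate an SNIS estimate against the true task
#'
#' Computes the estimate's policy complexity, its trial-averaged reward
#' under the true task, and its reward loss relative to the full-action-
#' space frontier.
#'
#' @param task the true `bandit_task`.
#' @param estimate a `snis_estimate` for that task.
#' @param full_frontier frontier traced on `task`.
#' @return list with `complexity_bits`, `reward`, `loss`.
#' @export
evaluate_snis <- function(task, estimate, full_frontier) {
  stopifnot(inherits(estimate, "snis_estimate"))
  pol <- estimate$policy
  list(complexity_bits = policy_complexity(task$state_probs, pol),
       reward = trial_averaged_reward(task, pol),
       loss = reward_loss(task, pol, full_frontier))
}

#' Export an SNIS estimate
#'
#' Writes the estimated policy in the standard policy CSV layout plus a
#' JSON metadata record (`beta`, number of draws, proposal kind,
#' convergence flag, iteration count).
#'
#' @param estimate a `snis_estimate`.
#' @param policy_path CSV output path for the policy.
#' @param meta_path JSON output path for the metadata.
#' @param action_labels optional policy CSV header.
#' @return `policy_path`, invisibly.
#' @export
write_snis_estimate <- function(estimate, policy_path, meta_path,
                                action_labels = NULL) {
  write_policy_csv(estimate$policy, policy_path, action_labels)
  jsonlite::write_json(
    list(beta = estimate$beta,
         n = length(estimate$sample$draws),
         proposal = estimate$sample$proposal$kind,
         converged = estimate$converged,
         iterations = estimate$iterations),
    meta_path, auto_unbox = TRUE, digits = I(17))
  invisible(policy_path)
}
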