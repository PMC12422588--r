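#' Simulate choice data from a known policy
#'
#' Generates a per-trial (state, action, reward) log from an agent that
#' follows `policy` on `task`. Under the `"counterbalanced"` schedule each
#' state appears exactly `n_trials / n_states` times in shuffled order
#' (mirroring blocked designs with a flat empirical state distribution);
#' under `"iid"` states are drawn from the task's state distribution.
#' Rewards are read off the task's reward matrix.
#'
#' @param task a `bandit_task`.
#' @param policy policy matrix over the task's actions.
#' @param n_trials number of trials; for `"counterbalanced"` it must be
#'   divisible by the number of states.
#' @param rng_seed integer seed.
#' @param state_schedule `"counterbalanced"` or `"iid"`.
#' @return a `choice_data`: data frame with columns `trial`, `state`,
#'   `action`, `reward` (1-based indices) and attributes `n_states`,
#'   `n_actions`, `task_fingerprint`.
#' @export
simulate_agent <- function(task, policy, n_trials, rng_seed,
                           state_schedule = c("counterbalanced", "iid")) {
  validate_task(task)
  policy <- validate_policy(policy)
  state_schedule <- match.arg(state_schedule)
  if (n_trials < 1 || n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  ns <- n_states(task)
  if (state_schedule == "counterbalanced" && n_trials %% ns != 0) {
    stop("counterbalanced schedules need n_trials divisible by n_states",
         call. = FALSE)
  }
  dat <- with_seed(rng_seed, {
    states <- if (state_schedule == "counterbalanced") {
      sample(rep(seq_len(ns), n_trials / ns))
    } else {
      sample.int(ns, n_trials, replace = TRUE, prob = task$state_probs)
    }
    actions <- vapply(states, function(s) {
      sample.int(n_actions(task), 1L, prob = policy[s, ])
    }, integer(1))
    data.frame(trial = seq_len(n_trials), state = states, action = actions,
               reward = task$rewards[cbind(states, actions)])
  })
  structure(dat, n_states = ns, n_actions = n_actions(task),
            task_fingerprint = task_fingerprint(task),
            class = c("choice_data", "data.frame"))
}

check_choice_data <- function(dataset) {
  if (!inherits(dataset, "choice_data") &&
      !all(c("state", "action", "reward") %in% names(dataset))) {
    stop("dataset must be choice data with state/action/reward columns",
         call. = FALSE)
  }
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  dataset
}

#' Dirichlet-regularized policy estimate from choice data
#'
#' Per state, assumes a symmetric Dirichlet(`alpha`) prior over actions
#' and returns the posterior-mean policy given the empirical action
#' counts: `pi_hat(a|s) = (count(s, a) + alpha) / (count(s) +
#' n_actions * alpha)`. The small default `alpha = 0.01` shrinks rarely
#' visited rows only slightly, keeping empirical reward at or below the
#' reward-complexity frontier. States never visited fall back to the prior
#' mean (uniform) with a warning.
#'
#' @param dataset a `choice_data` (or any data frame with `state`,
#'   `action` columns).
#' @param alpha positive Dirichlet concentration.
#' @param n_states,n_actions dimensions; taken from the dataset attributes
#'   when omitted.
#' @return list with `policy` (posterior-mean matrix) and `state_freqs`
#'   (empirical state frequencies).
#' @export
estimate_policy <- function(dataset, alpha = 0.01, n_states = NULL,
                            n_actions = NULL) {
  check_choice_data(dataset)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be positive", call. = FALSE)
  }
  ns <- if (is.null(n_states)) attr(dataset, "n_states") else n_states
  na <- if (is.null(n_actions)) attr(dataset, "n_actions") else n_actions
  if (is.null(ns)) ns <- max(dataset$state)
  if (is.null(na)) na <- max(dataset$action)
  counts <- matrix(0, ns, na)
  tab <- table(factor(dataset$state, levels = seq_len(ns)),
               factor(dataset$action, levels = seq_len(na)))
  counts[] <- as.numeric(tab)
  visits <- rowSums(counts)
  if (any(visits == 0)) {
    warning("some states were never visited; their rows use the prior mean",
            call. = FALSE)
  }
  policy <- (counts + alpha) / (visits + na * alpha)
  list(policy = policy, state_freqs = visits / sum(visits))
}

#' Estimate policy complexity from choice data
#'
#' The mutual information (in bits) of the Dirichlet posterior-mean policy
#' of [estimate_policy()] under the empirical state frequencies.
#'
#' @inheritParams estimate_policy
#' @return non-negative scalar, bits.
#' @export
estimate_complexity <- function(dataset, alpha = 0.01, n_states = NULL,
                                n_actions = NULL) {
  est <- estimate_policy(dataset, alpha, n_states, n_actions)
  policy_complexity(est$state_freqs, est$policy)
}

#' Count distinct actions used
#'
#' The number of actions chosen at least `min_count` times across the
#' dataset — the empirical consideration-set size. Raising `min_count`
#' (e.g. to 2 or 3) discards likely slips of the hand.
#'
#' @param dataset choice data.
#' @param min_count minimum number of choices for an action to count.
#' @return integer count.
#' @export
count_actions <- function(dataset, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  if (is.null(dataset) || nrow(dataset) == 0) return(0L)
  sum(table(dataset$action) >= min_count)
}

#' Summarize choice data against a task and its frontier
#'
#' Assembles the behavioral quantities reported per participant and
#' condition: estimated policy complexity, number of distinct actions
#' used, mean observed reward, and the deviation of that reward from the
#' full-action-space frontier at the estimated complexity.
#'
#' @param dataset choice data generated from `task`.
#' @param task the generating `bandit_task`.
#' @param full_frontier frontier traced on `task`.
#' @param alpha Dirichlet concentration for the complexity estimate.
#' @param min_count action-counting threshold.
#' @return a `behavior_summary`: list with `complexity_bits_est`,
#'   `n_actions_chosen`, `mean_reward`, `reward_loss_vs_frontier`.
#' @export
summarize_behavior <- function(dataset, task, full_frontier, alpha = 0.01,
                               min_count = 1L) {
  check_choice_data(dataset)
  fp <- attr(dataset, "task_fingerprint")
  if (!is.null(fp) && !identical(fp, task_fingerprint(task))) {
    stop("dataset was generated from a different task", call. = FALSE)
  }
  cb <- estimate_complexity(dataset, alpha,
                            n_states = n_states(task),
                            n_actions = n_actions(task))
  mr <- mean(dataset$reward)
  structure(list(complexity_bits_est = cb,
                 n_actions_chosen = count_actions(dataset, min_count),
                 mean_reward = mr,
                 reward_loss_vs_frontier =
                   mr - frontier_reward_at(full_frontier, cb)),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(paste0("<behavior_summary> complexity %.3f bits, ",
                     "%d distinct actions, mean reward %.4f (loss %.4f)\n"),
              x$complexity_bits_est, x$n_actions_chosen, x$mean_reward,
              x$reward_loss_vs_frontier))
  invisible(x)
}

#' Choice-data and summary round trips
#'
#' Choice data are written as CSV with header `trial,state,action,reward`
#' and 0-based state/action indices in the file; summaries as a JSON
#' record. Both round-trip exactly.
#'
#' @param dataset a `choice_data`.
#' @param path output path.
#' @return `path`, invisibly (writers); the object (readers).
#' @export
write_choices_csv <- function(dataset, path) {
  check_choice_data(dataset)
  out <- data.frame(trial = dataset$trial,
                    state = dataset$state - 1L,
                    action = dataset$action - 1L,
                    reward = dataset$reward)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @param n_states,n_actions dimensions to restore on the attributes.
#' @param task_fingerprint fingerprint to restore, if known.
#' @export
read_choices_csv <- function(path, n_states = NULL, n_actions = NULL,
                             task_fingerprint = NULL) {
  d <- utils::read.csv(path)
  dat <- data.frame(trial = d$trial, state = d$state + 1L,
                    action = d$action + 1L, reward = d$reward)
  structure(dat,
            n_states = if (is.null(n_states)) max(dat$state) else n_states,
            n_actions = if (is.null(n_actions)) max(dat$action) else n_actions,
            task_fingerprint = task_fingerprint,
            class = c("choice_data", "data.frame"))
}

#' @rdname write_choices_csv
#' @param summary a `behavior_summary`.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "behavior_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_summary_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "behavior_summary")
}
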