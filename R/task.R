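#' Contextual-bandit task objects
#'
#' A `bandit_task` bundles a state distribution `P(s)` with a state-by-action
#' reward matrix `Q(s, a)`. All frontier, consideration-set and simulation
#' machinery in this package operates on these objects.
#'
#' @param state_probs numeric vector of state probabilities (must be
#'   non-negative and sum to 1).
#' @param rewards numeric matrix of rewards, one row per state, one column
#'   per action.
#' @param action_labels optional character vector of action names; defaults
#'   to `a1, a2, ...`.
#' @param safety_index optional integer index (1-based) of a
#'   state-independent "safety" action whose reward column must be constant
#'   across states.
#'
#' @return An object of class `bandit_task`: a list with elements
#'   `state_probs`, `rewards`, `action_labels` and `safety_index`.
#' @export
bandit_task <- function(state_probs, rewards, action_labels = NULL,
                        safety_index = NULL) {
  rewards <- as.matrix(rewards)
  state_probs <- as.numeric(state_probs)
  if (is.null(action_labels)) {
    action_labels <- paste0("a", seq_len(ncol(rewards)))
  }
  task <- structure(
    list(state_probs = state_probs,
         rewards = rewards,
         action_labels = as.character(action_labels),
         safety_index = safety_index),
    class = "bandit_task")
  validate_task(task)
}

#' @rdname bandit_task
#' @param task a `bandit_task` object to validate.
#' @export
validate_task <- function(task) {
  p <- task$state_probs
  Q <- task$rewards
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    stop("state_probs must be a non-negative numeric vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("state_probs must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (!is.matrix(Q) || !is.numeric(Q) || any(!is.finite(Q))) {
    stop("rewards must be a finite numeric matrix", call. = FALSE)
  }
  if (nrow(Q) != length(p)) {
    stop("rewards must have one row per state", call. = FALSE)
  }
  if (length(task$action_labels) != ncol(Q)) {
    stop("action_labels must have one entry per action", call. = FALSE)
  }
  si <- task$safety_index
  if (!is.null(si)) {
    if (length(si) != 1L || si < 1L || si > ncol(Q) || si != round(si)) {
      stop("safety_index must be a single valid action index", call. = FALSE)
    }
    if (diff(range(Q[, si])) > 1e-12) {
      stop("the safety action's reward column must be constant", call. = FALSE)
    }
  }
  task
}

#' @export
print.bandit_task <- function(x, ...) {
  cat(sprintf("<bandit_task> %d states x %d actions\n",
              n_states(x), n_actions(x)))
  if (!is.null(x$safety_index)) {
    cat(sprintf("  safety action: %s (index %d, constant reward %.4g)\n",
                x$action_labels[x$safety_index], x$safety_index,
                x$rewards[1, x$safety_index]))
  }
  invisible(x)
}

#' @rdname bandit_task
#' @export
n_states <- function(task) nrow(task$rewards)

#' @rdname bandit_task
#' @export
n_actions <- function(task) ncol(task$rewards)

#' Symmetric one-optimal-action-per-state task
#'
#' Builds a square task in which every state has a unique optimal action
#' (the diagonal of the reward matrix) and all other actions share a common
#' lower reward, under a flat state distribution.
#'
#' @param n_states number of states (= number of actions); at least 2.
#' @param reward_hi reward of each state's optimal action.
#' @param reward_lo reward of every other action.
#' @return a `bandit_task`.
#' @export
make_symmetric_task <- function(n_states, reward_hi = 1, reward_lo = 0) {
  if (n_states < 2 || n_states != round(n_states)) {
    stop("n_states must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(reward_hi) || !is.finite(reward_lo) || reward_hi <= reward_lo) {
    stop("need finite rewards with reward_hi > reward_lo", call. = FALSE)
  }
  Q <- matrix(reward_lo, n_states, n_states)
  diag(Q) <- reward_hi
  bandit_task(rep(1 / n_states, n_states), Q)
}

#' Random-reward task
#'
#' Flat state distribution with i.i.d. Uniform(0, 1) reward entries, the
#' default large-action-space test bed (16 states, 32 actions in the
#' reference simulations). Reproducible under `rng_seed`.
#'
#' @param n_states,n_actions task dimensions.
#' @param rng_seed integer seed controlling the reward draws.
#' @return a `bandit_task`.
#' @export
make_random_task <- function(n_states, n_actions, rng_seed) {
  if (n_states < 1 || n_actions < 1) {
    stop("dimensions must be positive", call. = FALSE)
  }
  Q <- with_seed(rng_seed, matrix(stats::runif(n_states * n_actions),
                                  n_states, n_actions))
  bandit_task(rep(1 / n_states, n_states), Q)
}

#' Scarce-reward task
#'
#' A task where reward is concentrated on a few "rich" actions: those
#' columns draw Uniform(`rich_range`) per state while the remaining columns
#' draw Uniform(`poor_range`). The rich columns are the first
#' `n_rich_actions` columns. Flat state distribution.
#'
#' @param n_states,n_actions task dimensions.
#' @param n_rich_actions number of high-reward columns; must be strictly
#'   less than `n_actions`.
#' @param rng_seed integer seed.
#' @param rich_range,poor_range length-2 numeric ranges for the rich and
#'   poor reward draws.
#' @return a `bandit_task`.
#' @export
make_scarce_task <- function(n_states, n_actions, n_rich_actions, rng_seed,
                             rich_range = c(0.5, 1), poor_range = c(0, 0.05)) {
  if (n_states < 1 || n_actions < 1 || n_rich_actions < 1) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (n_rich_actions >= n_actions) {
    stop("n_rich_actions must be < n_actions", call. = FALSE)
  }
  Q <- with_seed(rng_seed, {
    m <- matrix(stats::runif(n_states * n_actions, poor_range[1], poor_range[2]),
                n_states, n_actions)
    m[, seq_len(n_rich_actions)] <-
      stats::runif(n_states * n_rich_actions, rich_range[1], rich_range[2])
    m
  })
  bandit_task(rep(1 / n_states, n_states), Q)
}

#' The six-state, seven-action experiment task
#'
#' Six states under a flat state distribution and seven actions: each state
#' has one uniquely optimal "unsafe" action yielding `reward_optimal`, the
#' other unsafe actions yield `reward_wrong`, and a seventh safety action
#' yields `reward_safety` in every state. The non-response timeout penalty
#' of the behavioral paradigm punishes not acting and is therefore not part
#' of the reward matrix.
#'
#' @param reward_optimal reward of a state's optimal action (default +1).
#' @param reward_wrong reward of a non-optimal unsafe action (default
#'   -0.18).
#' @param reward_safety constant reward of the safety action (default
#'   +0.2).
#' @return a `bandit_task` with `safety_index = 7`.
#' @export
make_experiment_task <- function(reward_optimal = 1, reward_wrong = -0.18,
                                 reward_safety = 0.2) {
  Q <- matrix(reward_wrong, 6, 7)
  Q[cbind(1:6, 1:6)] <- reward_optimal
  Q[, 7] <- reward_safety
  bandit_task(rep(1 / 6, 6), Q,
              action_labels = c(paste0("key", 1:6), "safety"),
              safety_index = 7L)
}

#' Add Gaussian noise to a task's rewards
#'
#' Returns a copy of `task` whose reward entries are independently smeared
#' with Gaussian noise of standard deviation `noise_sd`; the state
#' distribution is untouched. Models an agent whose learned reward values
#' are imperfect.
#'
#' @param task a `bandit_task`.
#' @param noise_sd non-negative noise standard deviation.
#' @param rng_seed integer seed.
#' @return a new `bandit_task` with perturbed rewards.
#' @export
perturb_rewards <- function(task, noise_sd, rng_seed) {
  validate_task(task)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  Q <- task$rewards
  if (noise_sd > 0) {
    Q <- Q + with_seed(rng_seed,
                       matrix(stats::rnorm(length(Q), 0, noise_sd),
                              nrow(Q), ncol(Q)))
  }
  # the noisy safety column is no longer constant, so drop the marker
  si <- if (noise_sd > 0) NULL else task$safety_index
  bandit_task(task$state_probs, Q, task$action_labels, si)
}

#' General (state-marginalized) action values
#'
#' `V(a) = sum_s P(s) Q(s, a)`: the expected reward of always taking action
#' `a` regardless of the state. Ranks actions by their context-free worth
#' and drives the general-value proposal distribution.
#'
#' @param task a `bandit_task`.
#' @return named numeric vector of length `n_actions(task)`.
#' @export
general_values <- function(task) {
  validate_task(task)
  v <- as.numeric(crossprod(task$state_probs, task$rewards))
  names(v) <- task$action_labels
  v
}

# Cheap deterministic content fingerprint used to guard against evaluating
# a policy on one task against a frontier traced on another.
task_fingerprint <- function(task) {
  Q <- task$rewards
  idx <- outer(seq_len(nrow(Q)), seq_len(ncol(Q)), function(i, j) i * 31 + j)
  sprintf("%dx%d|%s|%s|%s",
          nrow(Q), ncol(Q),
          format(sum(task$state_probs * seq_along(task$state_probs)),
                 digits = 15),
          format(sum(Q * idx), digits = 15),
          format(sum(abs(Q)), digits = 15))
}

#' Serialize a task to JSON or CSV
#'
#' The JSON layout is a single object with fields `state_probs`, `rewards`
#' (row-major nested arrays), `action_labels` and `safety_index`
#' (0-based in the file, `null` if absent). The CSV form is a pair of
#' files: the state-probability vector and the reward matrix with a header
#' row of action labels. The JSON round trip is bit-exact.
#'
#' @param task a `bandit_task`.
#' @param path output file path (for CSV, the reward-matrix file).
#' @param probs_path state-probability CSV path.
#' @return `path`, invisibly (writers); a `bandit_task` (readers).
#' @export
write_task_json <- function(task, path) {
  validate_task(task)
  obj <- list(
    state_probs = I(task$state_probs),
    rewards = lapply(seq_len(nrow(task$rewards)),
                     function(i) I(unname(task$rewards[i, ]))),
    action_labels = I(task$action_labels),
    safety_index = if (is.null(task$safety_index)) NULL else
      task$safety_index - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_task_json
#' @export
read_task_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  si <- obj$safety_index
  Q <- obj$rewards
  if (is.list(Q)) Q <- do.call(rbind, Q)
  bandit_task(obj$state_probs, as.matrix(Q), obj$action_labels,
              if (is.null(si)) NULL else as.integer(si) + 1L)
}

#' @rdname write_task_json
#' @export
write_task_csv <- function(task, path, probs_path) {
  validate_task(task)
  Q <- as.data.frame(task$rewards)
  names(Q) <- task$action_labels
  utils::write.csv(Q, path, row.names = FALSE)
  utils::write.csv(data.frame(state_prob = task$state_probs), probs_path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_task_json
#' @param safety_index optional 1-based safety-action index to reinstate
#'   when reading the CSV pair (CSV does not carry it).
#' @export
read_task_csv <- function(path, probs_path, safety_index = NULL) {
  Q <- utils::read.csv(path, check.names = FALSE)
  p <- utils::read.csv(probs_path)$state_prob
  bandit_task(p, as.matrix(Q), names(Q), safety_index)
}
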