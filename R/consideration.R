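#' Action proposal distributions
#'
#' The distribution from which candidate actions are sampled into an
#' agent's consideration set. Three kinds are supported:
#' \describe{
#'   \item{flat}{uniform over all actions.}
#'   \item{general_value}{proportional to the general value
#'     `V(a) = sum_s P(s) Q(s, a)`. If any `V(a)` is non-positive the
#'     whole vector is shifted by `-min(V) + 1e-6 * range(V)` before
#'     normalizing, which preserves the ranking while keeping the proposal
#'     a proper distribution; tasks with all-positive general values are
#'     unaffected.}
#'   \item{oracle}{the marginal action distribution of the full-task
#'     optimal policy at a given `beta` — a benchmark that requires
#'     knowing the optimum.}
#' }
#'
#' @param task a `bandit_task`.
#' @param kind one of `"flat"`, `"general_value"`, `"oracle"`.
#' @param beta Lagrange multiplier; required for `kind = "oracle"`.
#' @param ... further arguments (`tol`, `max_iter`) passed to
#'   [blahut_arimoto()] for the oracle kind.
#' @return an `action_proposal`: list with `kind`, `probs` and `beta`.
#' @export
proposal_distribution <- function(task,
                                  kind = c("flat", "general_value", "oracle"),
                                  beta = NULL, ...) {
  validate_task(task)
  kind <- match.arg(kind)
  na <- n_actions(task)
  probs <- switch(kind,
    flat = rep(1 / na, na),
    general_value = {
      v <- general_values(task)
      if (min(v) <= 0) {
        rng <- diff(range(v))
        v <- v - min(v) + 1e-6 * if (rng > 0) rng else 1
      }
      as.numeric(v / sum(v))
    },
    oracle = {
      if (is.null(beta)) {
        stop("the oracle proposal requires beta", call. = FALSE)
      }
      marginal_action_dist(task$state_probs,
                           blahut_arimoto(task, beta, ...))
    })
  structure(list(kind = kind, probs = probs,
                 beta = if (kind == "oracle") beta else NULL),
            class = "action_proposal")
}

#' @export
print.action_proposal <- function(x, ...) {
  cat(sprintf("<action_proposal> kind = %s over %d actions\n",
              x$kind, length(x$probs)))
  invisible(x)
}

#' Sample actions into a consideration set
#'
#' Draws `size` action indices from a proposal distribution, either i.i.d.
#' with replacement (the sample-size regime, resource = number of draws
#' `n`) or without replacement via sequential weighted draws with
#' renormalization over the remaining actions (the set-size regime,
#' resource = number of distinct actions).
#'
#' @param proposal an `action_proposal`.
#' @param size number of draws.
#' @param with_replacement logical sampling regime.
#' @param rng_seed integer seed.
#' @return an `action_sample`: list with `draws` (indices in draw order),
#'   `unique_actions` (sorted distinct indices), `with_replacement` and
#'   the generating `proposal`.
#' @export
sample_actions <- function(proposal, size, with_replacement, rng_seed) {
  stopifnot(inherits(proposal, "action_proposal"))
  if (size < 1 || size != round(size)) {
    stop("size must be a positive integer", call. = FALSE)
  }
  support <- sum(proposal$probs > 0)
  if (!with_replacement && size > support) {
    stop("cannot draw more distinct actions than the proposal supports",
         call. = FALSE)
  }
  draws <- with_seed(rng_seed,
    sample.int(length(proposal$probs), size = size,
               replace = with_replacement, prob = proposal$probs))
  structure(list(draws = draws,
                 unique_actions = sort(unique(draws)),
                 with_replacement = isTRUE(with_replacement),
                 proposal = proposal),
            class = "action_sample")
}

#' Restrict a task to an action consideration set
#'
#' Removes all reward columns outside `actions`; the state distribution is
#' unchanged. The retained original indices are kept in the
#' `parent_actions` attribute so that policies over the restricted task can
#' be embedded back into the full action space. The safety marker is
#' remapped when the safety action is retained and cleared otherwise.
#'
#' @param task a `bandit_task`.
#' @param actions non-empty vector of action indices to retain.
#' @return a restricted `bandit_task`.
#' @export
restrict_task <- function(task, actions) {
  validate_task(task)
  actions <- sort(unique(as.integer(actions)))
  if (length(actions) == 0) {
    stop("actions must be non-empty", call. = FALSE)
  }
  if (any(actions < 1 | actions > n_actions(task))) {
    stop("invalid action index", call. = FALSE)
  }
  si <- task$safety_index
  si <- if (!is.null(si) && si %in% actions) match(si, actions) else NULL
  out <- bandit_task(task$state_probs,
                     task$rewards[, actions, drop = FALSE],
                     task$action_labels[actions], si)
  attr(out, "parent_actions") <- actions
  out
}

#' Embed a restricted-task policy into the full action space
#'
#' Inverse of [restrict_task()] on the policy side: columns for excluded
#' actions are zero.
#'
#' @param policy policy over a restricted task's actions.
#' @param parent_actions the retained original indices (the restricted
#'   task's `parent_actions` attribute).
#' @param n_actions_full width of the full action space.
#' @return full-width policy matrix.
#' @export
expand_policy <- function(policy, parent_actions, n_actions_full) {
  policy <- validate_policy(policy)
  if (length(parent_actions) != ncol(policy)) {
    stop("parent_actions must match the policy's action count",
         call. = FALSE)
  }
  full <- matrix(0, nrow(policy), n_actions_full)
  full[, parent_actions] <- policy
  full
}

#' Maximum attainable policy complexity for a consideration set
#'
#' Mutual information is capped both by the set size (`log2` of the number
#' of distinct actions) and by the state entropy ceiling (`log2` of the
#' number of states, attained under a flat state distribution).
#'
#' @param set_size number of distinct actions considered.
#' @param n_states number of task states.
#' @return upper bound in bits.
#' @export
max_complexity_bound <- function(set_size, n_states) {
  if (set_size < 1 || n_states < 1) {
    stop("arguments must be positive", call. = FALSE)
  }
  min(log2(set_size), log2(n_states))
}

#' Enumerate subset reward-complexity frontiers
#'
#' Traces one frontier per action subset of a given size, optionally
#' constrained to subsets that include (or exclude) the task's safety
#' action. Refuses combinatorially infeasible enumerations (more than
#' 1e5 subsets).
#'
#' @param task a `bandit_task`.
#' @param set_size subset size.
#' @param safety_rule `"include"`, `"exclude"`, or `"ignore"` (no
#'   constraint).
#' @param beta_grid passed to [trace_frontier()].
#' @param tol,max_iter passed to [blahut_arimoto()].
#' @return list of entries, each with `actions` (original indices),
#'   `safety_included` and `frontier`.
#' @export
enumerate_subset_frontiers <- function(task, set_size,
                                       safety_rule = c("ignore", "include",
                                                       "exclude"),
                                       beta_grid = default_beta_grid(),
                                       tol = 1e-10, max_iter = 10000L) {
  validate_task(task)
  safety_rule <- match.arg(safety_rule)
  na <- n_actions(task)
  if (set_size < 1 || set_size > na) {
    stop("set_size must be between 1 and n_actions", call. = FALSE)
  }
  si <- task$safety_index
  if (safety_rule != "ignore" && is.null(si)) {
    stop("task has no safety action", call. = FALSE)
  }
  subsets <- switch(safety_rule,
    ignore = utils::combn(na, set_size, simplify = FALSE),
    include = {
      rest <- setdiff(seq_len(na), si)
      if (set_size == 1L) list(si)
      else lapply(utils::combn(rest, set_size - 1L, simplify = FALSE),
                  function(s) sort(c(si, s)))
    },
    exclude = {
      rest <- setdiff(seq_len(na), si)
      if (set_size > length(rest)) {
        stop("set_size exceeds the number of non-safety actions",
             call. = FALSE)
      }
      utils::combn(rest, set_size, simplify = FALSE)
    })
  if (length(subsets) > 1e5) {
    stop(sprintf("refusing to enumerate %d subsets (limit 1e5)",
                 length(subsets)), call. = FALSE)
  }
  lapply(subsets, function(s) {
    list(actions = as.integer(s),
         safety_included = !is.null(si) && si %in% s,
         frontier = trace_frontier(restrict_task(task, s),
                                   beta_grid = beta_grid,
                                   tol = tol, max_iter = max_iter))
  })
}

# Upper envelope of a list of frontiers on a shared complexity grid.
pointwise_max_frontier <- function(frontiers, grid) {
  rewards <- sapply(frontiers, frontier_reward_at,
                    complexity_bits = grid)
  if (is.null(dim(rewards))) rewards <- matrix(rewards, nrow = length(grid))
  data.frame(complexity_bits = grid,
             reward = apply(rewards, 1, max))
}

#' Set-size-specific reward-complexity frontier
#'
#' For a task with a safety action, the best achievable reward at every
#' complexity level when exactly `set_size` distinct actions are
#' considered: the pointwise maximum over the best safety-including and
#' best safety-excluding subset frontiers of that size, interpolated on a
#' shared complexity grid. For tasks whose non-safety actions are
#' exchangeable (such as the built-in experiment task) a single
#' representative subset per branch suffices (`use_symmetry = TRUE`);
#' set `use_symmetry = FALSE` to force full enumeration for asymmetric
#' tasks.
#'
#' @param task a `bandit_task` with a `safety_index`.
#' @param set_size number of distinct actions considered.
#' @param beta_grid passed to [trace_frontier()].
#' @param use_symmetry treat non-safety actions as exchangeable.
#' @param n_grid number of points on the shared complexity grid.
#' @param tol,max_iter passed to [blahut_arimoto()].
#' @return an `rc_frontier` whose points carry `NA` betas, sorted by
#'   complexity; attribute `branches` holds the per-branch frontiers.
#' @export
na_specific_frontier <- function(task, set_size,
                                 beta_grid = default_beta_grid(),
                                 use_symmetry = TRUE, n_grid = 512L,
                                 tol = 1e-10, max_iter = 10000L) {
  validate_task(task)
  si <- task$safety_index
  if (is.null(si)) {
    stop("task has no safety action", call. = FALSE)
  }
  na <- n_actions(task)
  if (set_size < 1 || set_size > na) {
    stop("set_size must be between 1 and n_actions", call. = FALSE)
  }
  unsafe <- setdiff(seq_len(na), si)
  branches <- list()
  if (use_symmetry) {
    include <- sort(c(si, unsafe[seq_len(set_size - 1L)]))
    branches$include <- trace_frontier(restrict_task(task, include),
                                       beta_grid, tol, max_iter)
    if (set_size <= length(unsafe)) {
      exclude <- unsafe[seq_len(set_size)]
      branches$exclude <- trace_frontier(restrict_task(task, exclude),
                                         beta_grid, tol, max_iter)
    }
  } else {
    all_fronts <- list()
    for (rule in c("include", "exclude")) {
      if (rule == "exclude" && set_size > length(unsafe)) next
      subs <- enumerate_subset_frontiers(task, set_size, rule, beta_grid,
                                         tol, max_iter)
      fs <- lapply(subs, `[[`, "frontier")
      branches[[rule]] <- fs[[which.max(vapply(
        fs, function(f) max(f$points$reward), numeric(1)))]]
      all_fronts <- c(all_fronts, fs)
    }
    branches$.all <- all_fronts
  }
  fronts <- if (is.null(branches$.all)) branches else branches$.all
  cmax <- max(vapply(fronts,
                     function(f) max(f$points$complexity_bits), numeric(1)))
  grid <- seq(0, cmax, length.out = n_grid)
  pts <- pointwise_max_frontier(fronts, grid)
  pts <- cbind(beta = NA_real_, pts)
  structure(list(points = pts,
                 task_fingerprint = task_fingerprint(task),
                 policies = NULL,
                 set_size = set_size),
            class = "rc_frontier",
            branches = branches[names(branches) != ".all"])
}

#' Export a bundle of subset frontiers
#'
#' Writes one frontier CSV per subset plus a JSON index mapping each
#' subset (0-based indices in the file) to its CSV file, set size and
#' safety flag.
#'
#' @param bundle result of [enumerate_subset_frontiers()].
#' @param dir output directory (created if needed).
#' @return the index file path, invisibly.
#' @export
write_subset_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- lapply(seq_along(bundle), function(i) {
    file <- sprintf("subset_%03d.csv", i)
    write_frontier_csv(bundle[[i]]$frontier, file.path(dir, file))
    list(subset = I(bundle[[i]]$actions - 1L),
         set_size = length(bundle[[i]]$actions),
         safety_included = bundle[[i]]$safety_included,
         file = file)
  })
  path <- file.path(dir, "index.json")
  jsonlite::write_json(index, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
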