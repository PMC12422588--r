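#' Simulation condition
#'
#' One cell of the Monte-Carlo sweep: a task, a proposal kind, a
#' bias-correction algorithm (`"BA"` runs Blahut-Arimoto on the retained
#' distinct actions; `"SNIS"` runs the self-normalized importance-sampling
#' estimator), a sampling regime, a resource size (number of distinct
#' actions for without-replacement sampling, number of draws for
#' with-replacement sampling), a `beta`, the number of replicates and a
#' master seed. SNIS is only defined for with-replacement sampling.
#'
#' @param task_name identifier recorded in outputs.
#' @param proposal_kind `"flat"`, `"general_value"` or `"oracle"`.
#' @param algorithm `"BA"` or `"SNIS"`.
#' @param sampling `"with_replacement"` or `"without_replacement"`.
#' @param size positive resource size.
#' @param beta non-negative Lagrange multiplier.
#' @param n_reps number of Monte-Carlo replicates.
#' @param master_seed integer master seed.
#' @return a `sim_condition` list.
#' @export
sim_condition <- function(task_name, proposal_kind, algorithm, sampling,
                          size, beta, n_reps = 200L, master_seed = 1L) {
  algorithm <- match.arg(algorithm, c("BA", "SNIS"))
  sampling <- match.arg(sampling, c("with_replacement",
                                    "without_replacement"))
  proposal_kind <- match.arg(proposal_kind,
                             c("flat", "general_value", "oracle"))
  if (algorithm == "SNIS" && sampling != "with_replacement") {
    stop("SNIS is only applicable to sampling with replacement",
         call. = FALSE)
  }
  if (size < 1 || size != round(size)) {
    stop("size must be a positive integer", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be positive", call. = FALSE)
  structure(list(task_name = task_name, proposal_kind = proposal_kind,
                 algorithm = algorithm, sampling = sampling,
                 size = as.integer(size), beta = beta,
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed)),
            class = "sim_condition")
}

# Replicate seeds are derived from the task, sampling regime, size and
# beta -- but NOT from the proposal kind or algorithm. Conditions that
# differ only in those two therefore share their random draws (common
# random numbers), which pairs the comparisons the sweep is designed for
# (proposal vs proposal, BA vs SNIS at matched samples) and sharply
# reduces the variance of their differences.
condition_key <- function(condition) {
  paste(condition$task_name, condition$sampling, condition$size,
        format(condition$beta, digits = 12), sep = "|")
}

#' Run one simulation condition
#'
#' For each replicate: derive a per-replicate seed from the master seed,
#' the condition and the replicate index; sample actions from the proposal
#' (oracle proposals use the condition's `beta`); fit the condition's
#' algorithm at `beta`; and evaluate the resulting policy's complexity,
#' reward under the true task, and loss against the full-action-space
#' frontier. Replicates that fail are excluded and counted.
#'
#' @param condition a `sim_condition`.
#' @param task the `bandit_task` to simulate on.
#' @param full_frontier frontier traced on `task`.
#' @param proposal optional precomputed `action_proposal` (oracle
#'   proposals are expensive, so sweeps cache them per beta).
#' @param ba_tol,ba_max_iter solver settings for the per-replicate fits.
#' @return a `sim_result`: list with `per_rep` (data frame `rep`,
#'   `complexity_bits`, `reward`, `loss`), `aggregates` (mean/SEM of each),
#'   `n_failed` and the `condition`.
#' @export
run_condition <- function(condition, task, full_frontier, proposal = NULL,
                          ba_tol = 1e-10, ba_max_iter = 10000L) {
  stopifnot(inherits(condition, "sim_condition"))
  validate_task(task)
  if (is.null(proposal)) {
    proposal <- proposal_distribution(task, condition$proposal_kind,
                                      beta = condition$beta)
  }
  key <- condition_key(condition)
  with_rep <- condition$sampling == "with_replacement"
  rows <- vector("list", condition$n_reps)
  n_failed <- 0L
  for (r in seq_len(condition$n_reps)) {
    seed <- derive_seed(condition$master_seed, key, r)
    res <- tryCatch({
      smp <- sample_actions(proposal, condition$size, with_rep, seed)
      if (condition$algorithm == "BA") {
        rt <- restrict_task(task, smp$unique_actions)
        pol <- suppressWarnings(
          blahut_arimoto(rt, condition$beta, tol = ba_tol,
                         max_iter = ba_max_iter))
        full <- expand_policy(pol, attr(rt, "parent_actions"),
                              n_actions(task))
        list(complexity_bits = policy_complexity(task$state_probs, full),
             reward = trial_averaged_reward(task, full),
             loss = reward_loss(task, full, full_frontier))
      } else {
        est <- suppressWarnings(
          snis_policy(task, smp, condition$beta, tol = ba_tol,
                      max_iter = ba_max_iter))
        evaluate_snis(task, est, full_frontier)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      rows[[r]] <- data.frame(rep = r,
                              complexity_bits = res$complexity_bits,
                              reward = res$reward, loss = res$loss)
    }
  }
  per_rep <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(per_rep = per_rep,
                 aggregates = aggregate_reps(per_rep),
                 n_failed = n_failed,
                 condition = condition),
            class = "sim_result")
}

# mean and standard error (sample SD / sqrt(n)) of each evaluated quantity
aggregate_reps <- function(per_rep) {
  agg <- function(x) {
    n <- length(x)
    c(mean = mean(x),
      sem = if (n > 1) stats::sd(x) / sqrt(n) else 0)
  }
  if (is.null(per_rep) || nrow(per_rep) == 0) {
    return(data.frame(n = 0L, complexity_mean = NA_real_,
                      complexity_sem = NA_real_, reward_mean = NA_real_,
                      reward_sem = NA_real_, loss_mean = NA_real_,
                      loss_sem = NA_real_))
  }
  cb <- agg(per_rep$complexity_bits)
  rw <- agg(per_rep$reward)
  ls <- agg(per_rep$loss)
  data.frame(n = nrow(per_rep),
             complexity_mean = cb[["mean"]], complexity_sem = cb[["sem"]],
             reward_mean = rw[["mean"]], reward_sem = rw[["sem"]],
             loss_mean = ls[["mean"]], loss_sem = ls[["sem"]])
}

#' Build a simulation suite configuration
#'
#' Describes the full Cartesian sweep: proposal kinds crossed with the
#' three algorithm/sampling rows (BA without replacement over distinct-set
#' sizes; SNIS with replacement over draw counts; BA with replacement over
#' draw counts) and a `beta` grid, replicated `n_reps` times from a master
#' seed.
#'
#' @param task_name identifier recorded in outputs.
#' @param beta_grid vector of `beta` values.
#' @param proposals proposal kinds to sweep.
#' @param na_sizes distinct-action set sizes for without-replacement
#'   sampling.
#' @param n_sizes draw counts for with-replacement sampling.
#' @param n_reps replicates per condition.
#' @param master_seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(task_name = "random_16x32",
                       beta_grid = default_beta_grid(12L, 0.05, 20),
                       proposals = c("flat", "general_value", "oracle"),
                       na_sizes = c(2L, 4L, 8L, 16L),
                       n_sizes = c(2L, 8L, 32L, 128L),
                       n_reps = 200L, master_seed = 1L) {
  structure(list(task_name = task_name, beta_grid = as.numeric(beta_grid),
                 proposals = proposals, na_sizes = as.integer(na_sizes),
                 n_sizes = as.integer(n_sizes), n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

#' Run the full simulation suite
#'
#' Sweeps every (proposal, algorithm/sampling row, size, beta) cell of the
#' configuration on `task`, returning one long-format row per replicate.
#' Oracle proposals are computed once per `beta` and reused across
#' replicates and sizes. The output is a pure function of
#' (config, task): rerunning with the same master seed reproduces it
#' exactly.
#'
#' @param config a `sim_config`.
#' @param task the `bandit_task` to simulate on.
#' @param full_frontier optional pre-traced full frontier (traced from the
#'   config's beta grid when omitted).
#' @param ba_tol,ba_max_iter solver settings.
#' @return long-format data frame with columns `task`, `proposal`,
#'   `algorithm`, `sampling`, `size`, `beta`, `rep`, `complexity_bits`,
#'   `reward`, `loss`.
#' @export
run_suite <- function(config, task, full_frontier = NULL,
                      ba_tol = 1e-10, ba_max_iter = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  validate_task(task)
  if (is.null(full_frontier)) {
    full_frontier <- trace_frontier(task, default_beta_grid())
  }
  rows <- list(
    list(algorithm = "BA", sampling = "without_replacement",
         sizes = config$na_sizes),
    list(algorithm = "SNIS", sampling = "with_replacement",
         sizes = config$n_sizes),
    list(algorithm = "BA", sampling = "with_replacement",
         sizes = config$n_sizes))
  out <- list()
  for (beta in config$beta_grid) {
    # cache each proposal once per beta (only oracle depends on beta)
    props <- lapply(stats::setNames(config$proposals, config$proposals),
                    function(k) proposal_distribution(task, k, beta = beta))
    for (row in rows) {
      for (size in row$sizes) {
        if (row$sampling == "without_replacement" &&
            size > n_actions(task)) next
        for (pk in config$proposals) {
          cond <- sim_condition(config$task_name, pk, row$algorithm,
                                row$sampling, size, beta,
                                n_reps = config$n_reps,
                                master_seed = config$master_seed)
          res <- run_condition(cond, task, full_frontier,
                               proposal = props[[pk]],
                               ba_tol = ba_tol, ba_max_iter = ba_max_iter)
          if (is.null(res$per_rep) || nrow(res$per_rep) == 0) next
          out[[length(out) + 1L]] <- cbind(
            data.frame(task = config$task_name, proposal = pk,
                       algorithm = row$algorithm, sampling = row$sampling,
                       size = size, beta = beta),
            res$per_rep)
        }
      }
    }
  }
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  long
}

#' Aggregate a long-format results table
#'
#' Collapses replicates to mean and SEM of complexity, reward and loss per
#' condition cell.
#'
#' @param long long-format data frame from [run_suite()] or
#'   [noisy_q_suite()].
#' @return aggregated data frame, one row per condition.
#' @export
aggregate_suite <- function(long) {
  keys <- intersect(c("task", "proposal", "algorithm", "sampling",
                      "safety_rule", "noise_sd", "size", "beta"),
                    names(long))
  split_idx <- interaction(long[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(long, split_idx)
  out <- do.call(rbind, lapply(parts, function(d) {
    cbind(d[1, keys, drop = FALSE], aggregate_reps(d))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Noisy reward-value simulation suite
#'
#' Models an agent whose learned reward values are corrupted: on each
#' replicate the task's `Q(s, a)` entries are smeared with Gaussian noise,
#' the agent draws its consideration set from the general-value proposal
#' computed on the **noisy** values (the safety action forced in or out
#' according to `safety_rule`), and fits Blahut-Arimoto on the noisy
#' restricted task. The resulting policy is then scored on the **true**
#' task against the true full-action-space frontier, so the loss reflects
#' both the restricted set and the corrupted values.
#'
#' @param task a `bandit_task` with a `safety_index`.
#' @param noise_sds vector of non-negative noise standard deviations.
#' @param set_sizes distinct-action consideration-set sizes.
#' @param beta_grid vector of `beta` values.
#' @param n_reps replicates per cell.
#' @param master_seed integer master seed.
#' @param safety_rules subset of `c("include", "exclude")`.
#' @param full_frontier optional pre-traced true frontier.
#' @param ba_tol,ba_max_iter solver settings.
#' @return long-format data frame with columns `safety_rule`, `noise_sd`,
#'   `size`, `beta`, `rep`, `complexity_bits`, `reward`, `loss`.
#' @export
noisy_q_suite <- function(task, noise_sds, set_sizes,
                          beta_grid = default_beta_grid(8L, 0.05, 20),
                          n_reps = 200L, master_seed = 1L,
                          safety_rules = c("include", "exclude"),
                          full_frontier = NULL,
                          ba_tol = 1e-10, ba_max_iter = 10000L) {
  validate_task(task)
  si <- task$safety_index
  if (is.null(si)) stop("task has no safety action", call. = FALSE)
  if (any(noise_sds < 0)) stop("noise_sds must be non-negative",
                               call. = FALSE)
  safety_rules <- match.arg(safety_rules, several.ok = TRUE)
  if (is.null(full_frontier)) {
    full_frontier <- trace_frontier(task, default_beta_grid())
  }
  unsafe <- setdiff(seq_len(n_actions(task)), si)
  out <- list()
  for (rule in safety_rules) {
    for (noise_sd in noise_sds) {
      for (size in set_sizes) {
        n_free <- if (rule == "include") size - 1L else size
        if (n_free > length(unsafe) || (rule == "include" && size < 1L)) next
        for (beta in beta_grid) {
          key <- paste("noisyq", rule, format(noise_sd, digits = 12), size,
                       format(beta, digits = 12), sep = "|")
          reps <- lapply(seq_len(n_reps), function(r) {
            seed <- derive_seed(master_seed, key, r)
            noisy <- perturb_rewards(task, noise_sd, seed)
            chosen <- if (n_free > 0L) {
              p0 <- proposal_distribution(noisy, "general_value")
              pu <- p0$probs[unsafe]
              with_seed(seed + 1, unsafe[sample.int(
                length(unsafe), n_free, replace = FALSE,
                prob = pu / sum(pu))])
            } else integer(0)
            set <- sort(c(if (rule == "include") si, chosen))
            rt <- restrict_task(noisy, set)
            pol <- suppressWarnings(
              blahut_arimoto(rt, beta, tol = ba_tol,
                             max_iter = ba_max_iter))
            full <- expand_policy(pol, attr(rt, "parent_actions"),
                                  n_actions(task))
            data.frame(rep = r,
                       complexity_bits = policy_complexity(
                         task$state_probs, full),
                       reward = trial_averaged_reward(task, full),
                       loss = reward_loss(task, full, full_frontier))
          })
          out[[length(out) + 1L]] <- cbind(
            data.frame(safety_rule = rule, noise_sd = noise_sd,
                       size = size, beta = beta),
            do.call(rbind, reps))
        }
      }
    }
  }
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  long
}
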