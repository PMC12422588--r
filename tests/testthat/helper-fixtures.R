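# Shared fixtures. Frontier tracing is the expensive step, so the tasks
# and their full frontiers are built once per test run.

experiment_task <- make_experiment_task()
experiment_frontier <- trace_frontier(experiment_task)

random_task <- make_random_task(16, 32, rng_seed = 1)

# deterministic state -> optimal-action policy on the experiment task
optimal_policy <- function(task = experiment_task) greedy_policy(task)

# state-independent point mass on one action
point_mass_policy <- function(task, action) {
  pol <- matrix(0, n_states(task), n_actions(task))
  pol[, action] <- 1
  pol
}

random_frontier <- function() {
  # traced lazily and memoised: only a few test files need it
  if (is.null(.fixture_env$random_frontier)) {
    .fixture_env$random_frontier <- trace_frontier(random_task)
  }
  .fixture_env$random_frontier
}
.fixture_env <- new.env()
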