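Package: policompress
Title: Policy Compression over Action Consideration Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resource-rational analysis of action selection in contextual
    multi-armed bandits under a channel-capacity constraint. Computes
    capacity-limited optimal policies and reward-complexity frontiers via
    the Blahut-Arimoto algorithm, restricts tasks to partial action
    consideration sets sampled from flat, general-value or oracle proposal
    distributions, corrects sampling bias with a self-normalized
    importance-sampling policy estimator, runs seeded Monte-Carlo
    simulation suites (including noisy reward-value variants), and
    estimates policy complexity and consideration-set size from choice
    data with a Dirichlet-regularized mutual-information estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
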