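# Shared fixtures: all fixtures are built in code at test time.

# All 256 possible 8-bit puzzle inputs, one per row.
all_puzzle_inputs <- function() {
  as.matrix(expand.grid(rep(list(0:1), 8)))
}

# Independent proficiency oracle: exhaustive mean of solved bits over all 256
# puzzles, scoring only register positions an OUTPUT gene wrote.
exhaustive_proficiency <- function(genome) {
  inputs <- all_puzzle_inputs()
  mean(apply(inputs, 1, function(bits) {
    out <- evaluate_genome(genome, puzzle(as.integer(bits)))
    sum(attr(out, "written") & out == 1L - as.integer(bits))
  }))
}

# Fully independent evaluator: drive the R step-wise executor to completion.
evaluate_stepwise <- function(genome, pz) {
  st <- new_exec_state(genome)
  while (st$read_head < genome_length(genome))
    st <- execute_next(genome, st, pz)
  st
}

# A small, fast configuration for engine unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(capacity = 40, max_steps = 500,
                                 proficiency_n_puzzles = 20), list(...))
  do.call(sim_config, args)
}

# Chi-square goodness of fit of observed counts against probabilities,
# merging bins until every expected count is at least 5.
chisq_gof_p <- function(observed, probs) {
  stopifnot(length(observed) == length(probs))
  n <- sum(observed)
  expected <- n * probs
  obs_m <- numeric(0); exp_m <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(expected)) {
    acc_o <- acc_o + observed[i]; acc_e <- acc_e + expected[i]
    if (acc_e >= 5) {
      obs_m <- c(obs_m, acc_o); exp_m <- c(exp_m, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {
    obs_m[length(obs_m)] <- obs_m[length(obs_m)] + acc_o
    exp_m[length(exp_m)] <- exp_m[length(exp_m)] + acc_e
  }
  stat <- sum((obs_m - exp_m)^2 / exp_m)
  stats::pchisq(stat, df = length(obs_m) - 1, lower.tail = FALSE)
}

# Total energy held by organisms in an engine state.
state_org_energy <- function(state) {
  sum(vapply(state$organisms, `[[`, numeric(1), "energy"))
}

state_gene_count <- function(state) {
  sum(vapply(state$organisms, function(o) nrow(o$genome), numeric(1))) +
    nrow(state$gene_pool)
}
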