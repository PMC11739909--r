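# Small builders used across the suite.

make_var <- function(counts, name = "var", reported_p = NULL) {
  cat_variable(name, as.matrix(counts), reported_p = reported_p)
}

make_trial <- function(group_sizes, ..., id = "trialA") {
  trial_record(id, group_sizes, list(...))
}

# One small two-arm trial with clean sums: counts columns sum to group sizes.
clean_trial <- function(id = "t1") {
  trial_record(id, c(20L, 20L), list(
    cat_variable("sex", matrix(c(12L, 8L, 11L, 9L), 2),
                 levels = c("m", "f")),
    cat_variable("smoker", matrix(c(5L, 15L, 7L, 13L), 2),
                 levels = c("yes", "no"))
  ))
}

# Memoized datasets so expensive generation runs once per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The honest desk-scale dataset at the generator's default study
# conditions (~170 trials).
honest_dataset <- function() {
  cached("honest", generate_trials(generator_config(seed = 20260201)))
}

# The anomaly-injection dataset: 20% over-similar, 5% sum errors,
# 10% corrupted p-values.
injected_dataset <- function() {
  cached("injected", generate_trials(generator_config(
    seed = 20260202,
    anomaly_rates = c(over_similar = 0.20, sum_error = 0.05,
                      corrupt_p = 0.10)
  )))
}

# Brute-force oracle: enumerate every allocation of n1 of the N
# participants to group 1 (total of the N carry the level) and tally
# d = |count_g1 - count_g2| exactly.
brute_force_diff <- function(total, n1, n2) {
  N <- n1 + n2
  carriers <- seq_len(total)
  alloc <- utils::combn(N, n1)
  d <- apply(alloc, 2, function(g1) {
    x <- sum(g1 %in% carriers)
    abs(x - (total - x))
  })
  tab <- table(factor(d, levels = 0:N))
  as.numeric(tab) / ncol(alloc)
}

example_table_path <- function() {
  system.file("extdata", "example_baseline_table.tsv",
              package = "trialscan")
}
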