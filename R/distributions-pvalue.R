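#' Test-selection policies for baseline p-value distributions
#'
#' A policy decides which variables enter a p-value distribution analysis
#' and which single test produces each variable's p-value, as a function of
#' the table shape and sparse-data status. The registered policies cover
#' the analysis variants of interest:
#'
#' * `chisq_all` — Pearson chi-square for every variable (the common
#'   published practice, sparse data included).
#' * `fisher_sparse_2x2` — sparse 2x2 tables only, Fisher exact.
#' * `midp_sparse_2x2` — sparse 2x2 tables only, mid-p.
#' * `chisq_nonsparse` — non-sparse tables only, Pearson chi-square.
#' * `midp2x2_chisq_larger` — non-sparse tables only; mid-p for 2x2,
#'   chi-square for larger.
#' * `chisq_plus_fisher_sparse` — all tables; chi-square when not sparse,
#'   Fisher (exact or Monte-Carlo) when sparse.
#' * `midp2x2_plus_chisq_or_fisher` — all tables; mid-p for 2x2, and for
#'   larger tables chi-square when not sparse, Monte-Carlo Fisher when
#'   sparse.
#'
#' All-or-nothing variables (no two-way table) are excluded by every
#' policy.
#'
#' @param name Policy name.
#' @return A policy object (list with `name`, `selects(shape, sparse)` and
#'   `test(shape, sparse)`).
#' @export
p_policy <- function(name) {
  policies <- list(
    chisq_all = list(
      selects = function(shape, sparse) TRUE,
      test = function(shape, sparse) "pearson"),
    fisher_sparse_2x2 = list(
      selects = function(shape, sparse) shape == "2x2" && sparse,
      test = function(shape, sparse) "fisher"),
    midp_sparse_2x2 = list(
      selects = function(shape, sparse) shape == "2x2" && sparse,
      test = function(shape, sparse) "midp"),
    chisq_nonsparse = list(
      selects = function(shape, sparse) !sparse,
      test = function(shape, sparse) "pearson"),
    midp2x2_chisq_larger = list(
      selects = function(shape, sparse) !sparse,
      test = function(shape, sparse)
        if (shape == "2x2") "midp" else "pearson"),
    chisq_plus_fisher_sparse = list(
      selects = function(shape, sparse) TRUE,
      test = function(shape, sparse)
        if (sparse) "fisher" else "pearson"),
    midp2x2_plus_chisq_or_fisher = list(
      selects = function(shape, sparse) TRUE,
      test = function(shape, sparse) {
        if (shape == "2x2") "midp"
        else if (sparse) "fisher" else "pearson"
      })
  )
  if (!name %in% names(policies))
    stop("unknown test policy ", sQuote(name), "; registered: ",
         paste(names(policies), collapse = ", "), call. = FALSE)
  c(list(name = name), policies[[name]])
}

#' @rdname p_policy
#' @export
p_policies <- function() {
  c("chisq_all", "fisher_sparse_2x2", "midp_sparse_2x2", "chisq_nonsparse",
    "midp2x2_chisq_larger", "chisq_plus_fisher_sparse",
    "midp2x2_plus_chisq_or_fisher")
}

# Apply a policy's test to one count matrix; NA when the variable is not
# selected or the test inapplicable. Sparse status is taken from
# `classify_sparse(ref_counts)` (by default the counts themselves); for
# simulated re-draws the observed table's classification is reused so the
# variable set and test choice stay fixed across simulations.
policy_p_value <- function(policy, counts, group_sizes, ref_counts = counts,
                           mc_n_sims = 2000, mc_seed = 20260101) {
  if (is_all_or_nothing(ref_counts, group_sizes)) return(NA_real_)
  sp <- classify_sparse(ref_counts)
  sparse <- sp$status == "sparse"
  if (!policy$selects(sp$table_shape, sparse)) return(NA_real_)
  test <- policy$test(sp$table_shape, sparse)
  res <- switch(test,
    pearson = pearson_chi_square(counts),
    midp = midp_2x2(counts),
    fisher = if (all(dim(counts) == c(2L, 2L))) fisher_exact_2x2(counts)
             else fisher_montecarlo_rxc(counts, mc_n_sims, mc_seed)
  )
  if (!res$applicable) NA_real_ else res$p
}

#' Simulate re-randomized null datasets
#'
#' Builds `n_sims` copies of a dataset in which every variable has been
#' independently re-randomized: each group's level counts are drawn from a
#' multinomial with that group's randomized size and the variable's pooled
#' level proportions (every individual's level assigned independently —
#' the binomial null model). Group sizes stay at their reported values, so
#' the simulated datasets share the real dataset's shape but carry no
#' between-group structure.
#'
#' @param trials List of [trial_record()] objects.
#' @param n_sims Number of simulated datasets.
#' @param seed Integer seed.
#' @return List of `n_sims` datasets (each a list of `trial_record`).
#' @export
simulate_null_datasets <- function(trials, n_sims = 100, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_sims), function(s) {
      lapply(trials, function(tr) {
        vars <- lapply(tr$variables, function(v) {
          tot <- sum(v$counts)
          if (tot == 0L) return(v)
          p <- rowSums(v$counts) / tot
          sim <- vapply(tr$group_sizes, function(n)
            stats::rmultinom(1, n, p)[, 1], numeric(nrow(v$counts)))
          sim <- matrix(as.integer(sim), nrow = nrow(v$counts))
          cat_variable(v$name, sim, v$levels, reported_p = NULL,
                       excluded = v$excluded,
                       exclude_reason = v$exclude_reason)
        })
        trial_record(tr$trial_id, tr$group_sizes, vars,
                     source_meta = paste0("simulated #", s))
      })
    })
  })
}

# p-values for every selected variable of a dataset under a policy.
# `ref_trials` supplies the observed tables whose shape/sparseness fix the
# variable selection and test choice.
dataset_policy_pvals <- function(trials, policy, ref_trials = trials,
                                 include_mismatched_sums = TRUE,
                                 mc_n_sims = 2000, mc_seed = 20260101) {
  ps <- numeric(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]; rtr <- ref_trials[[i]]
    vars <- trial_variables(tr); rvars <- trial_variables(rtr)
    for (j in seq_along(vars)) {
      rv <- rvars[[j]]
      if (sum(rv$counts) == 0L) next
      if (!include_mismatched_sums &&
          sum(rv$counts) != sum(rtr$group_sizes)) next
      p <- policy_p_value(policy, vars[[j]]$counts, tr$group_sizes,
                          ref_counts = rv$counts,
                          mc_n_sims = mc_n_sims, mc_seed = mc_seed)
      if (!is.na(p)) ps <- c(ps, p)
    }
  }
  ps
}

p_bins <- function() seq(0, 1, by = 0.1)

bin_pvals <- function(p) {
  # [0,0.1), [0.1,0.2), ..., [0.9,1.0] with the last bin closed
  idx <- pmin(floor(p * 10), 9) + 1L
  tabulate(idx, nbins = 10L)
}

#' Observed vs empirically expected baseline p-value distribution
#'
#' Computes the decile histogram of baseline p-values under a test policy,
#' and compares it with the expected histogram obtained empirically from
#' re-randomized null datasets ([simulate_null_datasets()]). Each
#' variable's test is fixed by its observed table (shape and sparseness),
#' so observed and expected distributions cover the same variable set.
#'
#' @param trials List of [trial_record()] objects.
#' @param policy Policy name (see [p_policy()]).
#' @param n_sims Number of simulated null datasets.
#' @param seed Integer seed (simulation and Monte-Carlo Fisher).
#' @param include_mismatched_sums Keep variables whose frequency sums
#'   disagree with the randomized totals? Default `FALSE`, the primary
#'   analysis set.
#' @param mc_n_sims Simulation count for Monte-Carlo Fisher tests inside
#'   the policy.
#' @return Object of class `p_distribution`: data.frame `distribution`
#'   (`bin`, `observed`, `expected` as proportions), matrix `per_sim`
#'   (simulation x bin proportions), `observed_p` (the raw p-values),
#'   `gof` (from [gof_compare()]), `policy`, `n_variables`, `n_sims`,
#'   `seed`.
#' @export
empirical_p_distribution <- function(trials, policy, n_sims = 100,
                                     seed = 1,
                                     include_mismatched_sums = FALSE,
                                     mc_n_sims = 2000) {
  pol <- p_policy(policy)
  obs_p <- dataset_policy_pvals(
    trials, pol, include_mismatched_sums = include_mismatched_sums,
    mc_n_sims = mc_n_sims, mc_seed = child_seed(seed, "mc_obs"))
  if (length(obs_p) == 0L)
    stop("no variables selected by policy ", sQuote(policy), call. = FALSE)
  sims <- simulate_null_datasets(trials, n_sims,
                                 seed = child_seed(seed, "null_sets"))
  per_sim <- t(vapply(seq_along(sims), function(s) {
    ps <- dataset_policy_pvals(
      sims[[s]], pol, ref_trials = trials,
      include_mismatched_sums = include_mismatched_sums,
      mc_n_sims = mc_n_sims, mc_seed = child_seed(seed, paste0("mc", s)))
    bin_pvals(ps) / length(ps)
  }, numeric(10)))
  obs_counts <- bin_pvals(obs_p)
  gof <- gof_compare(obs_counts, per_sim)
  edges <- p_bins()
  structure(
    list(distribution = data.frame(
           bin = sprintf("%.1f-%.1f", edges[-11], edges[-1]),
           observed = obs_counts / length(obs_p),
           expected = colMeans(per_sim)),
         per_sim = per_sim, observed_p = obs_p, gof = gof,
         policy = policy, n_variables = length(obs_p),
         n_sims = n_sims, seed = seed),
    class = "p_distribution"
  )
}

#' @export
print.p_distribution <- function(x, ...) {
  cat("<p_distribution>", x$n_variables, "p-values under policy",
      sQuote(x$policy), "vs", x$n_sims, "simulated datasets\n")
  print(x$distribution, row.names = FALSE)
  cat(sprintf("GOF: statistic %.3f, MC p = %.4f\n",
              x$gof$statistic, x$gof$p_mc))
  invisible(x)
}

#' Compare an observed histogram with simulated null histograms
#'
#' Chi-square-style goodness-of-fit of observed bin counts against the
#' mean simulated proportions. Bins with expected count below 5 are merged
#' with their neighbours (merge map reported). Because the simulated
#' histograms are themselves random, the reference distribution of the
#' statistic is taken from the simulations: each simulation's own
#' statistic is computed against the mean of the *other* simulations
#' (leave-one-out), and the Monte-Carlo p is the observed statistic's rank
#' among them. The asymptotic chi-square p is also reported for
#' transparency.
#'
#' @param observed_counts Integer vector of observed bin counts.
#' @param per_sim_props Matrix (simulation x bin) of simulated bin
#'   proportions; at least 2 simulations.
#' @return List: `statistic`, `df`, `p_chisq`, `p_mc`, `merge_map`
#'   (merged-bin index per original bin), `warning` (non-empty if the
#'   comparison is degenerate).
#' @export
gof_compare <- function(observed_counts, per_sim_props) {
  stopifnot(nrow(per_sim_props) >= 2,
            length(observed_counts) == ncol(per_sim_props))
  n_obs <- sum(observed_counts)
  mean_props <- colMeans(per_sim_props)
  E <- mean_props * n_obs

  # merge low-expectation bins with an adjacent neighbour until all
  # expected counts reach 5 (or one bin remains)
  merge_map <- seq_along(E)
  grp_of <- function(map) match(map, unique(map))
  repeat {
    g <- grp_of(merge_map)
    Eg <- tapply(E, g, sum)
    if (all(Eg >= 5) || length(Eg) == 1L) break
    i <- which.min(Eg)
    nb <- if (i == 1L) 2L
          else if (i == length(Eg)) i - 1L
          else if (Eg[i - 1] <= Eg[i + 1]) i - 1L else i + 1L
    merge_map[g == i] <- merge_map[which(g == nb)[1]]
    merge_map <- grp_of(merge_map)
  }
  g <- grp_of(merge_map)
  collapse <- function(x) as.numeric(tapply(x, g, sum))
  Om <- collapse(observed_counts); Em <- collapse(E)
  warn <- ""
  if (length(Om) == 1L) {
    return(list(statistic = 0, df = 0, p_chisq = 1, p_mc = 1,
                merge_map = g,
                warning = "all mass in one bin after merging"))
  }
  stat_fun <- function(o, e) sum((o - e)^2 / e)
  stat_obs <- stat_fun(Om, Em)
  n_sims <- nrow(per_sim_props)
  sim_counts <- per_sim_props * n_obs
  stat_sim <- vapply(seq_len(n_sims), function(s) {
    e_s <- colMeans(per_sim_props[-s, , drop = FALSE]) * n_obs
    stat_fun(collapse(sim_counts[s, ]), collapse(e_s))
  }, numeric(1))
  list(
    statistic = stat_obs, df = length(Om) - 1L,
    p_chisq = stats::pchisq(stat_obs, length(Om) - 1L, lower.tail = FALSE),
    p_mc = (1 + sum(stat_sim >= stat_obs)) / (n_sims + 1),
    merge_map = g, warning = warn
  )
}

#' Baseline p-value distribution of a single trial
#'
#' The single-study view: one trial's baseline p-values under one test,
#' against the empirically simulated expectation for that trial alone.
#' Useful for examining an individual flagged study (e.g. a small trial
#' whose exact-test p-values cluster in a narrow band).
#'
#' @param trial A [trial_record()].
#' @param test `"pearson"`, `"midp"` or `"fisher"` applied to all the
#'   trial's analysable variables.
#' @inheritParams empirical_p_distribution
#' @return A `p_distribution` object (see [empirical_p_distribution()]).
#' @export
study_p_distribution <- function(trial, test = "midp", n_sims = 100,
                                 seed = 1, mc_n_sims = 2000) {
  pol <- list(name = paste0("single_study_", test),
              selects = function(shape, sparse) TRUE,
              test = function(shape, sparse) test)
  obs_p <- dataset_policy_pvals(list(trial), pol,
                                mc_n_sims = mc_n_sims,
                                mc_seed = child_seed(seed, "mc_obs"))
  if (length(obs_p) == 0L)
    stop("trial ", sQuote(trial$trial_id), " has no analysable variables",
         call. = FALSE)
  sims <- simulate_null_datasets(list(trial), n_sims,
                                 seed = child_seed(seed, "null_sets"))
  per_sim <- t(vapply(seq_along(sims), function(s) {
    ps <- dataset_policy_pvals(
      sims[[s]], pol, ref_trials = list(trial),
      mc_n_sims = mc_n_sims, mc_seed = child_seed(seed, paste0("mc", s)))
    bin_pvals(ps) / length(ps)
  }, numeric(10)))
  gof <- gof_compare(bin_pvals(obs_p), per_sim)
  edges <- p_bins()
  structure(
    list(distribution = data.frame(
           bin = sprintf("%.1f-%.1f", edges[-11], edges[-1]),
           observed = bin_pvals(obs_p) / length(obs_p),
           expected = colMeans(per_sim)),
         per_sim = per_sim, observed_p = obs_p, gof = gof,
         policy = pol$name, n_variables = length(obs_p),
         n_sims = n_sims, seed = seed),
    class = "p_distribution"
  )
}
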