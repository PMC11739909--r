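#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the shape of a typical published collection of small
#' parallel-arm RCTs: about 170 trials, mostly two-arm with 1:1
#' allocation, a handful of baseline categorical variables per trial
#' (mostly binary, some with 3-4 levels), per-arm sizes of a few dozen
#' participants, and a reported p-value on roughly half the variables,
#' printed at 2-4 decimal places and produced by a chi-square test. All
#' anomaly rates default to 0 (an honest dataset); a mandatory seed makes
#' `config + seed -> dataset` fully reproducible.
#'
#' @param n_trials Number of trials.
#' @param arm_probs Named probabilities over the number of arms.
#' @param group_size_range Per-arm randomized N drawn uniformly from this
#'   integer range.
#' @param equal_arms Probability that all arms of a trial share one drawn
#'   size (1:1 randomization).
#' @param vars_per_trial_mean Mean variables per trial (1 + Poisson).
#' @param level_probs Named probabilities over the number of levels.
#' @param level_prior_alpha Symmetric Dirichlet concentration for the
#'   level probabilities of each variable.
#' @param reported_p_rate Fraction of variables carrying a reported p.
#' @param reported_test Battery test whose p-value the simulated authors
#'   report (`"pearson"`, `"fisher"`, `"midp"`, `"gtest"`).
#' @param decimals_probs Named probabilities over printed decimal places.
#' @param allocation `"fixed_margins"` (permuted assignment conditional on
#'   the level totals; the randomization null) or `"binomial"` (each
#'   group's counts drawn independently from the level distribution).
#' @param anomaly_rates Named rates in \[0, 1\] for
#'   `sum_error`, `over_similar`, `corrupt_p`, `wrong_test`,
#'   `threshold_p`.
#' @param seed Mandatory integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_trials = 170,
                             arm_probs = c(`2` = 0.8, `3` = 0.15,
                                           `4` = 0.05),
                             group_size_range = c(20, 80),
                             equal_arms = 0.7,
                             vars_per_trial_mean = 5.6,
                             level_probs = c(`2` = 0.7, `3` = 0.2,
                                             `4` = 0.1),
                             level_prior_alpha = 2,
                             reported_p_rate = 0.56,
                             reported_test = "pearson",
                             decimals_probs = c(`2` = 0.6, `3` = 0.3,
                                                `4` = 0.1),
                             allocation = c("fixed_margins", "binomial"),
                             anomaly_rates = c(over_similar = 0,
                                               sum_error = 0,
                                               corrupt_p = 0,
                                               wrong_test = 0,
                                               threshold_p = 0),
                             seed) {
  if (missing(seed)) stop("generator_config() requires a seed",
                          call. = FALSE)
  allocation <- match.arg(allocation)
  # count-changing anomalies are applied before p-value corruptions so a
  # later redraw cannot cancel an injected sum error
  rates <- c(over_similar = 0, sum_error = 0, corrupt_p = 0,
             wrong_test = 0, threshold_p = 0)
  rates[names(anomaly_rates)] <- anomaly_rates
  if (any(rates < 0 | rates > 1))
    stop("anomaly rates must lie in [0, 1]", call. = FALSE)
  if (group_size_range[1] < 2)
    stop("group sizes below 2 are not meaningful trial arms",
         call. = FALSE)
  structure(
    list(n_trials = n_trials, arm_probs = arm_probs,
         group_size_range = group_size_range, equal_arms = equal_arms,
         vars_per_trial_mean = vars_per_trial_mean,
         level_probs = level_probs,
         level_prior_alpha = level_prior_alpha,
         reported_p_rate = reported_p_rate,
         reported_test = reported_test,
         decimals_probs = decimals_probs, allocation = allocation,
         anomaly_rates = rates, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path File whose keys are [generator_config()] arguments.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("arm_probs", "level_probs", "decimals_probs",
               "anomaly_rates"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  do.call(generator_config,
          cfg[intersect(names(cfg), names(formals(generator_config)))])
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

sample_named <- function(probs) {
  as.integer(names(probs))[sample.int(length(probs), 1L, prob = probs)]
}

#' Generate a synthetic trial dataset with a ground-truth ledger
#'
#' Honest generation first: every variable's level probabilities come from
#' a Dirichlet prior, level totals from a multinomial over all randomized
#' participants, and per-arm counts from fixed-margins randomization
#' (uniform allocation conditional on level totals and arm sizes;
#' [stats::r2dtable()]) or, optionally, independent binomial assignment.
#' Reported p-values are the configured test's p rounded to the drawn
#' number of decimals — so on an honest dataset every reported p matches
#' its recalculation by construction. Anomalies are then injected via
#' [inject_anomaly()] at the configured rates, and every injection is
#' recorded in the returned ledger.
#'
#' @param config A [generator_config()].
#' @return List: `trials` (list of [trial_record()]) and `ledger`
#'   (data.frame `trial_id`, `variable`, `anomaly`, `detail`).
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    trials <- lapply(seq_len(config$n_trials), function(i) {
      tid <- sprintf("trial%03d", i)
      n_arms <- sample_named(config$arm_probs)
      if (stats::runif(1) < config$equal_arms) {
        gs <- rep(sample.int(diff(config$group_size_range) + 1L, 1L) +
                    config$group_size_range[1] - 1L, n_arms)
      } else {
        gs <- sample.int(diff(config$group_size_range) + 1L, n_arms,
                         replace = TRUE) + config$group_size_range[1] - 1L
      }
      n_vars <- 1L + stats::rpois(1, config$vars_per_trial_mean - 1)
      vars <- lapply(seq_len(n_vars), function(j) {
        L <- sample_named(config$level_probs)
        p <- rdirichlet1(rep(config$level_prior_alpha, L))
        totals <- stats::rmultinom(1, sum(gs), p)[, 1]
        counts <- if (config$allocation == "fixed_margins")
          stats::r2dtable(1, totals, gs)[[1]]
        else
          vapply(gs, function(n) stats::rmultinom(1, n, p)[, 1],
                 numeric(L))
        counts <- matrix(as.integer(counts), nrow = L)
        v <- cat_variable(sprintf("var%02d", j), counts,
                          levels = paste0("level", seq_len(L)))
        if (stats::runif(1) < config$reported_p_rate) {
          br <- run_battery(v, gs, battery = config$reported_test,
                            mc_n_sims = 2000,
                            mc_seed = child_seed(config$seed,
                                                 paste0(tid, "v", j)))
          br <- br[br$applicable, , drop = FALSE]
          if (nrow(br) >= 1L) {
            d <- sample_named(config$decimals_probs)
            v$reported_p <- parse_reported_p(format_p(br$p[1], d))
          }
        }
        v
      })
      trial_record(tid, gs, vars, source_meta = "synthetic")
    })
    ledger <- data.frame(trial_id = character(), variable = character(),
                         anomaly = character(), detail = character(),
                         stringsAsFactors = FALSE)
    for (anomaly in names(config$anomaly_rates)) {
      rate <- config$anomaly_rates[[anomaly]]
      if (rate == 0) next
      res <- inject_anomaly(trials, anomaly, rate = rate)
      trials <- res$trials
      ledger <- rbind(ledger, res$ledger)
    }
    list(trials = trials, ledger = ledger)
  })
}

#' Inject a controlled anomaly into a trial dataset
#'
#' Each eligible variable is independently selected with probability
#' `rate` and modified in place; every modification is recorded in the
#' returned ledger, so downstream detections can be scored against ground
#' truth. Anomalies:
#'
#' * `sum_error` — one count perturbed by a nonzero delta in -5..5, so the
#'   frequency sum disagrees with the randomized N.
#' * `over_similar` — the two arms' counts are made near-identical
#'   (|difference| <= 1 on every level); defined for two-arm trials with
#'   equal arm sizes, others are left untouched.
#' * `corrupt_p` — the reported p is replaced by an unrelated value at the
#'   same printed precision, rejection-sampled until it matches no battery
#'   p within the rounding band (so the corruption is always detectable).
#' * `wrong_test` — the reported p is recomputed with a different test
#'   than the generator's configured one (Fisher where chi-square was the
#'   convention, or chi-square otherwise).
#' * `threshold_p` — a numeric reported p is replaced by the threshold
#'   string `">0.9999"`.
#'
#' Uses the current RNG state; wrap in a seeded context (or rely on
#' [generate_trials()]) for reproducibility.
#'
#' @param trials List of [trial_record()] objects.
#' @param anomaly One of `"sum_error"`, `"over_similar"`, `"corrupt_p"`,
#'   `"wrong_test"`, `"threshold_p"`.
#' @param rate Per-variable selection probability.
#' @return List: modified `trials` and the injection `ledger`.
#' @export
inject_anomaly <- function(trials, anomaly, rate = 0.05) {
  injectors <- list(sum_error = inject_sum_error,
                    over_similar = inject_over_similar,
                    corrupt_p = inject_corrupt_p,
                    wrong_test = inject_wrong_test,
                    threshold_p = inject_threshold_p)
  if (!anomaly %in% names(injectors))
    stop("unknown anomaly ", sQuote(anomaly), call. = FALSE)
  fn <- injectors[[anomaly]]
  ledger <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    for (j in seq_along(tr$variables)) {
      if (stats::runif(1) >= rate) next
      res <- fn(tr$variables[[j]], tr$group_sizes)
      if (is.null(res)) next  # variable not eligible
      trials[[i]]$variables[[j]] <- res$variable
      ledger[[length(ledger) + 1L]] <- data.frame(
        trial_id = tr$trial_id, variable = tr$variables[[j]]$name,
        anomaly = anomaly, detail = res$detail, stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame(trial_id = character(),
                            variable = character(),
                            anomaly = character(), detail = character(),
                            stringsAsFactors = FALSE)
  list(trials = trials, ledger = ledger)
}

inject_sum_error <- function(v, group_sizes) {
  delta <- sample_one(c(-5:-1, 1:5))
  cell <- sample.int(length(v$counts), 1L)
  newval <- v$counts[cell] + delta
  if (newval < 0) { delta <- -delta; newval <- v$counts[cell] + delta }
  v$counts[cell] <- as.integer(newval)
  list(variable = v,
       detail = sprintf("cell %d perturbed by %+d", cell, delta))
}

inject_over_similar <- function(v, group_sizes) {
  if (length(group_sizes) != 2L || group_sizes[1] != group_sizes[2])
    return(NULL)
  p <- rowSums(v$counts) / max(1, sum(v$counts))
  if (all(p == 0)) return(NULL)
  c1 <- stats::rmultinom(1, group_sizes[1], p)[, 1]
  c2 <- c1
  jitter <- ""
  if (nrow(v$counts) >= 2L && stats::runif(1) < 0.5) {
    ij <- sample.int(nrow(v$counts), 2L)
    if (c2[ij[2]] > 0L) {
      c2[ij[1]] <- c2[ij[1]] + 1L
      c2[ij[2]] <- c2[ij[2]] - 1L
      jitter <- " with +/-1 jitter"
    }
  }
  v$counts <- matrix(as.integer(c(c1, c2)), ncol = 2)
  dimnames(v$counts) <- list(v$levels, c("group1", "group2"))
  # the original reported p no longer describes these counts; refresh it
  if (!is.null(v$reported_p) && v$reported_p$kind == "numeric") {
    br <- run_battery(v, group_sizes, battery = "pearson")
    br <- br[br$applicable, , drop = FALSE]
    if (nrow(br))
      v$reported_p <- parse_reported_p(
        format_p(br$p[1], max(1L, v$reported_p$decimals)))
    else v$reported_p <- NULL
  }
  list(variable = v, detail = paste0("counts redrawn with |d| <= 1",
                                     jitter))
}

inject_corrupt_p <- function(v, group_sizes) {
  if (is.null(v$reported_p) || v$reported_p$kind != "numeric")
    return(NULL)
  d <- max(1L, v$reported_p$decimals)
  br <- run_battery(v, group_sizes)
  br <- br[br$applicable, , drop = FALSE]
  band <- 0.5 * 10^(-d) + 1e-12
  for (try in 1:100) {
    cand <- round(stats::runif(1), d)
    if (nrow(br) == 0L || all(abs(br$p - cand) > band)) {
      old <- v$reported_p$raw
      v$reported_p <- parse_reported_p(format_p(cand, d))
      return(list(variable = v,
                  detail = sprintf("reported p %s -> %s", old,
                                   v$reported_p$raw)))
    }
  }
  NULL  # could not find a non-matching value (pathological battery)
}

inject_wrong_test <- function(v, group_sizes) {
  if (is.null(v$reported_p) || v$reported_p$kind != "numeric")
    return(NULL)
  is_2x2 <- all(dim(v$counts) == c(2L, 2L))
  alt <- if (is_2x2) "fisher" else "pearson"
  br <- run_battery(v, group_sizes, battery = alt)
  br <- br[br$applicable, , drop = FALSE]
  if (nrow(br) == 0L) return(NULL)
  old <- v$reported_p$raw
  v$reported_p <- parse_reported_p(
    format_p(br$p[1], max(1L, v$reported_p$decimals)))
  list(variable = v, detail = sprintf("reported p %s -> %s (from %s)",
                                      old, v$reported_p$raw, alt))
}

inject_threshold_p <- function(v, group_sizes) {
  if (is.null(v$reported_p) || v$reported_p$kind != "numeric")
    return(NULL)
  old <- v$reported_p$raw
  v$reported_p <- parse_reported_p(">0.9999")
  list(variable = v, detail = sprintf("reported p %s -> >0.9999", old))
}
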