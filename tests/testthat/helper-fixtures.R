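# Shared fixtures and oracles, built in code.

# Balanced long-format visits for simple mixture scenarios.
make_visits <- function(group_means_lvef, group_means_ea, n_per_group,
                        sd_lvef = 1, sd_ea = 0.05, visits_ages = c(65, 75, 81),
                        seed = 1) {
  set.seed(seed)
  G <- length(group_means_lvef)
  n <- n_per_group * G
  g <- rep(seq_len(G), each = n_per_group)
  id <- sprintf("p%04d", seq_len(n))
  V <- length(visits_ages)
  do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- visits_ages + stats::rnorm(V, 0, 1)
    data.frame(participant_id = id[i], visit = seq_len(V), age_years = ages,
               lvef_pct = group_means_lvef[g[i]] + stats::rnorm(V, 0, sd_lvef),
               ea_ratio = group_means_ea[g[i]] + stats::rnorm(V, 0, sd_ea),
               stringsAsFactors = FALSE)
  })) -> df
  attr(df, "truth") <- data.frame(participant_id = id, group = g)
  df
}

# Hand-built trajectory model (plain parameter container) for oracle
# checks of Bayes-rule assignment, curves, thresholds and round trips.
make_model <- function(weights, lvef_intercepts, ea_intercepts,
                       lvef_sd = 5, ea_sd = 0.2, basis = age_basis()) {
  K <- length(weights)
  groups <- lapply(seq_len(K), function(k) list(
    coefficients = list(lvef = c(lvef_intercepts[k], 0, 0)[1:(basis$degree + 1)],
                        ea = c(ea_intercepts[k], 0, 0)[1:(basis$degree + 1)]),
    residual_sd = c(lvef = lvef_sd, ea = ea_sd)
  ))
  structure(list(k_max = K, weights = weights, groups = groups,
                 concentration = 1, basis = basis,
                 priors = NULL,
                 targets = c(lvef = "lvef_pct", ea = "ea_ratio"),
                 variational = NULL,
                 fit_meta = list(seed = NA, restarts = 0, elbo = NA,
                                 iterations = 0, converged = TRUE,
                                 elbo_trace = numeric(0),
                                 restart_traces = list())),
            class = "trajectory_model")
}

# Every restart's ELBO trace must be non-decreasing (relative tolerance
# 1e-8 per step).
expect_elbo_monotone <- function(model) {
  traces <- model$fit_meta$restart_traces
  ok <- vapply(traces, function(tr) {
    if (length(tr) < 2) return(TRUE)
    all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1))
  }, TRUE)
  expect_true(all(ok), label = "ELBO non-decreasing in every restart")
}

# Exhaustive-pair Harrell C oracle (quadratic loop, small n only).
brute_force_c <- function(score, time, status) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || status[i] != 1) next
    if (time[j] > time[i] || (time[j] == time[i] && status[j] == 0)) {
      usable <- usable + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# Exact Cox partial likelihood (Breslow, binary covariate) for the
# grid/Newton oracle.
cox_partial_loglik <- function(beta, time, status, x) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
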