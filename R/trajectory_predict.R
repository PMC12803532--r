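#' Posterior trajectory membership from any subset of observations
#'
#' Applies Bayes rule with the fitted model's point parameters: the
#' posterior probability of group g is proportional to the expected
#' mixture weight times the product of Normal densities of every
#' observed (visit, target) value at the group curve with the group's
#' residual SD. A single visit is explicitly allowed, as is a missing
#' target at any visit (it contributes nothing).
#'
#' @param model A fitted [fit_trajectories()] model.
#' @param obs Data frame with columns `age_years` and the model's target
#'   columns (`lvef_pct`, `ea_ratio` by default); one row per visit.
#' @param participant_id Optional identifier carried into the result.
#' @return List of class `membership_posterior`: `participant_id`,
#'   `probabilities` (length `k_max`, sums to 1), `map_group` (argmax
#'   index, ties broken toward the lower index).
#' @export
posterior_membership <- function(model, obs, participant_id = NA_character_) {
  stopifnot(inherits(model, "trajectory_model"))
  check_columns(obs, c("age_years", unname(model$targets)), "observations")
  if (nrow(obs) < 1) stop_data("observation set must contain at least one visit")
  if (any(obs$age_years < 30 | obs$age_years > 110)) {
    stop_data("ages must lie within [30, 110] years")
  }
  nobs_total <- sum(vapply(model$targets,
                           function(cl) sum(is.finite(obs[[cl]])), 0L))
  if (nobs_total == 0) stop_data("all targets missing in observation set")

  X <- build_design(obs$age_years, model$basis)
  K <- model$k_max
  lp <- log(model$weights)
  for (k in seq_len(K)) {
    gr <- model$groups[[k]]
    for (tn in names(model$targets)) {
      y <- obs[[model$targets[[tn]]]]
      ok <- is.finite(y)
      if (!any(ok)) next
      mu <- drop(X[ok, , drop = FALSE] %*% gr$coefficients[[tn]])
      lp[k] <- lp[k] + sum(stats::dnorm(y[ok], mu, gr$residual_sd[[tn]],
                                        log = TRUE))
    }
  }
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  structure(list(participant_id = participant_id, probabilities = p,
                 map_group = which.max(p)),
            class = "membership_posterior")
}

#' Assign trajectory membership for a whole cohort
#'
#' Runs [posterior_membership()] for every participant in a long visits
#' table (one or more visits each).
#'
#' @inheritParams posterior_membership
#' @param visits Long data frame as in [fit_trajectories()].
#' @return Data frame with `participant_id`, `map_group`, and one
#'   `prob_k` column per mixture component.
#' @export
assign_trajectories <- function(model, visits) {
  check_columns(visits, c("participant_id", "age_years",
                          unname(model$targets)), "visits")
  ids <- unique(visits$participant_id)
  probs <- matrix(0, length(ids), model$k_max)
  map <- integer(length(ids))
  split_idx <- split(seq_len(nrow(visits)), visits$participant_id)
  for (i in seq_along(ids)) {
    post <- posterior_membership(model, visits[split_idx[[ids[i]]], ,
                                               drop = FALSE], ids[i])
    probs[i, ] <- post$probabilities
    map[i] <- post$map_group
  }
  out <- data.frame(participant_id = ids, map_group = map,
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", seq_len(model$k_max))
  cbind(out, probs)
}

#' Evaluate fitted group curves on an age grid
#'
#' @param model A fitted [fit_trajectories()] model.
#' @param age_grid Numeric vector of ages in years.
#' @return Data frame with `group` (internal index), `age_years`, and
#'   one column per target in original units.
#' @export
trajectory_curves <- function(model, age_grid) {
  stopifnot(inherits(model, "trajectory_model"))
  X <- build_design(age_grid, model$basis)
  out <- do.call(rbind, lapply(seq_len(model$k_max), function(k) {
    df <- data.frame(group = k, age_years = age_grid)
    for (tn in names(model$targets)) {
      df[[tn]] <- drop(X %*% model$groups[[k]]$coefficients[[tn]])
    }
    df
  }))
  rownames(out) <- NULL
  out
}

#' Effective mixture groups above a weight threshold
#'
#' @param model A fitted [fit_trajectories()] model.
#' @param min_weight Minimum expected membership (default 1%).
#' @return Data frame with `label` (1..K by descending weight),
#'   `internal_index`, and `weight`.
#' @export
effective_groups <- function(model, min_weight = 0.01) {
  stopifnot(inherits(model, "trajectory_model"))
  keep <- which(model$weights >= min_weight)
  ord <- keep[order(model$weights[keep], decreasing = TRUE)]
  data.frame(label = seq_along(ord), internal_index = ord,
             weight = model$weights[ord])
}

#' Simulate a single-visit cohort from a fitted model
#'
#' Draws participants from the fitted mixture itself (group from the
#' expected weights, one visit at a truncated-Gaussian age, targets from
#' the group curve plus residual noise). Used for self-consistency
#' checks of single-timepoint assignment.
#'
#' @param model A fitted [fit_trajectories()] model.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param age_mean,age_sd Age distribution of the single visit (years).
#' @return List with `visits` (one row per participant) and `truth`
#'   (`participant_id`, `group` = internal component index).
#' @export
simulate_from_model <- function(model, n, seed = 1, age_mean = 75.3,
                                age_sd = 5.1) {
  stopifnot(inherits(model, "trajectory_model"))
  set.seed(as.integer(seed))
  id <- sprintf("T%05d", seq_len(n))
  g <- sample.int(model$k_max, n, replace = TRUE, prob = model$weights)
  age <- rtruncnorm_inv(n, age_mean, age_sd, 45, 100)
  X <- build_design(age, model$basis)
  visits <- data.frame(participant_id = id, visit = 1L, age_years = age,
                       stringsAsFactors = FALSE)
  for (tn in names(model$targets)) {
    mu <- numeric(n)
    sdv <- numeric(n)
    for (k in unique(g)) {
      sel <- g == k
      mu[sel] <- drop(X[sel, , drop = FALSE] %*%
                        model$groups[[k]]$coefficients[[tn]])
      sdv[sel] <- model$groups[[k]]$residual_sd[[tn]]
    }
    visits[[model$targets[[tn]]]] <- mu + stats::rnorm(n, 0, sdv)
  }
  list(visits = visits,
       truth = data.frame(participant_id = id, group = g,
                          stringsAsFactors = FALSE))
}
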