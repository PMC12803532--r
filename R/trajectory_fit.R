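# Mean-field variational inference for a truncated stick-breaking
# (Dirichlet-process) mixture of joint age-polynomial regressions.
#
# Model, per participant i with group z_i = k:
#   y_{ivd} ~ Normal(x(age_iv)' beta_{kd}, 1/tau_{kd})   d in targets
#   z_i ~ Categorical(pi),  pi ~ stick-breaking GEM(alpha), truncated at K
#   beta_{kd} ~ Normal(m0_d, S0_d),  tau_{kd} ~ Gamma(a0_d, b0_d)
# Targets are conditionally independent given the group; participants may
# have any number of visits and either target may be missing at a visit.
#
# q factorises over z (categorical r), sticks v (Beta), beta (Gaussian)
# and tau (Gamma); all updates are exact coordinate ascent so the ELBO is
# non-decreasing.

# Per-participant sufficient statistics for one target: counts, X'X
# (flattened), X'y and y'y over the visits where the target is observed.
suff_stats <- function(visits, basis, target_col) {
  # sorted ids make the whole fit invariant to input row order
  ids <- sort(unique(visits$participant_id))
  n <- length(ids)
  P <- basis$degree + 1L
  idx <- match(visits$participant_id, ids)
  obs <- is.finite(visits[[target_col]])
  X <- build_design(visits$age_years, basis)
  y <- visits[[target_col]]

  XtX <- matrix(0, n, P * P)
  Xty <- matrix(0, n, P)
  yty <- numeric(n)
  nobs <- numeric(n)
  w <- which(obs)
  for (r in w) {
    i <- idx[r]
    xr <- X[r, ]
    XtX[i, ] <- XtX[i, ] + as.vector(tcrossprod(xr))
    Xty[i, ] <- Xty[i, ] + xr * y[r]
    yty[i] <- yty[i] + y[r]^2
    nobs[i] <- nobs[i] + 1
  }
  list(ids = ids, XtX = XtX, Xty = Xty, yty = yty, nobs = nobs, P = P)
}

empirical_priors <- function(stats_list) {
  lapply(stats_list, function(st) {
    P <- st$P
    XtX <- matrix(colSums(st$XtX), P, P)
    Xty <- colSums(st$Xty)
    ntot <- sum(st$nobs)
    beta0 <- solve(XtX, Xty)
    rss <- sum(st$yty) - sum(beta0 * Xty)
    s2 <- max(rss / max(ntot - P, 1), 1e-8)
    S0 <- 100 * ntot * s2 * solve(XtX)
    list(m0 = beta0, S0 = S0, S0inv = solve(S0), a0 = 2, b0 = 2 * s2,
         pooled_var = s2)
  })
}

# E_q[(y - x'beta)^2] summed over a participant's observed visits, for
# all participants at once.
equad_all <- function(st, m, S) {
  vecSmm <- as.vector(S + tcrossprod(m))
  st$yty - 2 * drop(st$Xty %*% m) + drop(st$XtX %*% vecSmm)
}

elogpi_from_sticks <- function(g1, g2, K) {
  if (K == 1) return(0)
  Elogv <- c(digamma(g1) - digamma(g1 + g2), 0)
  Elog1mv <- c(digamma(g2) - digamma(g1 + g2), 0)
  Elogv + cumsum(c(0, Elog1mv[-K]))
}

weights_from_sticks <- function(g1, g2, K) {
  if (K == 1) return(1)
  Ev <- c(g1 / (g1 + g2), 1)
  w <- Ev * cumprod(c(1, 1 - Ev[-K]))
  w / sum(w)
}

run_cavi <- function(stats_list, priors, k_max, alpha, r_init,
                     max_iter, tol) {
  n <- nrow(r_init)
  K <- k_max
  D <- length(stats_list)
  P <- stats_list[[1]]$P
  nobs <- lapply(stats_list, `[[`, "nobs")

  # parameter containers
  m <- array(0, c(K, P, D))
  S <- array(0, c(K, P, P, D))
  a <- b <- matrix(1, K, D)
  g1 <- g2 <- NULL

  update_params <- function(r) {
    Nk <- colSums(r)
    if (K > 1) {
      g1 <<- 1 + Nk[-K]
      g2 <<- alpha + rev(cumsum(rev(Nk)))[-1]
    }
    for (d in seq_len(D)) {
      st <- stats_list[[d]]
      pr <- priors[[d]]
      for (k in seq_len(K)) {
        rk <- r[, k]
        # tau update with current q(beta)
        eq <- equad_all(st, m[k, , d], S[k, , , d])
        a[k, d] <<- pr$a0 + 0.5 * sum(rk * st$nobs)
        b[k, d] <<- pr$b0 + 0.5 * sum(rk * eq)
        # beta update with new E[tau]
        et <- a[k, d] / b[k, d]
        SXtX <- matrix(crossprod(rk, st$XtX), P, P)
        SXty <- drop(crossprod(st$Xty, rk))
        Sinv <- pr$S0inv + et * SXtX
        ch <- chol(Sinv)
        S[k, , , d] <<- chol2inv(ch)
        m[k, , d] <<- S[k, , , d] %*% (pr$S0inv %*% pr$m0 + et * SXty)
      }
    }
  }

  scores <- function() {
    elogpi <- elogpi_from_sticks(g1, g2, K)
    s <- matrix(rep(elogpi, each = n), n, K)
    for (d in seq_len(D)) {
      st <- stats_list[[d]]
      for (k in seq_len(K)) {
        et <- a[k, d] / b[k, d]
        elt <- digamma(a[k, d]) - log(b[k, d])
        eq <- equad_all(st, m[k, , d], S[k, , , d])
        s[, k] <- s[, k] + 0.5 * st$nobs * (elt - log(2 * pi)) - 0.5 * et * eq
      }
    }
    s
  }

  kl_terms <- function() {
    kl <- 0
    if (K > 1) {
      Elogv <- digamma(g1) - digamma(g1 + g2)
      Elog1mv <- digamma(g2) - digamma(g1 + g2)
      kl <- kl + sum(log(alpha) + (alpha - 1) * Elog1mv) -
        sum((g1 - 1) * Elogv + (g2 - 1) * Elog1mv -
              (lgamma(g1) + lgamma(g2) - lgamma(g1 + g2)))
    }
    for (d in seq_len(D)) {
      pr <- priors[[d]]
      ld_S0 <- determinant(pr$S0, logarithm = TRUE)$modulus
      for (k in seq_len(K)) {
        Sk <- S[k, , , d]
        dm <- m[k, , d] - pr$m0
        ld_Sk <- determinant(Sk, logarithm = TRUE)$modulus
        kl <- kl +
          (-0.5 * ld_S0 - 0.5 * (drop(t(dm) %*% pr$S0inv %*% dm) +
                                   sum(pr$S0inv * Sk))) +
          0.5 * ld_Sk + 0.5 * P
        elt <- digamma(a[k, d]) - log(b[k, d])
        et <- a[k, d] / b[k, d]
        kl <- kl + pr$a0 * log(pr$b0) - lgamma(pr$a0) +
          (pr$a0 - 1) * elt - pr$b0 * et +
          a[k, d] - log(b[k, d]) + lgamma(a[k, d]) +
          (1 - a[k, d]) * digamma(a[k, d])
      }
    }
    as.numeric(kl)
  }

  update_params(r_init)
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  r <- r_init
  for (it in seq_len(max_iter)) {
    s <- scores()
    smax <- apply(s, 1, max)
    es <- exp(s - smax)
    rs <- rowSums(es)
    r <- es / rs
    elbo <- sum(smax + log(rs)) + kl_terms()
    elbo_trace <- c(elbo_trace, elbo)
    if (it > 1 && abs(elbo - elbo_prev) < tol * (abs(elbo_prev) + tol)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
    update_params(r)
  }
  list(r = r, m = m, S = S, a = a, b = b, g1 = g1, g2 = g2,
       elbo = elbo_trace[length(elbo_trace)], elbo_trace = elbo_trace,
       iterations = length(elbo_trace), converged = converged)
}

# Diverse initialisation portfolio. The ELBO surface of the mixture is
# highly multimodal, so restarts alternate between (a) k-means on
# per-person target means at several cluster counts, (b) random hard
# partitions of varying size, and (c) soft Dirichlet draws; the restart
# with the best final ELBO wins.
init_responsibilities <- function(n, K, restart_index, stats_list) {
  hard <- function(cl, k_used) {
    r <- matrix(0.02 / max(K - 1, 1), n, K)
    r[cbind(seq_len(n), cl)] <- 0.98
    r
  }
  kmeans_sizes <- pmin(K, c(4, 6, 8, 2, 12))
  if (restart_index <= length(kmeans_sizes) && n > 12) {
    feat <- sapply(stats_list, function(st) {
      mu <- st$Xty[, 1] / pmax(st$nobs, 1)        # per-person target mean
      mu[st$nobs == 0] <- mean(mu[st$nobs > 0])
      scale(mu)
    })
    k_use <- kmeans_sizes[restart_index]
    km <- stats::kmeans(feat, centers = k_use, nstart = 5, iter.max = 50)
    hard(km$cluster, k_use)
  } else if (restart_index %% 2 == 0) {
    k_use <- sample(2:min(K, 12), 1)
    hard(sample.int(k_use, n, replace = TRUE), k_use)
  } else {
    matrix(stats::rgamma(n * K, shape = 2), n, K)
  }
}

#' Fit the joint trajectory mixture model
#'
#' Fits a truncated stick-breaking Dirichlet-process mixture of
#' per-group polynomial age regressions jointly over LVEF and E/A by
#' coordinate-ascent variational Bayes. Handles unbalanced panels (any
#' number of visits per participant, either target missing at a visit).
#' Runs `restarts` independently initialised optimisations (one
#' k-means-seeded, the rest random) and returns the one with the highest
#' final evidence lower bound. Deterministic given `seed`.
#'
#' @param visits Long data frame with columns `participant_id`,
#'   `age_years`, `lvef_pct`, `ea_ratio` (NA allowed in either target).
#' @param basis [age_basis()] for the standardised-age polynomial.
#' @param k_max Truncation level of the stick-breaking prior.
#' @param alpha Dirichlet-process concentration (fixed).
#' @param priors Optional list per target of `m0`, `S0`, `a0`, `b0`;
#'   defaults are empirical (pooled least-squares coefficient mean with
#'   100-fold diffuse covariance, Gamma(2, 2*pooled residual variance)).
#' @param restarts Number of independent initialisations.
#' @param max_iter,tol Iteration cap and relative-ELBO convergence
#'   tolerance for each run.
#' @param seed Root seed for all initialisations.
#' @param targets Named character vector mapping target names to visit
#'   columns.
#' @return Object of class `trajectory_model`: stick-breaking expected
#'   `weights`, per-group/target `coefficients` (posterior mean) and
#'   `residual_sd` (inverse expected precision), the variational
#'   parameters, and `fit_meta` including the ELBO trace of every
#'   restart.
#' @export
fit_trajectories <- function(visits, basis = age_basis(), k_max = 20,
                             alpha = 1, priors = NULL, restarts = 20,
                             max_iter = 2000, tol = 1e-8, seed = 1,
                             targets = c(lvef = "lvef_pct", ea = "ea_ratio")) {
  check_columns(visits, c("participant_id", "age_years", unname(targets)),
                "visits")
  if (nrow(visits) == 0) stop_data("no visits supplied")
  bad_age <- which(!is.finite(visits$age_years))
  if (length(bad_age) > 0) {
    stop_data(sprintf("non-finite age at visit row(s) %s",
                      paste(utils::head(bad_age, 10), collapse = ", ")))
  }
  obs_any <- Reduce(`|`, lapply(targets, function(cl) is.finite(visits[[cl]])))
  if (any(!obs_any)) {
    stop_data(sprintf("visit row(s) with no observed target: %s",
                      paste(utils::head(which(!obs_any), 10), collapse = ", ")))
  }
  for (cl in targets) {
    bad <- which(!is.na(visits[[cl]]) & !is.finite(visits[[cl]]))
    if (length(bad) > 0) {
      stop_data(sprintf("non-finite values in '%s' at row(s) %s", cl,
                        paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  stats_list <- lapply(targets, function(cl) suff_stats(visits, basis, cl))
  n <- length(stats_list[[1]]$ids)
  if (n < 2) stop_data("need at least 2 participants")
  if (is.null(priors)) priors <- empirical_priors(stats_list)
  k_max <- as.integer(k_max)

  restart_seeds <- derive_seeds(seed, restarts)
  best <- NULL
  restart_elbos <- numeric(restarts)
  restart_traces <- vector("list", restarts)
  for (rs in seq_len(restarts)) {
    set.seed(restart_seeds[rs])
    r0 <- init_responsibilities(n, k_max, rs, stats_list)
    r0 <- r0 / rowSums(r0)
    fit <- run_cavi(stats_list, priors, k_max, alpha, r0, max_iter, tol)
    restart_elbos[rs] <- fit$elbo
    restart_traces[[rs]] <- fit$elbo_trace
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }

  weights <- weights_from_sticks(best$g1, best$g2, k_max)
  groups <- lapply(seq_len(k_max), function(k) {
    co <- lapply(seq_along(targets), function(d) best$m[k, , d])
    names(co) <- names(targets)
    rsd <- vapply(seq_along(targets),
                  function(d) sqrt(best$b[k, d] / best$a[k, d]), 0)
    names(rsd) <- names(targets)
    list(coefficients = co, residual_sd = rsd)
  })
  structure(list(
    k_max = k_max, weights = weights, groups = groups,
    concentration = alpha, basis = basis, priors = priors,
    targets = targets,
    variational = list(m = best$m, S = best$S, a = best$a, b = best$b,
                       g1 = best$g1, g2 = best$g2),
    fit_meta = list(seed = seed, restarts = restarts,
                    elbo = best$elbo, iterations = best$iterations,
                    converged = best$converged,
                    elbo_trace = best$elbo_trace,
                    restart_elbos = restart_elbos,
                    restart_traces = restart_traces)
  ), class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  eff <- effective_groups(x)
  cat(sprintf("Joint trajectory mixture: k_max = %d, %d effective group(s)\n",
              x$k_max, nrow(eff)))
  cat(sprintf("ELBO %.3f after %d iteration(s); weights of effective groups: %s\n",
              x$fit_meta$elbo, x$fit_meta$iterations,
              paste(sprintf("%.3f", eff$weight), collapse = ", ")))
  invisible(x)
}
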