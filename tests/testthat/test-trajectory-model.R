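test_that("design construction follows the standardised-age polynomial", {
  b <- age_basis(70, 10, 2)
  expect_equal(drop(build_design(70, b)), c(z0 = 1, z1 = 0, z2 = 0))
  expect_equal(drop(build_design(80, b)), c(z0 = 1, z1 = 1, z2 = 1))
  expect_equal(drop(build_design(65, b)), c(z0 = 1, z1 = -0.5, z2 = 0.25))
  expect_error(age_basis(scale = 0), "scale")
  expect_error(build_design(NA, b), "age")
})

test_that("a single flat group collapses the mixture onto one component", {
  v <- make_visits(65, 1.0, 300, sd_lvef = 5, sd_ea = 0.2, seed = 2)
  m <- fit_trajectories(v, restarts = 4, seed = 3)
  eff <- effective_groups(m, 0.01)
  expect_identical(nrow(eff), 1L)
  expect_gte(max(m$weights), 0.99)
  expect_elbo_monotone(m)
})

test_that("three well-separated groups are recovered with accurate assignment", {
  v <- make_visits(c(50, 65, 80), c(0.6, 1.0, 1.4), 200,
                   sd_lvef = 1, sd_ea = 0.05, seed = 4)
  truth <- attr(v, "truth")
  m <- fit_trajectories(v, restarts = 5, seed = 7)
  eff <- effective_groups(m, 0.01)
  expect_identical(nrow(eff), 3L)
  expect_true(all(abs(sort(eff$weight) - 1 / 3) < 0.05))
  a <- assign_trajectories(m, v)
  # map each fitted component to its majority truth group
  tg <- truth$group[match(a$participant_id, truth$participant_id)]
  comp_map <- sapply(split(tg, a$map_group),
                     function(x) as.integer(names(which.max(table(x)))))
  acc <- mean(comp_map[as.character(a$map_group)] == tg)
  expect_gte(acc, 0.98)
  expect_elbo_monotone(m)
})

test_that("participant order does not change the fitted mixture", {
  v <- make_visits(c(50, 80), c(0.6, 1.4), 100, seed = 5)
  m1 <- fit_trajectories(v, k_max = 6, restarts = 3, seed = 11)
  set.seed(99)
  ids <- unique(v$participant_id)
  perm <- sample(ids)
  vp <- v[order(match(v$participant_id, perm), v$visit), ]
  m2 <- fit_trajectories(vp, k_max = 6, restarts = 3, seed = 11)
  w1 <- sort(m1$weights[m1$weights > 0.01])
  w2 <- sort(m2$weights[m2$weights > 0.01])
  expect_equal(w1, w2, tolerance = 1e-4)
  c1 <- trajectory_curves(m1, c(65, 75))
  c2 <- trajectory_curves(m2, c(65, 75))
  k1 <- effective_groups(m1)$internal_index
  k2 <- effective_groups(m2)$internal_index
  expect_equal(c1$lvef[c1$group %in% k1][order(c1$lvef[c1$group %in% k1])],
               c2$lvef[c2$group %in% k2][order(c2$lvef[c2$group %in% k2])],
               tolerance = 1e-3)
})

test_that("refitting with the same seed reproduces the model exactly", {
  v <- make_visits(c(55, 75), c(0.8, 1.2), 60, seed = 6)
  m1 <- fit_trajectories(v, k_max = 5, restarts = 2, seed = 13)
  m2 <- fit_trajectories(v, k_max = 5, restarts = 2, seed = 13)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$variational$m, m2$variational$m)
})

test_that("posterior membership follows Bayes rule exactly", {
  # single nonzero-weight component
  m1 <- make_model(c(1, 0), c(60, 80), c(1, 1))
  p1 <- posterior_membership(m1, data.frame(age_years = 70, lvef_pct = 75,
                                            ea_ratio = 1.1))
  expect_equal(p1$probabilities, c(1, 0))

  # symmetric two-component model, observation equidistant, E/A missing
  m2 <- make_model(c(0.5, 0.5), c(60, 80), c(1, 1))
  p2 <- posterior_membership(m2, data.frame(age_years = 70, lvef_pct = 70,
                                            ea_ratio = NA))
  expect_equal(p2$probabilities, c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(p2$map_group, 1L)  # tie broken toward the lower index

  # stated weights and parameters: hand-normalised product of densities
  m3 <- make_model(c(0.7, 0.3), c(62, 78), c(0.8, 1.2),
                   lvef_sd = 6, ea_sd = 0.25)
  obs <- data.frame(age_years = 72, lvef_pct = 70, ea_ratio = 1.0)
  p3 <- posterior_membership(m3, obs)
  num <- c(0.7, 0.3) *
    dnorm(70, c(62, 78), 6) * dnorm(1.0, c(0.8, 1.2), 0.25)
  expect_equal(p3$probabilities, num / sum(num), tolerance = 1e-10)
  expect_equal(sum(p3$probabilities), 1, tolerance = 1e-10)

  expect_error(posterior_membership(
    m3, data.frame(age_years = 70, lvef_pct = NA, ea_ratio = NA)), "missing")
  expect_error(posterior_membership(
    m3, data.frame(age_years = 20, lvef_pct = 60, ea_ratio = 1)), "30")
})

test_that("training responsibilities equal plug-in Bayes-rule assignment", {
  v <- make_visits(c(55, 75), c(0.8, 1.2), 80, seed = 8)
  m <- fit_trajectories(v, k_max = 5, restarts = 2, seed = 17)
  a <- assign_trajectories(m, v)
  ids <- sample(unique(v$participant_id), 10)
  for (id in ids) {
    obs <- v[v$participant_id == id, ]
    lp <- log(m$weights)
    for (k in seq_len(m$k_max)) {
      for (tn in c("lvef", "ea")) {
        cl <- m$targets[[tn]]
        mu <- drop(build_design(obs$age_years, m$basis) %*%
                     m$groups[[k]]$coefficients[[tn]])
        lp[k] <- lp[k] + sum(dnorm(obs[[cl]], mu,
                                   m$groups[[k]]$residual_sd[[tn]], log = TRUE))
      }
    }
    expected <- exp(lp - max(lp)); expected <- expected / sum(expected)
    got <- as.numeric(a[a$participant_id == id,
                        paste0("prob_", seq_len(m$k_max))])
    expect_lt(max(abs(got - expected)), 1e-6)
  }
})

test_that("curves evaluate polynomials in original units", {
  m <- make_model(c(0.6, 0.4), c(66.3, 80), c(1.0, 0.7))
  cc <- trajectory_curves(m, c(55, 64.5, 70, 90))
  expect_true(all(cc$lvef[cc$group == 1] == 66.3))
  expect_true(all(cc$ea[cc$group == 2] == 0.7))
  # curve at the reference age equals the intercept coefficient exactly
  m2 <- make_model(1, 70, 1.1)
  m2$groups[[1]]$coefficients$lvef <- c(64, -3, 1.2)
  cr <- trajectory_curves(m2, m2$basis$reference_age)
  expect_identical(cr$lvef, 64)
})

test_that("effective group selection thresholds and orders by weight", {
  m <- make_model(c(0.5, 0.5, 0), c(60, 70, 80), c(1, 1, 1))
  expect_identical(nrow(effective_groups(m, 0.01)), 2L)
  m2 <- make_model(c(0.996, 0.004), c(60, 70), c(1, 1))
  expect_identical(nrow(effective_groups(m2, 0.01)), 1L)
  m3 <- make_model(c(0.2, 0.5, 0.3), c(60, 70, 80), c(1, 1, 1))
  eff <- effective_groups(m3, 0.01)
  expect_identical(eff$internal_index, c(2L, 3L, 1L))
  expect_identical(eff$label, 1:3)
})

test_that("model JSON round trip is lossless", {
  v <- make_visits(c(55, 75), c(0.8, 1.2), 50, seed = 9)
  m <- fit_trajectories(v, k_max = 4, restarts = 2, seed = 19)
  path <- tempfile(fileext = ".json")
  write_trajectory_model(m, path)
  m2 <- read_trajectory_model(path)
  expect_lt(max(abs(m$weights - m2$weights)), 1e-12)
  for (k in seq_len(m$k_max)) {
    expect_lt(max(abs(m$groups[[k]]$coefficients$lvef -
                        m2$groups[[k]]$coefficients$lvef)), 1e-12)
    expect_lt(max(abs(m$groups[[k]]$residual_sd - m2$groups[[k]]$residual_sd)),
              1e-12)
  }
  obs <- data.frame(age_years = 74, lvef_pct = 60, ea_ratio = 1.0)
  expect_equal(posterior_membership(m2, obs)$probabilities,
               posterior_membership(m, obs)$probabilities, tolerance = 1e-12)
})

test_that("single-visit MAP accuracy approaches 1 as residual noise vanishes", {
  m <- make_model(c(0.5, 0.3, 0.2), c(50, 65, 80), c(0.6, 1.0, 1.4),
                  lvef_sd = 0.5, ea_sd = 0.02)
  sim <- simulate_from_model(m, 400, seed = 23)
  a <- assign_trajectories(m, sim$visits)
  acc <- mean(a$map_group == sim$truth$group[match(a$participant_id,
                                                  sim$truth$participant_id)])
  expect_gte(acc, 0.999)
})

test_that("malformed longitudinal input is rejected with row diagnostics", {
  v <- make_visits(65, 1, 5, seed = 10)
  v$lvef_pct[3] <- Inf
  expect_error(fit_trajectories(v, restarts = 1), "row")
  v2 <- make_visits(65, 1, 5, seed = 10)
  v2$lvef_pct[2] <- NA; v2$ea_ratio[2] <- NA
  expect_error(fit_trajectories(v2, restarts = 1), "no observed target")
  expect_error(fit_trajectories(make_visits(65, 1, 1, seed = 1), restarts = 1),
               "2 participants")
})
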