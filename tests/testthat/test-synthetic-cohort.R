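test_that("cohort generation is byte-identical under a repeated seed", {
  cfg <- cohort_config(200, "derivation", seed = 5)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1, d2)
  d3 <- generate_cohort(cohort_config(200, "derivation", seed = 6))
  expect_false(identical(d1$visits, d3$visits))
})

test_that("derivation-default group counts fall within binomial 99% bounds", {
  d <- generate_cohort(cohort_config(747, "derivation", seed = 2))
  p <- default_group_prevalences("derivation")
  counts <- table(factor(d$truth$group, levels = names(p)))
  for (g in names(p)) {
    expect_gte(counts[[g]], qbinom(0.005, 747, p[[g]]))
    expect_lte(counts[[g]], qbinom(0.995, 747, p[[g]]))
  }
})

test_that("attendance pattern matches the 747/731/488 design", {
  d <- generate_cohort(cohort_config(747, "derivation", seed = 3))
  nv <- table(d$visits$visit)
  expect_identical(unname(nv[["1"]]), 747L)
  expect_gte(nv[["2"]], qbinom(0.005, 747, 731 / 747))
  expect_lte(nv[["2"]], 747)
  expect_gte(nv[["3"]], qbinom(0.005, 747, 488 / 747))
  expect_lte(nv[["3"]], qbinom(0.995, 747, 488 / 747))
  # within-person ages strictly increase across visits
  byp <- split(d$visits$age_years, d$visits$participant_id)
  expect_true(all(vapply(byp, function(a) all(diff(a) > 0), TRUE)))
})

test_that("zero hazards yield administrative censoring for everyone", {
  hz <- default_hazards("testing")
  for (nm in names(hz)) hz[[nm]]$base <- 0
  d <- generate_cohort(cohort_config(100, "testing", hazards = hz, seed = 1))
  expect_true(all(d$survival$event == "none"))
  expect_true(all(d$survival$time_years == 7.4))
})

test_that("empirical group frequencies converge to the configured prevalences", {
  d <- generate_cohort(cohort_config(50000, "testing", seed = 9))
  p <- default_group_prevalences("testing")
  freq <- table(factor(d$truth$group, levels = names(p))) / 50000
  expect_true(all(abs(as.numeric(freq) - as.numeric(p)) <= 0.005))
})

test_that("per-group event times are exponential at rate baseline x HR", {
  # one-group cohorts, no administrative censoring, all-cause first event
  for (g in c("pink", "dark_green")) {
    prev <- setNames(rep(0, 6), names(default_group_prevalences()))
    prev[g] <- 1
    cfg <- cohort_config(10000, "testing", group_prevalences = prev,
                         admin_censor_years = 1e6, seed = 21)
    d <- generate_cohort(cfg)
    lam <- sum(cardiotraj:::component_hazards(cfg)[g, ])
    ks <- ks.test(d$survival$time_years, "pexp", rate = lam)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(0, "testing"), "n_participants")
  expect_error(
    cohort_config(10, "testing",
                  group_prevalences = c(pink = 0.5, light_green = 0.2,
                                        red = 0.2, dark_green = 0.04,
                                        orange = 0.02, blue = 0.2)),
    "group_prevalences")
  expect_error(
    cohort_config(10, "derivation", attendance = c(0.9, 0.5, 0.5),
                  visit_ages = cbind(mean = c(64.7, 74.7, 80.5),
                                     sd = c(5, 5, 5))),
    "attendance")
  rsd <- default_residual_sd()
  rsd$pink[["lvef"]] <- -1
  expect_error(cohort_config(10, "testing", residual_sd = rsd), "residual_sd")
})

test_that("proteome generator plants, shares and nulls signals as configured", {
  d <- generate_cohort(cohort_config(300, "testing", seed = 4))
  pc <- proteome_config(n_aptamers = 50, n_signal_per_group = 3,
                        effect_size = 1.2, overlap_spec = list("red&blue" = 1),
                        seed = 8)
  pr <- generate_proteome(d$truth, pc)
  expect_identical(dim(pr$matrix), c(300L, 50L))
  sig <- pr$signal_truth
  red_set <- sig$aptamer_id[grepl("(^|&)red(&|$)", sig$groups)]
  blue_set <- sig$aptamer_id[grepl("(^|&)blue(&|$)", sig$groups)]
  expect_length(intersect(red_set, blue_set), 1)
  # planted mean shift realised in target group
  j <- match(red_set[1], colnames(pr$matrix))
  in_red <- d$truth$group == "red"
  expect_gt(mean(pr$matrix[in_red, j]) - mean(pr$matrix[!in_red, j]), 0.5)

  null_pr <- generate_proteome(d$truth,
                               proteome_config(20, 3, effect_size = 0, seed = 1))
  expect_true(all(null_pr$signal_truth$groups == ""))
  expect_error(generate_proteome(d$truth, proteome_config(5, 10, seed = 1)),
               "n_signal")
})

test_that("gwas pair generator honours noiseless and cis constructions", {
  g <- generate_gwas_pair(gwas_sim_config(n_variants = 1,
                                          true_causal_effect = 0.4,
                                          se_exposure = 1e-12,
                                          se_outcome = 1e-12,
                                          flip_fraction = 0, seed = 3))
  expect_equal(g$outcome$beta / g$exposure$beta, 0.4, tolerance = 1e-6)

  g2 <- generate_gwas_pair(gwas_sim_config(n_variants = 40, cis_fraction = 1,
                                           seed = 5))
  status <- classify_cis_trans(g2$exposure$chrom, g2$exposure$pos_bp,
                               g2$gene$chrom, g2$gene$tss_bp)
  expect_true(all(status == "cis"))

  # null causal effect: IVW estimate within 3 SE of zero
  g3 <- generate_gwas_pair(gwas_sim_config(n_variants = 50,
                                           true_causal_effect = 0, seed = 11))
  res <- ivw(harmonize_variants(g3$exposure, g3$outcome))
  expect_lt(abs(res$estimate), 3 * res$se)
})
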