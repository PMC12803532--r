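ve <- function(id, ea, oa, beta, se = 0.05, chrom = "1", pos = 1e6) {
  data.frame(variant_id = id, chrom = chrom, pos_bp = pos,
             effect_allele = ea, other_allele = oa, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), eaf = 0.3,
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns allele codings and logs drops", {
  exp_t <- rbind(ve("v1", "A", "G", 0.10), ve("v2", "C", "T", -0.12),
                 ve("v3", "A", "T", 0.20), ve("v4", "G", "T", 0.15),
                 ve("v5", "A", "C", 0.08))
  out_t <- rbind(ve("v1", "A", "G", 0.05),        # identical coding
                 ve("v2", "T", "C", 0.06),        # swapped -> flip
                 ve("v3", "A", "T", 0.07),        # palindromic -> drop
                 ve("v4", "C", "A", 0.09),        # strand complement
                 ve("v5", "A", "G", 0.04))        # irreconcilable
  h <- harmonize_variants(exp_t, out_t)
  expect_identical(h$variants$variant_id, c("v1", "v2", "v4"))
  expect_equal(h$variants$beta_outcome, c(0.05, -0.06, 0.09))
  expect_identical(sort(h$drop_log$reason),
                   sort(c("palindromic", "irreconcilable alleles")))
  expect_identical(h$n_dropped, 2L)
  expect_error(harmonize_variants(rbind(exp_t, exp_t[1, ]), out_t), "unique")
})

test_that("harmonization is an involution on generator output", {
  for (s in 1:10) {
    g <- generate_gwas_pair(gwas_sim_config(n_variants = 100,
                                            true_causal_effect = 0.2,
                                            flip_fraction = 0.5,
                                            strand_fraction = 0.3,
                                            palindromic_fraction = 0.1,
                                            seed = s))
    h1 <- harmonize_variants(g$exposure, g$outcome)
    h2 <- harmonize_variants(h1$exposure_matched, h1$outcome_aligned)
    expect_identical(h2$n_dropped, 0L)
    expect_equal(h2$variants, h1$variants, tolerance = 1e-15)
  }
})

test_that("Wald ratio matches the closed-form delta method", {
  r <- wald_ratio(0.5, 0.01, 0.25, 0.02)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.02 / 0.5, tolerance = 1e-15)
  expect_equal(r$p, 2 * pnorm(-abs(0.5 / (0.02 / 0.5))), tolerance = 1e-15)
  z <- wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(z$estimate, 0)
  expect_equal(z$p, 1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "nonzero")
})

test_that("IVW equals the closed-form weighted mean with Cochran's Q", {
  v <- data.frame(variant_id = c("a", "b", "c"),
                  beta_exposure = c(0.2, -0.3, 0.25),
                  se_exposure = c(0.01, 0.01, 0.01),
                  beta_outcome = c(0.08, -0.15, 0.05),
                  se_outcome = c(0.02, 0.03, 0.02))
  res <- ivw(v)
  ratio <- v$beta_outcome / v$beta_exposure
  w <- (abs(v$beta_exposure) / v$se_outcome)^2
  expect_equal(res$estimate, sum(w * ratio) / sum(w), tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(res$q_statistic, sum(w * (ratio - res$estimate)^2),
               tolerance = 1e-12)

  # single variant delegates to the Wald ratio
  one <- ivw(v[1, ])
  wr <- wald_ratio(v[1, ])
  expect_identical(one$method, "wald")
  expect_equal(one$estimate, wr$estimate)

  # duplicating the instrument set preserves the estimate, shrinks se by sqrt(2)
  v2 <- rbind(v, transform(v, variant_id = paste0(variant_id, "_dup")))
  res2 <- ivw(v2)
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-12)
  expect_equal(res2$se, res$se / sqrt(2), tolerance = 1e-12)

  # ordering invariance
  res3 <- ivw(v[c(3, 1, 2), ])
  expect_equal(res3$estimate, res$estimate, tolerance = 1e-15)

  # Q = 0 exactly when all per-variant ratios are equal
  veq <- transform(v, beta_outcome = 0.4 * beta_exposure)
  expect_equal(ivw(veq)$q_statistic, 0, tolerance = 1e-12)
  expect_gt(res$q_statistic, 0)

  # k identical variants: same estimate, se shrunk by sqrt(k)
  vk <- do.call(rbind, lapply(1:4, function(i)
    transform(v[1, ], variant_id = paste0("k", i))))
  resk <- ivw(vk)
  expect_equal(resk$estimate, wr$estimate, tolerance = 1e-12)
  expect_equal(resk$se, wr$se / 2, tolerance = 1e-12)
})

test_that("cis/trans classification uses an inclusive 1 Mb window", {
  expect_identical(classify_cis_trans("1", 5e7, "1", 5e7), "cis")
  expect_identical(classify_cis_trans("2", 5e7, "1", 5e7), "trans")
  expect_identical(classify_cis_trans("1", 5e7 + 1e6, "1", 5e7), "cis")
  expect_identical(classify_cis_trans("1", 5e7 + 1e6 + 1, "1", 5e7), "trans")
})

test_that("the MR scan recovers generator truth and flags untestable proteins", {
  g <- generate_gwas_pair(gwas_sim_config(n_variants = 30,
                                          true_causal_effect = 0.3,
                                          se_exposure = 0.005,
                                          se_outcome = 0.01, seed = 31))
  scan <- mr_scan(list(P1 = list(exposure = g$exposure,
                                 gene_chrom = g$gene$chrom,
                                 gene_tss = g$gene$tss_bp)),
                  list(lvef = g$outcome))
  expect_true(scan$testable[1])
  expect_lt(abs(scan$estimate[1] - 0.3), 2 * scan$se[1])
  expect_identical(scan$cis_status[1], "cis")

  pal <- generate_gwas_pair(gwas_sim_config(n_variants = 10,
                                            palindromic_fraction = 1,
                                            seed = 32))
  scan2 <- mr_scan(list(P2 = list(exposure = pal$exposure,
                                  gene_chrom = pal$gene$chrom,
                                  gene_tss = pal$gene$tss_bp)),
                   list(lvef = pal$outcome))
  expect_false(scan2$testable[1])
})
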