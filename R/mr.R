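GWAS_COLS <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Inner-joins the two tables on `variant_id` and puts outcome effects
#' on the exposure's effect-allele coding: swapped alleles flip the
#' outcome beta sign; alleles that match only after strand
#' complementation are complemented first; palindromic variants (A/T or
#' C/G) are dropped unconditionally; irreconcilable allele pairs are
#' dropped. All drops are logged with reasons.
#'
#' @param exposure,outcome Data frames with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se` (extra columns kept
#'   from the exposure side).
#' @return Object of class `gwas_pair`: `variants` (variant_id,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome),
#'   `outcome_aligned` (the outcome table on exposure coding),
#'   `n_dropped`, `drop_log` (variant_id, reason).
#' @export
harmonize_variants <- function(exposure, outcome) {
  check_columns(exposure, GWAS_COLS, "exposure GWAS")
  check_columns(outcome, GWAS_COLS, "outcome GWAS")
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id)) {
    stop_data("variant_id must be unique within each GWAS table")
  }
  if (any(exposure$se <= 0) || any(outcome$se <= 0)) {
    stop_data("standard errors must be > 0")
  }
  m <- match(exposure$variant_id, outcome$variant_id)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]

  drop_reason <- rep(NA_character_, nrow(ex))
  flip <- rep(FALSE, nrow(ex))

  pal <- (ex$effect_allele == COMPLEMENT[ex$other_allele])
  drop_reason[pal] <- "palindromic"

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  comp_same <- COMPLEMENT[ou$effect_allele] == ex$effect_allele &
    COMPLEMENT[ou$other_allele] == ex$other_allele
  comp_swapped <- COMPLEMENT[ou$effect_allele] == ex$other_allele &
    COMPLEMENT[ou$other_allele] == ex$effect_allele
  flip <- !pal & !same & !comp_same & (swapped | comp_swapped)
  bad <- !pal & !(same | swapped | comp_same | comp_swapped)
  drop_reason[bad] <- "irreconcilable alleles"

  ok <- is.na(drop_reason)
  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  variants <- data.frame(
    variant_id = ex$variant_id[ok],
    beta_exposure = ex$beta[ok], se_exposure = ex$se[ok],
    beta_outcome = beta_out[ok], se_outcome = ou$se[ok],
    stringsAsFactors = FALSE
  )
  aligned <- ou[ok, , drop = FALSE]
  aligned$effect_allele <- ex$effect_allele[ok]
  aligned$other_allele <- ex$other_allele[ok]
  aligned$beta <- beta_out[ok]
  if ("eaf" %in% names(aligned)) {
    aligned$eaf <- ifelse(flip[ok], 1 - aligned$eaf, aligned$eaf)
  }
  rownames(variants) <- rownames(aligned) <- NULL
  log_df <- data.frame(variant_id = ex$variant_id[!ok],
                       reason = drop_reason[!ok],
                       stringsAsFactors = FALSE)
  structure(list(variants = variants, outcome_aligned = aligned,
                 exposure_matched = ex[ok, , drop = FALSE],
                 n_dropped = nrow(log_df), drop_log = log_df),
            class = "gwas_pair")
}

mr_result <- function(estimate, se, method, n_variants, q_statistic = NA,
                      q_p = NA, cis_status = NA_character_) {
  p <- if (se > 0) 2 * stats::pnorm(-abs(estimate / se))
       else if (estimate == 0) 1 else 0
  structure(list(estimate = estimate, se = se, p = p, method = method,
                 n_variants = n_variants, q_statistic = q_statistic,
                 q_p = q_p, cis_status = cis_status),
            class = "mr_result")
}

#' Wald-ratio Mendelian randomization estimate (single instrument)
#'
#' `estimate = beta_outcome / beta_exposure` with first-order
#' delta-method SE `se_outcome / |beta_exposure|` and a two-sided
#' normal p-value.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Per-variant
#'   summary statistics; alternatively pass a one-row `variants` data
#'   frame from [harmonize_variants()] as the first argument.
#' @return Object of class `mr_result`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure = NULL,
                       beta_outcome = NULL, se_outcome = NULL) {
  if (is.data.frame(beta_exposure)) {
    v <- beta_exposure
    stopifnot(nrow(v) == 1)
    return(wald_ratio(v$beta_exposure, v$se_exposure, v$beta_outcome,
                      v$se_outcome))
  }
  if (beta_exposure == 0) stop_data("beta_exposure must be nonzero")
  est <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  mr_result(est, se, "wald", 1L)
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' Combines per-variant Wald ratios with weights `1 / se_ratio^2`
#' (first-order delta-method ratio SEs); attaches Cochran's Q and its
#' chi-square p-value on `k - 1` degrees of freedom. A single variant
#' delegates to [wald_ratio()].
#'
#' @param pair A [harmonize_variants()] result or its `variants` data
#'   frame.
#' @return Object of class `mr_result`.
#' @export
ivw <- function(pair) {
  v <- if (inherits(pair, "gwas_pair")) pair$variants else pair
  if (nrow(v) == 0) stop_data("no harmonized variants to combine")
  if (any(v$beta_exposure == 0)) stop_data("beta_exposure must be nonzero")
  if (nrow(v) == 1) return(wald_ratio(v))
  ratio <- v$beta_outcome / v$beta_exposure
  se_r <- v$se_outcome / abs(v$beta_exposure)
  w <- 1 / se_r^2
  est <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - est)^2)
  qp <- stats::pchisq(q, df = nrow(v) - 1, lower.tail = FALSE)
  mr_result(est, se, "ivw", nrow(v), q_statistic = q, q_p = qp)
}

#' Classify a variant as cis or trans to a gene
#'
#' cis if and only if the variant is on the gene's chromosome and
#' within `window` base pairs of the TSS (inclusive boundary).
#'
#' @param chrom,pos_bp Variant location.
#' @param gene_chrom,gene_tss Gene location.
#' @param window Half-width of the cis window in bp (default 1 Mb).
#' @return `"cis"` or `"trans"` (vectorised).
#' @export
classify_cis_trans <- function(chrom, pos_bp, gene_chrom, gene_tss,
                               window = 1e6) {
  ifelse(as.character(chrom) == as.character(gene_chrom) &
           abs(pos_bp - gene_tss) <= window, "cis", "trans")
}

#' MR scan of proteins against outcome GWAS panels
#'
#' For every protein x outcome combination: harmonizes the instrument
#' set against the outcome table, computes the IVW (or single-variant
#' Wald) estimate, labels the instrument set cis/trans/mixed relative
#' to the protein's encoding gene, and applies the multiple-testing
#' policy (Bonferroni across all tests by default). Proteins whose
#' instruments are all dropped are recorded as untestable rather than
#' failing the scan.
#'
#' @param proteins Named list; each element is
#'   `list(exposure = GWAS table, gene_chrom = , gene_tss = )`.
#' @param outcomes Named list of outcome GWAS tables.
#' @param alpha Family-wise significance level (default 0.05).
#' @param alpha_policy `"bonferroni"` or `"none"`.
#' @param cis_window Cis window half-width in bp.
#' @return Data frame with one row per protein x outcome: estimate, se,
#'   p, method, n_variants, Q statistic, cis status, `testable`, and
#'   `significant` under the policy.
#' @export
mr_scan <- function(proteins, outcomes, alpha = 0.05,
                    alpha_policy = c("bonferroni", "none"),
                    cis_window = 1e6) {
  alpha_policy <- match.arg(alpha_policy)
  rows <- list()
  for (pn in names(proteins)) {
    pr <- proteins[[pn]]
    for (on in names(outcomes)) {
      pair <- harmonize_variants(pr$exposure, outcomes[[on]])
      if (nrow(pair$variants) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          protein = pn, outcome = on, testable = FALSE, method = NA,
          n_variants = 0L, estimate = NA_real_, se = NA_real_,
          p = NA_real_, q_statistic = NA_real_, cis_status = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      res <- ivw(pair)
      ex <- pair$exposure_matched
      status <- classify_cis_trans(ex$chrom, ex$pos_bp, pr$gene_chrom,
                                   pr$gene_tss, cis_window)
      cis_status <- if (all(status == "cis")) "cis"
        else if (all(status == "trans")) "trans" else "mixed"
      rows[[length(rows) + 1]] <- data.frame(
        protein = pn, outcome = on, testable = TRUE, method = res$method,
        n_variants = res$n_variants, estimate = res$estimate, se = res$se,
        p = res$p, q_statistic = res$q_statistic %||% NA_real_,
        cis_status = cis_status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- sum(out$testable)
  thr <- if (alpha_policy == "bonferroni") alpha / max(n_tests, 1) else alpha
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "alpha_threshold") <- thr
  out
}
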