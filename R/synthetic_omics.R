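#' Synthetic proteome configuration
#'
#' @param n_aptamers Number of aptamer features.
#' @param n_signal_per_group Number of truly group-associated aptamers
#'   for each non-reference group (scalar or named vector).
#' @param effect_size Mean shift (in SD units) of a signal aptamer in
#'   its target group(s); on the standardised scale this is
#'   approximately the multinomial log-odds per SD.
#' @param overlap_spec Optional named list of shared-signal patterns,
#'   e.g. `list("red&blue" = 4)` plants 4 aptamers associated with both
#'   groups; counts are in addition to the per-group unique signals.
#' @param equicorrelation Optional common-factor correlation among all
#'   aptamers (default 0 = independence).
#' @param seed Integer seed.
#' @return Object of class `proteome_config`.
#' @export
proteome_config <- function(n_aptamers, n_signal_per_group = 0,
                            effect_size = 0.5, overlap_spec = NULL,
                            equicorrelation = 0, seed = 1L) {
  if (n_aptamers < 1) stop_config("n_aptamers", "must be a positive count")
  if (!is.finite(effect_size)) stop_config("effect_size", "must be finite")
  if (equicorrelation < 0 || equicorrelation >= 1) {
    stop_config("equicorrelation", "must lie in [0, 1)")
  }
  structure(list(n_aptamers = as.integer(n_aptamers),
                 n_signal_per_group = n_signal_per_group,
                 effect_size = effect_size, overlap_spec = overlap_spec,
                 equicorrelation = equicorrelation,
                 seed = as.integer(seed)),
            class = "proteome_config")
}

#' Generate a synthetic aptamer proteome with planted group signals
#'
#' Null aptamers are standard normal independent of group; signal
#' aptamers have their mean shifted by `effect_size` in their target
#' group(s). Each aptamer receives a synthetic gene annotation
#' (gene, chromosome, TSS) for downstream cis/trans labelling.
#'
#' @param truth Data frame with `participant_id` and `group` (the
#'   generator's true assignments).
#' @param config A [proteome_config()].
#' @param reference Reference group that never carries signal.
#' @return List: `matrix` (participants x aptamers), `annotation`
#'   (aptamer_id, gene, chrom, tss_bp), `signal_truth` (aptamer_id,
#'   groups — `&`-joined target groups, empty for null aptamers).
#' @export
generate_proteome <- function(truth, config, reference = "pink") {
  stopifnot(inherits(config, "proteome_config"))
  if (nrow(truth) == 0) stop_data("truth table is empty")
  set.seed(config$seed)
  n <- nrow(truth)
  p <- config$n_aptamers
  groups <- setdiff(unique(truth$group), reference)
  nsig <- config$n_signal_per_group
  if (length(nsig) == 1) nsig <- stats::setNames(rep(nsig, length(groups)), groups)
  n_overlap <- sum(unlist(config$overlap_spec))
  if (sum(nsig) + n_overlap > p) {
    stop_config("n_signal_per_group", "total signal aptamers exceed n_aptamers")
  }

  apt <- sprintf("apt_%05d", seq_len(p))
  Z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(truth$participant_id, apt))
  if (config$equicorrelation > 0) {
    f <- stats::rnorm(n)
    Z <- sqrt(config$equicorrelation) * f +
      sqrt(1 - config$equicorrelation) * Z
  }

  assign_groups <- character(p)
  nxt <- 1L
  for (g in names(nsig)) {
    if (nsig[[g]] == 0) next
    idx <- nxt:(nxt + nsig[[g]] - 1L)
    assign_groups[idx] <- g
    nxt <- nxt + nsig[[g]]
  }
  for (pat in names(config$overlap_spec)) {
    cnt <- config$overlap_spec[[pat]]
    if (cnt == 0) next
    idx <- nxt:(nxt + cnt - 1L)
    assign_groups[idx] <- pat
    nxt <- nxt + cnt
  }
  if (config$effect_size != 0) {
    for (j in which(assign_groups != "")) {
      tg <- strsplit(assign_groups[j], "&", fixed = TRUE)[[1]]
      sel <- truth$group %in% tg
      Z[sel, j] <- Z[sel, j] + config$effect_size
    }
  } else {
    assign_groups[] <- ""
  }

  annotation <- data.frame(
    aptamer_id = apt,
    gene = sprintf("GENE%05d", seq_len(p)),
    chrom = as.character(sample(1:22, p, replace = TRUE)),
    tss_bp = sample.int(2.4e8, p, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(matrix = Z, annotation = annotation,
       signal_truth = data.frame(aptamer_id = apt, groups = assign_groups,
                                 stringsAsFactors = FALSE))
}

#' GWAS-pair simulation configuration
#'
#' @param n_variants Instruments per protein (pre-clumped, independent).
#' @param true_causal_effect Outcome units per SD of exposure.
#' @param instrument_strength Scale of per-variant exposure effects.
#' @param se_exposure,se_outcome Reported standard errors.
#' @param cis_fraction Probability the sentinel variant lies within the
#'   cis window of the encoding gene.
#' @param flip_fraction Probability an outcome record has its effect and
#'   other alleles swapped (beta sign-flipped) relative to exposure.
#' @param strand_fraction Probability an outcome record is reported on
#'   the opposite strand (alleles complemented).
#' @param palindromic_fraction Probability a variant is palindromic
#'   (A/T or C/G), exercising the drop rule.
#' @param seed Integer seed.
#' @return Object of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(n_variants = 30, true_causal_effect = 0,
                            instrument_strength = 0.15,
                            se_exposure = 0.02, se_outcome = 0.02,
                            cis_fraction = 1, flip_fraction = 0.3,
                            strand_fraction = 0.1,
                            palindromic_fraction = 0, seed = 1L) {
  if (n_variants < 1) stop_config("n_variants", "must be >= 1")
  if (se_exposure <= 0 || se_outcome <= 0) {
    stop_config("se_scales", "must be > 0")
  }
  if (!is.finite(true_causal_effect)) {
    stop_config("true_causal_effect", "must be finite")
  }
  structure(as.list(environment()), class = "gwas_sim_config")
}

NONPALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a paired exposure/outcome GWAS summary-statistics table
#'
#' Per-variant true exposure effects are drawn at the configured
#' instrument strength; observed exposure betas add noise at the
#' exposure SE, and outcome betas equal `true_causal_effect` times the
#' true exposure effect plus noise at the outcome SE. Outcome allele
#' coding is randomly swapped and/or strand-complemented relative to
#' exposure to exercise harmonization; palindromic variants are
#' injectable. The sentinel (smallest exposure p) lies within the cis
#' window of the synthetic gene with probability `cis_fraction`.
#'
#' @param config A [gwas_sim_config()].
#' @return List: `exposure` and `outcome` data frames (variant_id,
#'   chrom, pos_bp, effect_allele, other_allele, beta, se, pval, eaf),
#'   `gene` (gene, chrom, tss_bp), `truth` (the causal effect).
#' @export
generate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "gwas_sim_config"))
  set.seed(config$seed)
  k <- config$n_variants
  gene <- list(gene = "GENE00001", chrom = "1", tss_bp = 5e7)

  beta_true <- config$instrument_strength * stats::runif(k, 0.5, 1.5) *
    sample(c(-1, 1), k, replace = TRUE)
  beta_exp <- beta_true + stats::rnorm(k, 0, config$se_exposure)
  beta_out <- config$true_causal_effect * beta_true +
    stats::rnorm(k, 0, config$se_outcome)

  pal <- stats::runif(k) < config$palindromic_fraction
  all_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), k, replace = TRUE)
  pal_idx <- sample.int(nrow(PALINDROMIC_PAIRS), k, replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[pal_idx, 1], NONPALINDROMIC_PAIRS[all_idx, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[pal_idx, 2], NONPALINDROMIC_PAIRS[all_idx, 2])

  cis <- stats::runif(1) < config$cis_fraction
  chrom <- rep(if (cis) gene$chrom else "2", k)
  pos <- if (cis) {
    gene$tss_bp + sample(seq(-9e5, 9e5, by = 1e3), k, replace = TRUE)
  } else {
    sample.int(2e8, k, replace = TRUE)
  }
  eaf <- stats::runif(k, 0.1, 0.9)
  vid <- sprintf("rs%06d", sample.int(999999, k))

  exposure <- data.frame(
    variant_id = vid, chrom = chrom, pos_bp = pos,
    effect_allele = ea, other_allele = oa,
    beta = beta_exp, se = config$se_exposure,
    pval = 2 * stats::pnorm(-abs(beta_exp / config$se_exposure)),
    eaf = eaf, stringsAsFactors = FALSE
  )

  swap <- stats::runif(k) < config$flip_fraction
  strand <- stats::runif(k) < config$strand_fraction
  ea_o <- ifelse(swap, oa, ea)
  oa_o <- ifelse(swap, ea, oa)
  ea_o2 <- ifelse(strand, COMPLEMENT[ea_o], ea_o)
  oa_o2 <- ifelse(strand, COMPLEMENT[oa_o], oa_o)
  outcome <- data.frame(
    variant_id = vid, chrom = chrom, pos_bp = pos,
    effect_allele = unname(ea_o2), other_allele = unname(oa_o2),
    beta = ifelse(swap, -beta_out, beta_out), se = config$se_outcome,
    pval = 2 * stats::pnorm(-abs(beta_out / config$se_outcome)),
    eaf = ifelse(swap, 1 - eaf, eaf), stringsAsFactors = FALSE
  )
  list(exposure = exposure, outcome = outcome, gene = gene,
       truth = config$true_causal_effect)
}
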