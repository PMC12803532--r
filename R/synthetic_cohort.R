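#' Default trajectory-group prevalences
#'
#' Derivation-cohort group sizes are 375/130/168/29/17/28 of 747;
#' testing-cohort (assigned-membership) sizes are
#' 2201/676/942/162/90/348 of 4419 for the pink, light-green, red,
#' dark-green, orange and blue groups.
#'
#' @param mode `"derivation"` or `"testing"`.
#' @return Named probability vector of length 6.
#' @export
default_group_prevalences <- function(mode = c("derivation", "testing")) {
  mode <- match.arg(mode)
  p <- if (mode == "derivation") {
    c(375, 130, 168, 29, 17, 28) / 747
  } else {
    c(2201, 676, 942, 162, 90, 348) / 4419
  }
  names(p) <- TRAJ_LABELS
  p
}

# Baseline (age 64.5) group means and SDs of the two modelled targets.
GROUP_BASELINE <- list(
  lvef_mean = c(pink = 66.3, light_green = 79.6, red = 72.3,
                dark_green = 56.8, orange = 82.8, blue = 71.5),
  lvef_sd   = c(pink = 15.5, light_green = 5.9, red = 8.5,
                dark_green = 10.5, orange = 7.1, blue = 8.9),
  ea_mean   = c(pink = 1.01, light_green = 0.96, red = 0.69,
                dark_green = 0.72, orange = 0.93, blue = 1.19),
  ea_sd     = c(pink = 0.21, light_green = 0.28, red = 0.13,
                dark_green = 0.16, orange = 0.29, blue = 0.24)
)

# Per-decade slopes chosen to match the qualitative group patterns:
# pink/light-green/blue rising LVEF, red flat, dark-green declining,
# orange steeply declining; pink/light-green falling E/A, orange/blue
# rising E/A.
GROUP_SLOPES <- list(
  lvef = c(pink = 3, light_green = 2, red = 0,
           dark_green = -6, orange = -14, blue = 3),
  ea   = c(pink = -0.15, light_green = -0.12, red = -0.03,
           dark_green = -0.03, orange = 0.15, blue = 0.12)
)

#' Default group trajectory curves
#'
#' Quadratic-basis coefficients per group and target, anchored so the
#' curve value at age 64.5 equals the group's baseline mean and the
#' linear term equals the configured change per decade (curvature 0 by
#' default; the fitted model may still estimate curvature).
#'
#' @param basis An [age_basis()]; the anchor assumes `scale = 10`.
#' @return Named list per group of `list(lvef = , ea = )` coefficient
#'   vectors on the standardised-age basis.
#' @export
default_group_curves <- function(basis = age_basis()) {
  z0 <- (64.5 - basis$reference_age) / basis$scale
  out <- lapply(TRAJ_LABELS, function(g) {
    cf <- function(target) {
      mean_bl <- GROUP_BASELINE[[paste0(target, "_mean")]][[g]]
      slope <- GROUP_SLOPES[[target]][[g]]
      beta <- numeric(basis$degree + 1)
      beta[1] <- mean_bl - slope * z0
      if (basis$degree >= 1) beta[2] <- slope
      beta
    }
    list(lvef = cf("lvef"), ea = cf("ea"))
  })
  names(out) <- TRAJ_LABELS
  out
}

#' Default within-group residual SDs
#' @return Named list per group of `c(lvef = , ea = )`.
#' @export
default_residual_sd <- function() {
  out <- lapply(TRAJ_LABELS, function(g) {
    c(lvef = unname(GROUP_BASELINE$lvef_sd[g]),
      ea = unname(GROUP_BASELINE$ea_sd[g]))
  })
  names(out) <- TRAJ_LABELS
  out
}

#' Default per-group binary covariate prevalences
#'
#' Derivation-cohort prevalences of male sex, obesity, hypertension,
#' diabetes, chronic kidney disease, coronary heart disease and atrial
#' fibrillation by trajectory group. Covariates are generated
#' independently of outcomes given group (no confounding by
#' construction).
#'
#' @param mode `"derivation"` (no atrial fibrillation at baseline) or
#'   `"testing"` (4% atrial fibrillation in all groups).
#' @return Matrix, groups x covariates.
#' @export
default_covariate_prevalences <- function(mode = c("testing", "derivation")) {
  mode <- match.arg(mode)
  m <- rbind(
    male         = c(0.33, 0.11, 0.29, 0.69, 0.53, 0.32),
    obesity      = c(0.51, 0.51, 0.52, 0.55, 0.41, 0.54),
    hypertension = c(0.68, 0.64, 0.83, 0.76, 0.94, 0.71),
    diabetes     = c(0.22, 0.23, 0.31, 0.32, 0.35, 0.32),
    ckd          = c(0.04, 0.06, 0.04, 0.03, 0.06, 0.11),
    chd          = c(0.06, 0.04, 0.08, 0.17, 0.00, 0.14),
    afib         = if (mode == "testing") rep(0.04, 6) else rep(0, 6)
  )
  colnames(m) <- TRAJ_LABELS
  t(m)
}

#' Default cause-specific hazard configuration
#'
#' Baseline (pink) rates are anchored on the testing-cohort event counts
#' (163 any-HF = 87 HFpEF + 50 HFrEF + 26 unknown-EF among 2201 pink
#' participants over 7.4 years); group hazard ratios for any-HF, HFpEF
#' and HFrEF are the published cause-specific estimates. Death is an
#' independent competing event with no group effect by default.
#'
#' @param mode `"testing"` uses the testing-cohort hazard ratios
#'   (any-HF / HFpEF / HFrEF); `"derivation"` uses the derivation-cohort
#'   any-HF ratios (1.97, 2.78, 4.21, 3.86 for red, dark-green, orange,
#'   blue) with the same endpoint split, scaled to ~60 events in 747
#'   participants over 12 years.
#' @return List with elements `any_hf`, `hf_pef`, `hf_ref`, `death`,
#'   each `list(base = events/person-year, loghr = named per-group log
#'   hazard ratio vs. pink)`.
#' @export
default_hazards <- function(mode = c("testing", "derivation")) {
  mode <- match.arg(mode)
  lhr <- function(x) { names(x) <- TRAJ_LABELS; log(x) }
  if (mode == "testing") {
    py <- 2201 * 7.4
    list(
      any_hf = list(base = 163 / py,
                    loghr = lhr(c(1, 0.65, 1.18, 3.26, 2.32, 1.64))),
      hf_pef = list(base = 87 / py,
                    loghr = lhr(c(1, 0.57, 0.97, 1.17, 2.33, 1.76))),
      hf_ref = list(base = 50 / py,
                    loghr = lhr(c(1, 0.59, 1.67, 8.08, 3.74, 1.34))),
      death  = list(base = 0.02, loghr = lhr(rep(1, 6)))
    )
  } else {
    base_any <- 60 / (747 * 11.5)
    hr_any <- c(1, 1, 1.97, 2.78, 4.21, 3.86)
    list(
      any_hf = list(base = base_any, loghr = lhr(hr_any)),
      hf_pef = list(base = base_any * 87 / 163, loghr = lhr(hr_any)),
      hf_ref = list(base = base_any * 50 / 163, loghr = lhr(hr_any)),
      death  = list(base = 0.02, loghr = lhr(rep(1, 6)))
    )
  }
}

#' Synthetic-cohort configuration
#'
#' Bundles every knob of the cohort generator. Defaults emulate the two
#' study designs: `"derivation"` gives up to three echocardiograms at
#' mean ages 64.7 / 74.7 / 80.5 years with attendance 1, 731/747 and
#' 488/747 and a 12-year composite follow-up; `"testing"` gives a single
#' echocardiogram at mean age 75.3 and 7.4 years of cause-specific
#' follow-up.
#'
#' @param n_participants Number of participants.
#' @param mode `"testing"` or `"derivation"`.
#' @param seed Integer seed; every draw of the generator derives from it.
#' @param group_prevalences,group_curves,residual_sd,covariate_prevalences
#'   Optional overrides of the defaults documented in
#'   [default_group_prevalences()] and friends.
#' @param visit_ages Matrix-like with columns `mean`, `sd`, one row per
#'   visit (years).
#' @param attendance Per-visit attendance probability; first entry must
#'   be 1 (everyone has a baseline echo); later visits are independent
#'   Bernoulli.
#' @param hazards See [default_hazards()].
#' @param admin_censor_years Administrative censoring horizon.
#' @param basis [age_basis()] on which `group_curves` live.
#' @param ea_floor Lower truncation for E/A (non-physiologic values).
#' @param lvef_range Truncation range for LVEF in percent.
#' @param gap_jitter_sd SD (years) of the jitter on between-visit gaps.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          mode = c("testing", "derivation"),
                          seed = 1L,
                          group_prevalences = NULL,
                          group_curves = NULL,
                          residual_sd = default_residual_sd(),
                          covariate_prevalences = NULL,
                          visit_ages = NULL,
                          attendance = NULL,
                          hazards = NULL,
                          admin_censor_years = NULL,
                          basis = age_basis(),
                          ea_floor = 0.2,
                          lvef_range = c(5, 100),
                          gap_jitter_sd = 0.7) {
  mode <- match.arg(mode)
  if (length(n_participants) != 1 || !is.finite(n_participants) ||
      n_participants < 1) {
    stop_config("n_participants", "must be a positive count")
  }
  if (is.null(group_prevalences)) {
    group_prevalences <- default_group_prevalences(mode)
  }
  if (is.null(group_curves)) group_curves <- default_group_curves(basis)
  if (is.null(covariate_prevalences)) {
    covariate_prevalences <- default_covariate_prevalences(mode)
  }
  if (is.null(visit_ages)) {
    visit_ages <- if (mode == "derivation") {
      cbind(mean = c(64.7, 74.7, 80.5), sd = c(5.0, 4.9, 4.6))
    } else {
      cbind(mean = 75.3, sd = 5.1)
    }
  }
  if (is.null(attendance)) {
    attendance <- if (mode == "derivation") c(1, 731 / 747, 488 / 747) else 1
  }
  if (is.null(hazards)) hazards <- default_hazards(mode)
  if (is.null(admin_censor_years)) {
    admin_censor_years <- if (mode == "derivation") 12 else 7.4
  }

  labels <- names(group_prevalences)
  if (is.null(labels)) labels <- paste0("g", seq_along(group_prevalences))
  check_prob_vector(group_prevalences, "group_prevalences")
  if (attendance[1] != 1) stop_config("attendance", "must be 1 at baseline")
  if (any(attendance < 0 | attendance > 1)) {
    stop_config("attendance", "entries must be probabilities")
  }
  if (nrow(visit_ages) != length(attendance)) {
    stop_config("visit_ages", "must have one row per attendance entry")
  }
  for (g in labels) {
    if (any(!is.finite(unlist(group_curves[[g]])))) {
      stop_config("group_curves", sprintf("has non-finite entries for group '%s'", g))
    }
    if (any(residual_sd[[g]] <= 0)) {
      stop_config("residual_sd", sprintf("must be > 0 for group '%s'", g))
    }
  }
  for (nm in names(hazards)) {
    if (hazards[[nm]]$base < 0) stop_config("hazards", sprintf("baseline rate for '%s' must be >= 0", nm))
  }
  if (hazards$any_hf$base < hazards$hf_pef$base + hazards$hf_ref$base - 1e-12) {
    stop_config("hazards", "any_hf baseline must be >= hf_pef + hf_ref baselines")
  }
  structure(list(
    n_participants = as.integer(n_participants), mode = mode,
    seed = as.integer(seed), labels = labels,
    group_prevalences = group_prevalences, group_curves = group_curves,
    residual_sd = residual_sd,
    covariate_prevalences = covariate_prevalences,
    visit_ages = visit_ages, attendance = attendance, hazards = hazards,
    admin_censor_years = admin_censor_years, basis = basis,
    ea_floor = ea_floor, lvef_range = lvef_range,
    gap_jitter_sd = gap_jitter_sd
  ), class = "cohort_config")
}

# Per-group rates of the four competing event components. The any-HF
# hazard is decomposed into HFpEF + HFrEF + unknown-EF; the unknown-EF
# component is the remainder, clamped at zero when the published
# per-endpoint ratios overshoot the any-HF ratio.
component_hazards <- function(config) {
  hz <- config$hazards
  G <- length(config$labels)
  lam <- matrix(0, G, 4, dimnames = list(config$labels,
                                         c("hf_pef", "hf_ref", "hf_unknown", "death")))
  base_unk <- hz$any_hf$base - hz$hf_pef$base - hz$hf_ref$base
  for (g in seq_len(G)) {
    lp <- hz$hf_pef$base * exp(hz$hf_pef$loghr[g])
    lr <- hz$hf_ref$base * exp(hz$hf_ref$loghr[g])
    la <- hz$any_hf$base * exp(hz$any_hf$loghr[g])
    lam[g, "hf_pef"] <- lp
    lam[g, "hf_ref"] <- lr
    lam[g, "hf_unknown"] <- max(0, la - lp - lr)
    lam[g, "death"] <- hz$death$base * exp(hz$death$loghr[g])
  }
  lam
}

rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic echocardiographic cohort
#'
#' Draws, per participant: a latent trajectory group; ordered visit ages
#' on the configured schedule; LVEF and E/A at each attended visit equal
#' to the group curve at standardised age plus independent Gaussian
#' noise (E/A floored, LVEF restricted to a physiologic range); binary
#' covariates with group-specific prevalences; and a typed survival
#' outcome from competing exponential cause-specific hazards (HFpEF,
#' HFrEF, HF with unknown EF, death), first event wins, administrative
#' censoring at the configured horizon. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with elements `visits` (long data frame: participant_id,
#'   visit, age_years, lvef_pct, ea_ratio), `covariates`, `survival`
#'   (participant_id, time_years, event), and `truth` (participant_id,
#'   group).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  G <- length(config$labels)
  V <- nrow(config$visit_ages)
  id <- sprintf("P%05d", seq_len(n))

  group_idx <- sample.int(G, n, replace = TRUE, prob = config$group_prevalences)
  group <- config$labels[group_idx]

  # Ordered visit ages: truncated-Gaussian baseline, then mean gaps plus
  # jitter (gap floored at half a year).
  ages <- matrix(NA_real_, n, V)
  ages[, 1] <- rtruncnorm_inv(n, config$visit_ages[1, "mean"],
                              config$visit_ages[1, "sd"], 45, 100)
  if (V > 1) {
    for (v in 2:V) {
      gap <- config$visit_ages[v, "mean"] - config$visit_ages[v - 1, "mean"]
      ages[, v] <- ages[, v - 1] +
        pmax(0.5, gap + stats::rnorm(n, 0, config$gap_jitter_sd))
    }
  }

  attend <- matrix(TRUE, n, V)
  if (V > 1) {
    for (v in 2:V) attend[, v] <- stats::runif(n) < config$attendance[v]
  }

  # Echo values at every scheduled visit (drawn regardless of attendance
  # so the value stream does not depend on the attendance stream).
  lvef <- ea <- matrix(NA_real_, n, V)
  for (v in seq_len(V)) {
    X <- build_design(ages[, v], config$basis)
    for (g in seq_len(G)) {
      sel <- group_idx == g
      if (!any(sel)) next
      cv <- config$group_curves[[g]]
      sdv <- config$residual_sd[[g]]
      lvef[sel, v] <- X[sel, , drop = FALSE] %*% cv$lvef +
        stats::rnorm(sum(sel), 0, sdv[["lvef"]])
      ea[sel, v] <- X[sel, , drop = FALSE] %*% cv$ea +
        stats::rnorm(sum(sel), 0, sdv[["ea"]])
    }
  }
  lvef <- pmin(pmax(lvef, config$lvef_range[1]), config$lvef_range[2])
  ea <- pmax(ea, config$ea_floor)

  keep <- which(attend)
  visits <- data.frame(
    participant_id = id[(keep - 1L) %% n + 1L],
    visit = (keep - 1L) %/% n + 1L,
    age_years = ages[keep],
    lvef_pct = lvef[keep],
    ea_ratio = ea[keep],
    stringsAsFactors = FALSE
  )
  visits <- visits[order(visits$participant_id, visits$visit), ]
  rownames(visits) <- NULL

  cp <- config$covariate_prevalences
  covariates <- data.frame(participant_id = id, age_years = ages[, 1],
                           stringsAsFactors = FALSE)
  for (cov in colnames(cp)) {
    covariates[[cov]] <- as.integer(stats::runif(n) < cp[group_idx, cov])
  }

  lam <- component_hazards(config)[group_idx, , drop = FALSE]
  u <- matrix(stats::runif(n * 4), n, 4)
  tt <- -log(u) / lam        # rate 0 -> Inf, i.e. the event never occurs
  first <- max.col(-tt, ties.method = "first")
  t_event <- tt[cbind(seq_len(n), first)]
  censored <- t_event > config$admin_censor_years
  survival <- data.frame(
    participant_id = id,
    time_years = pmin(t_event, config$admin_censor_years),
    event = ifelse(censored, "none", colnames(lam)[first]),
    stringsAsFactors = FALSE
  )

  list(visits = visits, covariates = covariates, survival = survival,
       truth = data.frame(participant_id = id, group = group,
                          stringsAsFactors = FALSE))
}
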