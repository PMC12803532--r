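#' Build a cause-specific analysis dataset
#'
#' Recodes typed survival records into a binary event indicator for one
#' endpoint under cause-specific censoring: for the HFpEF endpoint, HF
#' events with reduced or unknown EF are censored at the time of that
#' event (and vice versa for HFrEF); death always censors the HF
#' endpoints; `any_hf` counts all three HF codes as events; and
#' `hf_or_death` is the composite used for derivation-cohort follow-up.
#' Every record appears exactly once with its time unchanged.
#'
#' @param records Data frame with `participant_id`, `time_years`,
#'   `event` in `none, hf_pef, hf_ref, hf_unknown, death`.
#' @param endpoint One of `"any_hf"`, `"hf_pef"`, `"hf_ref"`,
#'   `"hf_or_death"`.
#' @return The input with an added integer `status` column (1 = event).
#' @export
cause_specific_dataset <- function(records,
                                   endpoint = c("any_hf", "hf_pef", "hf_ref",
                                                "hf_or_death")) {
  endpoint <- match.arg(endpoint)
  check_columns(records, c("participant_id", "time_years", "event"),
                "survival records")
  bad <- setdiff(unique(records$event), EVENT_LEVELS)
  if (length(bad) > 0) {
    stop_data(sprintf("unknown event code(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(records$time_years <= 0)) stop_data("times must be positive")
  ev <- records$event
  records$status <- switch(endpoint,
    any_hf = as.integer(ev %in% c("hf_pef", "hf_ref", "hf_unknown")),
    hf_pef = as.integer(ev == "hf_pef"),
    hf_ref = as.integer(ev == "hf_ref"),
    hf_or_death = as.integer(ev != "none")
  )
  attr(records, "endpoint") <- endpoint
  records
}

#' Cox proportional-hazards model of trajectory membership
#'
#' Fits a Cox model (Breslow tie handling by default) of the
#' cause-specific dataset on trajectory indicators versus a reference
#' group, optionally adjusted for covariates. Constant covariates are
#' dropped with a warning.
#'
#' @param dataset Output of [cause_specific_dataset()].
#' @param trajectory Vector of group labels aligned with `dataset` rows.
#' @param reference Reference group label (conventionally the largest,
#'   lowest-risk group).
#' @param covariates Optional data frame of adjustment covariates
#'   aligned with `dataset` rows.
#' @param ties Tie handling passed to [survival::coxph()].
#' @return Object of class `cox_result`: a `table` data frame (term,
#'   coef, hr, ci_lower, ci_upper, se, p), `n_events`, `endpoint`, and
#'   the underlying `fit`.
#' @export
fit_cox <- function(dataset, trajectory, reference, covariates = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_columns(dataset, c("time_years", "status"), "cause-specific dataset")
  if (sum(dataset$status) < 1) stop_data("no events in dataset")
  if (!reference %in% trajectory) {
    stop_data(sprintf("reference group '%s' not present", reference))
  }
  df <- data.frame(time = dataset$time_years, status = dataset$status)
  tr <- factor(trajectory)
  if (nlevels(tr) >= 2) {
    df$trajectory <- stats::relevel(tr, ref = as.character(reference))
  }
  if (!is.null(covariates)) {
    keep <- vapply(covariates, function(x) length(unique(x)) > 1, TRUE)
    if (any(!keep)) {
      warning(sprintf("dropping constant covariate(s): %s",
                      paste(names(covariates)[!keep], collapse = ", ")))
    }
    df <- cbind(df, covariates[, keep, drop = FALSE])
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, status) ~",
                            paste(setdiff(names(df), c("time", "status")),
                                  collapse = " + "))),
    data = df, ties = ties)
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    hr = sm$coefficients[, "exp(coef)"],
    ci_lower = sm$conf.int[, "lower .95"],
    ci_upper = sm$conf.int[, "upper .95"],
    se = sm$coefficients[, "se(coef)"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_events = sum(dataset$status),
                 endpoint = attr(dataset, "endpoint"),
                 reference = reference, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox model (%s endpoint, %d events, reference = %s)\n",
              x$endpoint %||% "custom", x$n_events, x$reference))
  print(x$table, digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harrell's concordance index
#'
#' C over usable pairs: a pair is usable when one member has an event
#' and the other is known to survive longer (later time of any status,
#' or censored at the same time). Ties in risk score count 0.5.
#'
#' @param risk_scores Numeric vector; higher = higher risk.
#' @param time,status Follow-up time and binary event indicator.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(risk_scores, time, status) {
  if (any(!is.finite(risk_scores))) stop_data("non-finite risk scores")
  stopifnot(length(risk_scores) == length(time),
            length(time) == length(status))
  conc <- 0
  usable <- 0
  for (i in which(status == 1)) {
    cmp <- (time > time[i]) | (time == time[i] & status == 0)
    nu <- sum(cmp)
    if (nu == 0) next
    usable <- usable + nu
    conc <- conc + sum(risk_scores[i] > risk_scores[cmp]) +
      0.5 * sum(risk_scores[i] == risk_scores[cmp])
  }
  if (usable == 0) stop_data("no usable pairs for concordance")
  conc / usable
}

#' Compare the concordance of two risk models by paired bootstrap
#'
#' Resamples participants with replacement, recomputes both C-statistics
#' on each resample, and tests `delta = C_b - C_a = 0` with a normal
#' approximation using the bootstrap standard error. Deterministic given
#' `seed`.
#'
#' @param scores_a,scores_b Risk scores of the two models on the same
#'   records.
#' @param time,status Follow-up and event indicator.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return List with `c_a`, `c_b`, `delta`, `se`, `p_value`, and the
#'   bootstrap draws `boot_delta`.
#' @export
compare_c <- function(scores_a, scores_b, time, status, n_boot = 1000,
                      seed = 1) {
  if (n_boot < 100) stop_data("n_boot must be at least 100")
  stopifnot(length(scores_a) == length(scores_b))
  n <- length(time)
  c_a <- harrell_c(scores_a, time, status)
  c_b <- harrell_c(scores_b, time, status)
  delta <- c_b - c_a
  set.seed(as.integer(seed))
  bd <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(status[idx]) == 0) { bd[b] <- NA_real_; next }
    bd[b] <- tryCatch(
      harrell_c(scores_b[idx], time[idx], status[idx]) -
        harrell_c(scores_a[idx], time[idx], status[idx]),
      error = function(e) NA_real_)
  }
  bd <- bd[is.finite(bd)]
  se <- stats::sd(bd)
  p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(delta) / se)
  list(c_a = c_a, c_b = c_b, delta = delta, se = se, p_value = p,
       boot_delta = bd)
}
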