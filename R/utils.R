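#' @keywords internal
"_PACKAGE"

# Canonical trajectory-group labels, ordered by derivation-cohort prevalence.
TRAJ_LABELS <- c("pink", "light_green", "red", "dark_green", "orange", "blue")

# Event codes for survival records.
EVENT_LEVELS <- c("none", "hf_pef", "hf_ref", "hf_unknown", "death")

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

stop_data <- function(msg) {
  stop(sprintf("invalid data: %s", msg), call. = FALSE)
}

check_prob_vector <- function(p, field, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_config(field, "must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_config(field, sprintf("must sum to 1 (got %.15f)", sum(p)))
  }
  invisible(p)
}

check_columns <- function(df, cols, file = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_data(sprintf("%s is missing required column(s): %s",
                      file, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Draw sub-seeds from a root seed; keeps every derived seed < 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
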