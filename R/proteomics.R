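#' Centre and scale feature columns
#'
#' Standardises each column to mean 0 and SD 1 (sample, n-1 convention).
#' Constant columns cannot be scaled; they are excluded with a warning
#' and listed in the `"excluded"` attribute.
#'
#' @param mat Numeric matrix (observations x features).
#' @return Standardised matrix, possibly with fewer columns.
#' @export
scale_features <- function(mat) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning(sprintf("excluding %d constant column(s): %s", sum(const),
                    paste(colnames(mat)[const], collapse = ", ")))
  }
  kept <- mat[, !const, drop = FALSE]
  out <- scale(kept)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "excluded") <- colnames(mat)[const]
  out
}

# Newton-Raphson maximum likelihood for the multinomial logit. Written
# in-package because the proteome-wide scan refits the model thousands
# of times; the analytic Hessian provides Wald SEs at no extra cost.
multinom_newton <- function(X, y_idx, K, max_iter = 50, tol = 1e-10,
                            start = NULL) {
  n <- nrow(X)
  P <- ncol(X)
  Km1 <- K - 1
  B <- if (is.null(start)) matrix(0, P, Km1) else start
  Y <- matrix(0, n, Km1)
  for (k in seq_len(Km1)) Y[, k] <- as.numeric(y_idx == k + 1)

  loglik <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    lden <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(eta * Y) - sum(lden)
  }

  ll <- loglik(B)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    den <- exp(-m) + rowSums(exp(eta - m))
    Pm <- exp(eta - m) / den
    G <- crossprod(X, Y - Pm)                      # P x (K-1)
    H <- matrix(0, P * Km1, P * Km1)
    for (k in seq_len(Km1)) {
      for (l in k:Km1) {
        w <- if (k == l) Pm[, k] * (1 - Pm[, k]) else -Pm[, k] * Pm[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1) * P + seq_len(P)
        ci <- (l - 1) * P + seq_len(P)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      Bn <- B + lam * matrix(step, P, Km1)
      lln <- loglik(Bn)
      if (lln >= ll - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    moved <- abs(lln - ll)
    B <- Bn
    ll <- lln
    if (max(abs(G)) < 1e-8 || moved < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  # separation: runaway coefficients or an essentially perfect fit
  if (max(abs(B)) > 15 || ll > -1e-6) converged <- FALSE
  se <- matrix(NA_real_, P, Km1)
  if (!is.null(H)) {
    Vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vc)) se <- matrix(sqrt(pmax(diag(Vc), 0)), P, Km1)
  }
  list(coefficients = B, se = se, loglik = ll, converged = converged)
}

#' Multinomial logistic regression of trajectory labels
#'
#' Maximum-likelihood multinomial logit of group membership on a protein
#' (and covariates) with a stated reference category, with Wald
#' standard errors and p-values from the analytic Hessian.
#' Non-convergence (including separation, flagged by runaway
#' coefficients) is reported via `converged = FALSE` rather than an
#' error so that scans can log and skip.
#'
#' @param labels Group labels (factor or character), >= 2 categories.
#' @param protein Numeric vector (conventionally standardised).
#' @param covariates Optional data frame of adjustment covariates.
#' @param reference Reference category (default: first factor level).
#' @return Object of class `multinomial_fit` with `coefficients`, `se`,
#'   `p` matrices (rows = terms, columns = non-reference categories),
#'   `loglik`, `converged`.
#' @export
fit_multinomial <- function(labels, protein, covariates = NULL,
                            reference = NULL, start = NULL) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop_data("need at least 2 label categories")
  if (!is.null(reference)) y <- stats::relevel(y, ref = as.character(reference))
  X <- cbind(`(Intercept)` = 1, protein = protein)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (any(!is.finite(X))) stop_data("non-finite values in design")
  fit <- multinom_newton(X, as.integer(y), nlevels(y), start = start)
  z <- fit$coefficients / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  dn <- list(colnames(X), levels(y)[-1])
  dimnames(fit$coefficients) <- dimnames(fit$se) <- dimnames(p) <- dn
  structure(list(coefficients = fit$coefficients, se = fit$se, p = p,
                 loglik = fit$loglik, converged = fit$converged,
                 reference = levels(y)[1]),
            class = "multinomial_fit")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin, validated wrapper
#' over [stats::p.adjust()].
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values, monotone in `p_values`.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop_data("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Proteome-wide multinomial association scan
#'
#' Fits one multinomial model per aptamer (all effective groups
#' simultaneously, stated reference) and applies FDR control. The FDR
#' family is per non-reference contrast across aptamers by default; a
#' pooled family over all contrasts is available.
#'
#' @param proteins Numeric matrix, participants x aptamers
#'   (standardised; see [scale_features()]).
#' @param labels Trajectory labels per participant.
#' @param covariates Optional covariate data frame (conventionally
#'   standardised age and sex).
#' @param reference Reference trajectory label.
#' @param fdr_family `"per_contrast"` (default) or `"pooled"`.
#' @return Data frame with one row per aptamer x non-reference contrast:
#'   `aptamer_id`, `contrast`, `beta` (log-odds per SD), `se`, `p`, `q`,
#'   `converged`. Non-converged fits carry NA q and are excluded from
#'   the FDR family.
#' @export
protein_scan <- function(proteins, labels, covariates = NULL,
                         reference = "pink",
                         fdr_family = c("per_contrast", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  proteins <- as.matrix(proteins)
  if (is.null(colnames(proteins))) {
    colnames(proteins) <- sprintf("apt_%04d", seq_len(ncol(proteins)))
  }
  # Warm start every per-aptamer fit from the covariates-only model:
  # identical maximiser, fewer Newton steps.
  y0 <- factor(labels)
  y0 <- stats::relevel(y0, ref = as.character(reference))
  X0 <- cbind(rep(1, length(y0)),
              if (is.null(covariates)) NULL else as.matrix(covariates))
  null_fit <- multinom_newton(X0, as.integer(y0), nlevels(y0))
  start <- rbind(null_fit$coefficients[1, , drop = FALSE],
                 0,
                 if (nrow(null_fit$coefficients) > 1)
                   null_fit$coefficients[-1, , drop = FALSE])
  res <- vector("list", ncol(proteins))
  for (j in seq_len(ncol(proteins))) {
    fit <- fit_multinomial(labels, proteins[, j], covariates, reference,
                           start = start)
    res[[j]] <- data.frame(
      aptamer_id = colnames(proteins)[j],
      contrast = colnames(fit$coefficients),
      beta = fit$coefficients["protein", ],
      se = fit$se["protein", ],
      p = fit$p["protein", ],
      converged = fit$converged,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- out$converged & is.finite(out$p)
  if (fdr_family == "per_contrast") {
    for (ct in unique(out$contrast)) {
      sel <- ok & out$contrast == ct
      out$q[sel] <- fdr_adjust(out$p[sel])
    }
  } else {
    out$q[ok] <- fdr_adjust(out$p[ok])
  }
  out
}

#' Unique and shared set counts (upset-style)
#'
#' Counts, for a collection of per-trajectory significant-aptamer sets,
#' every nonempty intersection pattern plus per-set unique counts.
#'
#' @param significant_sets Named list of character vectors.
#' @return List with `patterns` (data frame: pattern label, count) and
#'   `unique_counts` (named vector: members found in exactly one set).
#' @export
shared_unique_counts <- function(significant_sets) {
  stopifnot(is.list(significant_sets), length(significant_sets) > 0)
  nm <- names(significant_sets)
  universe <- unique(unlist(significant_sets))
  if (length(universe) == 0) {
    return(list(patterns = data.frame(pattern = character(),
                                      count = integer()),
                unique_counts = stats::setNames(integer(length(nm)), nm)))
  }
  member <- sapply(significant_sets, function(s) universe %in% s)
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, nm))
  sig <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  counts <- table(sig)
  uniq <- vapply(nm, function(g) sum(sig == g), 0L)
  list(patterns = data.frame(pattern = names(counts),
                             count = as.integer(counts),
                             row.names = NULL, stringsAsFactors = FALSE),
       unique_counts = uniq)
}
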