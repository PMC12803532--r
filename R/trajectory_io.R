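# Versioned JSON serialisation of fitted trajectory models. Numbers are
# written at full precision so a write/read round trip is lossless well
# below 1e-12.

mat_to_list <- function(x) list(dim = dim(x), data = as.vector(x))
list_to_mat <- function(l) array(unlist(l$data), dim = unlist(l$dim))

#' Write a fitted trajectory model to JSON
#'
#' @param model A [fit_trajectories()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_model <- function(model, path) {
  stopifnot(inherits(model, "trajectory_model"))
  doc <- list(
    format = "cardiotraj-model", version = 1L,
    k_max = model$k_max, weights = model$weights,
    concentration = model$concentration,
    basis = unclass(model$basis),
    targets = as.list(model$targets),
    groups = lapply(model$groups, function(g) {
      list(coefficients = g$coefficients,
           residual_sd = as.list(g$residual_sd))
    }),
    priors = lapply(model$priors, function(pr) list(
      m0 = pr$m0, S0 = mat_to_list(pr$S0), a0 = pr$a0, b0 = pr$b0
    )),
    variational = list(
      m = mat_to_list(model$variational$m),
      S = mat_to_list(model$variational$S),
      a = mat_to_list(model$variational$a),
      b = mat_to_list(model$variational$b),
      g1 = model$variational$g1, g2 = model$variational$g2
    ),
    fit_meta = model$fit_meta[c("seed", "restarts", "elbo", "iterations",
                                "converged")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trajectory model written by [write_trajectory_model()]
#'
#' @param path JSON file path.
#' @return A `trajectory_model` object.
#' @export
read_trajectory_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "cardiotraj-model")) {
    stop_data("not a cardiotraj model document")
  }
  targets <- unlist(doc$targets)
  groups <- lapply(doc$groups, function(g) {
    list(coefficients = lapply(g$coefficients, function(x) unlist(x)),
         residual_sd = unlist(g$residual_sd))
  })
  priors <- lapply(doc$priors, function(pr) {
    S0 <- list_to_mat(pr$S0)
    list(m0 = unlist(pr$m0), S0 = S0, S0inv = solve(S0),
         a0 = pr$a0, b0 = pr$b0)
  })
  structure(list(
    k_max = as.integer(doc$k_max), weights = as.numeric(doc$weights),
    concentration = doc$concentration,
    basis = structure(list(reference_age = doc$basis$reference_age,
                           scale = doc$basis$scale,
                           degree = as.integer(doc$basis$degree)),
                      class = "age_basis"),
    priors = priors, targets = targets,
    groups = groups,
    variational = list(m = list_to_mat(doc$variational$m),
                       S = list_to_mat(doc$variational$S),
                       a = list_to_mat(doc$variational$a),
                       b = list_to_mat(doc$variational$b),
                       g1 = unlist(doc$variational$g1),
                       g2 = unlist(doc$variational$g2)),
    fit_meta = lapply(doc$fit_meta, function(x) if (is.list(x)) unlist(x) else x)
  ), class = "trajectory_model")
}
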