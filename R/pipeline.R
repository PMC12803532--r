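# Derivation / testing orchestration over the module functions. Configs
# are plain lists (or YAML/JSON files); every stage writes its outputs
# and a manifest (input hashes, seed, parameters) so reruns are
# auditable and reproducible.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_data("yaml package required to read YAML configs")
      }
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

load_table <- function(x, required, what) {
  if (is.character(x) && length(x) == 1) {
    df <- if (grepl("\\.tsv$", x)) {
      utils::read.delim(x, stringsAsFactors = FALSE)
    } else {
      utils::read.csv(x, stringsAsFactors = FALSE)
    }
    check_columns(df, required, sprintf("%s ('%s')", what, x))
    df
  } else {
    check_columns(as.data.frame(x), required, what)
  }
}

write_manifest <- function(out_dir, stage, config, inputs = character()) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(stage = stage, seed = config$seed %||% NA,
                   parameters = config[setdiff(names(config),
                                               c("visits", "survival",
                                                 "covariates", "proteins"))],
                   input_hashes = hashes)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Run the derivation stage: recalibrate, fit, report
#'
#' Recalibrates baseline-visit echo measures to reference moments (when
#' `recalibrate` is configured), fits the trajectory mixture on the
#' longitudinal visits, and writes the model JSON, the effective-group
#' table, curve values on an age grid, and (when survival data are
#' supplied) composite HF-or-death Cox results with the largest group as
#' reference.
#'
#' @param config List (or YAML/JSON path) with `visits` (path or data
#'   frame), `out_dir`, `seed`, optional `recalibrate` (per measure:
#'   `mean`, `sd`), optional `k_max`, `restarts`, optional `survival`
#'   and `covariates` tables.
#' @return List with the fitted `model`, `effective` groups table and
#'   output paths, invisibly.
#' @export
run_derivation <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  visits <- load_table(config$visits,
                       c("participant_id", "visit", "age_years",
                         "lvef_pct", "ea_ratio"), "visits table")

  recal_log <- list()
  if (!is.null(config$recalibrate)) {
    for (ms in names(config$recalibrate)) {
      col <- c(lvef = "lvef_pct", ea = "ea_ratio")[[ms]]
      ref <- config$recalibrate[[ms]]
      base_rows <- visits$visit == 1
      map <- fit_recalibration(visits[[col]][base_rows], ref$mean, ref$sd,
                               measure = ms)
      visits[[col]][base_rows] <-
        apply_recalibration(map, visits[[col]][base_rows])
      recal_log[[ms]] <- list(slope = map$slope, intercept = map$intercept)
    }
    jsonlite::write_json(recal_log, file.path(out_dir, "recalibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  model <- fit_trajectories(
    visits, basis = config$basis %||% age_basis(),
    k_max = config$k_max %||% 20, restarts = config$restarts %||% 20,
    seed = config$seed %||% 1
  )
  model_path <- file.path(out_dir, "trajectory_model.json")
  write_trajectory_model(model, model_path)
  eff <- effective_groups(model, config$min_weight %||% 0.01)
  utils::write.table(eff, file.path(out_dir, "effective_groups.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  grid <- seq(55, 90, by = 0.5)
  utils::write.table(trajectory_curves(model, grid),
                     file.path(out_dir, "trajectory_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cox <- NULL
  if (!is.null(config$survival)) {
    surv <- load_table(config$survival,
                       c("participant_id", "time_years", "event"),
                       "survival table")
    assign <- assign_trajectories(model, visits)
    eff_map <- integer(model$k_max)
    eff_map[eff$internal_index] <- eff$label
    traj <- eff_map[assign$map_group[match(surv$participant_id,
                                           assign$participant_id)]]
    ds <- cause_specific_dataset(surv, "hf_or_death")
    covs <- if (!is.null(config$covariates)) {
      cv <- load_table(config$covariates, "participant_id", "covariate table")
      cv[match(surv$participant_id, cv$participant_id),
         setdiff(names(cv), "participant_id"), drop = FALSE]
    } else NULL
    if (sum(ds$status) > 0) {
      cox <- fit_cox(ds, factor(traj), reference = "1", covariates = covs)
      utils::write.table(cox$table,
                         file.path(out_dir, "derivation_cox.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  inputs <- unlist(Filter(is.character,
                          config[c("visits", "survival", "covariates")]))
  write_manifest(out_dir, "derivation", config, inputs)
  invisible(list(model = model, effective = eff, cox = cox,
                 model_path = model_path, out_dir = out_dir))
}

#' Run the testing stage: assign, survive, scan
#'
#' Assigns every participant to their most probable trajectory from
#' their (possibly single) visit, fits cause-specific Cox models for
#' any-HF, HFpEF and HFrEF with the largest effective group as
#' reference, and (when a protein matrix is supplied) runs the
#' proteome-wide multinomial scan. Stages with no usable data (e.g.
#' zero events) are skipped with an explicit log entry.
#'
#' @param config List (or YAML/JSON path) with `model` (path or fitted
#'   model), `visits`, optional `survival`, `covariates`, `proteins`
#'   (matrix), `out_dir`, `seed`.
#' @return List with `assignments`, `cox` (per endpoint), `scan`, and
#'   the run `log`, invisibly.
#' @export
run_testing <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (inherits(config$model, "trajectory_model")) config$model
    else read_trajectory_model(config$model)
  visits <- load_table(config$visits,
                       c("participant_id", "age_years", "lvef_pct",
                         "ea_ratio"), "visits table")
  log_lines <- character()

  assign <- assign_trajectories(model, visits)
  eff <- effective_groups(model, config$min_weight %||% 0.01)
  eff_map <- rep(NA_integer_, model$k_max)
  eff_map[eff$internal_index] <- eff$label
  assign$effective_label <- eff_map[assign$map_group]
  utils::write.table(assign, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_lines <- c(log_lines,
                 sprintf("assigned %d participants to %d effective groups",
                         nrow(assign), nrow(eff)))

  cox_results <- list()
  if (!is.null(config$survival)) {
    surv <- load_table(config$survival,
                       c("participant_id", "time_years", "event"),
                       "survival table")
    traj <- factor(assign$effective_label[match(surv$participant_id,
                                                assign$participant_id)])
    covs <- if (!is.null(config$covariates)) {
      cv <- load_table(config$covariates, "participant_id", "covariate table")
      cv[match(surv$participant_id, cv$participant_id),
         setdiff(names(cv), "participant_id"), drop = FALSE]
    } else NULL
    for (ep in c("any_hf", "hf_pef", "hf_ref")) {
      ds <- cause_specific_dataset(surv, ep)
      if (sum(ds$status) == 0) {
        log_lines <- c(log_lines,
                       sprintf("survival stage skipped for %s: zero events", ep))
        next
      }
      cox_results[[ep]] <- fit_cox(ds, traj, reference = "1",
                                   covariates = covs)
      utils::write.table(cox_results[[ep]]$table,
                         file.path(out_dir, sprintf("cox_%s.tsv", ep)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log_lines <- c(log_lines, sprintf("cox %s: %d events", ep,
                                        cox_results[[ep]]$n_events))
    }
  }

  scan <- NULL
  if (!is.null(config$proteins)) {
    prot <- scale_features(as.matrix(config$proteins))
    ids <- rownames(prot) %||% assign$participant_id
    labels <- assign$effective_label[match(ids, assign$participant_id)]
    covs <- NULL
    if (!is.null(config$covariates)) {
      cv <- load_table(config$covariates, "participant_id", "covariate table")
      cv <- cv[match(ids, cv$participant_id), , drop = FALSE]
      covs <- data.frame(age = drop(scale(cv$age_years)), male = cv$male)
    }
    scan <- protein_scan(prot, labels, covs, reference = "1")
    utils::write.table(scan, file.path(out_dir, "protein_scan.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_lines <- c(log_lines,
                   sprintf("protein scan: %d aptamers, %d converged",
                           ncol(prot),
                           as.integer(sum(scan$converged) /
                                        length(unique(scan$contrast)))))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  inputs <- unlist(Filter(is.character,
                          config[c("model", "visits", "survival",
                                   "covariates")]))
  write_manifest(out_dir, "testing", config, inputs)
  invisible(list(assignments = assign, cox = cox_results, scan = scan,
                 log = log_lines))
}
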