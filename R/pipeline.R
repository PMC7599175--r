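## End-to-end driver: simulate (optional) -> LD selection -> DDCRZ ->
## ensemble training -> two-step prediction -> metrics, with one config and
## one seed, writing every artifact to a run directory.

.config_defaults <- function() list(
  outcome = "motor",
  simulate = NULL,
  ld_threshold = 0.375,
  inner_size = NULL,          # 5 for motor, 4 for cognitive
  min_delayed = 3L,
  relaxation = 0.10,
  membership_fraction = 1.0,
  fit_zones = "per_fold",
  folds = 4L,
  nets_per_type = 100L,
  vote_threshold_final = 2L,
  n_hidden = NULL,
  max_epochs = 200L,
  decay = 5e-4,
  exclude_severe = FALSE,
  seed = 1L)

.simulate_defaults <- function(outcome) {
  if (outcome == "motor")
    list(n_subjects = 103L, prevalence = 0.126, planted_localised = integer(),
         dropout_rate = 0.007, severe_injury_rate = 2 / 7)
  else
    list(n_subjects = 115L, prevalence = 0.061, planted_localised = integer(),
         dropout_rate = 0.007, severe_injury_rate = 2 / 7)
}

#' Pipeline run configuration
#'
#' All stage parameters in one validated, JSON-serialisable object. Unknown
#' keys are rejected. `inner_size` defaults to 5 for the motor outcome and
#' 4 for the cognitive outcome.
#'
#' @param ... Any of: `outcome` ("motor"/"cognitive"), `simulate` (list of
#'   [cohort_spec()] fields, or `NULL` to require an input cohort),
#'   `ld_threshold`, `inner_size`, `min_delayed`, `relaxation`,
#'   `membership_fraction`, `fit_zones` ("per_fold"/"once"), `folds`,
#'   `nets_per_type`, `vote_threshold_final`, `n_hidden`, `max_epochs`,
#'   `decay`, `exclude_severe`, `seed`.
#' @return A `run_config` list with all effective values filled in.
#' @export
run_config <- function(...) {
  as_run_config(list(...))
}

#' @rdname run_config
#' @param x A named list of configuration values.
#' @export
as_run_config <- function(x) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (!cfg$outcome %in% c("motor", "cognitive"))
    stop("outcome must be 'motor' or 'cognitive'")
  if (!cfg$fit_zones %in% c("per_fold", "once"))
    stop("fit_zones must be 'per_fold' or 'once'")
  if (is.null(cfg$inner_size))
    cfg$inner_size <- if (cfg$outcome == "motor") 5L else 4L
  if (!is.null(cfg$simulate)) {
    sim <- utils::modifyList(.simulate_defaults(cfg$outcome),
                             as.list(cfg$simulate))
    known <- names(.simulate_defaults(cfg$outcome))
    bad <- setdiff(names(sim), known)
    if (length(bad))
      stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
    if (!is.null(sim$planted_localised) && length(sim$planted_localised))
      sim$planted_localised <- stats::setNames(
        as.integer(unlist(sim$planted_localised)),
        names(unlist(sim$planted_localised)))
    cfg$simulate <- sim
  }
  stopifnot(cfg$ld_threshold >= 0.125, cfg$ld_threshold <= 1,
            cfg$inner_size >= 1, cfg$relaxation >= 0,
            cfg$membership_fraction > 0, cfg$membership_fraction <= 1,
            cfg$folds >= 2, cfg$nets_per_type >= 1,
            cfg$vote_threshold_final >= 1,
            cfg$vote_threshold_final <= cfg$folds)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  as_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate) && length(cfg$simulate$planted_localised))
    cfg$simulate$planted_localised <-
      as.list(cfg$simulate$planted_localised)  # keep names as a JSON object
  jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full two-step prediction pipeline
#'
#' Executes simulate (when `config$simulate` is set and no `cohort` is
#' given) -> LD selection -> DDCRZ fitting -> ensemble training -> two-step
#' prediction -> evaluation, writing `cohort.csv`, `config.json`,
#' `selection.json`, `zones.json`, `model.json`, `predictions.csv`,
#' `metrics.json` and `run.log` into `out_dir`. Re-running with an
#' identical config reproduces `metrics.json` byte for byte.
#'
#' With `fit_zones = "per_fold"` (the default, leak-free protocol) the
#' analysis subjects are first split into stratified folds; the zones
#' routing a fold-`k` subject are built from the other folds, and network
#' type `k` trains on the members of its own folds-not-`k` zone fit. With
#' `fit_zones = "once"` a single zone set built on all analysis subjects
#' both routes subjects and delimits the training members.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional cohort table or CSV path; required when
#'   `config$simulate` is `NULL`.
#' @return Invisibly, a list with the cohort, selection, zones, ensemble,
#'   predictions and metrics.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  tab <- stage("simulate", {
    if (is.null(cohort)) {
      if (is.null(config$simulate))
        stop("no cohort given and config$simulate is NULL")
      sim <- config$simulate
      spec <- cohort_spec(sim$n_subjects, sim$prevalence,
                          planted_localised = sim$planted_localised %||% integer(),
                          dropout_rate = sim$dropout_rate,
                          severe_injury_rate = sim$severe_injury_rate,
                          seed = seeds[1])
      generate_cohort(spec, default_class_distribution(config$outcome))
    } else if (is.character(cohort)) read_cohort(cohort) else {
      validate_cohort(cohort)
    }
  })
  write_cohort(tab, file.path(out_dir, "cohort.csv"))
  write_run_config(config, file.path(out_dir, "config.json"))

  if (config$exclude_severe) tab <- tab[tab$severe_injury == 0L, ]

  selection <- stage("select", select_characteristics(
    tab, ld_threshold = config$ld_threshold,
    inner_size = config$inner_size, min_delayed = config$min_delayed))
  write_selection(selection, file.path(out_dir, "selection.json"))

  ## analysis set: subjects complete on every selected characteristic;
  ## the rest are excluded, mirroring the missing-peak exclusions
  incomplete <- is_incomplete(tab, selection$selected)
  analysis <- tab[!incomplete, , drop = FALSE]
  if (!nrow(analysis)) stop("stage 'zones' failed: no complete subjects")

  set.seed(seeds[2])
  fold <- stratified_folds(analysis$label, config$folds)

  zres <- stage("zones", {
    if (config$fit_zones == "once") {
      z <- build_ddcrz(analysis, selection, config$relaxation,
                       config$membership_fraction)
      membership <- zone_membership_table(analysis, z)
      mask <- matrix(membership == "member", nrow(analysis), config$folds)
      list(zone_sets = list(z), membership = membership, mask = mask)
    } else {
      zone_sets <- lapply(seq_len(config$folds), function(k)
        build_ddcrz(analysis[fold != k, , drop = FALSE], selection,
                    config$relaxation, config$membership_fraction))
      per_fold <- vapply(seq_len(config$folds), function(k)
        zone_membership_table(analysis, zone_sets[[k]]),
        character(nrow(analysis)))
      membership <- per_fold[cbind(seq_len(nrow(analysis)), fold)]
      mask <- per_fold == "member"
      list(zone_sets = zone_sets, membership = membership, mask = mask)
    }
  })
  write_zones(zres$zone_sets, config, file.path(out_dir, "zones.json"))

  is_member <- zres$membership == "member"
  if (sum(is_member) < 8L || sum(analysis$label[is_member]) < 4L)
    stop("stage 'train' failed: need at least 8 DDCRZ members including ",
         "at least 4 delayed (have ", sum(is_member), " members, ",
         sum(analysis$label[is_member]), " delayed)")

  spec <- fnn_spec(n_hidden = config$n_hidden, max_epochs = config$max_epochs,
                   decay = config$decay)
  ensemble <- stage("train", train_ensemble(
    analysis, selection, spec, seed = seeds[3], n_folds = config$folds,
    nets_per_type = config$nets_per_type,
    vote_threshold_final = config$vote_threshold_final,
    fold_assignment = fold, train_member_mask = zres$mask))
  write_model(ensemble, file.path(out_dir, "model.json"))

  preds <- stage("predict", {
    prediction <- rep("normal", nrow(analysis))
    rec <- NULL
    if (any(is_member)) {
      rec <- predict(ensemble, analysis[is_member, , drop = FALSE],
                     type = "record")
      prediction[is_member] <- ifelse(rec$final == 1L, "delayed", "normal")
    }
    out <- data.frame(subject_id = analysis$subject_id,
                      label = analysis$label, fold = fold,
                      step1_membership = zres$membership,
                      prediction = prediction, stringsAsFactors = FALSE)
    vote_cols <- c(paste0("count_", seq_len(config$folds)),
                   paste0("vote_", seq_len(config$folds)), "final")
    for (cl in vote_cols) out[[cl]] <- NA_integer_
    if (!is.null(rec)) out[is_member, vote_cols] <- rec[, vote_cols]
    if (any(incomplete)) {
      exc <- data.frame(subject_id = tab$subject_id[incomplete],
                        label = tab$label[incomplete], fold = NA_integer_,
                        step1_membership = "incomplete",
                        prediction = "excluded_incomplete",
                        stringsAsFactors = FALSE)
      for (cl in vote_cols) exc[[cl]] <- NA_integer_
      out <- rbind(out, exc)
    }
    out
  })
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  metrics <- stage("evaluate", {
    keep <- preds$prediction != "excluded_incomplete"
    ev <- evaluate_two_step(preds$prediction[keep], preds$label[keep],
                            preds$step1_membership[keep])
    ev$n_excluded <- sum(!keep)
    ev
  })
  write_metrics(metrics, config, file.path(out_dir, "metrics.json"))
  write_run_log(config, metrics, out_dir)

  invisible(list(cohort = tab, selection = selection,
                 zones = zres$zone_sets, membership = zres$membership,
                 fold = fold, ensemble = ensemble, predictions = preds,
                 metrics = metrics))
}

write_selection <- function(selection, path) {
  jsonlite::write_json(list(
    ld_threshold = selection$ld_threshold,
    inner_size = selection$inner_size,
    selected = selection$selected,
    inner_subset = selection$inner_subset,
    profiles = selection$profiles), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

write_zones <- function(zone_sets, config, path) {
  jsonlite::write_json(list(
    fit_zones = config$fit_zones,
    relaxation = zone_sets[[1]]$relaxation,
    membership_fraction = zone_sets[[1]]$membership_fraction,
    zone_sets = lapply(zone_sets, `[[`, "zones")), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

write_model <- function(ensemble, path) {
  jsonlite::write_json(list(
    inner_subset = ensemble$inner_subset,
    n_hidden = ensemble$n_hidden,
    n_folds = ensemble$n_folds,
    nets_per_type = ensemble$nets_per_type,
    vote_threshold_final = ensemble$vote_threshold_final,
    fold_assignment = stats::setNames(as.list(ensemble$fold_assignment),
                                      ensemble$subject_id),
    types = lapply(ensemble$types, function(ty) list(
      center = ty$center, scale = ty$scale,
      n_train = ty$n_train, n_train_delayed = ty$n_train_delayed,
      weights = lapply(ty$nets, `[[`, "wts")))), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

metrics_json <- function(rep) {
  list(counts = rep$counts[c("tp", "fp", "tn", "fn")],
       sensitivity_pct = as_percent(rep$sensitivity),
       specificity_pct = as_percent(rep$specificity),
       ppv_pct = as_percent(rep$ppv),
       npv_pct = as_percent(rep$npv))
}

write_metrics <- function(metrics, config, path) {
  jsonlite::write_json(list(
    outcome = config$outcome, seed = config$seed,
    n_excluded_incomplete = metrics$n_excluded,
    in_zone = metrics_json(metrics$in_zone),
    whole_dataset = metrics_json(metrics$whole_dataset)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

write_run_log <- function(config, metrics, out_dir) {
  cfg_path <- file.path(out_dir, "config.json")
  hash <- unname(tools::md5sum(cfg_path))
  lines <- c(
    paste0("neoprog ", as.character(utils::packageVersion("neoprog"))),
    paste0("config md5: ", hash),
    "effective parameters:",
    paste0("  ", names(unclass(config)), " = ",
           vapply(unclass(config), function(v)
             paste(utils::capture.output(utils::str(v, give.head = FALSE)),
                   collapse = " "), "")),
    sprintf("whole-dataset counts: TP %d FP %d TN %d FN %d",
            metrics$whole_dataset$counts$tp, metrics$whole_dataset$counts$fp,
            metrics$whole_dataset$counts$tn, metrics$whole_dataset$counts$fn))
  writeLines(lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}
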