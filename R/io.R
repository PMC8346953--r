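#' Write and read trial tables
#'
#' Trials travel as UTF-8 comma-separated text with a header, `.` decimal
#' separator and ml quantities serialized to 6 decimal places, one row per
#' trial: `session_id, day_index, distribution, left_m1, left_p1, left_m2,
#' left_p2, right_m1, right_p1, right_m2, right_p2, chosen, sequence_tag`
#' (safe options leave `m2`/`p2` empty).
#'
#' `read_trials()` validates the schema and the option fields; malformed
#' rows are reported with their row numbers.
#'
#' @param trials trial data frame.
#' @param path file path.
#' @return `read_trials()` the validated data frame (a warning and an empty
#'   frame for a header-only file); `write_trials()` the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, trial_columns(), drop = FALSE]
  num <- grep("_(m|p)[12]$", names(out))
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "",
                                                  sprintf("%.6f", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  # suppressWarnings: colClasses naming a column absent from a malformed
  # file warns before our own schema error below
  raw <- suppressWarnings(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(session_id = "character",
                                   distribution = "character",
                                   chosen = "character",
                                   sequence_tag = "character")))
  missing_cols <- setdiff(trial_columns(), names(raw))
  if (length(missing_cols)) {
    stop("trial file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, trial_columns(), drop = FALSE]
  if (nrow(raw) == 0) {
    warning("trial file contains a header but no trials")
    return(raw)
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(rows, collapse = ", "), ")"))
    }
  }
  note(which(!raw$chosen %in% c("left", "right")),
       "chosen must be 'left' or 'right'")
  for (side in c("left", "right")) {
    p1 <- raw[[paste0(side, "_p1")]]
    p2 <- raw[[paste0(side, "_p2")]]
    m1 <- raw[[paste0(side, "_m1")]]
    is_safe <- is.na(p2)
    note(which(is_safe & abs(p1 - 1) > 1e-6),
         paste0(side, " safe option must have p1 = 1"))
    note(which(!is_safe & abs(p1 + p2 - 1) > 1e-6),
         paste0(side, " probabilities must sum to 1"))
    note(which(is.na(m1) | m1 < 0), paste0(side, "_m1 must be >= 0"))
  }
  if (length(problems)) {
    stop("invalid trial file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  raw
}

#' Read a pipeline configuration from YAML
#'
#' The configuration has two blocks: `agent` (`family`, `params`, `lambda`,
#' `theta`, `adaptation_mode`, optional `adapt_weight`, `reference`,
#' `seed`) and `schedule` (`blocks`: list of `distribution`/`n_days`
#' pairs), plus optional `fitting` (`families`, `n_starts`, `k_folds`) and
#' `validation` (`enabled`) blocks.
#'
#' @param path YAML file path.
#' @return the configuration list, checked for required fields.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$agent) || is.null(cfg$schedule)) {
    stop("config needs 'agent' and 'schedule' blocks", call. = FALSE)
  }
  if (!cfg$agent$family %in% utility_families()) {
    stop("unknown utility family '", cfg$agent$family, "'", call. = FALSE)
  }
  if (is.null(cfg$agent$seed)) stop("agent seed must be explicit",
                                    call. = FALSE)
  if (is.null(cfg$schedule$blocks) || !length(cfg$schedule$blocks)) {
    stop("schedule needs at least one block", call. = FALSE)
  }
  fams <- cfg$fitting$families
  if (!is.null(fams) && !all(fams %in% utility_families())) {
    stop("unknown fitting family: ",
         paste(setdiff(fams, utility_families()), collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Ties the stages together: simulate daily fractile (and optional
#' validation) sessions per the schedule; extract certainty equivalents
#' with the fractile bookkeeping; fit the configured utility families per
#' day by maximum likelihood; select the family with the lowest median BIC;
#' build the adaptation report (median curves, inflections, curvature
#' ratios, SAC/GAC); and fit the out-of-sample risk regression.  Every
#' stage's table is written under `out_dir` (`trials.csv`, `cepoints.csv`,
#' `fits.jsonl`, `adaptation.json`, `validation.csv`, `report.md`), each
#' output stamped with the driving seed; the run is deterministic given the
#' configuration.
#'
#' @param config configuration list (see [read_pipeline_config()]).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return list with the in-memory results: `trials`, `cepoints`, `fits`,
#'   `selected_family`, `report` ([adaptation_report()]), `validation`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- validate_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(cfg$agent$seed)

  schedule <- build_schedule(cfg$schedule$blocks)
  dists <- attr(schedule, "distributions")
  ref <- if (!is.null(cfg$agent$reference)) {
    reward_distribution(cfg$agent$reference)
  } else dists[[1]]
  agent <- agent_config(
    utility_curve(cfg$agent$family, unlist(cfg$agent$params)),
    lambda = cfg$agent$lambda,
    theta = if (is.null(cfg$agent$theta)) 0 else cfg$agent$theta,
    adaptation_mode = if (is.null(cfg$agent$adaptation_mode)) "full"
                      else cfg$agent$adaptation_mode,
    reference = ref,
    adapt_weight = cfg$agent$adapt_weight,
    seed = seed)

  run_validation <- isTRUE(cfg$validation$enabled)
  say("simulating %d days", nrow(schedule))
  trials <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
    d <- dists[[schedule$distribution[i]]]
    day <- schedule$day_index[i]
    tr <- generate_fractile_session(agent, d, day_index = day)
    if (run_validation) {
      tr <- rbind(tr, generate_validation_session(agent, d, day_index = day))
    }
    tr
  }))

  say("extracting certainty equivalents")
  cepoints <- do.call(rbind, lapply(split(trials, trials$session_id),
    function(sess) {
      if (!any(grepl("^fractile", sess$sequence_tag))) return(NULL)
      run_fractile(sess[grepl("^fractile", sess$sequence_tag), , drop = FALSE],
                   dists[[sess$distribution[1]]])
    }))

  families <- if (!is.null(cfg$fitting$families)) cfg$fitting$families
              else utility_families()
  n_starts <- if (!is.null(cfg$fitting$n_starts)) cfg$fitting$n_starts else 5
  say("fitting %d families x %d days", length(families), nrow(schedule))
  fits <- list()
  for (i in seq_len(nrow(schedule))) {
    day <- schedule$day_index[i]
    lab <- schedule$distribution[i]
    sess <- trials[trials$day_index == day &
                     grepl("^fractile", trials$sequence_tag), , drop = FALSE]
    for (fam in families) {
      fit <- tryCatch(
        fit_dcm(sess, fam, dists[[lab]], n_starts = n_starts,
                seed = session_seed(seed, day, salt = 4L)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        fit$day_index <- day
        fits[[length(fits) + 1]] <- fit
      }
    }
  }
  fit_fam <- vapply(fits, function(f) f$family, character(1))
  med_bic <- vapply(families, function(fam)
    stats::median(vapply(fits[fit_fam == fam], function(f) f$bic,
                         numeric(1))), numeric(1))
  selected <- families[which.min(med_bic)]
  say("selected family by median BIC: %s", selected)

  sel_fits <- fits[fit_fam == selected]
  sel_dist <- vapply(sel_fits, function(f) f$distribution, character(1))
  if (length(sel_fits) >= 3) {
    keep <- flag_outliers(sel_fits)$keep
    sel_fits <- sel_fits[keep]; sel_dist <- sel_dist[keep]
  }
  order_labels <- unique(schedule$distribution)
  fits_by_dist <- lapply(order_labels, function(lab)
    sel_fits[sel_dist == lab])
  names(fits_by_dist) <- order_labels
  fits_by_dist <- fits_by_dist[vapply(fits_by_dist, length, integer(1)) > 0]
  full_label <- if ("full" %in% names(fits_by_dist)) "full"
                else if ("full_alt" %in% names(fits_by_dist)) "full_alt"
                else NULL
  report <- adaptation_report(fits_by_dist, dists, full_label = full_label)

  validation <- NULL
  if (run_validation) {
    validation <- do.call(rbind, lapply(names(fits_by_dist), function(lab) {
      vt <- trials[trials$distribution == lab &
                     trials$sequence_tag == "validation", , drop = FALSE]
      if (!nrow(vt)) return(NULL)
      ces <- tryCatch(measure_validation_ces(vt, dists[[lab]]),
                      error = function(e) NULL)
      if (is.null(ces)) return(NULL)
      infl <- report$metrics$inflection_ml[report$metrics$distribution == lab]
      reg <- if (!is.na(infl)) tryCatch(fit_risk_regression(ces, infl),
                                        error = function(e) NULL) else NULL
      cbind(distribution = lab, ces,
            ev_minus_inflection_ml = ces$ev_ml - infl,
            beta0 = if (is.null(reg)) NA_real_ else reg$beta0,
            beta1 = if (is.null(reg)) NA_real_ else reg$beta1)
    }))
  }

  result <- list(trials = trials, cepoints = cepoints, fits = fits,
                 selected_family = selected, report = report,
                 validation = validation, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, cfg, out_dir)
  result
}

write_pipeline_outputs <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("seed %d", result$seed)
  write_trials(result$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(result$cepoints, file.path(out_dir, "cepoints.csv"),
                   row.names = FALSE)
  con <- file(file.path(out_dir, "fits.jsonl"), "w")
  for (f in result$fits) {
    writeLines(jsonlite::toJSON(list(
      day_index = f$day_index, distribution = f$distribution,
      family = f$family, params = as.list(f$utility$params),
      lambda = f$lambda, theta = f$theta, neg_ll = f$neg_ll,
      n_trials = f$n_trials, k = f$k, bic = f$bic,
      converged = f$converged, seed = result$seed),
      auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  rep <- result$report
  jsonlite::write_json(list(
    seed = result$seed, selected_family = result$selected_family,
    metrics = rep$metrics, sac = rep$sac, gac = rep$gac,
    predicted_inflections = rep$predicted_inflections),
    file.path(out_dir, "adaptation.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (!is.null(result$validation)) {
    utils::write.csv(result$validation,
                     file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  lines <- c(
    "# Utility-adaptation pipeline report", "",
    paste0("Run stamp: ", stamp), "",
    paste0("Selected family (lowest median BIC): **",
           result$selected_family, "**"), "",
    "## Per-distribution shape metrics", "",
    utils::capture.output(print(rep$metrics)), "")
  if (!is.null(rep$sac)) {
    lines <- c(lines, "## Sequential adaptation coefficients", "",
               utils::capture.output(print(rep$sac)), "")
  }
  if (!is.null(rep$gac)) {
    lines <- c(lines, "## General adaptation coefficients", "",
               utils::capture.output(print(rep$gac)), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
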