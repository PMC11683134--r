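#' Assemble a run configuration
#'
#' A run configuration lists the samples of an experiment with their roles
#' and the analysis options. Each sample entry names either a file `path`
#' (FCS or CSV) or an in-memory `table` ([event_table()]), plus:
#' `mito_status` (`"rho_plus"`/`"rho_zero"`), `condition`
#' (`"control_25C"`/`"arrested_37C"`), `arrest_ploidy` (`"1n"`, `"2n"`, or
#' `"none"` for a non-CDC control sample) and `replicate_id`. Every
#' replicate that contains an arrested sample must contain all four members
#' of the arrest contrast (rho+/rho0 at 25 and 37 degC).
#'
#' @param samples List of sample entries as above.
#' @param genome [genome_params()].
#' @param options Named list of analysis options; recognised:
#'   `bandwidth` (NULL = Silverman), `gate_width` (0.5), `bin_width` (0.1),
#'   `min_events` (200), `scaling_halfwidth` (0.25), `surplus_method`
#'   (`"background_partition"`).
#' @param seed Optional integer seed recorded in the report.
#' @return A `run_config`.
#' @export
run_config <- function(samples, genome = genome_params(), options = list(),
                       seed = NULL) {
  defaults <- list(bandwidth = NULL, gate_width = 0.5, bin_width = 0.1,
                   min_events = 200L, scaling_halfwidth = 0.25,
                   surplus_method = "background_partition")
  options <- utils::modifyList(defaults, options)
  cfg <- structure(list(samples = samples, genome = genome, options = options,
                        seed = seed),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: a `samples` list (each with `path`,
#' `mito_status`, `condition`, `arrest_ploidy`, `replicate_id` and optional
#' `fluor_channel`/`fsc_channel`/`format`), an optional `genome` block with
#' [genome_params()] fields, an `options` block, and a `seed`.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  genome <- do.call(genome_params, y$genome %||% list())
  run_config(y$samples, genome = genome, options = y$options %||% list(),
             seed = y$seed)
}

validate_run_config <- function(cfg) {
  req <- c("mito_status", "condition", "replicate_id")
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    missing <- setdiff(req, names(s))
    if (length(missing) || (is.null(s$path) && is.null(s$table))) {
      stop_cytomito(sprintf("sample %d is missing: %s", i,
                            paste(c(missing,
                                    if (is.null(s$path) && is.null(s$table)) "path/table"),
                                  collapse = ", ")),
                    "cytomito_config_error")
    }
    if (!s$mito_status %in% c("rho_plus", "rho_zero") ||
        !s$condition %in% c("control_25C", "arrested_37C")) {
      stop_cytomito(sprintf("sample %d has an unknown mito_status/condition", i),
                    "cytomito_config_error")
    }
  }
  roles <- data.frame(
    mito = vapply(cfg$samples, `[[`, "", "mito_status"),
    cond = vapply(cfg$samples, `[[`, "", "condition"),
    rep = vapply(cfg$samples, function(s) as.character(s$replicate_id), "")
  )
  for (r in unique(roles$rep)) {
    sub <- roles[roles$rep == r, ]
    if (any(sub$cond == "arrested_37C")) {
      need <- expand.grid(mito = c("rho_plus", "rho_zero"),
                          cond = c("control_25C", "arrested_37C"),
                          stringsAsFactors = FALSE)
      have <- paste(sub$mito, sub$cond)
      miss <- need[!paste(need$mito, need$cond) %in% have, ]
      if (nrow(miss)) {
        stop_cytomito(
          sprintf("replicate '%s' has an arrest contrast but is missing: %s", r,
                  paste(sprintf("%s/%s", miss$mito, miss$cond), collapse = ", ")),
          "cytomito_config_error")
      }
    } else if (!all(c("rho_plus", "rho_zero") %in% sub$mito)) {
      stop_cytomito(sprintf("replicate '%s' needs both rho_plus and rho_zero samples", r),
                    "cytomito_config_error")
    }
  }
  invisible(cfg)
}

load_sample <- function(s) {
  t <- if (!is.null(s$table)) s$table
       else read_events(s$path,
                        fluor_channel = s$fluor_channel %||% "FITC-A",
                        fsc_channel = s$fsc_channel %||% "FSC-A",
                        format = s$format %||% "auto")
  log2_transform(t)
}

with_stage <- function(stage, sample_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_cytomito(sprintf("stage '%s' failed for sample '%s': %s",
                          stage, sample_id, conditionMessage(e)),
                  "cytomito_pipeline_error",
                  data = list(stage = stage, sample_id = sample_id, parent = e))
  })
}

pipeline_log <- function(stage, sample, ...) {
  message(sprintf("[cytomito] stage=%s sample=%s %s", stage, sample,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

sample_key <- function(s) paste(s$mito_status, s$condition, sep = ".")

#' Run the full analysis pipeline
#'
#' Executes, per replicate: event loading, log2 transform, density-mode
#' detection, the rho+/rho0 copy-number contrast at 25 degC, the arrest
#' contrast (surplus and fold change) when arrested samples are present, the
#' fluorescence-size regression on arrested samples, and the size-binned CV
#' profiles of the rho+ control/arrested pair. Replicate estimates are
#' aggregated as mean and SD. When `output_dir` is given, a JSON report and
#' per-analysis CSVs are written; re-running with the same configuration and
#' seed reproduces them byte for byte.
#'
#' @param config A [run_config()] (or a YAML path, passed through
#'   [read_run_config()]).
#' @param output_dir Optional directory for the JSON report and CSV outputs.
#' @param quiet Suppress per-stage log lines (default FALSE).
#' @return A `run_report` list: `replicates` (per-replicate modes, shifts and
#'   fits), `copies` (aggregated `copy_number_estimate`), `arrest`
#'   (aggregated `arrest_result` or NULL), `scaling`, `cv`, `config_summary`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  opt <- config$options
  log_fn <- if (quiet) function(...) invisible() else pipeline_log

  reps <- split(config$samples,
                vapply(config$samples, function(s) as.character(s$replicate_id), ""))
  has_arrest <- any(vapply(config$samples, function(s)
    s$condition == "arrested_37C", logical(1)))
  arrest_ploidy <- if (has_arrest) {
    ap <- unique(unlist(lapply(config$samples, function(s)
      if (!is.null(s$arrest_ploidy) && s$arrest_ploidy != "none") s$arrest_ploidy)))
    if (length(ap) != 1) {
      stop_cytomito("arrested samples must agree on one arrest_ploidy",
                    "cytomito_config_error")
    }
    ap
  } else NA_character_

  if (length(reps) >= 1 && length(reps) < 3) {
    warning(sprintf("only %d replicate(s); estimates are conventionally reported over at least three",
                    length(reps)), call. = FALSE)
  }

  rep_results <- lapply(names(reps), function(rid) {
    entries <- reps[[rid]]
    keyed <- setNames(entries, vapply(entries, sample_key, ""))
    tables <- lapply(keyed, function(s) {
      sid <- s$sample_id %||% sample_key(s)
      t <- with_stage("read", sid, load_sample(s))
      log_fn("read", sid, n_events = nrow(t), dropped = attr(t, "dropped_count"))
      t
    })
    peaks <- lapply(names(tables), function(k) {
      s <- keyed[[k]]
      expected <- if (s$condition == "arrested_37C" && has_arrest) arrest_ploidy
                  else "2n"
      p <- with_stage("modes", k, find_peak_modes(
        estimate_density(tables[[k]]$fluor_log2, bandwidth = opt$bandwidth),
        expected_ploidy = expected))
      log_fn("modes", k, mode_1n = sprintf("%.3f", p$mode_1n),
             mode_2n = sprintf("%.3f", p$mode_2n))
      p
    })
    names(peaks) <- names(tables)
    mode_of <- function(key, ploidy) {
      p <- peaks[[key]]
      if (is.null(p)) return(NA_real_)
      if (ploidy == "1n") p$mode_1n else p$mode_2n
    }

    out <- list(replicate_id = rid, peaks = peaks)
    # rho contrast at control temperature, 2n peak
    d_rho <- mode_of("rho_plus.control_25C", "2n") -
      mode_of("rho_zero.control_25C", "2n")
    out$delta_rho_2n <- d_rho
    if (has_arrest) {
      out$delta_arrest_plus <- mode_of("rho_plus.arrested_37C", arrest_ploidy) -
        mode_of("rho_plus.control_25C", arrest_ploidy)
      out$delta_arrest_zero <- mode_of("rho_zero.arrested_37C", arrest_ploidy) -
        mode_of("rho_zero.control_25C", arrest_ploidy)
      # fluorescence-size scaling on arrested samples at the arrested peak
      fits <- lapply(c(plus = "rho_plus.arrested_37C", zero = "rho_zero.arrested_37C"),
                     function(k) {
        with_stage("scaling", k, fit_size_scaling(
          gate_ploidy(tables[[k]], peaks[[k]], ploidy = arrest_ploidy,
                      halfwidth = opt$scaling_halfwidth)))
      })
      out$scaling <- compare_scaling(fits$plus, fits$zero)
      log_fn("scaling", rid, slope_plus = sprintf("%.3f", fits$plus$slope),
             slope_zero = sprintf("%.3f", fits$zero$slope))
    }
    # size-binned CV of the rho+ samples, right of the 2n peak
    cv_keys <- c(control = "rho_plus.control_25C",
                 arrested = if (has_arrest) "rho_plus.arrested_37C")
    out$cv <- lapply(cv_keys, function(k) {
      if (is.na(peaks[[k]]$mode_2n)) return(NULL)
      prof <- with_stage("cv", k, compute_binned_cv(
        gate_right_of_2n(tables[[k]], peaks[[k]], width = opt$gate_width),
        bin_width = opt$bin_width, min_events = opt$min_events))
      log_fn("cv", k, bins = nrow(prof$bins),
             population_cv = sprintf("%.4f", prof$population_cv))
      prof
    })
    if (!is.null(out$cv$control) && !is.null(out$cv$arrested)) {
      out$cv_comparison <- tryCatch(
        compare_cv_profiles(out$cv$arrested, out$cv$control),
        cytomito_comparison_error = function(e) NULL)
    }
    out
  })
  names(rep_results) <- names(reps)

  deltas <- vapply(rep_results, `[[`, numeric(1), "delta_rho_2n")
  deltas <- deltas[is.finite(deltas)]
  copies <- if (length(deltas)) {
    copies_from_rho_contrast(mode_shift(deltas, "2n", "rho_contrast"),
                             config$genome)
  } else NULL

  arrest <- NULL
  if (has_arrest && !is.null(copies)) {
    dp <- vapply(rep_results, `[[`, numeric(1), "delta_arrest_plus")
    dz <- vapply(rep_results, `[[`, numeric(1), "delta_arrest_zero")
    ok <- is.finite(dp) & is.finite(dz)
    if (any(ok)) {
      arrest <- arrest_surplus(
        mode_shift(dp[ok], arrest_ploidy, "arrest_contrast"),
        mode_shift(dz[ok], arrest_ploidy, "arrest_contrast"),
        baseline = copies, genome = config$genome,
        method = opt$surplus_method)
    }
  }

  report <- structure(list(replicates = rep_results, copies = copies,
                           arrest = arrest,
                           n_replicates = length(rep_results),
                           arrest_ploidy = arrest_ploidy,
                           options = opt, seed = config$seed),
                      class = "run_report")
  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d replicate(s)\n", x$n_replicates))
  if (!is.null(x$copies)) print(x$copies)
  if (!is.null(x$arrest)) print(x$arrest)
  invisible(x)
}

report_to_list <- function(report) {
  num <- function(v) if (is.null(v)) NULL else round(unname(v), 6)
  peaks_list <- function(p) list(mode_1n = num(p$mode_1n), mode_2n = num(p$mode_2n),
                                 n_modes_found = p$n_modes_found,
                                 bandwidth = num(p$bandwidth))
  list(
    n_replicates = report$n_replicates,
    arrest_ploidy = report$arrest_ploidy,
    seed = report$seed,
    copies = if (!is.null(report$copies)) list(
      copies = num(report$copies$copies), copies_sd = num(report$copies$copies_sd),
      per_replicate = num(report$copies$per_replicate),
      ploidy = report$copies$ploidy),
    arrest = if (!is.null(report$arrest)) list(
      surplus_copies = num(report$arrest$surplus_copies),
      surplus_sd = num(report$arrest$surplus_sd),
      fold_change = num(report$arrest$fold_change),
      baseline_copies = num(report$arrest$baseline_copies),
      delta_rho_plus = num(report$arrest$delta_rho_plus),
      delta_rho_zero = num(report$arrest$delta_rho_zero),
      method = report$arrest$method),
    replicates = lapply(report$replicates, function(r) list(
      replicate_id = r$replicate_id,
      delta_rho_2n = num(r$delta_rho_2n),
      delta_arrest_plus = num(r$delta_arrest_plus),
      delta_arrest_zero = num(r$delta_arrest_zero),
      peaks = lapply(r$peaks, peaks_list),
      scaling = if (!is.null(r$scaling)) list(
        slope_plus = num(r$scaling$fit_rho_plus$slope),
        slope_zero = num(r$scaling$fit_rho_zero$slope),
        slope_ratio = num(r$scaling$slope_ratio),
        slope_diff = num(r$scaling$slope_diff),
        plus_at_least_twice = r$scaling$plus_at_least_twice)))
  )
}

write_run_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  per_rep <- do.call(rbind, lapply(report$replicates, function(r) {
    data.frame(replicate_id = r$replicate_id,
               delta_rho_2n = r$delta_rho_2n %||% NA_real_,
               delta_arrest_plus = r$delta_arrest_plus %||% NA_real_,
               delta_arrest_zero = r$delta_arrest_zero %||% NA_real_)
  }))
  write.csv(per_rep, file.path(output_dir, "replicates.csv"), row.names = FALSE)
  for (rid in names(report$replicates)) {
    cvs <- report$replicates[[rid]]$cv
    for (k in names(cvs)) {
      if (!is.null(cvs[[k]])) {
        write_cv_profile_csv(cvs[[k]],
          file.path(output_dir, sprintf("cv_%s_%s.csv", rid, k)))
      }
    }
  }
  invisible(output_dir)
}
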