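timecourse_cols <- c("condition", "replicate", "metabolite", "n_carbons",
                     "mass_shift", "time_s", "value", "value_type")

#' Read a long-format isotopologue time-course table
#'
#' Expects a UTF-8 CSV with header and columns `condition`, `replicate`,
#' `metabolite`, `n_carbons`, `mass_shift`, `time_s`, `value`,
#' `value_type` (`"intensity"` or `"fraction"`), '.' decimal separator.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_timecourse <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(timecourse_cols, names(tab))
  if (length(missing)) {
    stop("time-course CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$value_type %in% c("intensity", "fraction"))) {
    stop("value_type must be 'intensity' or 'fraction'", call. = FALSE)
  }
  if (any(tab$time_s < 0)) stop("negative time_s in table", call. = FALSE)
  tab
}

#' Write a long-format time-course table
#'
#' @param table Data frame with the time-course columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(table, path) {
  utils::write.csv(table[, timecourse_cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalise and (optionally) natural-abundance-correct a time-course table
#'
#' Converts every per-sample isotopologue vector (one condition, replicate,
#' metabolite, time point) to fractions: intensity rows are normalised with
#' [normalize_to_mid()]; with `correct = TRUE` each MID is then corrected
#' for natural 13C abundance via [correct_mid()]. Whether correction was
#' applied is recorded in `attr(, "corrected")`.
#'
#' @param table Long-format table (intensities and/or fractions).
#' @param correct Apply natural-abundance correction (default `TRUE`).
#' @param p13C Natural 13C abundance used for the correction matrices.
#' @return A table of fractions with the same key columns.
#' @export
preprocess_timecourse <- function(table, correct = TRUE, p13C = 0.0107) {
  stopifnot(is.data.frame(table),
            all(timecourse_cols %in% names(table)))
  keys <- interaction(table$condition, table$replicate, table$metabolite,
                      table$time_s, drop = TRUE)
  mats <- if (correct) {
    ncs <- unique(table$n_carbons)
    stats::setNames(lapply(ncs, natural_abundance_matrix, p13C = p13C),
                    as.character(ncs))
  } else NULL
  pieces <- lapply(split(table, keys), function(g) {
    g <- g[order(g$mass_shift), , drop = FALSE]
    nc <- g$n_carbons[1]
    if (nrow(g) != nc + 1L || !identical(g$mass_shift, 0:nc)) {
      stop("sample ", g$condition[1], "/", g$metabolite[1], "/t=",
           g$time_s[1], " rep ", g$replicate[1],
           " lacks a full m0..m", nc, " vector", call. = FALSE)
    }
    m <- if (g$value_type[1] == "intensity") {
      normalize_to_mid(g$value, paste0(g$condition[1], "/", g$metabolite[1],
                                       "/t=", g$time_s[1]))
    } else {
      mid(g$value / sum(g$value), metabolite_id = g$metabolite[1],
          n_carbons = nc)
    }
    if (correct) m <- correct_mid(m, mats[[as.character(nc)]])
    g$value <- as.numeric(m$fractions)
    g$value_type <- "fraction"
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$condition, out$metabolite, out$time_s,
                   out$replicate, out$mass_shift), ]
  rownames(out) <- NULL
  attr(out, "corrected") <- correct
  out
}

#' Steady-state enrichment quality control
#'
#' Checks that all conditions reached the same isotopic steady-state
#' enrichment of a reference metabolite (default G6P) at the final time
#' point — the precondition for comparing labelled-Ru5P dilution rates
#' across treatments without correcting for enrichment bias. Computes the
#' replicate-mean [mean_enrichment()] per condition and flags conditions
#' whose mean differs from control by more than `threshold` (absolute).
#'
#' @param table Long-format fraction table.
#' @param reference Reference metabolite (default `"G6P"`).
#' @param control Control condition label.
#' @param threshold Absolute enrichment-difference flag threshold
#'   (default 0.05).
#' @return A data.frame of class `"steady_state_qc"` with columns
#'   `condition`, `enrichment`, `sd`, `diff_vs_control`, `flagged`.
#' @export
qc_steady_state <- function(table, reference = "G6P", control = "siCon",
                            threshold = 0.05) {
  stopifnot(is.data.frame(table))
  t_final <- max(table$time_s)
  sub <- table[table$metabolite == reference & table$time_s == t_final, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("reference metabolite '", reference,
         "' absent at the final time point", call. = FALSE)
  }
  conds <- unique(table$condition)
  if (!control %in% conds) {
    stop("control condition '", control, "' not present", call. = FALSE)
  }
  missing <- setdiff(conds, unique(sub$condition))
  if (length(missing)) {
    stop("reference metabolite missing at final time for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_cond <- lapply(conds, function(cc) {
    g <- sub[sub$condition == cc, , drop = FALSE]
    enr <- vapply(split(g, g$replicate), function(r) {
      r <- r[order(r$mass_shift), ]
      mean_enrichment(mid(r$value / sum(r$value), n_carbons = r$n_carbons[1]))
    }, numeric(1))
    data.frame(condition = cc, enrichment = mean(enr),
               sd = if (length(enr) > 1) stats::sd(enr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_cond)
  ctrl_enr <- out$enrichment[out$condition == control]
  out$diff_vs_control <- abs(out$enrichment - ctrl_enr)
  out$flagged <- out$diff_vs_control > threshold
  out$flagged[out$condition == control] <- FALSE
  rownames(out) <- NULL
  class(out) <- c("steady_state_qc", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "threshold") <- threshold
  out
}

# ---- run configuration ----------------------------------------------------

default_run_config <- function() {
  list(
    control = "siCon",
    seed = 1L,
    n_draws = 1000L,
    p13C = 0.0107,
    correct = FALSE,
    qc_threshold = 0.05,
    targets = list(list(metabolite = "Ru5P", mass_shift = 1L),
                   list(metabolite = "Ru5P", mass_shift = 2L)),
    simulate = list(
      scenarios = "default",
      tracer_fraction = 0.5,
      purity = 1,
      times = default_times(),
      replicates = 3L,
      sd_fraction = 0.01
    ),
    input_csv = NULL,
    output_dir = "pppflux-run"
  )
}

#' Assemble and validate a pipeline run configuration
#'
#' A run is configured by a named list (or a YAML file containing one) with
#' fields `control`, `seed`, `n_draws`, `p13C`, `correct`, `qc_threshold`,
#' `targets`, `output_dir`, and either `input_csv` (a measured table) or a
#' `simulate` block (`scenarios`, `tracer_fraction`, `purity`, `times`,
#' `replicates`, `sd_fraction`). Unset fields take the defaults shown by
#' `run_config()`.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @return Validated config list of class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  cfg <- default_run_config()
  for (nm in names(config)) {
    if (!nm %in% names(cfg)) {
      stop("unknown config field: ", nm, call. = FALSE)
    }
    if (nm == "simulate" && is.list(config[[nm]])) {
      for (sn in names(config[[nm]])) {
        if (!sn %in% names(cfg$simulate)) {
          stop("unknown config field: simulate.", sn, call. = FALSE)
        }
        cfg$simulate[[sn]] <- config[[nm]][[sn]]
      }
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  if (is.null(cfg$control) || !nzchar(cfg$control)) {
    stop("config field 'control' is required", call. = FALSE)
  }
  if (cfg$n_draws < 1) stop("config field 'n_draws' must be >= 1",
                            call. = FALSE)
  if (is.null(cfg$input_csv) && is.null(cfg$simulate)) {
    stop("config needs either 'input_csv' or a 'simulate' block",
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_targets <- function(cfg) {
  data.frame(
    metabolite = vapply(cfg$targets, function(t) as.character(t$metabolite),
                        character(1)),
    mass_shift = vapply(cfg$targets, function(t) as.integer(t$mass_shift),
                        integer(1)),
    stringsAsFactors = FALSE)
}

#' Run the full flux-analysis pipeline
#'
#' Chains the stages simulate (or load) -> normalise/correct -> steady-state
#' QC -> Monte Carlo CSTR fits -> treatment-vs-control comparison, writing
#' `timecourse.csv` (if simulated), `qc.csv`, `comparison.csv`,
#' `residuals.csv`, a structured `log.txt` and a `manifest.yaml` (config +
#' seed + package version) to the output directory. Identical config and
#' seed give identical numeric outputs.
#'
#' @param config A [run_config()], a named list of overrides, or a YAML
#'   path.
#' @param quiet Suppress per-stage messages.
#' @return A list with `table`, `qc`, `comparison` and `output_dir`,
#'   invisibly.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "log.txt")
  log_lines <- character()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  say("config", sprintf("seed=%d n_draws=%d control=%s correction=%s",
                        cfg$seed, cfg$n_draws, cfg$control,
                        if (isTRUE(cfg$correct)) "on" else "off"))

  if (!is.null(cfg$input_csv)) {
    table <- read_timecourse(cfg$input_csv)
    say("input", sprintf("read %d rows from %s", nrow(table), cfg$input_csv))
  } else {
    sim <- cfg$simulate
    scen <- if (identical(sim$scenarios, "default")) {
      default_scenarios()
    } else {
      lapply(sim$scenarios, function(s) do.call(network_config, s))
    }
    table <- generate_experiment(
      scenarios = scen,
      tracer = tracer_spec(sim$tracer_fraction, sim$purity),
      times = as.numeric(sim$times),
      replicates = sim$replicates,
      noise = noise_model(sim$sd_fraction, seed = cfg$seed))
    write_timecourse(table, file.path(cfg$output_dir, "timecourse.csv"))
    say("simulate", sprintf("%d conditions x %d times x %d replicates",
                            length(scen), length(sim$times), sim$replicates))
  }

  table <- preprocess_timecourse(table, correct = isTRUE(cfg$correct),
                                 p13C = cfg$p13C)
  say("correct", sprintf("natural-abundance correction %s (p13C=%g)",
                         if (isTRUE(cfg$correct)) "applied" else "skipped",
                         cfg$p13C))

  qc <- qc_steady_state(table, control = cfg$control,
                        threshold = cfg$qc_threshold)
  utils::write.csv(qc, file.path(cfg$output_dir, "qc.csv"),
                   row.names = FALSE)
  say("qc", sprintf("flagged conditions: %s",
                    if (any(qc$flagged))
                      paste(qc$condition[qc$flagged], collapse = ", ")
                    else "none"))

  cmp <- compare_all(table, control = cfg$control,
                     targets = config_targets(cfg),
                     n_draws = cfg$n_draws, seed = cfg$seed)
  utils::write.csv(cmp$report, file.path(cfg$output_dir, "comparison.csv"),
                   row.names = FALSE)
  if (!is.null(cmp$diagnostics)) {
    utils::write.csv(cmp$diagnostics,
                     file.path(cfg$output_dir, "residuals.csv"),
                     row.names = FALSE)
  }
  dropped <- vapply(cmp$fits, function(f) f$n_dropped, integer(1))
  say("fit", sprintf("%d series fitted, %d draws dropped",
                     length(cmp$fits), sum(dropped)))

  manifest <- list(package = "pppflux",
                   version = as.character(utils::packageVersion("pppflux")),
                   seed = cfg$seed,
                   config = unclass(cfg))
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  writeLines(log_lines, log_path)
  say("done", sprintf("outputs in %s", cfg$output_dir))

  invisible(list(table = table, qc = qc, comparison = cmp,
                 output_dir = cfg$output_dir))
}
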