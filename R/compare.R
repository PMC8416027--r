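#' Empirical one-sided p-value for a dilution-rate difference
#'
#' Pairs Monte Carlo draws by index and tests, by default, a flux
#' *decrease* in treatment versus control against the null
#' `H0: D_treatment - D_control >= 0`. `r` counts the paired draws
#' consistent with the null and the empirical p-value is
#' `p = (r + 1) / (n + 1)`, so `p` can never fall below `1/(n+1)`.
#'
#' @param treatment,control [monte_carlo_fit()] results with equal
#'   `n_draws`.
#' @param alternative `"less"` (default: treatment rate decreased) or
#'   `"greater"` (null becomes `D_treatment - D_control <= 0`).
#' @return A list of class `"group_comparison"`: `condition_pair`,
#'   `delta_draws`, `r`, `n`, `p_empirical`, `alternative`.
#' @export
dilution_rate_pvalue <- function(treatment, control,
                                 alternative = c("less", "greater")) {
  stopifnot(inherits(treatment, "cstr_mc_fit"),
            inherits(control, "cstr_mc_fit"))
  alternative <- match.arg(alternative)
  if (treatment$n_draws != control$n_draws) {
    stop("treatment and control must use the same n_draws (",
         treatment$n_draws, " vs ", control$n_draws, ")", call. = FALSE)
  }
  keep <- treatment$converged & control$converged
  dt <- rep(NA_real_, treatment$n_draws)
  dc <- rep(NA_real_, control$n_draws)
  dt[treatment$converged] <- treatment$D_draws
  dc[control$converged] <- control$D_draws
  delta <- (dt - dc)[keep]
  n <- length(delta)
  if (n < 1L) stop("no converged paired draws", call. = FALSE)
  r <- if (alternative == "less") sum(delta >= 0) else sum(delta <= 0)
  structure(list(condition_pair = c(treatment = NA_character_,
                                    control = NA_character_),
                 delta_draws = delta, r = r, n = n,
                 p_empirical = (r + 1) / (n + 1),
                 alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Paired dilution-rate comparison: r = %d, n = %d, p = %.4g\n",
              x$r, x$n, x$p_empirical))
  invisible(x)
}

# pull one (condition, metabolite, mass shift) fraction series from the
# long table
extract_series <- function(table, condition, metabolite, mass_shift) {
  rows <- table[table$condition == condition &
                  table$metabolite == metabolite &
                  table$mass_shift == mass_shift, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  rows[order(rows$time_s, rows$replicate), c("time_s", "value", "replicate")]
}

#' Fit dilution rates for all conditions and compare against control
#'
#' Runs [monte_carlo_fit()] for every condition on each target
#' metabolite/isotopologue series (defaults: Ru5P m1, the oxidative-branch
#' reporter, and Ru5P m2, the non-oxidative reporter) and computes
#' [dilution_rate_pvalue()] for each treatment against the control.
#' Per-(condition, target) noise streams are spawned deterministically
#' from the master seed, and treatment/control draws are paired by index.
#'
#' @param table Long-format time-course table (fractions), as produced by
#'   [generate_experiment()] or [read_timecourse()].
#' @param control Control condition label (default `"siCon"`).
#' @param targets Data frame with columns `metabolite` and `mass_shift`
#'   (default Ru5P m1 and m2).
#' @param n_draws Monte Carlo draws per fit (default 1000).
#' @param seed Master seed.
#' @return A list of class `"flux_comparison"`: `report` (data frame with
#'   columns condition, metabolite, isotopologue, D_hat, D_ci_low,
#'   D_ci_high, r, n, p_empirical), `fits` (nested list of
#'   [monte_carlo_fit()] results) and `diagnostics` (residuals per series).
#' @export
compare_all <- function(table, control = "siCon",
                        targets = data.frame(metabolite = "Ru5P",
                                             mass_shift = c(1L, 2L)),
                        n_draws = 1000L, seed = 1L) {
  stopifnot(is.data.frame(table),
            all(c("condition", "metabolite", "mass_shift",
                  "time_s", "value") %in% names(table)))
  conditions <- unique(table$condition)
  if (!control %in% conditions) {
    stop("control condition '", control, "' not present in table",
         call. = FALSE)
  }
  conditions <- c(control, setdiff(conditions, control))
  key <- function(cond, met, shift) paste(cond, met, shift, sep = "|")
  combos <- expand.grid(ci = seq_along(conditions), ti = seq_len(nrow(targets)))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(combos)))

  fits <- list()
  diag_rows <- list()
  for (k in seq_len(nrow(combos))) {
    cond <- conditions[combos$ci[k]]
    met <- as.character(targets$metabolite[combos$ti[k]])
    shift <- targets$mass_shift[combos$ti[k]]
    ser <- extract_series(table, cond, met, shift)
    if (is.null(ser)) {
      warning("missing series: ", key(cond, met, shift), call. = FALSE)
      next
    }
    fit <- tryCatch(
      monte_carlo_fit(ser$time_s, ser$value, n_draws = n_draws,
                      seed = seeds[k]),
      error = function(e) {
        warning("fit failed for ", key(cond, met, shift), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fits[[key(cond, met, shift)]] <- fit
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      condition = cond, metabolite = met, isotopologue = paste0("m", shift),
      time_s = ser$time_s, replicate = ser$replicate,
      residual = fit$residuals, stringsAsFactors = FALSE)
  }

  report <- list()
  for (k in seq_len(nrow(combos))) {
    cond <- conditions[combos$ci[k]]
    met <- as.character(targets$metabolite[combos$ti[k]])
    shift <- targets$mass_shift[combos$ti[k]]
    fit <- fits[[key(cond, met, shift)]]
    if (is.null(fit)) next
    ci <- if (length(fit$D_draws) >= 2) {
      stats::quantile(fit$D_draws, c(0.025, 0.975), names = FALSE)
    } else c(NA_real_, NA_real_)
    row <- data.frame(condition = cond, metabolite = met,
                      isotopologue = paste0("m", shift),
                      D_hat = fit$params$D,
                      D_ci_low = ci[1], D_ci_high = ci[2],
                      r = NA_integer_, n = NA_integer_,
                      p_empirical = NA_real_, stringsAsFactors = FALSE)
    if (cond != control) {
      ctrl_fit <- fits[[key(control, met, shift)]]
      if (!is.null(ctrl_fit)) {
        cmp <- dilution_rate_pvalue(fit, ctrl_fit)
        row$r <- cmp$r
        row$n <- cmp$n
        row$p_empirical <- cmp$p_empirical
      }
    }
    report[[length(report) + 1L]] <- row
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(condition = character(), metabolite = character(),
               isotopologue = character(), D_hat = numeric(),
               D_ci_low = numeric(), D_ci_high = numeric(),
               r = integer(), n = integer(), p_empirical = numeric())
  rownames(report) <- NULL
  structure(list(report = report, fits = fits,
                 diagnostics = if (length(diag_rows))
                   do.call(rbind, diag_rows) else NULL,
                 control = control, seed = as.integer(seed)),
            class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat("Dilution-rate comparison vs '", x$control, "':\n", sep = "")
  print(x$report, digits = 4)
  invisible(x)
}
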