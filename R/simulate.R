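n_carbons_table <- c(G6P = 6L, F6P = 6L, GAP = 3L, Ru5P = 5L)

#' Tracer specification for a 1,2-13C2 glucose spike-in
#'
#' Describes the isotopic composition of medium glucose after spiking
#' 1,2-13C2 glucose into natural-glucose medium. The tracer molecule is
#' doubly labelled (m2, carbons C1 and C2); `purity` is the fraction of
#' tracer molecules that actually carry both labels (impure molecules are
#' treated as unlabelled and applied as a pre-mixing dilution).
#'
#' @param tracer_fraction Fraction of medium glucose that is tracer
#'   (default 0.5: spiked 1:1 with natural glucose).
#' @param purity Isotopic purity of the tracer, in `[0, 1]` (default 1).
#' @return An object of class `"tracer_spec"`.
#' @export
tracer_spec <- function(tracer_fraction = 0.5, purity = 1) {
  stopifnot(is.numeric(tracer_fraction), length(tracer_fraction) == 1,
            is.numeric(purity), length(purity) == 1)
  if (tracer_fraction < 0 || tracer_fraction > 1) {
    stop("tracer_fraction must be in [0, 1]", call. = FALSE)
  }
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]", call. = FALSE)
  structure(list(tracer_fraction = tracer_fraction, purity = purity),
            class = "tracer_spec")
}

#' Medium glucose MID implied by a tracer specification
#'
#' @param tracer A [tracer_spec()] object.
#' @return A [mid()] for glucose (6 carbons): a mixture of m0 and m2.
#' @export
medium_glucose_mid <- function(tracer = tracer_spec()) {
  stopifnot(inherits(tracer, "tracer_spec"))
  f <- numeric(7)
  m2 <- tracer$tracer_fraction * tracer$purity
  f[3] <- m2
  f[1] <- 1 - m2
  mid(f, metabolite_id = "Glc", n_carbons = 6L)
}

#' Metabolic network configuration for the labelling simulator
#'
#' Pool sizes and fluxes of the simplified glycolysis/PPP network:
#' glucose -> G6P; G6P -> F6P (glycolysis) and G6P -> Ru5P + CO2 (oxidative
#' PPP branch, C1 lost); F6P -> GAP (aldolase split, both trioses lumped
#' into one GAP pool); F6P + GAP -> Ru5P (net non-oxidative branch).
#' Steady-state metabolism is assumed: pool sizes are constant and only the
#' isotopic composition evolves.
#'
#' Default fluxes give a Ru5P turnover `(v_ox + v_nonox) / pool = 0.005`
#' per second, so Ru5P labelling approaches isotopic steady state within
#' the 15-minute experimental window. The G6P pool is small (fast
#' turnover, ~0.1/s: hexose phosphate equilibrates with medium glucose
#' within seconds-to-a-minute, as seen in kinetic flux profiling), while
#' the `F6P` and `GAP` nodes carry larger pools because they lump the
#' downstream fructose-bisphosphate and DHAP pools respectively, so the
#' non-oxidative (m2) route labels with a pronounced upstream lag.
#'
#' @param pool_sizes Named numeric vector of pool amounts for
#'   `G6P`, `F6P`, `GAP`, `Ru5P` (arbitrary units, > 0 where fed).
#' @param v_glycolysis Glucose uptake flux into G6P (amount/s).
#' @param v_ox Oxidative-branch flux G6P -> Ru5P (amount/s).
#' @param v_nonox Net non-oxidative flux F6P/GAP -> Ru5P (amount/s).
#' @param v_lower Lower-glycolysis flux F6P -> GAP (amount/s); each F6P
#'   yields two trioses.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(pool_sizes = c(G6P = 0.1, F6P = 1, GAP = 1,
                                          Ru5P = 1),
                           v_glycolysis = 0.01,
                           v_ox = 0.003,
                           v_nonox = 0.002,
                           v_lower = 0.005) {
  need <- c("G6P", "F6P", "GAP", "Ru5P")
  if (!all(need %in% names(pool_sizes))) {
    stop("pool_sizes must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pool_sizes <- pool_sizes[need]
  flux <- c(v_glycolysis = v_glycolysis, v_ox = v_ox,
            v_nonox = v_nonox, v_lower = v_lower)
  if (any(pool_sizes < 0) || any(flux < 0)) {
    stop("pool sizes and fluxes must be nonnegative", call. = FALSE)
  }
  if (v_ox > v_glycolysis) {
    stop("v_ox cannot exceed v_glycolysis (G6P mass balance)", call. = FALSE)
  }
  structure(list(pool_sizes = pool_sizes, v_glycolysis = v_glycolysis,
                 v_ox = v_ox, v_nonox = v_nonox, v_lower = v_lower),
            class = "network_config")
}

#' Default knockdown scenario set
#'
#' A control plus three knockdown conditions mirroring the siRNA design:
#' `si6PGD` scales the oxidative-branch flux by `ox_scale`; `siAR` and
#' `siSREBP1` scale both branch fluxes by `both_scale`. The effect sizes
#' are synthetic choices, not estimates from data.
#'
#' @param control A [network_config()] used for the control condition.
#' @param ox_scale Multiplier on `v_ox` for the 6PGD-knockdown-like
#'   condition (default 0.4).
#' @param both_scale Multiplier on both `v_ox` and `v_nonox` for the
#'   AR/SREBP1-knockdown-like conditions (default 0.4).
#' @return Named list of `"network_config"` objects
#'   (`siCon`, `si6PGD`, `siAR`, `siSREBP1`).
#' @export
default_scenarios <- function(control = network_config(),
                              ox_scale = 0.4, both_scale = 0.4) {
  stopifnot(inherits(control, "network_config"))
  tweak <- function(cfg, ox = 1, nonox = 1) {
    network_config(pool_sizes = cfg$pool_sizes,
                   v_glycolysis = cfg$v_glycolysis,
                   v_ox = cfg$v_ox * ox,
                   v_nonox = cfg$v_nonox * nonox,
                   v_lower = cfg$v_lower)
  }
  list(siCon    = control,
       si6PGD   = tweak(control, ox = ox_scale),
       siAR     = tweak(control, ox = both_scale, nonox = both_scale),
       siSREBP1 = tweak(control, ox = both_scale, nonox = both_scale))
}

#' Measurement-noise model for simulated experiments
#'
#' Additive Gaussian noise on isotopologue fractions, applied per sampled
#' MID, then clamped to `[0, 1]` and renormalised.
#'
#' @param sd_fraction Standard deviation of the noise on fractions
#'   (default 0.01, matching small triplicate error bars).
#' @param seed Integer RNG seed making generated tables reproducible.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd_fraction = 0.01, seed = 1L) {
  stopifnot(is.numeric(sd_fraction), sd_fraction >= 0)
  structure(list(sd_fraction = sd_fraction, seed = as.integer(seed)),
            class = "noise_model")
}

# --- atom-transition rules for the 1,2-13C2 tracer ------------------------
# Labels enter on glucose C1-C2 only, so positional information reduces to
# labelled-carbon counts plus these fixed fragment rules.

# oxidative branch: C1 (labelled first) lost as CO2 -> G6P m_k yields
# Ru5P m_max(k-1, 0)
transition_ox <- function() {
  m <- matrix(0, 6, 7)
  for (k in 0:6) m[max(k - 1, 0) + 1, k + 1] <- 1
  m
}

# aldolase split: F6P gives equal parts C1-C3 triose (carries the labels)
# and C4-C6 triose (unlabelled)
transition_gap <- function() {
  m <- matrix(0, 4, 7)
  for (k in 0:6) {
    top <- min(k, 3)
    m[top + 1, k + 1] <- m[top + 1, k + 1] + 0.5
    m[(k - top) + 1, k + 1] <- m[(k - top) + 1, k + 1] + 0.5
  }
  m
}

# non-oxidative branch: Ru5P label count = labels on the F6P C1-C2 fragment
# plus labels carried by the GAP-derived fragment
nonox_input_mid <- function(f6p, gap) {
  a <- numeric(3)                       # F6P C1-C2 fragment: 0..2 labels
  for (k in 0:6) a[min(k, 2) + 1] <- a[min(k, 2) + 1] + f6p[k + 1]
  out <- numeric(6)                     # convolve with GAP labels 0..3
  for (i in 0:2) for (j in 0:3) {
    out[i + j + 1] <- out[i + j + 1] + a[i + 1] * gap[j + 1]
  }
  out
}

ru5p_input_mid <- function(config, g6p, f6p, gap, t_ox) {
  v_in <- config$v_ox + config$v_nonox
  if (v_in <= 0) return(NULL)
  (config$v_ox * as.numeric(t_ox %*% g6p) +
     config$v_nonox * nonox_input_mid(f6p, gap)) / v_in
}

check_pools <- function(config) {
  q <- config$pool_sizes
  influx <- c(G6P = config$v_glycolysis,
              F6P = config$v_glycolysis - config$v_ox,
              GAP = 2 * config$v_lower,
              Ru5P = config$v_ox + config$v_nonox)
  bad <- names(q)[q <= 0 & influx > 0]
  if (length(bad)) {
    stop("zero pool size with positive influx: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(influx)
}

#' Forward-simulate label incorporation through glycolysis and the PPP
#'
#' Integrates the isotopologue balance for each pool,
#' `d(MID)/dt = (influx / pool) * (input MID - pool MID)`, where input MIDs
#' are composed through the 1,2-13C2-specific atom-transition rules
#' (oxidative branch loses C1 as CO2: m2 G6P -> m1 Ru5P; the non-oxidative
#' branch retains both labels via F6P/GAP: -> m2 Ru5P). All pools start
#' unlabelled (m0 = 1) at `t = 0`. CO2 is a sink; there is no refixation.
#'
#' @param config A [network_config()].
#' @param tracer A [tracer_spec()].
#' @param times Numeric vector of sampling times in seconds, sorted,
#'   starting at 0.
#' @return A list of class `"labeling_trajectories"`: one
#'   `length(times) x (n_carbons+1)` fraction matrix per metabolite
#'   (`G6P`, `F6P`, `GAP`, `Ru5P`), with `attr(, "times")`.
#' @export
simulate_labeling <- function(config, tracer = tracer_spec(),
                              times = default_times()) {
  stopifnot(inherits(config, "network_config"), inherits(tracer, "tracer_spec"))
  if (any(times < 0)) stop("negative time in `times`", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  check_pools(config)

  glc <- medium_glucose_mid(tracer)$fractions
  t_ox <- transition_ox()
  t_gap <- transition_gap()
  q <- config$pool_sizes
  idx <- list(G6P = 1:7, F6P = 8:14, GAP = 15:18, Ru5P = 19:24)

  derivs <- function(t, y, parms) {
    g6p <- y[idx$G6P]; f6p <- y[idx$F6P]
    gap <- y[idx$GAP]; ru5p <- y[idx$Ru5P]
    dy <- numeric(24)
    if (config$v_glycolysis > 0) {
      dy[idx$G6P] <- (config$v_glycolysis / q[["G6P"]]) * (glc - g6p)
    }
    v_f6p <- config$v_glycolysis - config$v_ox
    if (v_f6p > 0) dy[idx$F6P] <- (v_f6p / q[["F6P"]]) * (g6p - f6p)
    if (config$v_lower > 0) {
      dy[idx$GAP] <- (2 * config$v_lower / q[["GAP"]]) *
        (as.numeric(t_gap %*% f6p) - gap)
    }
    inp <- ru5p_input_mid(config, g6p, f6p, gap, t_ox)
    if (!is.null(inp)) {
      dy[idx$Ru5P] <- ((config$v_ox + config$v_nonox) / q[["Ru5P"]]) *
        (inp - ru5p)
    }
    list(dy)
  }

  y0 <- numeric(24)
  y0[vapply(idx, `[`, integer(1), 1L)] <- 1   # all pools m0 = 1 at t = 0
  sol <- deSolve::lsoda(y0, times, derivs, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  out <- lapply(names(idx), function(met) {
    m <- sol[, idx[[met]] + 1L, drop = FALSE]
    m <- pmax(m, 0)
    m <- m / rowSums(m)                 # guard tiny integration drift
    dimnames(m) <- list(NULL, paste0("m", seq_len(ncol(m)) - 1L))
    m
  })
  names(out) <- names(idx)
  structure(out, times = times, class = "labeling_trajectories")
}

#' Experimental time grid
#'
#' The sampling grid used throughout: 0, 10, 60, 120, 240, 480, 900 seconds.
#' @return Numeric vector of seconds.
#' @export
default_times <- function() c(0, 10, 60, 120, 240, 480, 900)

#' Isotopic steady-state MIDs of the labelling network
#'
#' Closed-form fixed point of the labelling dynamics. The network is
#' feed-forward (glucose -> G6P -> F6P -> GAP -> Ru5P), so steady states are
#' obtained sequentially: each fed pool's MID equals its influx-weighted
#' input MID; an unfed pool stays unlabelled. [simulate_labeling()]
#' trajectories converge to these values as t grows.
#'
#' @inheritParams simulate_labeling
#' @return Named list of [mid()] objects for `G6P`, `F6P`, `GAP`, `Ru5P`.
#' @export
steady_state_mids <- function(config, tracer = tracer_spec()) {
  stopifnot(inherits(config, "network_config"), inherits(tracer, "tracer_spec"))
  check_pools(config)
  m0 <- function(n) c(1, numeric(n))
  glc <- medium_glucose_mid(tracer)$fractions

  g6p <- if (config$v_glycolysis > 0) as.numeric(glc) else m0(6)
  f6p <- if (config$v_glycolysis - config$v_ox > 0) g6p else m0(6)
  gap <- if (config$v_lower > 0) as.numeric(transition_gap() %*% f6p) else m0(3)
  inp <- ru5p_input_mid(config, g6p, f6p, gap, transition_ox())
  ru5p <- if (is.null(inp)) m0(5) else inp

  list(G6P = mid(g6p, "G6P"), F6P = mid(f6p, "F6P"),
       GAP = mid(gap, "GAP"), Ru5P = mid(ru5p, "Ru5P"))
}

# run code with a temporary RNG state so generators are deterministic
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

noisy_fractions <- function(fr, sd) {
  if (sd > 0) {
    fr <- fr + stats::rnorm(length(fr), 0, sd)
    fr <- pmin(pmax(fr, 0), 1)
    if (sum(fr) <= 0) fr <- rep(1 / length(fr), length(fr))
  }
  fr / sum(fr)
}

#' Generate a synthetic labelling experiment
#'
#' Simulates every scenario, samples it at the requested times with
#' replicate measurement noise, and returns a long-format time-course
#' table. Deterministic given the noise model's seed: per-condition noise
#' streams are spawned from it, so adding or reordering conditions does not
#' perturb the others.
#'
#' @param scenarios Named list of [network_config()] objects, one per
#'   condition (e.g. [default_scenarios()]).
#' @param tracer A [tracer_spec()].
#' @param times Sampling times (seconds), sorted, starting at 0.
#' @param replicates Number of replicate measurements per time point
#'   (default 3).
#' @param noise A [noise_model()].
#' @return A data.frame with columns `condition`, `replicate`, `metabolite`,
#'   `n_carbons`, `mass_shift`, `time_s`, `value`, `value_type`
#'   (`"fraction"`).
#' @export
generate_experiment <- function(scenarios = default_scenarios(),
                                tracer = tracer_spec(),
                                times = default_times(),
                                replicates = 3L,
                                noise = noise_model()) {
  if (!is.list(scenarios) || length(scenarios) < 1L ||
      is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("`scenarios` must be a non-empty named list of network configs",
         call. = FALSE)
  }
  if (length(times) < 1L) stop("empty time grid", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  stopifnot(inherits(noise, "noise_model"))

  cond_seeds <- with_seed(noise$seed,
                          sample.int(.Machine$integer.max,
                                     length(scenarios)))
  rows <- vector("list", length(scenarios))
  for (ci in seq_along(scenarios)) {
    cond <- names(scenarios)[ci]
    traj <- simulate_labeling(scenarios[[ci]], tracer, times)
    rows[[ci]] <- with_seed(cond_seeds[ci], {
      out <- list()
      for (met in names(traj)) {
        nmass <- ncol(traj[[met]])
        for (ti in seq_along(times)) {
          for (rep_i in seq_len(replicates)) {
            fr <- noisy_fractions(traj[[met]][ti, ], noise$sd_fraction)
            out[[length(out) + 1L]] <- data.frame(
              condition = cond, replicate = rep_i, metabolite = met,
              n_carbons = nmass - 1L, mass_shift = 0:(nmass - 1L),
              time_s = times[ti], value = as.numeric(fr),
              value_type = "fraction", stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, out)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
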