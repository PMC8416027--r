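# shared fixtures built in code

paper_times <- c(0, 10, 60, 120, 240, 480, 900)

random_mid <- function(n_carbons) {
  f <- stats::runif(n_carbons + 1)
  mid(f / sum(f), n_carbons = n_carbons)
}

# minimal Monte Carlo fit object with prescribed draws, for testing the
# p-value arithmetic independently of the fitting machinery
fake_mc_fit <- function(D_draws, D_hat = mean(D_draws)) {
  structure(list(params = cstr_params(0, 0, max(D_hat, 0)),
                 residuals = numeric(0), degenerate = FALSE,
                 D_draws = D_draws, n_draws = length(D_draws),
                 converged = rep(TRUE, length(D_draws)),
                 n_dropped = 0L, seed = 0L),
            class = "cstr_mc_fit")
}

# triplicate CSTR observations with Gaussian noise
make_cstr_data <- function(params, sd = 0.01, replicates = 3,
                           times = paper_times) {
  t_obs <- rep(times, each = replicates)
  y <- cstr_model(t_obs, params) + stats::rnorm(length(t_obs), 0, sd)
  list(time_s = t_obs, value = pmin(pmax(y, 0), 1))
}
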