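test_that("without tracer every pool stays unlabelled", {
  traj <- simulate_labeling(network_config(), tracer_spec(tracer_fraction = 0),
                            paper_times)
  for (met in names(traj)) {
    expect_equal(traj[[met]][, 1], rep(1, length(paper_times)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ablating the oxidative branch removes m1 but not m2 Ru5P", {
  cfg <- network_config(v_ox = 0)
  traj <- simulate_labeling(cfg, tracer_spec(), paper_times)
  expect_lt(max(traj$Ru5P[, "m1"]), 1e-9)
  expect_gt(traj$Ru5P[length(paper_times), "m2"], 0.01)
})

test_that("G6P converges to the 1:1 medium mixture on a long horizon", {
  traj <- simulate_labeling(network_config(), tracer_spec(0.5, 1),
                            c(0, 500, 1000, 2000, 5000))
  final <- traj$G6P[5, ]
  expect_equal(final[["m0"]], 0.5, tolerance = 1e-6)
  expect_equal(final[["m2"]], 0.5, tolerance = 1e-6)
})

test_that("closed-form steady state matches mixing oracles and trajectories", {
  cfg <- network_config()
  tr <- tracer_spec(0.5, 1)
  ss <- steady_state_mids(cfg, tr)
  # single-source pool: G6P limit is the medium glucose MID
  expect_equal(ss$G6P$fractions, medium_glucose_mid(tr)$fractions,
               tolerance = 1e-12)
  # closed-form mixing oracle for the Ru5P m1 limit
  expect_equal(ss$Ru5P$fractions[["m1"]],
               0.5 * cfg$v_ox / (cfg$v_ox + cfg$v_nonox), tolerance = 1e-12)
  # finite-difference: raising v_ox raises the m1 limit
  up <- steady_state_mids(network_config(v_ox = cfg$v_ox * 1.2), tr)
  expect_gt(up$Ru5P$fractions[["m1"]], ss$Ru5P$fractions[["m1"]])
  # reducing v_ox leaves G6P enrichment unchanged (the QC mechanism)
  down <- steady_state_mids(network_config(v_ox = cfg$v_ox * 0.4), tr)
  expect_lt(down$Ru5P$fractions[["m1"]], ss$Ru5P$fractions[["m1"]])
  expect_equal(mean_enrichment(down$G6P), mean_enrichment(ss$G6P),
               tolerance = 1e-12)
  # trajectories converge to the closed-form fixed point
  traj <- simulate_labeling(cfg, tr, c(0, 2500, 5000))
  for (met in names(traj)) {
    expect_equal(as.numeric(traj[[met]][3, ]),
                 as.numeric(ss[[met]]$fractions), tolerance = 1e-5)
  }
})

test_that("labelling trajectories conserve mass and accumulate monotonically", {
  traj <- simulate_labeling(network_config(), tracer_spec(),
                            seq(0, 900, by = 60))
  for (met in names(traj)) {
    expect_equal(rowSums(traj[[met]]), rep(1, nrow(traj[[met]])),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
  # product isotopologues rise toward steady state without overshoot
  expect_true(all(diff(traj$Ru5P[, "m1"]) > -1e-9))
  expect_true(all(diff(traj$Ru5P[, "m2"]) > -1e-9))
  expect_true(all(diff(traj$G6P[, "m2"]) > -1e-9))
})

test_that("scaling all fluxes and compressing time leaves trajectories unchanged", {
  cfg <- network_config()
  fast <- network_config(v_glycolysis = 2 * cfg$v_glycolysis,
                         v_ox = 2 * cfg$v_ox, v_nonox = 2 * cfg$v_nonox,
                         v_lower = 2 * cfg$v_lower)
  t1 <- simulate_labeling(cfg, tracer_spec(), c(0, 120, 480, 900))
  t2 <- simulate_labeling(fast, tracer_spec(), c(0, 60, 240, 450))
  for (met in names(t1)) {
    expect_equal(t1[[met]], t2[[met]], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("simulate_labeling rejects inconsistent inputs", {
  expect_error(simulate_labeling(network_config(), tracer_spec(),
                                 c(-1, 0, 10)), "negative time")
  expect_error(simulate_labeling(network_config(), tracer_spec(),
                                 c(0, 100, 50)), "increasing")
  expect_error(simulate_labeling(network_config(), tracer_spec(),
                                 c(10, 50)), "start at 0")
  bad <- network_config(pool_sizes = c(G6P = 1, F6P = 1, GAP = 0, Ru5P = 1))
  expect_error(simulate_labeling(bad, tracer_spec(), c(0, 10)),
               "zero pool size.*GAP")
  expect_error(network_config(v_ox = 0.02), "v_ox")
})

test_that("generate_experiment is deterministic and dimensioned correctly", {
  scen <- default_scenarios()[c("siCon", "si6PGD")]
  nm <- noise_model(0.01, seed = 5)
  t1 <- generate_experiment(scen, tracer_spec(), paper_times, 3, nm)
  t2 <- generate_experiment(scen, tracer_spec(), paper_times, 3, nm)
  expect_identical(t1, t2)
  # 7 time points x 3 replicates = 21 rows per metabolite per mass shift
  ru5p_m1 <- t1[t1$condition == "siCon" & t1$metabolite == "Ru5P" &
                  t1$mass_shift == 1, ]
  expect_equal(nrow(ru5p_m1), 21)
  # fractions per sample sum to 1
  s <- tapply(t1$value, interaction(t1$condition, t1$replicate,
                                    t1$metabolite, t1$time_s), sum)
  expect_true(all(abs(s - 1) < 1e-9))
})

test_that("noise-free tables equal the noiseless trajectories", {
  scen <- list(siCon = network_config())
  tab <- generate_experiment(scen, tracer_spec(), paper_times, 2,
                             noise_model(0, seed = 1))
  traj <- simulate_labeling(network_config(), tracer_spec(), paper_times)
  for (ti in seq_along(paper_times)) {
    rows <- tab[tab$metabolite == "Ru5P" & tab$time_s == paper_times[ti] &
                  tab$replicate == 1, ]
    rows <- rows[order(rows$mass_shift), ]
    expect_equal(rows$value, as.numeric(traj$Ru5P[ti, ]), tolerance = 1e-9)
  }
})

test_that("generate_experiment validates its design arguments", {
  scen <- list(siCon = network_config())
  expect_error(generate_experiment(scen, tracer_spec(), numeric(0), 3,
                                   noise_model()), "empty time grid")
  expect_error(generate_experiment(scen, tracer_spec(), paper_times, 0,
                                   noise_model()), "replicates")
  expect_error(generate_experiment(list(network_config()), tracer_spec(),
                                   paper_times, 3, noise_model()), "named")
  expect_error(tracer_spec(1.2), "tracer_fraction")
  expect_error(tracer_spec(0.5, -0.1), "purity")
})
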