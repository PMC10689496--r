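small_inference_data <- function(seed = 5, n_concepts = 10) {
  tree <- kartvelian_reference_tree(seed = 1)
  cm <- simulate_cognate_matrix(
    tree, sim_config(seed, cognates = list(n_concepts = n_concepts)))
  add_ascertainment_columns(cm)
}

zan_cal <- function(sigma = 10) {
  calibration_set(node_calibrations = list(
    list(tips = c("Megrelian", "Laz"), mean = 1200, sigma = sigma)))
}

test_that("retained sample count follows floor(n/thin) * (1 - burnin)", {
  m <- small_inference_data()
  ps <- run_mcmc(m, substitution_model("ctmc"), clock_model("strict", 2.5e-4),
                 zan_cal(), mcmc_config(n_generations = 2000, thin = 50,
                                        burnin_fraction = 0.1, seed = 2,
                                        sample_likelihood = FALSE))
  expect_equal(ps$n_retained, 36)           # 40 samples, 4 dropped
  expect_equal(nrow(ps$trace), 36)
  expect_length(ps$trees, 36)
  # the study configuration scales to 36,000 by the same arithmetic
  expect_equal(floor(200e6 / 5000) * (1 - 0.1), 36000)
})

test_that("chains are seed-deterministic", {
  m <- small_inference_data()
  cfg <- mcmc_config(n_generations = 3000, thin = 100, seed = 11)
  ps1 <- run_mcmc(m, substitution_model("covarion"),
                  clock_model("ucln", 2.5e-4), zan_cal(), cfg)
  ps2 <- run_mcmc(m, substitution_model("covarion"),
                  clock_model("ucln", 2.5e-4), zan_cal(), cfg)
  expect_equal(ps1$trace, ps2$trace)
  expect_equal(ape::write.tree(ps1$trees[[5]]), ape::write.tree(ps2$trees[[5]]))
})

test_that("a prior-only chain recovers the normal node calibration", {
  m <- small_inference_data()
  ps <- run_mcmc(m, substitution_model("covarion"),
                 clock_model("ucln", 2.5e-4), zan_cal(10),
                 mcmc_config(n_generations = 60000, thin = 25, seed = 3,
                             sample_likelihood = FALSE))
  v <- ps$trace$cal_node_age_1
  expect_gt(as.numeric(trace_ess(v)), 200)
  expect_lt(abs(mean(v) - 1200), 1.5)
  expect_lt(abs(stats::sd(v) - 10), 1)
})

test_that("the calibrated clade stays monophyletic throughout", {
  m <- small_inference_data(7)
  ps <- run_mcmc(m, substitution_model("ctmc"), clock_model("ucln", 2.5e-4),
                 zan_cal(), mcmc_config(n_generations = 5000, thin = 100,
                                        seed = 5))
  mono <- vapply(ps$trees, function(tr) {
    ape::is.monophyletic(tr, c("Megrelian", "Laz"))
  }, TRUE)
  expect_true(all(mono))
  # tip dates are preserved in every sampled tree
  ages <- node_ages(ps$trees[[1]])
  expect_equal(unname(ages[match("OldGeorgian", ps$trees[[1]]$tip.label)]),
               900, tolerance = 1e-6)
})

test_that("invalid MCMC configurations are rejected", {
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(burnin_fraction = 1), "burnin")
  expect_error(phylo_priors(nonsense = 1), "unknown prior")
})

test_that("simulation-based coverage: the true root age falls in the 95% HPD", {
  # simulation-based calibration at reduced scale: each replicate draws its
  # truth (tree, clock and covarion parameters) from the inference prior via
  # a prior-only chain, simulates cognates on it, and checks the 95% HPD.
  # Five-tip tip-dated designs leave the root age weakly identified (the
  # height-rate ridge), so credible-interval coverage is only meaningful
  # against prior-drawn truths.
  dummy <- add_ascertainment_columns(simulate_cognate_matrix(
    kartvelian_reference_tree(seed = 1),
    sim_config(1, cognates = list(n_concepts = 5))))
  n_rep <- 12
  hits <- 0
  for (r in seq_len(n_rep)) {
    pr <- run_mcmc(dummy, substitution_model("covarion"),
                   clock_model("ucln", 2.5e-4), zan_cal(),
                   mcmc_config(n_generations = 40000, thin = 1000,
                               seed = 2000 + r, sample_likelihood = FALSE))
    tree <- pr$trees[[length(pr$trees)]]
    last <- pr$trace[nrow(pr$trace), ]
    true_root <- max(node_ages(tree))
    cfg <- sim_config(2100 + r, cognates = list(
      n_concepts = 40,
      substitution_params = list(freq_present = last$freq_present,
                                 switch_rate = last$switch_rate,
                                 slow_fraction = last$slow_fraction),
      clock_rate = last$clock_rate, clock_sd_log = last$clock_sd))
    cm <- add_ascertainment_columns(simulate_cognate_matrix(tree, cfg))
    ps <- run_mcmc(cm, substitution_model("covarion"),
                   clock_model("ucln", 2.5e-4), zan_cal(),
                   mcmc_config(n_generations = 40000, thin = 40,
                               seed = 2200 + r))
    hpd <- hpd_interval(ps$trace$tree_height)
    if (hpd[["low"]] <= true_root && true_root <= hpd[["high"]]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, ceiling(0.75 * n_rep))
})
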