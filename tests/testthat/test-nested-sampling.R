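toy_kernel <- function(log_lik, prior_rnorm_sd = 1, steps = 20) {
  function(state, floor_ll) {
    for (i in seq_len(steps)) {
      cand <- state + stats::rnorm(1, 0, 0.5)
      # prior is N(0, 1): Metropolis on the prior with a likelihood floor
      if (log(stats::runif(1)) <
            stats::dnorm(cand, 0, prior_rnorm_sd, log = TRUE) -
            stats::dnorm(state, 0, prior_rnorm_sd, log = TRUE) &&
          log_lik(cand) > floor_ll) {
        state <- cand
      }
    }
    state
  }
}

test_that("a constant likelihood returns logZ = log L0 with zero spread", {
  ll <- function(s) -3.7
  res <- nested_sampling(ll, function() stats::rnorm(1), toy_kernel(ll),
                         n_particles = 10, seed = 1)
  expect_equal(res$log_marginal_likelihood, -3.7, tolerance = 1e-9)
  expect_lt(res$sd, 1e-6)
})

test_that("the conjugate normal toy recovers the analytic evidence within 3 sd", {
  # prior N(0,1), likelihood N(x | mu0, s0): evidence = N(mu0; 0, sqrt(1+s0^2))
  mu0 <- 0.5; s0 <- 0.3
  ll <- function(x) stats::dnorm(mu0, x, s0, log = TRUE)
  true_logz <- stats::dnorm(mu0, 0, sqrt(1 + s0^2), log = TRUE)
  res <- nested_sampling(ll, function() stats::rnorm(1), toy_kernel(ll),
                         n_particles = 20, seed = 7)
  expect_lt(abs(res$log_marginal_likelihood - true_logz), 3 * res$sd + 0.05)
  expect_gt(res$sd, 0)
  # the likelihood ladder is non-decreasing
  expect_true(all(diff(res$ladder) >= 0))
})

test_that("doubling the particle count shrinks the mean absolute error", {
  mu0 <- 0.8; s0 <- 0.4
  ll <- function(x) stats::dnorm(mu0, x, s0, log = TRUE)
  true_logz <- stats::dnorm(mu0, 0, sqrt(1 + s0^2), log = TRUE)
  err <- function(N) {
    mean(vapply(1:30, function(r) {
      res <- nested_sampling(ll, function() stats::rnorm(1), toy_kernel(ll),
                             n_particles = N, seed = 1000 + r)
      abs(res$log_marginal_likelihood - true_logz)
    }, 0))
  }
  expect_lt(err(16), err(8))
})

test_that("Bayes factors: reported model pair, identity, inclusive threshold", {
  bf <- bayes_factor(-2034.34, -2062.58)
  expect_equal(bf$log_bf, 28.24, tolerance = 1e-10)
  expect_equal(bf$verdict, "very strong")
  expect_equal(bayes_factor(-10, -10)$bf, 1)
  expect_equal(bayes_factor(-10, -10)$verdict, "not very strong")
  expect_equal(bayes_factor(-5, -10)$verdict, "very strong")  # exactly 5
})

test_that("comparison tables sort by logML and score against the best row", {
  res <- list(
    bc_relaxed = list(log_marginal_likelihood = -2034.34, sd = 1.92),
    bc_strict = list(log_marginal_likelihood = -2062.58, sd = 1.96)
  )
  tbl <- build_comparison_table(res)
  expect_equal(tbl$model[1], "bc_relaxed")
  expect_equal(tbl$log_bf[2], 28.24, tolerance = 1e-10)
  expect_equal(tbl$log_bf[1], 0)
  # shuffled entries come out sorted (oracle: sort())
  set.seed(2)
  vals <- stats::rnorm(10, -2000, 50)
  res10 <- lapply(vals, function(v) list(log_marginal_likelihood = v, sd = 1))
  names(res10) <- paste0("m", 1:10)
  tbl10 <- build_comparison_table(res10)
  expect_equal(tbl10$log_marginal_likelihood, sort(vals, decreasing = TRUE))
  expect_error(build_comparison_table(res10[c(1, 1)]), "unique")
})

test_that("adding an ascertainment-corrected concept lowers the evidence", {
  tree <- kartvelian_reference_tree(seed = 1)
  cm <- simulate_cognate_matrix(tree, sim_config(21, cognates = list(
    n_concepts = 8)))
  cma <- add_ascertainment_columns(cm)
  cal <- calibration_set(node_calibrations = list(
    list(tips = c("Megrelian", "Laz"), mean = 1200, sigma = 10)))
  run_for <- function(m) {
    nested_sampling_phylo(m, substitution_model("ctmc"),
                          clock_model("strict", 2.5e-4), cal,
                          n_particles = 6, subchain_length = 8,
                          prior_spacing = 60, tol = 1e-4, seed = 3)
  }
  full <- run_for(cma)
  # drop the last concept entirely
  keep <- cma$columns$concept_id != tail(concepts(cma), 1)
  smaller <- cognate_matrix(cma$cells[, keep], cma$columns[keep, ],
                            cma$tip_dates)
  part <- run_for(smaller)
  expect_lt(full$log_marginal_likelihood, part$log_marginal_likelihood)
})

test_that("model ranking on covarion-generated data favours the covarion", {
  # reduced-scale replicate study: covarion vs CTMC vs stochastic Dollo
  tree <- kartvelian_reference_tree(seed = 1)
  cal <- calibration_set(node_calibrations = list(
    list(tips = c("Megrelian", "Laz"), mean = 1200, sigma = 10)))
  n_rep <- 6
  wins <- c(covarion = 0, ctmc = 0, sdollo = 0)
  logml <- matrix(NA_real_, n_rep, 3,
                  dimnames = list(NULL, c("covarion", "ctmc", "sdollo")))
  for (r in seq_len(n_rep)) {
    cm <- simulate_cognate_matrix(
      tree, sim_config(500 + r, cognates = list(n_concepts = 25)))
    cma <- add_ascertainment_columns(cm)
    for (kind in colnames(logml)) {
      res <- nested_sampling_phylo(
        cma, substitution_model(kind), clock_model("ucln", 2.5e-4), cal,
        n_particles = 8, subchain_length = 12, prior_spacing = 40,
        tol = 1e-4, seed = 700 + r)
      logml[r, kind] <- res$log_marginal_likelihood
    }
    winner <- colnames(logml)[which.max(logml[r, ])]
    wins[winner] <- wins[winner] + 1
  }
  # the generating model wins more replicates than any other configuration
  expect_equal(names(which.max(wins)), "covarion")
  # the stochastic Dollo misfit is unambiguous
  expect_lt(mean(logml[, "sdollo"]), mean(logml[, "covarion"]))
})
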