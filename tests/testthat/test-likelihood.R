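test_that("two-tip CTMC column matches the closed form", {
  tr <- two_tip_tree()
  m <- tiny_matrix(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  clock <- clock_model("strict", rate = 2e-4)
  mod <- substitution_model("ctmc", freq_present = 0.6)
  ll <- dataset_loglikelihood(tr, m, mod, clock)
  P <- ctmc_transition_matrix(2e-4, 1000, c(0.4, 0.6))
  expect_equal(ll, log(0.4 * P[1, 2]^2 + 0.6 * P[2, 2]^2), tolerance = 1e-12)
})

test_that("all-'?' columns contribute nothing", {
  tr <- two_tip_tree()
  cells <- matrix(c(1L, 0L, NA, NA), 2, 2, dimnames = list(c("A", "B"), NULL))
  m_with <- tiny_matrix(cells)
  m_without <- tiny_matrix(cells[, 1, drop = FALSE])
  clock <- clock_model("strict", rate = 2e-4)
  mod <- substitution_model("ctmc")
  expect_equal(dataset_loglikelihood(tr, m_with, mod, clock),
               dataset_loglikelihood(tr, m_without, mod, clock))
})

test_that("ascertainment correction follows -n log(1 - P0) and adds n log 2 at P0 = 1/2", {
  tr <- two_tip_tree()
  cells <- matrix(c(1L, 1L, 1L, 0L, 0L, 1L), 2, 3,
                  dimnames = list(c("A", "B"), NULL))
  m <- tiny_matrix(cells)
  ma <- add_ascertainment_columns(m)
  clock <- clock_model("strict", rate = 2e-4)
  mod <- substitution_model("ctmc", freq_present = 0.6)
  P <- ctmc_transition_matrix(2e-4, 1000, c(0.4, 0.6))
  P0 <- 0.4 * P[1, 1]^2 + 0.6 * P[2, 1]^2
  expect_equal(dataset_loglikelihood(tr, ma, mod, clock),
               dataset_loglikelihood(tr, m, mod, clock) - 3 * log(1 - P0),
               tolerance = 1e-12)
  # find a branch length with P(all absent) exactly 1/2 (presence frequency
  # 0.25 makes that attainable); the correction for three columns is then
  # exactly 3 log 2
  p0_at <- function(t) {
    P <- ctmc_transition_matrix(2e-4, t, c(0.65, 0.35))
    0.65 * P[1, 1]^2 + 0.35 * P[2, 1]^2
  }
  # P(all absent) runs from pi0 at t = 0 down to pi0^2 = 0.4225, so it
  # crosses one half at a finite branch length
  t_half <- stats::uniroot(function(t) p0_at(t) - 0.5, c(1, 1e6))$root
  tr2 <- two_tip_tree(t_half, t_half)
  m2 <- tiny_matrix(cells)
  m2a <- add_ascertainment_columns(m2)
  mod2 <- substitution_model("ctmc", freq_present = 0.35)
  expect_equal(
    dataset_loglikelihood(tr2, m2a, mod2, clock) -
      dataset_loglikelihood(tr2, m2, mod2, clock),
    3 * log(2), tolerance = 1e-6
  )
})

test_that("ascertainment correction strictly increases the log-likelihood", {
  for (seed in 1:4) {
    m <- random_cognate_matrix(seed, n_concepts = 5, n_langs = 3)
    tr <- three_tip_tree()
    rownames(m$cells) <- tr$tip.label
    names(m$tip_dates) <- tr$tip.label
    ma <- add_ascertainment_columns(m)
    clock <- clock_model("strict", rate = 3e-4)
    mod <- substitution_model("covarion")
    expect_gt(dataset_loglikelihood(tr, ma, mod, clock),
              dataset_loglikelihood(tr, m, mod, clock))
  }
})

test_that("likelihood is invariant to consistent tip relabeling", {
  tr <- three_tip_tree()
  cells <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2,
                  dimnames = list(c("A", "B", "C"), NULL))
  m <- tiny_matrix(cells)
  clock <- clock_model("strict", rate = 2e-4)
  mod <- substitution_model("covarion")
  ll1 <- dataset_loglikelihood(tr, m, mod, clock)
  # permute rows of the matrix; trees match by label, so nothing changes
  m2 <- m
  perm <- c(3, 1, 2)
  m2$cells <- m$cells[perm, ]
  m2$tip_dates <- m$tip_dates[perm]
  expect_equal(dataset_loglikelihood(tr, m2, mod, clock), ll1,
               tolerance = 1e-10)
})

test_that("CTMC likelihood depends only on path length between two tips (reversibility)", {
  cells <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("A", "B"), NULL))
  m <- tiny_matrix(cells)
  clock <- clock_model("strict", rate = 2e-4)
  mod <- substitution_model("ctmc", freq_present = 0.3)
  ll_mid <- dataset_loglikelihood(two_tip_tree(1000, 1000), m, mod, clock)
  # move the root along the path using branch-rate multipliers that keep the
  # total substitution length fixed
  ll_off <- dataset_loglikelihood(two_tip_tree(1000, 1000), m, mod, clock,
                                  branch_rates = c(1.6, 0.4))
  expect_equal(ll_mid, ll_off, tolerance = 1e-8)
})

test_that("stochastic Dollo matches a direct birth-position integration oracle", {
  tr <- two_tip_tree()
  clock <- clock_model("strict", rate = 2e-4)
  mu <- 0.8
  mod <- substitution_model("sdollo", death_rate = mu)
  b <- 0.2  # branch length in substitution units
  IA <- (1 - exp(-mu * b)) / mu
  IB <- b - IA
  M <- 2 * b + 1 / mu
  m_zero <- 2 * IB + (1 - exp(-mu * b))^2 / mu
  # pattern (1,1): birth must be on the stem and survive both branches;
  # integrate the stem survival numerically as an independent oracle
  stem <- stats::integrate(function(h) exp(-mu * h), 0, Inf)$value
  m11 <- exp(-2 * mu * b) * stem
  ll11 <- dataset_loglikelihood(
    tr, tiny_matrix(matrix(c(1L, 1L), 2, 1,
                           dimnames = list(c("A", "B"), NULL))), mod, clock)
  expect_equal(ll11, log(m11 / (M - m_zero)), tolerance = 1e-8)
  # pattern (1,0): birth on A's branch (integrated numerically), or above the
  # root with death on the way to B
  mA <- stats::integrate(function(h) exp(-mu * h), 0, b)$value
  m_stem <- stats::integrate(function(h) exp(-mu * h), 0, Inf)$value *
    exp(-mu * b) * (1 - exp(-mu * b))
  ll10 <- dataset_loglikelihood(
    tr, tiny_matrix(matrix(c(1L, 0L), 2, 1,
                           dimnames = list(c("A", "B"), NULL))), mod, clock)
  expect_equal(ll10, log((mA + m_stem) / (M - m_zero)), tolerance = 1e-8)
})

test_that("stochastic Dollo likelihood vanishes as the death rate explodes", {
  tr <- two_tip_tree()
  m <- tiny_matrix(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  clock <- clock_model("strict", rate = 2e-4)
  lls <- vapply(c(1, 10, 100), function(mu) {
    dataset_loglikelihood(tr, m, substitution_model("sdollo", death_rate = mu),
                          clock)
  }, 0)
  expect_true(all(diff(lls) < 0))
  expect_lt(lls[3], -8)
})
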