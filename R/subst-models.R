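#' Substitution models for binary cognate data
#'
#' Three models of cognate gain and loss are supported:
#' * `"ctmc"` — reversible two-state chain with stationary presence frequency
#'   `freq_present`, the binary analogue of simple nucleotide substitution.
#' * `"covarion"` — the two-state covarion: each cognate set carries a hidden
#'   slow/fast regime; within the slow regime substitutions run at relative
#'   rate `slow_fraction` (alpha in (0,1]), within the fast regime at rate 1,
#'   and the hidden regime switches at rate `switch_rate` without changing the
#'   visible state. Hidden equilibrium frequencies are equal.
#' * `"sdollo"` — stochastic Dollo: a cognate set is born exactly once on the
#'   tree (intensity `birth_intensity` per year) and is lost independently at
#'   rate `death_rate` thereafter; it can never be regained.
#'
#' CTMC and covarion generators are normalized so the expected visible
#' substitution rate at stationarity is 1; absolute time scaling lives in the
#' clock model. Optional discrete-gamma rate heterogeneity across cognate sets
#' (`gamma_categories` 1 or 4) and per-concept rate multipliers (mean one)
#' apply to `"ctmc"` and `"covarion"`.
#'
#' @param kind `"ctmc"`, `"covarion"` or `"sdollo"`
#' @param freq_present stationary frequency of the present state, in (0,1)
#' @param switch_rate covarion hidden-regime switch rate (> 0), relative to
#'   the unit substitution rate
#' @param slow_fraction covarion slow-regime relative rate, in (0, 1]
#' @param death_rate stochastic Dollo loss rate, per unit clock time (> 0)
#' @param birth_intensity stochastic Dollo birth intensity; cancels from the
#'   observability-conditioned likelihood but kept for completeness
#' @param gamma_categories 1 (off) or 4 discrete-gamma rate categories
#' @param gamma_shape gamma shape parameter (> 0)
#' @return an object of class `subst_model`
#' @export
substitution_model <- function(kind = c("ctmc", "covarion", "sdollo"),
                               freq_present = 0.5,
                               switch_rate = 0.5,
                               slow_fraction = 0.5,
                               death_rate = 1,
                               birth_intensity = 1,
                               gamma_categories = 1L,
                               gamma_shape = 1) {
  kind <- match.arg(kind)
  stopifnot(freq_present > 0, freq_present < 1, gamma_categories %in% c(1L, 4L),
            gamma_shape > 0)
  if (kind == "covarion") {
    if (slow_fraction <= 0 || slow_fraction > 1) {
      stop("slow_fraction must be in (0, 1]", call. = FALSE)
    }
    if (switch_rate <= 0) stop("switch_rate must be > 0", call. = FALSE)
  }
  if (kind == "sdollo" && death_rate <= 0) {
    stop("death_rate must be > 0", call. = FALSE)
  }
  structure(list(
    kind = kind, freq_present = freq_present, switch_rate = switch_rate,
    slow_fraction = slow_fraction, death_rate = death_rate,
    birth_intensity = birth_intensity,
    gamma_categories = as.integer(gamma_categories), gamma_shape = gamma_shape
  ), class = "subst_model")
}

#' Two-state transition probability matrix
#'
#' Closed-form matrix exponential of the reversible binary generator
#' normalized to unit expected substitution rate:
#' `P[i, j](t) = pi_j + (delta_ij - pi_j) exp(-t / (2 pi_0 pi_1))`.
#'
#' @param rate rate multiplier (substitutions per year once multiplied by
#'   branch time)
#' @param t elapsed time (years); `rate * t` is the branch length in expected
#'   substitutions
#' @param freqs stationary frequencies `c(pi0, pi1)`
#' @return 2x2 stochastic matrix, rows = from-state (0, 1).
#' @export
ctmc_transition_matrix <- function(rate, t, freqs = c(0.5, 0.5)) {
  if (t < 0) stop("negative time", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  stopifnot(length(freqs) == 2, all(freqs > 0), abs(sum(freqs) - 1) < 1e-12)
  beta <- 1 / (2 * freqs[1] * freqs[2])
  decay <- exp(-beta * rate * t)
  P <- matrix(c(
    freqs[1] + freqs[2] * decay, freqs[1] * (1 - decay),
    freqs[2] * (1 - decay), freqs[2] + freqs[1] * decay
  ), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  P
}

#' Covarion rate matrix
#'
#' @param model a covarion [substitution_model()]
#' @return 4x4 generator over states (0-slow, 1-slow, 0-fast, 1-fast), rows
#'   summing to zero, normalized to unit expected visible substitution rate at
#'   stationarity.
#' @export
covarion_generator <- function(model) {
  stopifnot(inherits(model, "subst_model"), model$kind == "covarion")
  p0 <- 1 - model$freq_present
  p1 <- model$freq_present
  a <- model$slow_fraction
  s <- model$switch_rate
  Q <- matrix(0, 4, 4,
              dimnames = rep(list(c("0s", "1s", "0f", "1f")), 2))
  Q["0s", "1s"] <- a * p1; Q["1s", "0s"] <- a * p0
  Q["0f", "1f"] <- p1;     Q["1f", "0f"] <- p0
  Q["0s", "0f"] <- s; Q["0f", "0s"] <- s
  Q["1s", "1f"] <- s; Q["1f", "1s"] <- s
  diag(Q) <- -rowSums(Q)
  # stationary distribution is (p0, p1, p0, p1) / 2; expected visible rate:
  norm <- p0 * p1 * (a + 1)
  Q / norm
}

#' Stationary frequencies of the covarion chain
#' @param model a covarion [substitution_model()]
#' @return length-4 probability vector over (0s, 1s, 0f, 1f).
#' @export
covarion_frequencies <- function(model) {
  c(1 - model$freq_present, model$freq_present,
    1 - model$freq_present, model$freq_present) / 2
}

#' Discrete-gamma rate categories
#'
#' Mean-one category rates using the equal-probability quantile-mean
#' construction.
#'
#' @param shape gamma shape (> 0)
#' @param k number of categories
#' @return length-`k` vector of rates with mean 1.
#' @export
discrete_gamma <- function(shape, k = 4L) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape, shape)
  bounds <- c(0, q, Inf)
  upper <- stats::pgamma(bounds[-1], shape + 1, shape)
  lower <- stats::pgamma(bounds[-(k + 1)], shape + 1, shape)
  r <- (upper - lower) * k
  r / mean(r)
}

#' Clock models
#'
#' @param kind `"strict"` (one rate for every branch) or `"ucln"`
#'   (branch rates drawn independently from a lognormal with real-space mean
#'   `rate` and log-space standard deviation `sd_log`).
#' @param rate substitutions per year (strict rate, or ucln real-space mean)
#' @param sd_log ucln log-space standard deviation (>= 0)
#' @return an object of class `clock_model`
#' @export
clock_model <- function(kind = c("strict", "ucln"), rate = 1e-4, sd_log = 0.3) {
  kind <- match.arg(kind)
  stopifnot(rate > 0)
  if (sd_log < 0) stop("sd_log must be >= 0", call. = FALSE)
  structure(list(kind = kind, rate = rate,
                 sd_log = if (kind == "strict") 0 else sd_log),
            class = "clock_model")
}

#' Log-density of branch rates under a clock model
#'
#' Under the uncorrelated-lognormal clock, branch rates are iid lognormal
#' with real-space mean `rate` (so meanlog = log(rate) - sd_log^2 / 2). Under
#' the strict clock the rates must all equal `rate` exactly.
#'
#' @param rates positive per-branch rate vector
#' @param clock a [clock_model()]
#' @return log density (0 for a valid strict-clock configuration).
#' @export
clock_prior_logdensity <- function(rates, clock) {
  stopifnot(all(rates > 0))
  if (clock$kind == "strict") {
    if (any(abs(rates - clock$rate) > 1e-12 * clock$rate)) {
      stop("strict clock requires all branch rates equal to the clock rate",
           call. = FALSE)
    }
    return(0)
  }
  if (clock$sd_log == 0) {
    return(if (all(abs(rates - clock$rate) < 1e-9 * clock$rate)) 0 else -Inf)
  }
  meanlog <- log(clock$rate) - clock$sd_log^2 / 2
  sum(stats::dlnorm(rates, meanlog, clock$sd_log, log = TRUE))
}

#' Draw branch rates from a clock model
#' @param n number of branches
#' @param clock a [clock_model()]
#' @return vector of `n` positive rates.
#' @export
sample_branch_rates <- function(n, clock) {
  if (clock$kind == "strict" || clock$sd_log == 0) return(rep(clock$rate, n))
  meanlog <- log(clock$rate) - clock$sd_log^2 / 2
  stats::rlnorm(n, meanlog, clock$sd_log)
}
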