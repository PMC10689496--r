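#' Nested-sampling marginal likelihood estimation
#'
#' Classic nested sampling: `n_particles` draws from the prior are iteratively
#' contracted by replacing the worst (lowest-likelihood) particle with a new
#' prior draw constrained to exceed the current likelihood floor, obtained by
#' evolving a surviving particle with a prior-invariant MCMC kernel.
#' Prior-mass shrinkage uses the deterministic schedule `X_i = exp(-i / N)`.
#' The run terminates when the maximum remaining contribution
#' `max(L) * X_i` falls below `tol` times the accumulated evidence, and the
#' surviving particles' average tops up the estimate. The standard deviation
#' is the information-based `sqrt(H / N)`.
#'
#' @param log_lik function(state) -> log-likelihood
#' @param sample_prior function() -> a fresh prior draw
#' @param kernel function(state, log_lik_floor) -> a new state distributed
#'   according to the prior truncated to `log_lik(state) > floor` (an MCMC
#'   kernel started from `state`)
#' @param n_particles number of live particles (>= 2)
#' @param tol termination tolerance on the remaining-evidence fraction
#' @param seed integer seed
#' @param max_iter safety cap on iterations
#' @return object of class `nested_sampling_result`: `log_marginal_likelihood`,
#'   `sd`, `n_particles`, `n_iterations`, `information`, and the
#'   log-likelihood `ladder`.
#' @export
nested_sampling <- function(log_lik, sample_prior, kernel, n_particles = 20,
                            tol = 1e-6, seed = 1L, max_iter = 100000) {
  if (n_particles < 2) stop("need at least 2 particles", call. = FALSE)
  set.seed(seed)
  particles <- lapply(seq_len(n_particles), function(i) sample_prior())
  logls <- vapply(particles, log_lik, 0)
  if (any(is.nan(logls) | logls == Inf)) stop("invalid likelihood", call. = FALSE)
  N <- n_particles
  ladder <- numeric(0)
  log_x_prev <- 0
  log_z <- -Inf
  for (i in seq_len(max_iter)) {
    worst <- which.min(logls)
    l_star <- logls[worst]
    ladder <- c(ladder, l_star)
    log_x <- -i / N
    log_w <- log_diff_exp(log_x_prev, log_x)
    log_z <- log_sum_exp(c(log_z, l_star + log_w))
    log_x_prev <- log_x
    # termination: remaining mass cannot move the estimate by more than tol
    if (max(logls) + log_x - log_z < log(tol)) break
    seed_idx <- if (N > 1) safe_pick(setdiff(seq_len(N), worst)) else worst
    particles[[worst]] <- kernel(particles[[seed_idx]], l_star)
    logls[worst] <- log_lik(particles[[worst]])
    if (logls[worst] <= l_star) {
      # kernel failed to exceed the floor; keep the seed particle instead
      particles[[worst]] <- particles[[seed_idx]]
      logls[worst] <- logls[seed_idx]
    }
  }
  # top-up with the surviving particles at the final prior mass
  log_z <- log_sum_exp(c(log_z, log_x_prev - log(N) + logls))
  # information H and its sd estimate
  all_logl <- c(ladder, logls)
  all_logw <- c(
    vapply(seq_along(ladder),
           function(i) log_diff_exp(-(i - 1) / N, -i / N), 0),
    rep(log_x_prev - log(N), N)
  )
  p <- exp(all_logw + all_logl - log_z)
  h_terms <- ifelse(p > 0, p * (all_logl - log_z), 0)
  H <- sum(h_terms)
  structure(list(
    log_marginal_likelihood = log_z,
    sd = sqrt(max(H, 0) / N),
    n_particles = N,
    n_iterations = length(ladder),
    information = H,
    ladder = ladder
  ), class = "nested_sampling_result")
}

log_diff_exp <- function(a, b) {
  # log(exp(a) - exp(b)), a > b
  a + log1p(-exp(b - a))
}

#' @export
print.nested_sampling_result <- function(x, ...) {
  cat(sprintf("<nested_sampling> logML = %.3f (sd %.3f), %d particles, %d iterations\n",
              x$log_marginal_likelihood, x$sd, x$n_particles, x$n_iterations))
  invisible(x)
}

#' Nested sampling for a phylogenetic model configuration
#'
#' Runs [nested_sampling()] over the full tip-dated model state (tree, ages,
#' clock, substitution and tree-prior parameters) of [run_mcmc()]. Prior
#' particles come from spaced draws of a prior-only chain; the constrained
#' kernel applies `subchain_length` ordinary proposals, accepting only moves
#' that keep the likelihood above the current floor.
#'
#' @inheritParams run_mcmc
#' @param n_particles live particles (the study setting is 20)
#' @param subchain_length proposals per constrained-kernel invocation
#' @param tol termination tolerance
#' @param seed integer seed
#' @param prior_spacing prior-only proposals between particle initializations
#' @return a `nested_sampling_result`.
#' @export
nested_sampling_phylo <- function(m, model, clock, cal = calibration_set(),
                                  priors = phylo_priors(), n_particles = 20,
                                  subchain_length = 100, tol = 1e-6,
                                  seed = 1L, prior_spacing = 200,
                                  concept_rates = FALSE) {
  set.seed(seed)
  pack <- build_data_pack(m, model)
  tun <- mcmc_config()$tuning
  make_state <- function() {
    st <- new_state(m, model, clock, cal, priors, concept_rates)
    if (concept_rates) st$concept_rates <- rep(1, pack$n_concepts)
    st
  }
  prior_step <- function(st, lp, floor_ll = NULL) {
    prop <- propose(st, pack, tun, cal, priors)
    if (is.null(prop)) return(list(st = st, lp = lp))
    lp_new <- state_logprior(prop$state, pack, cal, priors)
    if (!is.finite(lp_new)) return(list(st = st, lp = lp))
    if (log(stats::runif(1)) >= lp_new - lp + prop$log_hr) {
      return(list(st = st, lp = lp))
    }
    if (!is.null(floor_ll) && prop$affects_lik) {
      if (state_loglik(prop$state, pack) <= floor_ll) {
        return(list(st = st, lp = lp))
      }
    }
    list(st = prop$state, lp = lp_new)
  }
  # one long prior-only chain supplies the initial particles
  cur <- make_state()
  cur_lp <- state_logprior(cur, pack, cal, priors)
  tries <- 0
  while (!is.finite(cur_lp) && tries < 50) {
    cur <- make_state(); cur_lp <- state_logprior(cur, pack, cal, priors)
    tries <- tries + 1
  }
  sample_prior <- function() {
    for (i in seq_len(prior_spacing)) {
      res <- prior_step(cur, cur_lp)
      cur <<- res$st; cur_lp <<- res$lp
    }
    cur
  }
  kernel <- function(st, floor_ll) {
    lp <- state_logprior(st, pack, cal, priors)
    for (i in seq_len(subchain_length)) {
      res <- prior_step(st, lp, floor_ll)
      st <- res$st; lp <- res$lp
    }
    st
  }
  nested_sampling(
    log_lik = function(st) state_loglik(st, pack),
    sample_prior = sample_prior,
    kernel = kernel,
    n_particles = n_particles, tol = tol, seed = seed + 1L
  )
}

#' Bayes factor from two log marginal likelihoods
#'
#' @param logml_a,logml_b log marginal likelihoods of models A and B
#' @return list with `bf`, `log_bf` (`logml_a - logml_b`) and `verdict`
#'   (`"very strong"` when `log_bf >= 5`, the conventional threshold,
#'   inclusive).
#' @export
bayes_factor <- function(logml_a, logml_b) {
  stopifnot(is.finite(logml_a), is.finite(logml_b))
  log_bf <- logml_a - logml_b
  list(bf = exp(log_bf), log_bf = log_bf,
       verdict = if (log_bf >= 5) "very strong" else "not very strong")
}

#' Model comparison table
#'
#' @param results named list of `nested_sampling_result` objects (or of lists
#'   with `log_marginal_likelihood` and `sd`); names are the model labels
#' @return tibble sorted by log marginal likelihood (descending) with Bayes
#'   factors against the best model (`log_bf` is 0 for the top row).
#' @export
build_comparison_table <- function(results) {
  if (length(results) < 2) stop("need at least two results", call. = FALSE)
  if (is.null(names(results)) || anyDuplicated(names(results))) {
    stop("results must have unique labels", call. = FALSE)
  }
  tbl <- tibble::tibble(
    model = names(results),
    log_marginal_likelihood =
      unname(vapply(results, `[[`, 0, "log_marginal_likelihood")),
    sd = unname(vapply(results, `[[`, 0, "sd"))
  )
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$log_marginal_likelihood))
  tbl$log_bf <- tbl$log_marginal_likelihood[1] - tbl$log_marginal_likelihood
  tbl$bayes_factor <- exp(tbl$log_bf)
  tbl$support <- ifelse(tbl$log_bf == 0, "best",
                        ifelse(tbl$log_bf >= 5, "very strong against",
                               "indecisive"))
  tbl
}

#' @export
glance.nested_sampling_result <- function(x, ...) {
  tibble::tibble(
    log_marginal_likelihood = x$log_marginal_likelihood,
    sd = x$sd,
    n_particles = x$n_particles,
    n_iterations = x$n_iterations,
    information = x$information
  )
}
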