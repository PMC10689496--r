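#' MCMC run configuration
#'
#' @param n_generations number of proposals
#' @param thin trace/tree sampling interval (must divide reporting; samples
#'   are taken at generations `thin, 2*thin, ...`)
#' @param burnin_fraction fraction of samples discarded from the front
#' @param seed integer seed
#' @param sample_likelihood `FALSE` runs the chain on the prior alone
#'   (likelihood identically 0), used for prior-recovery checks
#' @param tuning named list of proposal step sizes (see Details)
#' @return object of class `mcmc_config`
#' @details Tuning entries (all optional): `age_window` is unused (age moves
#'   are uniform within their bounds), `scale` is the log-scale half-width of
#'   multiplier proposals, `slide` the half-width of bounded slides.
#' @export
mcmc_config <- function(n_generations = 1e5, thin = 100,
                        burnin_fraction = 0.1, seed = 1L,
                        sample_likelihood = TRUE, tuning = list()) {
  if (thin <= 0) stop("thin must be positive", call. = FALSE)
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)", call. = FALSE)
  }
  tun <- utils::modifyList(list(scale = 0.4, slide = 0.1), tuning)
  structure(list(n_generations = n_generations, thin = thin,
                 burnin_fraction = burnin_fraction, seed = as.integer(seed),
                 sample_likelihood = sample_likelihood, tuning = tun),
            class = "mcmc_config")
}

#' Prior configuration for tip-dated inference
#'
#' Hyperpriors for the parameters the chain samples. Defaults: tree-wide
#' diversification (birth minus death, per year) lognormal(log 2e-4, 1.5) —
#' centred on the 1e-4/year scale typical of language families rather than on
#' biological speciation rates, so the weakly identified root age is not
#' squeezed toward the present — turnover
#' Uniform(0,1), fossil-sampling proportion Beta(1,1), extant sampling fixed
#' at 1; clock rate lognormal(log(2.5e-4), 1.5); relaxed-clock log-sd
#' Exponential(mean 1/3); covarion switch rate lognormal(log 0.1, 1.5),
#' centred below the substitution rate because occasional regime switching is
#' the covarion's defining behaviour; visible
#' frequencies and the slow fraction Uniform(0,1); gamma shape and Dollo
#' death rate lognormal(0, 1); per-concept rates lognormal(0, 0.5) under a
#' mean-one delta-exchange constraint.
#'
#' @param ... overrides of the defaults listed above
#' @return a named list of class `phylo_priors`
#' @export
phylo_priors <- function(...) {
  p <- list(
    diversification_meanlog = log(2e-4), diversification_sdlog = 1.5,
    clock_rate_meanlog = log(2.5e-4), clock_rate_sdlog = 1.5,
    ucln_sd_mean = 1 / 3,
    switch_rate_meanlog = log(0.1), switch_rate_sdlog = 1.5,
    gamma_shape_meanlog = 0, gamma_shape_sdlog = 1,
    death_rate_meanlog = 0, death_rate_sdlog = 1,
    concept_rate_sdlog = 0.5,
    rho = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown prior field: ", bad[1], call. = FALSE)
  p[names(over)] <- over
  structure(p, class = "phylo_priors")
}

# ---- internal sampler state ------------------------------------------------

new_state <- function(m, model, clock, cal, priors, use_concept_rates) {
  langs <- languages(m)
  ntip <- length(langs)
  tip_ages <- unname(m$tip_dates[langs])
  n_node <- 2L * ntip - 1L
  parent <- integer(n_node)
  ages <- c(tip_ages, rep(NA_real_, ntip - 1L))

  # pre-join calibrated clades near their calibration mean, then join the
  # remaining units at increasing ages
  units <- lapply(seq_len(ntip),
                  function(i) list(node = i, tips = i, top = tip_ages[i]))
  next_node <- ntip + 1L
  join <- function(i, j, age) {
    id <- next_node
    next_node <<- next_node + 1L
    parent[units[[i]]$node] <<- id
    parent[units[[j]]$node] <<- id
    ages[id] <<- age
    units[[i]] <<- list(node = id,
                        tips = sort(c(units[[i]]$tips, units[[j]]$tips)),
                        top = age)
    units[[j]] <<- NULL
  }
  for (nc in cal$nodes) {
    idx <- sort(match(nc$tips, langs))
    repeat {
      ui <- which(vapply(units, function(u) all(u$tips %in% idx), TRUE))
      if (length(ui) <= 1) break
      age <- max(units[[ui[1]]]$top, units[[ui[2]]]$top) + stats::runif(1, 1, 20)
      closes <- length(ui) == 2
      if (closes) age <- max(age, nc$mean + stats::rnorm(1, 0, nc$sigma / 4))
      join(ui[1], ui[2], age)
    }
  }
  while (length(units) > 1) {
    tops <- vapply(units, `[[`, 0, "top")
    o <- order(tops)
    i <- o[1]; j <- o[2]
    age <- max(tops[i], tops[j]) + stats::runif(1, 200, 1500)
    join(i, j, age)
  }
  st <- list(
    ntip = ntip, n_node = n_node, parent = parent, ages = ages,
    tip_labels = langs, tip_ages = tip_ages,
    clock_rate = clock$rate,
    clock_sd = if (clock$kind == "ucln") max(clock$sd_log, 0.1) else 0,
    relaxed = clock$kind == "ucln",
    rate_mult = rep(1, n_node),
    freq_present = model$freq_present,
    switch_rate = model$switch_rate,
    slow_fraction = model$slow_fraction,
    gamma_shape = model$gamma_shape,
    death_rate = model$death_rate,
    concept_rates = NULL,
    d = exp(priors$diversification_meanlog), nu = 0.3, s = 0.5
  )
  st$kids <- children_list(parent, n_node)
  st
}

state_clade_tips <- function(st, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= st$ntip) out <- c(out, v) else stack <- c(stack, st$kids[[v]])
  }
  sort(out)
}

children_list <- function(parent, n_node) {
  kids <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    p <- parent[v]
    if (p > 0) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

state_root <- function(st) which(st$parent == 0L)

state_edges <- function(st) {
  child <- setdiff(seq_len(st$n_node), state_root(st))
  child <- child[order(st$ages[child])]
  cbind(st$parent[child], child)
}

state_to_phylo <- function(st) {
  edges <- state_edges(st)
  root <- state_root(st)
  internal <- c(root, setdiff((st$ntip + 1L):st$n_node, root))
  remap <- integer(st$n_node)
  remap[seq_len(st$ntip)] <- seq_len(st$ntip)
  remap[internal] <- st$ntip + seq_along(internal)
  phy <- structure(list(
    edge = cbind(remap[edges[, 1]], remap[edges[, 2]]),
    edge.length = st$ages[edges[, 1]] - st$ages[edges[, 2]],
    tip.label = st$tip_labels,
    Nnode = st$ntip - 1L
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

state_loglik <- function(st, pack) {
  edges <- state_edges(st)
  blen <- (st$ages[edges[, 1]] - st$ages[edges[, 2]]) * st$clock_rate *
    st$rate_mult[edges[, 2]]
  gamma_rates <- discrete_gamma(st$gamma_shape, pack$gamma_categories)
  cr <- st$concept_rates %||% rep(1, pack$n_concepts)
  if (pack$kind == "sdollo") {
    sdollo_loglik_cpp(edges, st$ntip, st$n_node, blen, pack$dat,
                      pack$concept_idx, pack$is_asc, cr, st$death_rate,
                      gamma_rates)
  } else {
    cognate_loglik_cpp(edges, st$ntip, st$n_node, blen, pack$dat,
                       pack$concept_idx, pack$is_asc, cr,
                       if (pack$kind == "ctmc") 0L else 1L,
                       c(st$freq_present, st$switch_rate, st$slow_fraction),
                       gamma_rates)
  }
}

state_fbd_logdensity <- function(st, priors) {
  lambda <- st$d / (1 - st$nu)
  mu <- lambda * st$nu
  psi <- if (st$s >= 1) Inf else mu * st$s / (1 - st$s)
  fossil <- which(st$tip_ages > 1e-8)
  if (length(fossil) && psi <= 0) return(-Inf)
  p <- list(lambda = lambda, mu = mu, psi = psi, rho = priors$rho)
  internal <- (st$ntip + 1L):st$n_node
  root <- state_root(st)
  root_age <- st$ages[root]
  others <- st$ages[setdiff(internal, root)]
  ld <- 2 * fbd_log_q(root_age, p) +
    sum(log(p$lambda) + fbd_log_q(others, p)) +
    sum(st$tip_ages <= 1e-8) * log(p$rho)
  if (length(fossil)) {
    p0 <- fbd_p0(st$tip_ages[fossil], p)
    if (any(p0 <= 0)) return(-Inf)
    ld <- ld + sum(log(psi) + log(p0) - fbd_log_q(st$tip_ages[fossil], p))
  }
  ld
}

state_logprior <- function(st, pack, cal, priors) {
  lp <- state_fbd_logdensity(st, priors)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + stats::dlnorm(st$d, priors$diversification_meanlog,
                           priors$diversification_sdlog, log = TRUE)
  # turnover ~ U(0,1), sampling proportion ~ Beta(1,1): flat, bounds checked
  if (st$nu < 0 || st$nu >= 1 || st$s <= 0 || st$s >= 1) return(-Inf)
  lp <- lp + stats::dlnorm(st$clock_rate, priors$clock_rate_meanlog,
                           priors$clock_rate_sdlog, log = TRUE)
  if (st$relaxed) {
    if (st$clock_sd <= 0) return(-Inf)
    lp <- lp + stats::dexp(st$clock_sd, 1 / priors$ucln_sd_mean, log = TRUE)
    mult <- st$rate_mult[-state_root(st)]
    lp <- lp + sum(stats::dlnorm(mult, -st$clock_sd^2 / 2, st$clock_sd,
                                 log = TRUE))
  }
  if (pack$kind == "covarion") {
    if (st$freq_present <= 0 || st$freq_present >= 1 ||
        st$slow_fraction <= 0 || st$slow_fraction > 1) return(-Inf)
    lp <- lp + stats::dlnorm(st$switch_rate, priors$switch_rate_meanlog,
                             priors$switch_rate_sdlog, log = TRUE)
  }
  if (pack$kind == "ctmc" &&
      (st$freq_present <= 0 || st$freq_present >= 1)) return(-Inf)
  if (pack$gamma_categories > 1) {
    lp <- lp + stats::dlnorm(st$gamma_shape, priors$gamma_shape_meanlog,
                             priors$gamma_shape_sdlog, log = TRUE)
  }
  if (pack$kind == "sdollo") {
    lp <- lp + stats::dlnorm(st$death_rate, priors$death_rate_meanlog,
                             priors$death_rate_sdlog, log = TRUE)
  }
  if (!is.null(st$concept_rates)) {
    if (any(st$concept_rates <= 0)) return(-Inf)
    lp <- lp + sum(stats::dlnorm(st$concept_rates, 0,
                                 priors$concept_rate_sdlog, log = TRUE))
  }
  for (nc in cal$nodes) {
    idx <- sort(match(nc$tips, st$tip_labels))
    node <- state_mrca(st, idx)
    if (!identical(state_clade_tips(st, node), idx)) {
      return(-Inf)  # calibrated clade must be monophyletic
    }
    lp <- lp + stats::dnorm(st$ages[node], nc$mean, nc$sigma, log = TRUE)
  }
  lp
}

state_mrca <- function(st, tip_idx) {
  anc <- function(v) {
    out <- v
    while (st$parent[v] != 0L) { v <- st$parent[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(tip_idx, anc))
  common[1]
}

# ---- proposals -------------------------------------------------------------

propose <- function(st, pack, tun, cal = NULL, priors = NULL) {
  moves <- c("age", "age_local", "root", "updown", "exchange", "clock")
  w <- c(2, 2, 1, 2, 1.5, 1)
  if (!is.null(cal) && length(cal$nodes)) { moves <- c(moves, "cal_age"); w <- c(w, 1.5) }
  if (st$relaxed) {
    moves <- c(moves, "mult", "mult_indep", "ucln_sd")
    w <- c(w, 2, 1, 0.5)
  }
  if (pack$kind %in% c("ctmc", "covarion")) {
    moves <- c(moves, "freq"); w <- c(w, 0.4)
  }
  if (pack$kind == "covarion") {
    moves <- c(moves, "switch", "slow"); w <- c(w, 0.4, 0.4)
    if (!is.null(priors)) {
      # independence draws from the prior jump straight between switching
      # regimes instead of diffusing there
      moves <- c(moves, "switch_indep", "slow_indep"); w <- c(w, 0.3, 0.3)
    }
  }
  if (pack$kind == "sdollo") { moves <- c(moves, "death"); w <- c(w, 0.6) }
  if (pack$gamma_categories > 1) { moves <- c(moves, "shape"); w <- c(w, 0.4) }
  if (!is.null(st$concept_rates)) { moves <- c(moves, "crate"); w <- c(w, 1.5) }
  moves <- c(moves, "fbd_d", "fbd_nu", "fbd_s")
  w <- c(w, 0.4, 0.4, 0.4)
  mv <- sample(moves, 1, prob = w)
  log_hr <- 0
  affects_lik <- TRUE
  root <- state_root(st)
  internal <- (st$ntip + 1L):st$n_node
  switch(mv,
    age = {
      v <- safe_pick(setdiff(internal, root))
      lower <- max(st$ages[st$kids[[v]]])
      upper <- st$ages[st$parent[v]]
      st$ages[v] <- stats::runif(1, lower, upper)
    },
    age_local = {
      v <- safe_pick(setdiff(internal, root))
      lower <- max(st$ages[st$kids[[v]]])
      upper <- st$ages[st$parent[v]]
      cand <- st$ages[v] + stats::rnorm(1, 0, (upper - lower) / 20)
      if (cand <= lower || cand >= upper) return(NULL)
      st$ages[v] <- cand
    },
    cal_age = {
      nc <- cal$nodes[[safe_pick(seq_along(cal$nodes))]]
      v <- state_mrca(st, sort(match(nc$tips, st$tip_labels)))
      if (v == root) {
        lower <- max(st$ages[st$kids[[v]]]); upper <- Inf
      } else {
        lower <- max(st$ages[st$kids[[v]]])
        upper <- st$ages[st$parent[v]]
      }
      cand <- stats::rnorm(1, nc$mean, nc$sigma)
      if (cand <= lower || cand >= upper) return(NULL)
      log_hr <- stats::dnorm(st$ages[v], nc$mean, nc$sigma, log = TRUE) -
        stats::dnorm(cand, nc$mean, nc$sigma, log = TRUE)
      st$ages[v] <- cand
    },
    root = {
      lower <- max(st$ages[st$kids[[root]]])
      gap <- st$ages[root] - lower
      f <- exp(3 * tun$scale * (stats::runif(1) - 0.5))
      st$ages[root] <- lower + gap * f
      log_hr <- log(f)
    },
    updown = {
      # travel the tree-height / clock-rate ridge: stretch every
      # uncalibrated internal age while compressing the rate, leaving
      # expected substitution counts roughly stable
      pinned <- integer(0)
      if (!is.null(cal)) {
        pinned <- vapply(cal$nodes, function(nc) {
          state_mrca(st, sort(match(nc$tips, st$tip_labels)))
        }, 0L)
      }
      scale_set <- setdiff(internal, pinned)
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$ages[scale_set] <- st$ages[scale_set] * f
      st$clock_rate <- st$clock_rate / f
      bad <- any(st$ages[st$parent[st$parent > 0]] <=
                   st$ages[which(st$parent > 0)])
      if (bad) return(NULL)
      log_hr <- (length(scale_set) - 1) * log(f)
    },
    exchange = {
      cand <- setdiff(internal, root)
      v <- safe_pick(cand)
      p <- st$parent[v]
      sib <- setdiff(st$kids[[p]], v)
      c1 <- safe_pick(st$kids[[v]])
      if (st$ages[v] <= st$ages[sib]) return(NULL)  # invalid, reject
      # swap: c1 up to p, sib down to v
      st$parent[c1] <- p
      st$parent[sib] <- v
      st$kids[[p]] <- c(setdiff(st$kids[[p]], sib), c1)
      st$kids[[v]] <- c(setdiff(st$kids[[v]], c1), sib)
    },
    clock = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$clock_rate <- st$clock_rate * f
      log_hr <- log(f)
    },
    mult = {
      v <- safe_pick(setdiff(seq_len(st$n_node), root))
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$rate_mult[v] <- st$rate_mult[v] * f
      log_hr <- log(f)
    },
    mult_indep = {
      # fresh prior draw for one branch-rate multiplier
      v <- safe_pick(setdiff(seq_len(st$n_node), root))
      sdl <- max(st$clock_sd, 1e-6)
      cand <- stats::rlnorm(1, -sdl^2 / 2, sdl)
      log_hr <- stats::dlnorm(st$rate_mult[v], -sdl^2 / 2, sdl, log = TRUE) -
        stats::dlnorm(cand, -sdl^2 / 2, sdl, log = TRUE)
      st$rate_mult[v] <- cand
    },
    ucln_sd = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$clock_sd <- st$clock_sd * f
      log_hr <- log(f)
      affects_lik <- FALSE
    },
    freq = {
      st$freq_present <- reflect01(st$freq_present +
                                     tun$slide * (stats::runif(1) - 0.5))
    },
    switch = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$switch_rate <- st$switch_rate * f
      log_hr <- log(f)
    },
    slow = {
      st$slow_fraction <- reflect01(st$slow_fraction +
                                      tun$slide * (stats::runif(1) - 0.5))
    },
    switch_indep = {
      cand <- stats::rlnorm(1, priors$switch_rate_meanlog,
                            priors$switch_rate_sdlog)
      log_hr <- stats::dlnorm(st$switch_rate, priors$switch_rate_meanlog,
                              priors$switch_rate_sdlog, log = TRUE) -
        stats::dlnorm(cand, priors$switch_rate_meanlog,
                      priors$switch_rate_sdlog, log = TRUE)
      st$switch_rate <- cand
    },
    slow_indep = {
      st$slow_fraction <- stats::runif(1)
    },
    death = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$death_rate <- st$death_rate * f
      log_hr <- log(f)
    },
    shape = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$gamma_shape <- st$gamma_shape * f
      log_hr <- log(f)
    },
    crate = {
      k <- length(st$concept_rates)
      ij <- sample.int(k, 2)
      delta <- tun$slide * (stats::runif(1) - 0.5)
      st$concept_rates[ij[1]] <- st$concept_rates[ij[1]] + delta
      st$concept_rates[ij[2]] <- st$concept_rates[ij[2]] - delta
      if (any(st$concept_rates[ij] <= 0)) return(NULL)
    },
    fbd_d = {
      f <- exp(tun$scale * (stats::runif(1) - 0.5))
      st$d <- st$d * f
      log_hr <- log(f)
      affects_lik <- FALSE
    },
    fbd_nu = {
      st$nu <- reflect01(st$nu + tun$slide * (stats::runif(1) - 0.5))
      affects_lik <- FALSE
    },
    fbd_s = {
      st$s <- reflect01(st$s + tun$slide * (stats::runif(1) - 0.5))
      affects_lik <- FALSE
    }
  )
  list(state = st, log_hr = log_hr, affects_lik = affects_lik, move = mv)
}

safe_pick <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

reflect01 <- function(x) {
  x <- x %% 2
  if (x > 1) 2 - x else x
}

# ---- driver ----------------------------------------------------------------

#' Run tip-dated Bayesian MCMC on a cognate matrix
#'
#' Metropolis-Hastings over topology (narrow exchange, with calibrated clades
#' held monophyletic), node ages, clock and substitution parameters, and the
#' fossilized birth-death hyperparameters (diversification, turnover,
#' fossil-sampling proportion; extant sampling fixed). Node calibrations
#' multiply normal densities into the posterior. Trees and the scalar trace
#' are sampled every `cfg$thin` generations; the first
#' `burnin_fraction` of samples is dropped.
#'
#' @param m a [cognate_matrix()] with ascertainment columns (CTMC/covarion)
#' @param model a [substitution_model()]
#' @param clock a [clock_model()] (its `rate` initializes the sampled clock
#'   rate)
#' @param cal a [calibration_set()]
#' @param cfg an [mcmc_config()]
#' @param priors a [phylo_priors()]
#' @param concept_rates `TRUE` to sample mean-one per-concept rate
#'   multipliers
#' @return object of class `posterior_sample`: `trace` (tibble), `trees`
#'   (list of dated `phylo`), and the settings used.
#' @export
run_mcmc <- function(m, model, clock, cal = calibration_set(),
                     cfg = mcmc_config(), priors = phylo_priors(),
                     concept_rates = FALSE) {
  set.seed(cfg$seed)
  pack <- build_data_pack(m, model)
  st <- new_state(m, model, clock, cal, priors, concept_rates)
  if (concept_rates) {
    st$concept_rates <- rep(1, pack$n_concepts)
  }
  lp <- state_logprior(st, pack, cal, priors)
  attempts <- 0
  while (!is.finite(lp) && attempts < 50) {
    st <- new_state(m, model, clock, cal, priors, concept_rates)
    if (concept_rates) st$concept_rates <- rep(1, pack$n_concepts)
    lp <- state_logprior(st, pack, cal, priors)
    attempts <- attempts + 1
  }
  if (!is.finite(lp)) stop("could not initialize a valid state", call. = FALSE)
  ll <- if (cfg$sample_likelihood) state_loglik(st, pack) else 0

  n_samples <- floor(cfg$n_generations / cfg$thin)
  trace <- vector("list", n_samples)
  trees <- vector("list", n_samples)
  si <- 0L
  accepted <- 0L
  cal_nodes <- lapply(cal$nodes, function(nc) sort(match(nc$tips,
                                                         st$tip_labels)))
  for (gen in seq_len(cfg$n_generations)) {
    prop <- propose(st, pack, cfg$tuning, cal, priors)
    if (!is.null(prop)) {
      lp_new <- state_logprior(prop$state, pack, cal, priors)
      if (is.finite(lp_new)) {
        ll_new <- if (!cfg$sample_likelihood) 0
          else if (prop$affects_lik) state_loglik(prop$state, pack) else ll
        log_alpha <- (lp_new + ll_new) - (lp + ll) + prop$log_hr
        if (log(stats::runif(1)) < log_alpha) {
          st <- prop$state; lp <- lp_new; ll <- ll_new
          accepted <- accepted + 1L
        }
      }
    }
    if (gen %% cfg$thin == 0) {
      si <- si + 1L
      root <- state_root(st)
      row <- list(
        state = gen, posterior = lp + ll, likelihood = ll, prior = lp,
        tree_height = st$ages[root], clock_rate = st$clock_rate,
        clock_sd = st$clock_sd, freq_present = st$freq_present,
        switch_rate = st$switch_rate, slow_fraction = st$slow_fraction,
        gamma_shape = st$gamma_shape, death_rate = st$death_rate,
        diversification = st$d, turnover = st$nu, sampling_prop = st$s
      )
      for (ci in seq_along(cal_nodes)) {
        row[[paste0("cal_node_age_", ci)]] <-
          st$ages[state_mrca(st, cal_nodes[[ci]])]
      }
      trace[[si]] <- tibble::as_tibble(row)
      trees[[si]] <- state_to_phylo(st)
    }
  }
  drop_n <- floor(n_samples * cfg$burnin_fraction)
  keep <- if (drop_n > 0) (drop_n + 1):n_samples else seq_len(n_samples)
  structure(list(
    trace = dplyr::bind_rows(trace[keep]),
    trees = trees[keep],
    acceptance_rate = accepted / cfg$n_generations,
    n_retained = length(keep),
    settings = list(model = model, clock = clock, cfg = cfg, priors = priors)
  ), class = "posterior_sample")
}

build_data_pack <- function(m, model) {
  cps <- concepts(m)
  ord <- order(match(m$columns$concept_id, cps))
  dat <- m$cells[, ord, drop = FALSE]
  dat[is.na(dat)] <- -1L
  storage.mode(dat) <- "integer"
  list(
    dat = dat,
    concept_idx = match(m$columns$concept_id[ord], cps),
    is_asc = m$columns$is_ascertainment[ord],
    n_concepts = length(cps),
    kind = model$kind,
    gamma_categories = model$gamma_categories
  )
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("<posterior_sample> %d retained samples, acceptance %.2f\n",
              x$n_retained, x$acceptance_rate))
  invisible(x)
}

#' @export
tidy.posterior_sample <- function(x, ...) {
  keep <- c("posterior", "likelihood", "prior", "tree_height", "clock_rate")
  dplyr::bind_rows(lapply(keep, function(p) {
    v <- x$trace[[p]]
    hpd <- hpd_interval(v)
    tibble::tibble(parameter = p, mean = mean(v), sd = stats::sd(v),
                   hpd_low = hpd[["low"]], hpd_high = hpd[["high"]],
                   ess = as.numeric(trace_ess(v)))
  }))
}

#' @export
glance.posterior_sample <- function(x, ...) {
  tibble::tibble(
    n_retained = x$n_retained,
    acceptance_rate = x$acceptance_rate,
    ess_tree_height = as.numeric(trace_ess(x$trace$tree_height)),
    mean_tree_height = mean(x$trace$tree_height)
  )
}
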