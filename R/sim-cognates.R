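#' Simulate a binary cognate matrix on a dated tree
#'
#' Cognate sets evolve independently down the tree under the configured
#' substitution model (CTMC or covarion) with branch durations in years times
#' a clock rate (optionally uncorrelated-lognormal across branches) and
#' optional per-concept rate multipliers. The number of synonymous cognate
#' sets per meaning concept is shifted-Poisson (at least one per concept).
#' Only observable columns are kept: a simulated column with no presence in
#' any sampled language is discarded and redrawn, mirroring the fact that
#' wholly latent cognate sets can never be attested. Uncertain codings (`?`)
#' are then inserted completely at random at `missing_fraction`.
#'
#' @param tree dated `phylo` from [simulate_dated_tree()] (tips at their
#'   sampling ages)
#' @param cfg a [sim_config()]; `cfg$cognates` holds the model choice,
#'   substitution parameters, clock rate and missingness
#' @return A [cognate_matrix()] without ascertainment columns. The true branch
#'   rates and concept rates used are attached as attributes `branch_rates`
#'   and `concept_rates`.
#' @export
simulate_cognate_matrix <- function(tree, cfg) {
  cc <- cfg$cognates
  set.seed(derive_seed(cfg$seed, "cognates"))
  model <- substitution_model(
    kind = cc$model,
    freq_present = cc$substitution_params$freq_present,
    switch_rate = cc$substitution_params$switch_rate %||% 0.5,
    slow_fraction = cc$substitution_params$slow_fraction %||% 0.5
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  tip_dates <- stats::setNames(ages[seq_len(ntip)], tree$tip.label)

  clock <- clock_model(if (cc$clock_sd_log > 0) "ucln" else "strict",
                       rate = cc$clock_rate, sd_log = cc$clock_sd_log)
  branch_rates <- sample_branch_rates(nrow(tree$edge), clock)
  subs_len <- tree$edge.length * branch_rates  # expected substitutions / branch

  # shifted-Poisson sets per concept, conditioned on the configured total
  # (the attested matrix fixes the total number of cognate sets exactly)
  n_sets <- 1L + stats::rpois(cc$n_concepts, cc$mean_sets_per_concept - 1)
  total <- round(cc$n_concepts * cc$mean_sets_per_concept)
  while (sum(n_sets) > total) {
    i <- safe_pick(which(n_sets > 1L))
    n_sets[i] <- n_sets[i] - 1L
  }
  while (sum(n_sets) < total) {
    i <- sample.int(cc$n_concepts, 1)
    n_sets[i] <- n_sets[i] + 1L
  }
  concept_ids <- sprintf("c%03d", seq_len(cc$n_concepts))
  concept_rates <- if ((cc$concept_rate_sd_log %||% 0) > 0) {
    r <- stats::rlnorm(cc$n_concepts, 0, cc$concept_rate_sd_log)
    r / mean(r)
  } else {
    rep(1, cc$n_concepts)
  }

  if (model$kind == "covarion") {
    Q <- covarion_generator(model)
    freqs <- covarion_frequencies(model)
    visible <- c(0L, 1L, 0L, 1L)
  } else {
    freqs <- c(1 - model$freq_present, model$freq_present)
    visible <- c(0L, 1L)
  }

  p_cache <- new.env(parent = emptyenv())
  branch_matrices <- function(rate_mult) {
    key <- format(rate_mult, digits = 12)
    if (!is.null(p_cache[[key]])) return(p_cache[[key]])
    lens <- subs_len * rate_mult
    P <- if (model$kind == "covarion") {
      lapply(lens, function(l) Matrix_expm_small(Q * l))
    } else {
      lapply(lens, function(l) ctmc_transition_matrix(1, l, freqs = freqs))
    }
    p_cache[[key]] <- P
    P
  }

  sim_column <- function(rate_mult) {
    P <- branch_matrices(rate_mult)
    states <- integer(ntip + tree$Nnode)
    root <- ntip + 1L
    states[root] <- sample.int(length(freqs), 1, prob = freqs)
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
      states[child] <- sample.int(length(freqs), 1,
                                  prob = P[[i]][states[par], ])
    }
    visible[states[seq_len(ntip)]]
  }

  cols <- list()
  col_concept <- character(0)
  for (ci in seq_len(cc$n_concepts)) {
    for (si in seq_len(n_sets[ci])) {
      ok <- FALSE
      for (try in seq_len(cc$max_retries)) {
        col <- sim_column(concept_rates[ci])
        if (any(col == 1L)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not simulate an observable column; ",
                    "substitution parameters degenerate", call. = FALSE)
      cols[[length(cols) + 1L]] <- col
      col_concept <- c(col_concept, concept_ids[ci])
    }
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- tree$tip.label
  if (cc$missing_fraction > 0) {
    mask <- stats::runif(length(cells)) < cc$missing_fraction
    cells[mask] <- NA_integer_
  }
  cognate_id <- paste0(col_concept, ".",
                       stats::ave(seq_along(col_concept), col_concept,
                                  FUN = seq_along))
  out <- cognate_matrix(
    cells,
    tibble::tibble(concept_id = col_concept, cognate_id = cognate_id,
                   is_ascertainment = FALSE),
    round(tip_dates, 6)
  )
  attr(out, "branch_rates") <- branch_rates
  attr(out, "concept_rates") <- stats::setNames(concept_rates, concept_ids)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 4x4 matrix exponential via eigendecomposition (real spectrum here)
Matrix_expm_small <- function(M) {
  e <- eigen(M)
  V <- e$vectors
  P <- Re(V %*% diag(exp(e$values)) %*% solve(V))
  pmax(P, 0)
}
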