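#' Log-likelihood of a cognate matrix on a dated tree
#'
#' Felsenstein pruning over cognate-set columns under the chosen substitution
#' model, with `?` cells summing over both states, optional discrete-gamma
#' category averaging per column, per-concept rate multipliers, and the
#' per-concept ascertainment correction
#' `logL_c = sum(log P(col)) - n_cols(c) * log(1 - P_c(all absent))`,
#' where `P_c(all absent)` is the likelihood of the concept's flagged all-zero
#' column under the same concept rate. Columns with no observed cell
#' contribute nothing. Under the stochastic Dollo model each column's single
#' birth is integrated in closed form over all branches (plus the root stem)
#' with independent loss at the model's death rate, and observability
#' conditioning replaces the correction term.
#'
#' @param tree dated `phylo`; tip labels must match the matrix languages and
#'   tip depths must be consistent with the matrix tip dates
#' @param m a [cognate_matrix()] (with ascertainment columns for CTMC /
#'   covarion fits that require the correction)
#' @param model a [substitution_model()]
#' @param clock a [clock_model()]; its rate converts branch years into
#'   expected substitutions
#' @param branch_rates optional per-edge rate multipliers (in the order of
#'   `tree$edge` rows), e.g. latent uncorrelated-lognormal rates; defaults to
#'   1 (strict clock)
#' @param concept_rates optional named per-concept multipliers, mean one
#' @return scalar log-likelihood.
#' @export
dataset_loglikelihood <- function(tree, m, model, clock,
                                  branch_rates = NULL, concept_rates = NULL) {
  if (!setequal(tree$tip.label, languages(m))) {
    stop("tree tips and matrix languages differ", call. = FALSE)
  }
  post <- ape::reorder.phylo(tree, "postorder")
  if (is.null(branch_rates)) branch_rates <- rep(1, nrow(tree$edge))
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(post$edge), key(tree$edge))
  blen_subs <- post$edge.length * branch_rates[perm] * clock$rate

  cps <- concepts(m)
  if (is.null(concept_rates)) {
    concept_rates <- stats::setNames(rep(1, length(cps)), cps)
  }
  ord <- order(match(m$columns$concept_id, cps))
  cells <- m$cells[post$tip.label, ord, drop = FALSE]
  dat <- cells
  dat[is.na(dat)] <- -1L
  storage.mode(dat) <- "integer"
  concept_idx <- match(m$columns$concept_id[ord], cps)
  is_asc <- m$columns$is_ascertainment[ord]
  gamma_rates <- discrete_gamma(model$gamma_shape, model$gamma_categories)

  if (model$kind == "sdollo") {
    sdollo_loglik_cpp(post$edge, ape::Ntip(post),
                      ape::Ntip(post) + post$Nnode, blen_subs, dat,
                      concept_idx, is_asc, concept_rates[cps],
                      model$death_rate, gamma_rates)
  } else {
    kind <- if (model$kind == "ctmc") 0L else 1L
    cognate_loglik_cpp(post$edge, ape::Ntip(post),
                       ape::Ntip(post) + post$Nnode, blen_subs, dat,
                       concept_idx, is_asc, concept_rates[cps], kind,
                       c(model$freq_present, model$switch_rate,
                         model$slow_fraction),
                       gamma_rates)
  }
}

#' @rdname dataset_loglikelihood
#' @export
sdollo_loglikelihood <- function(tree, m, model, clock,
                                 branch_rates = NULL, concept_rates = NULL) {
  stopifnot(model$kind == "sdollo")
  dataset_loglikelihood(tree, m, model, clock, branch_rates, concept_rates)
}
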