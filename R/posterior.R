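#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' the initial monotone positive-pair-sum rule (the sum of autocorrelations at
#' consecutive lag pairs is accumulated until a pair sum turns non-positive).
#' A zero-variance trace is flagged degenerate and returns `n`.
#'
#' @param trace numeric series of length >= 10
#' @return ESS (numeric scalar); attribute `degenerate` is `TRUE` for a
#'   constant trace.
#' @export
trace_ess <- function(trace) {
  n <- length(trace)
  if (n < 10) stop("trace too short (need >= 10)", call. = FALSE)
  if (stats::sd(trace) == 0) {
    warning("zero-variance trace; ESS undefined, returning n")
    return(structure(as.numeric(n), degenerate = TRUE))
  }
  lag_max <- min(n - 1, 2000)
  rho <- drop(stats::acf(trace, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  acc <- 0
  i <- 1
  while (i <= length(rho)) {
    pair <- rho[i] + if (i + 1 <= length(rho)) rho[i + 1] else 0
    if (pair <= 0) break
    acc <- acc + pair
    i <- i + 2
  }
  structure(n / (1 + 2 * acc), degenerate = FALSE)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted sample containing
#' `ceiling(mass * n)` points; ties go to the leftmost such window.
#'
#' @param samples numeric vector, length >= 20
#' @param mass probability mass, in (0, 1)
#' @return named numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples", call. = FALSE)
  s <- sort(samples)
  k <- ceiling(mass * n)
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(low = s[i], high = s[i + k - 1])
}

tree_clades <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(phy)
  n_node <- ntip + phy$Nnode
  below <- vector("list", n_node)
  for (t in seq_len(ntip)) below[[t]] <- phy$tip.label[t]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  internal <- (ntip + 1):n_node
  keys <- vapply(internal, function(v) paste(sort(below[[v]]), collapse = "|"),
                 "")
  ages <- node_ages(phy)[internal]
  stats::setNames(ages, keys)
}

#' Maximum clade credibility tree
#'
#' Picks the sampled topology maximizing the product of its clades' posterior
#' frequencies; each clade's age is summarized as the mean (and 95% HPD) of
#' that clade's MRCA age over all sampled trees containing it.
#'
#' @param trees list of dated `phylo` trees (a posterior sample), or a
#'   [run_mcmc()] result
#' @param mass HPD mass for node-age intervals
#' @return list of class `mcc_summary`: `tree` (the MCC `phylo`), `clades`
#'   (tibble: clade, posterior, mean age, HPD bounds), `log_score`.
#' @export
mcc_tree <- function(trees, mass = 0.95) {
  if (inherits(trees, "posterior_sample")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty posterior sample", call. = FALSE)
  clades_by_tree <- lapply(trees, tree_clades)
  n <- length(trees)
  all_keys <- unlist(lapply(clades_by_tree, names))
  freq <- table(all_keys) / n
  scores <- vapply(clades_by_tree, function(cl) {
    sum(log(freq[names(cl)]))
  }, 0)
  best <- which.max(scores)
  mcc_clades <- names(clades_by_tree[[best]])
  summarize_clade <- function(key) {
    ages <- unlist(lapply(clades_by_tree, function(cl) {
      unname(cl[names(cl) == key])
    }))
    hpd <- if (length(ages) >= 20) hpd_interval(ages, mass) else
      c(low = min(ages), high = max(ages))
    tibble::tibble(clade = key, posterior = as.numeric(freq[key]),
                   age_mean = mean(ages), age_low = hpd[["low"]],
                   age_high = hpd[["high"]], n_trees = length(ages))
  }
  clade_tbl <- dplyr::bind_rows(lapply(mcc_clades, summarize_clade))
  structure(list(tree = trees[[best]], clades = clade_tbl,
                 log_score = scores[best]),
            class = "mcc_summary")
}

#' @export
print.mcc_summary <- function(x, ...) {
  cat("<mcc_summary>\n")
  print(x$clades)
  invisible(x)
}

#' Mean age of the most recent common ancestor of a tip set
#'
#' Averaged over the sampled trees in which the tip set is monophyletic
#' (every tree if the clade is not required to be monophyletic).
#'
#' @param trees list of dated `phylo` (or [run_mcmc()] result)
#' @param tips character vector of tip labels
#' @param monophyletic_only average only over trees where `tips` form a clade
#' @return tibble with mean, HPD bounds and the number of trees used.
#' @export
clade_age_summary <- function(trees, tips, monophyletic_only = FALSE) {
  if (inherits(trees, "posterior_sample")) trees <- trees$trees
  key <- paste(sort(tips), collapse = "|")
  ages <- vapply(trees, function(phy) {
    cl <- tree_clades(phy)
    if (monophyletic_only) {
      v <- cl[names(cl) == key]
      if (length(v)) unname(v[1]) else NA_real_
    } else {
      mrca_age(phy, tips)
    }
  }, 0)
  ages <- ages[!is.na(ages)]
  hpd <- if (length(ages) >= 20) hpd_interval(ages) else
    c(low = min(ages), high = max(ages))
  tibble::tibble(age_mean = mean(ages), age_low = hpd[["low"]],
                 age_high = hpd[["high"]], n_trees = length(ages))
}

mrca_age <- function(phy, tips) {
  node <- ape::getMRCA(phy, tips)
  node_ages(phy)[node]
}
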