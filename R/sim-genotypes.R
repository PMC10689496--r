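#' Simulate a modern + ancient genotype panel
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); population
#' frequencies follow the Balding-Nichols model with the configured FST
#' (`p_k ~ Beta(p (1-F)/F, (1-p)(1-F)/F)`; `fst = 0` shares the ancestral
#' frequency exactly); diploid genotypes are binomial draws in {0, 1, 2}.
#' Modern individuals form the reference panel. Ancient individuals are
#' assigned populations round-robin (a configurable fraction instead 50/50
#' admixed between two populations) and have `ancient_missing_rate` of their
#' calls deleted completely at random, emulating low-coverage ancient data.
#'
#' @param cfg a [sim_config()]; see `cfg$genotypes`
#' @return object of class `genotype_matrix`: `calls` (individuals x SNPs,
#'   values 0/1/2/`NA`) and `ind` (tibble: `id`, `pop`, `role`). True
#'   population frequencies are attached as attribute `pop_freqs`.
#' @export
simulate_genotype_data <- function(cfg) {
  gc <- cfg$genotypes
  stopifnot(gc$n_pops >= 2, gc$n_snps >= 100)
  if (gc$fst < 0 || gc$fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "genotypes"))
  L <- gc$n_snps
  p_anc <- stats::runif(L, 0.05, 0.95)
  pops <- paste0("P", seq_len(gc$n_pops))
  freqs <- sapply(seq_len(gc$n_pops), function(k) {
    if (gc$fst == 0) return(p_anc)
    a <- p_anc * (1 - gc$fst) / gc$fst
    b <- (1 - p_anc) * (1 - gc$fst) / gc$fst
    stats::rbeta(L, a, b)
  })
  colnames(freqs) <- pops

  draw <- function(p) stats::rbinom(length(p), 2L, p)
  modern <- lapply(seq_len(gc$n_pops), function(k) {
    t(replicate(gc$n_modern_per_pop, draw(freqs[, k])))
  })
  modern_calls <- do.call(rbind, modern)
  modern_ind <- tibble::tibble(
    id = sprintf("mod_%s_%03d", rep(pops, each = gc$n_modern_per_pop),
                 rep(seq_len(gc$n_modern_per_pop), gc$n_pops)),
    pop = rep(pops, each = gc$n_modern_per_pop),
    role = "modern-reference"
  )

  n_anc <- gc$n_ancient
  anc_pop_idx <- rep_len(seq_len(gc$n_pops), n_anc)
  n_admixed <- round((gc$admixed_fraction %||% 0) * n_anc)
  admixed <- seq_len(n_anc) <= n_admixed
  anc_calls <- matrix(NA_integer_, n_anc, L)
  anc_pop <- character(n_anc)
  for (i in seq_len(n_anc)) {
    if (admixed[i]) {
      ks <- sample(gc$n_pops, 2)
      p <- (freqs[, ks[1]] + freqs[, ks[2]]) / 2
      anc_pop[i] <- paste0(pops[ks[1]], "x", pops[ks[2]])
    } else {
      p <- freqs[, anc_pop_idx[i]]
      anc_pop[i] <- pops[anc_pop_idx[i]]
    }
    g <- draw(p)
    if (gc$ancient_missing_rate > 0) {
      g[stats::runif(L) < gc$ancient_missing_rate] <- NA_integer_
    }
    anc_calls[i, ] <- g
  }
  anc_ind <- tibble::tibble(
    id = sprintf("anc_%03d", seq_len(n_anc)),
    pop = anc_pop,
    role = "projected"
  )

  calls <- rbind(modern_calls, anc_calls)
  ind <- dplyr::bind_rows(modern_ind, anc_ind)
  rownames(calls) <- ind$id
  colnames(calls) <- sprintf("snp%06d", seq_len(L))
  out <- structure(list(calls = calls, ind = ind), class = "genotype_matrix")
  attr(out, "pop_freqs") <- freqs
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals (%d reference, %d projected) x %d SNPs, %.1f%% missing\n",
    nrow(x$calls), sum(x$ind$role == "modern-reference"),
    sum(x$ind$role == "projected"), ncol(x$calls),
    100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Hudson FST estimator between two populations
#'
#' Ratio-of-averages Hudson estimator from genotype counts:
#' per-SNP numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` over
#' denominator `p1(1-p2) + p2(1-p1)`, averaged before the ratio.
#'
#' @param g a `genotype_matrix`
#' @param pop_a,pop_b population labels
#' @return scalar FST estimate.
#' @export
hudson_fst <- function(g, pop_a, pop_b) {
  ga <- g$calls[g$ind$pop == pop_a, , drop = FALSE]
  gb <- g$calls[g$ind$pop == pop_b, , drop = FALSE]
  na <- 2 * colSums(!is.na(ga)); nb <- 2 * colSums(!is.na(gb))
  pa <- colSums(ga, na.rm = TRUE) / na
  pb <- colSums(gb, na.rm = TRUE) / nb
  keep <- na > 2 & nb > 2
  pa <- pa[keep]; pb <- pb[keep]; na <- na[keep]; nb <- nb[keep]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  mean(num) / mean(den)
}

#' Write and read EIGENSTRAT triplets
#'
#' Plain-ASCII EIGENSTRAT: `.geno` (one row per SNP, one digit per
#' individual, 9 = missing), `.snp` (id, chromosome, genetic position,
#' physical position), `.ind` (id, sex `U`, population label). The role split
#' (reference vs projected) is recovered on read from `project_pops` or, by
#' default, from population labels written for projected individuals.
#'
#' @param g a `genotype_matrix`
#' @param prefix path prefix for the three files
#' @return the prefix (write) or a `genotype_matrix` (read).
#' @export
write_eigenstrat <- function(g, prefix) {
  geno <- t(g$calls)  # SNPs x individuals
  geno[is.na(geno)] <- 9L
  writeLines(apply(geno, 1, paste, collapse = ""), paste0(prefix, ".geno"))
  writeLines(sprintf("%s 1 0.0 %d A G", colnames(g$calls),
                     seq_len(ncol(g$calls))), paste0(prefix, ".snp"))
  pop_field <- ifelse(g$ind$role == "projected",
                      paste0(g$ind$pop, ".proj"), g$ind$pop)
  writeLines(sprintf("%s U %s", g$ind$id, pop_field), paste0(prefix, ".ind"))
  invisible(prefix)
}

#' @rdname write_eigenstrat
#' @param project_pops character vector of population labels to treat as
#'   projected; by default labels suffixed `.proj` are projected.
#' @export
read_eigenstrat <- function(prefix, project_pops = NULL) {
  ind_lines <- strsplit(readLines(paste0(prefix, ".ind")), "\\s+")
  ind <- tibble::tibble(
    id = vapply(ind_lines, `[`, "", 1),
    pop = vapply(ind_lines, `[`, "", 3)
  )
  snp_lines <- strsplit(readLines(paste0(prefix, ".snp")), "\\s+")
  snp_ids <- vapply(snp_lines, `[`, "", 1)
  geno_lines <- readLines(paste0(prefix, ".geno"))
  # vapply over SNP rows yields an individuals x SNPs matrix directly
  calls <- vapply(geno_lines, function(l) {
    v <- as.integer(strsplit(l, "")[[1]])
    v[v == 9L] <- NA_integer_
    v
  }, integer(nrow(ind)), USE.NAMES = FALSE)
  rownames(calls) <- ind$id
  colnames(calls) <- snp_ids
  projected <- if (is.null(project_pops)) {
    grepl("\\.proj$", ind$pop)
  } else {
    ind$pop %in% project_pops
  }
  ind$role <- ifelse(projected, "projected", "modern-reference")
  ind$pop <- sub("\\.proj$", "", ind$pop)
  structure(list(calls = calls, ind = ind), class = "genotype_matrix")
}
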