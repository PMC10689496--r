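#' Normalize genotypes for PCA
#'
#' Follows the eigenanalysis convention of the smartpca program: per SNP, the
#' allele frequency over the modern reference panel is estimated with the
#' shrinkage form `p = (1 + sum(calls)) / (2 + 2 n_nonmissing)` (plain
#' `mean/2` behind `shrink = FALSE`), each call is centered by `2p` and scaled
#' by `sqrt(p (1 - p))`, and missing calls become 0 after centering (mean
#' imputation). SNPs monomorphic in the reference panel are dropped.
#'
#' @param g a `genotype_matrix`
#' @param shrink use the `(1 + sum)/(2 + 2n)` frequency estimator (default)
#' @return list: `normalized` (reference-individual matrix), `stats` (tibble
#'   of per-SNP `snp`, `freq`, `scale`), `n_dropped`, and the retained SNP
#'   names.
#' @export
normalize_genotypes <- function(g, shrink = TRUE) {
  ref <- g$calls[g$ind$role == "modern-reference", , drop = FALSE]
  if (nrow(ref) < 2) stop("need at least two modern-reference individuals",
                          call. = FALSE)
  n_obs <- colSums(!is.na(ref))
  s <- colSums(ref, na.rm = TRUE)
  p <- if (shrink) (1 + s) / (2 + 2 * n_obs) else s / (2 * n_obs)
  mono <- n_obs == 0 | apply(ref, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) < 2
  })
  keep <- which(!mono & p > 0 & p < 1)
  if (!length(keep)) stop("all SNPs dropped as monomorphic", call. = FALSE)
  p <- p[keep]
  sc <- sqrt(p * (1 - p))
  X <- sweep(ref[, keep, drop = FALSE], 2, 2 * p, `-`)
  X <- sweep(X, 2, sc, `/`)
  X[is.na(X)] <- 0
  list(
    normalized = X,
    stats = tibble::tibble(snp = colnames(g$calls)[keep],
                           freq = unname(p), scale = unname(sc)),
    snps = colnames(g$calls)[keep],
    n_dropped = ncol(g$calls) - length(keep)
  )
}

#' Principal components of the modern reference panel
#'
#' Top-K eigendecomposition (via SVD) of the normalized reference matrix with
#' no outlier-removal iterations: every reference individual stays in.
#' SNP loadings are orthonormal; each PC's sign is fixed so its largest
#' loading is positive, making runs comparable.
#'
#' @param g a `genotype_matrix`
#' @param k number of components to keep (>= 2)
#' @param shrink passed to [normalize_genotypes()]
#' @return object of class `pca_model`: `loadings` (SNP x K), `eigenvalues`,
#'   `scores` (reference individuals x K), `stats`, `snps`.
#' @export
fit_pca <- function(g, k = 10, shrink = TRUE) {
  nz <- normalize_genotypes(g, shrink = shrink)
  X <- nz$normalized
  k <- as.integer(k)
  if (k < 2 || k > min(nrow(X) - 1, ncol(X))) {
    stop("k must be in [2, min(n_individuals - 1, n_snps)]", call. = FALSE)
  }
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(loadings) <- nz$snps
  rownames(scores) <- rownames(X)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    loadings = loadings,
    eigenvalues = sv$d[seq_len(k)]^2 / (nrow(X) - 1),
    scores = scores,
    stats = nz$stats,
    snps = nz$snps,
    n_dropped = nz$n_dropped
  ), class = "pca_model")
}

#' Least-squares projection of (possibly missing-heavy) samples
#'
#' Projects each individual onto the fitted PCs by solving the least-squares
#' fit of its normalized non-missing calls against the loadings restricted to
#' those SNPs — the `lsqproject` convention that keeps high-missingness
#' ancient samples from shrinking toward the origin more than necessary.
#' With no missingness this reduces exactly to the plain dot product with the
#' orthonormal loadings.
#'
#' @param model a [fit_pca()] model
#' @param g a `genotype_matrix`; all individuals with role `"projected"` are
#'   projected (or pass `ids`)
#' @param ids optional individual ids to project instead
#' @return tibble: `id`, `pop`, `role`, `PC1..PCk`, `snps_used`.
#' @export
lsq_project <- function(model, g, ids = NULL) {
  if (is.null(ids)) ids <- g$ind$id[g$ind$role == "projected"]
  snp_idx <- match(model$snps, colnames(g$calls))
  freq <- model$stats$freq
  sc <- model$stats$scale
  rows <- lapply(ids, function(id) {
    calls <- g$calls[id, snp_idx]
    obs <- which(!is.na(calls))
    if (!length(obs)) stop("individual ", id, " has no usable SNPs",
                           call. = FALSE)
    z <- (calls[obs] - 2 * freq[obs]) / sc[obs]
    V <- model$loadings[obs, , drop = FALSE]
    coords <- stats::lsfit(V, z, intercept = FALSE)$coefficients
    meta <- g$ind[g$ind$id == id, ]
    tibble::tibble(id = id, pop = meta$pop, role = meta$role,
                   !!!stats::setNames(as.list(coords),
                                      colnames(model$loadings)),
                   snps_used = length(obs))
  })
  dplyr::bind_rows(rows)
}

#' Combined PCA coordinate report
#'
#' Reference scores and projected coordinates in one ordered table, the
#' tabular form of a two-PC population-structure plot.
#'
#' @param model a [fit_pca()] model
#' @param g the `genotype_matrix` the model was fitted on
#' @param projections optional precomputed [lsq_project()] output
#' @return tibble: `id`, `pop`, `role`, `PC1..PCk`, `snps_used`.
#' @export
pca_report <- function(model, g, projections = NULL) {
  ref_ids <- rownames(model$scores)
  meta <- g$ind[match(ref_ids, g$ind$id), ]
  ref <- tibble::tibble(
    id = ref_ids, pop = meta$pop, role = meta$role,
    tibble::as_tibble(model$scores),
    snps_used = length(model$snps)
  )
  if (is.null(projections) && any(g$ind$role == "projected")) {
    projections <- lsq_project(model, g)
  }
  dplyr::bind_rows(ref, projections)
}

#' @export
#' @importFrom generics tidy
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$scores),
    n_snps = length(x$snps),
    n_snps_dropped = x$n_dropped,
    k = ncol(x$loadings)
  )
}

#' Scatter of the first two principal components
#' @param object a [pca_report()]-shaped tibble
#' @param ... unused
#' @return a ggplot.
#' @export
plot_pca <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$pop,
                                       shape = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "population",
                  shape = "role") +
    ggplot2::theme_minimal()
}
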