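pca_cfg <- function(seed, ...) {
  sim_config(seed, genotypes = utils::modifyList(
    list(n_pops = 2L, n_modern_per_pop = 50L, n_ancient = 30L,
         n_snps = 5000L, fst = 0.1, ancient_missing_rate = 0.5), list(...)))
}

test_that("normalization matches the shrinkage-frequency hand computation", {
  calls <- matrix(c(0L, 1L, 2L,
                    2L, 2L, 1L), 3, 2,
                  dimnames = list(c("i1", "i2", "i3"), c("s1", "s2")))
  g <- structure(list(
    calls = calls,
    ind = tibble::tibble(id = c("i1", "i2", "i3"),
                         pop = "P", role = "modern-reference")
  ), class = "genotype_matrix")
  nz <- normalize_genotypes(g)
  p1 <- (1 + 3) / (2 + 6)   # 0.5
  p2 <- (1 + 5) / (2 + 6)   # 0.75
  expect_equal(nz$stats$freq, c(p1, p2))
  expect_equal(nz$normalized[, 1],
               c(i1 = 0 - 1, i2 = 1 - 1, i3 = 2 - 1) / sqrt(0.25))
  expect_equal(nz$normalized[2, 2], (2 - 1.5) / sqrt(0.75 * 0.25))
  # a monomorphic SNP is dropped
  g$calls <- cbind(g$calls, s3 = c(0L, 0L, 0L))
  nz2 <- normalize_genotypes(g)
  expect_equal(nz2$n_dropped, 1)
  expect_false("s3" %in% nz2$snps)
})

test_that("reference columns are centered and loadings orthonormal", {
  g <- simulate_genotype_data(pca_cfg(1, ancient_missing_rate = 0,
                                      n_snps = 800L))
  nz <- normalize_genotypes(g, shrink = FALSE)
  expect_lt(max(abs(colMeans(nz$normalized))), 1e-10)
  model <- fit_pca(g, k = 5)
  gram <- crossprod(model$loadings)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-8))
  expect_error(fit_pca(g, k = 1), "k must be")
})

test_that("PC1 separates two populations at FST 0.1 with no overlap", {
  g <- simulate_genotype_data(pca_cfg(2))
  model <- fit_pca(g, k = 4)
  pc1 <- model$scores[, 1]
  pops <- g$ind$pop[match(rownames(model$scores), g$ind$id)]
  r1 <- range(pc1[pops == "P1"])
  r2 <- range(pc1[pops == "P2"])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
})

test_that("projection without missingness equals the plain dot product", {
  g <- simulate_genotype_data(pca_cfg(3, ancient_missing_rate = 0,
                                      n_snps = 1000L))
  model <- fit_pca(g, k = 3)
  id <- g$ind$id[g$ind$role == "projected"][1]
  proj <- lsq_project(model, g, ids = id)
  z <- (g$calls[id, model$snps] - 2 * model$stats$freq) / model$stats$scale
  direct <- drop(z %*% model$loadings)
  expect_equal(unlist(proj[, c("PC1", "PC2", "PC3")]), direct,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("half-masked duplicates of a reference individual barely move", {
  g <- simulate_genotype_data(pca_cfg(4, n_snps = 5000L))
  model <- fit_pca(g, k = 3)
  set.seed(9)
  id <- g$ind$id[1]
  masked <- g$calls[id, ]
  masked[stats::runif(length(masked)) < 0.5] <- NA_integer_
  g$calls <- rbind(g$calls, masked)
  rownames(g$calls)[nrow(g$calls)] <- "dup"
  g$ind <- dplyr::bind_rows(
    g$ind, tibble::tibble(id = "dup", pop = g$ind$pop[1], role = "projected"))
  pm <- lsq_project(model, g, ids = "dup")
  for (pc in c("PC1", "PC2")) {
    drift <- abs(pm[[pc]] - model$scores[id, pc]) /
      diff(range(model$scores[, pc]))
    expect_lt(drift, 0.10)
  }
  # masking never inflates the projected norm on average
  norms <- numeric(40)
  base <- sqrt(sum(model$scores[id, 1:2]^2))
  for (r in 1:40) {
    mk <- g$calls[id, ]
    mk[stats::runif(length(mk)) < 0.5] <- NA_integer_
    g$calls["dup", ] <- mk
    p <- lsq_project(model, g, ids = "dup")
    norms[r] <- sqrt(p$PC1^2 + p$PC2^2)
  }
  expect_lt(mean(norms), base * 1.05)
})

test_that("all-missing individuals are refused", {
  g <- simulate_genotype_data(pca_cfg(5, n_snps = 300L))
  model <- fit_pca(g, k = 2)
  g$calls[g$ind$id[g$ind$role == "projected"][1], ] <- NA_integer_
  expect_error(lsq_project(model, g,
                           ids = g$ind$id[g$ind$role == "projected"][1]),
               "no usable SNPs")
})

test_that("projected ancients land nearest their own population centroid", {
  g <- simulate_genotype_data(pca_cfg(6, n_ancient = 40L))
  model <- fit_pca(g, k = 2)
  rep <- pca_report(model, g)
  cent <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(rep, .data$role == "modern-reference"),
                    .data$pop),
    c1 = mean(.data$PC1), c2 = mean(.data$PC2))
  proj <- dplyr::filter(rep, .data$role == "projected")
  nearest <- vapply(seq_len(nrow(proj)), function(i) {
    cent$pop[which.min((cent$c1 - proj$PC1[i])^2 + (cent$c2 - proj$PC2[i])^2)]
  }, "")
  expect_gte(mean(nearest == proj$pop), 0.9)
})

test_that("50/50 admixed individuals project between the parent centroids", {
  g <- simulate_genotype_data(pca_cfg(7, admixed_fraction = 1,
                                      n_ancient = 30L))
  model <- fit_pca(g, k = 2)
  rep <- pca_report(model, g)
  cent <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(rep, .data$role == "modern-reference"),
                    .data$pop),
    c1 = mean(.data$PC1), c2 = mean(.data$PC2))
  proj <- dplyr::filter(rep, .data$role == "projected")
  inside <- vapply(seq_len(nrow(proj)), function(i) {
    lo1 <- min(cent$c1); hi1 <- max(cent$c1)
    pad1 <- 0.1 * (hi1 - lo1)
    lo2 <- min(cent$c2); hi2 <- max(cent$c2)
    pad2 <- 0.1 * (hi2 - lo2) + 0.1 * (hi1 - lo1)
    proj$PC1[i] >= lo1 - pad1 && proj$PC1[i] <= hi1 + pad1 &&
      proj$PC2[i] >= lo2 - pad2 && proj$PC2[i] <= hi2 + pad2
  }, TRUE)
  expect_gte(mean(inside), 0.9)
})

test_that("the coordinate report contains one row per usable individual", {
  g <- simulate_genotype_data(pca_cfg(8, n_snps = 400L))
  model <- fit_pca(g, k = 2)
  rep <- pca_report(model, g)
  expect_equal(nrow(rep), nrow(g$calls))
  expect_true(all(c("id", "pop", "role", "PC1", "PC2", "snps_used") %in%
                    names(rep)))
  # with no projected individuals, only reference rows appear
  g2 <- g
  keep <- g2$ind$role == "modern-reference"
  g2$calls <- g2$calls[keep, ]
  g2$ind <- g2$ind[keep, ]
  model2 <- fit_pca(g2, k = 2)
  expect_equal(nrow(pca_report(model2, g2)), sum(keep))
})
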