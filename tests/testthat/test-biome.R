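test_that("biome binning follows the stated bin boundaries", {
  expect_equal(assign_biome(60), "50-75% AP")
  expect_equal(assign_biome(4, "Steppe"), "Steppe")
  expect_equal(assign_biome(25), "25-50% AP")   # lower-inclusive
  expect_equal(assign_biome(5), "5-25% AP")
  expect_equal(assign_biome(50), "50-75% AP")
  expect_equal(assign_biome(75), "50-75% AP")   # 75 stays in the 50-75 bin
  expect_equal(assign_biome(75.01), ">75% AP")
  expect_equal(assign_biome(100), ">75% AP")
  expect_error(assign_biome(3), "low-AP label")
  expect_error(assign_biome(2, "Forest"), "low-AP label")
  expect_error(assign_biome(101), "outside")
  # total and idempotent over the whole domain
  x <- seq(0, 100, by = 0.5)
  lab <- ifelse(x < 5, "Desert", NA)
  out <- assign_biome(x, lab)
  expect_true(all(out %in% biome_classes()))
})

test_that("two-class multinomial fits match a logistic-regression oracle", {
  set.seed(1)
  n <- 600
  mat <- stats::rnorm(n, 10, 5)
  ap <- stats::rnorm(n, 1000, 300)
  eta <- -0.3 + 0.8 * scale(mat) - 1.1 * scale(ap)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  sites <- tibble::tibble(mat = mat, ap = ap,
                          biome = ifelse(y == 1, "Steppe", ">75% AP"))
  bm <- fit_biome_model(sites)
  df <- data.frame(y = as.integer(sites$biome == sort(unique(sites$biome))[2]),
                   mat_z = scale(mat)[, 1] * stats::sd(mat) /
                     stats::sd(mat),  # placeholder, rebuilt below
                   ap_z = 0)
  std <- bm$standardization
  df$mat_z <- (mat - std$mat_mean) / std$mat_sd
  df$ap_z <- (ap - std$ap_mean) / std$ap_sd
  glm_fit <- stats::glm(y ~ mat_z + ap_z, data = df, family = "binomial")
  expect_equal(unname(bm$coefficients[2, ]),
               unname(stats::coef(glm_fit)), tolerance = 1e-4)
})

test_that("fitted probabilities sum to one and recover generator coefficients", {
  w <- small_world(3)
  cfg <- w$cfg
  cfg$pollen$n_sites <- 5000L
  pol <- simulate_pollen_sites(w$grids, cfg)
  bm <- fit_biome_model(pol)
  p <- predict(bm, pol[1:50, ], type = "prob")
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  # compare against truth in reference-class form (softmax coefficients are
  # identified only up to a common offset per column)
  tru <- attr(pol, "true_coefficients")
  ref <- bm$classes[1]
  tru_ref <- sweep(tru, 2, tru[ref, ])
  est <- bm$coefficients[rownames(tru_ref), ]
  big <- abs(tru_ref) > 0.5
  rel <- abs(est[big] - tru_ref[big]) / abs(tru_ref[big])
  expect_lt(stats::median(rel), 0.15)
  expect_true(mean(rel < 0.15) > 0.6)
})

test_that("single-class data are rejected", {
  sites <- tibble::tibble(mat = stats::rnorm(30), ap = stats::rnorm(30),
                          biome = "Steppe")
  expect_error(fit_biome_model(sites), "two observed")
})

test_that("classification metrics: hand-computed confusion and permutation null", {
  conf <- as.table(matrix(c(40, 20, 10, 30), 2, 2,
                          dimnames = list(observed = c("a", "b"),
                                          predicted = c("a", "b"))))
  met <- metrics_from_confusion(conf)
  expect_equal(met$accuracy, 0.70)
  expect_equal(met$kappa, 0.40, tolerance = 1e-12)
  # perfect prediction
  perf <- metrics_from_confusion(as.table(diag(c(5, 7, 9))))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$kappa, 1)
  # shuffled labels give kappa near zero
  set.seed(2)
  obs <- sample(letters[1:4], 10000, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  prd <- sample(obs)
  met0 <- metrics_from_confusion(table(obs, prd))
  expect_lt(abs(met0$kappa), 0.05)
  # kappa = 1 iff the confusion matrix is diagonal
  nd <- as.table(matrix(c(5, 1, 0, 6), 2, 2))
  expect_lt(metrics_from_confusion(nd)$kappa, 1)
})

test_that("biome projection takes the per-cell argmax", {
  w <- small_world(4)
  cfg <- w$cfg
  pol <- simulate_pollen_sites(w$grids, cfg)
  bm <- fit_biome_model(pol)
  g <- w$grids[[1]]
  map <- project_biome_map(bm, g)
  idx <- which(g$mask)[1:100]
  p <- predict_biome_prob(bm, tibble::tibble(mat = g$mat[idx], ap = g$ap[idx]))
  expect_equal(map[idx], max.col(p, ties.method = "first"))
  # a grid cell identical to a site's climate classifies like the site
  site1 <- pol[1, ]
  cls <- predict(bm, site1)
  gi <- which(g$mat == site1$mat & g$ap == site1$ap, arr.ind = TRUE)
  if (nrow(gi)) expect_equal(attr(map, "classes")[map[gi[1, 1], gi[1, 2]]], cls)
})

test_that("society maps reproduce the printed associations", {
  classes <- biome_classes()
  biomes <- matrix(rep(seq_along(classes), 2), 4, 4)
  attr(biomes, "classes") <- classes
  tbl <- society_biome_table()
  # Neolithic societies do not exist in the oldest window
  expect_true(all(society_map(biomes, 12000, "N", tbl) == 0))
  expect_true(all(society_map(biomes, 12000, "BA", tbl) == 0))
  # hunter-gatherers between 8000 and 6000 BP only in the densest forest
  hg <- society_map(biomes, 7000, "HG", tbl)
  expect_equal(unique(classes[biomes[hg == 1]]), ">75% AP")
  # Bronze Age in the final window includes steppe
  ba <- society_map(biomes, 3000, "BA", tbl)
  expect_true(all(ba[biomes == match("Steppe", classes)] == 1))
  # the extension flag pushes the final window to 1500 BP
  expect_error(society_associations(tbl, 1700), "outside")
  tbl2 <- society_biome_table(extend_to_1500 = TRUE)
  expect_length(society_associations(tbl2, 1700)$IA, 5)
  # monotonicity: adding a biome to an association never removes cells
  tbl3 <- dplyr::bind_rows(tbl, tibble::tibble(
    window_start = 8000, window_end = 6000, culture = "HG", biome = "Steppe"))
  hg2 <- society_map(biomes, 7000, "HG", tbl3)
  expect_true(all(hg2[hg == 1] == 1))
  expect_gte(sum(hg2), sum(hg))
})

test_that("modal aggregation matches a frequency-count oracle", {
  a <- matrix(1L, 3, 3); b <- matrix(2L, 3, 3)
  expect_equal(aggregate_mode(list(a, a, b)), a, ignore_attr = TRUE)
  expect_equal(aggregate_mode(list(b)), b)
  set.seed(3)
  slices <- lapply(1:5, function(i) matrix(sample(1:3, 25, TRUE), 5, 5))
  got <- aggregate_mode(slices)
  for (i in 1:5) for (j in 1:5) {
    v <- vapply(slices, function(s) s[i, j], 0L)
    counts <- table(v)
    best <- as.integer(names(counts)[counts == max(counts)])
    # tie-break: earliest slice's value among the tied ones
    expect_equal(got[i, j], v[v %in% best][1])
  }
  expect_error(aggregate_mode(list()), "empty")
})

test_that("culture-biome crosstab counts every on-grid site and recovers the table", {
  w <- small_world(5)
  cfg <- w$cfg
  cfg$cultures$n_sites <- 1229L
  cs <- simulate_culture_sites(w$grids, cfg)
  # classify biomes with the true model so recovery is exact up to sampling
  tru_model <- structure(list(
    classes = biome_classes(),
    coefficients = {
      co <- default_biome_coefficients()
      colnames(co) <- c("intercept", "mat_z", "ap_z")
      co
    },
    standardization = urheimat:::climate_standardization(w$grids)
  ), class = "biome_model")
  rasters <- lapply(w$grids, function(g) project_biome_map(tru_model, g))
  slice_times <- vapply(w$grids, `[[`, 0, "time_bp")
  res <- culture_biome_crosstab(cs, rasters, slice_times)
  expect_equal(sum(res$crosstab$n) + res$n_skipped, 1229)
  # derived associations should reproduce the generating table
  tbl <- society_biome_table()
  derived_keys <- with(res$derived_table,
                       paste(window_start, culture, biome))
  true_keys <- with(tbl, paste(window_start, culture, biome))
  # every derived association is a true one
  expect_true(all(derived_keys %in% true_keys))
  # and the bulk of true associations are recovered
  expect_gt(mean(true_keys %in% derived_keys), 0.7)
})
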