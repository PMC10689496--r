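test_that("thinning keeps exactly one point per pixel, first in sorted order", {
  w <- small_world(3)
  g <- w$grids[[1]]
  pts <- tibble::tibble(row = c(5, 5, 5, 7, 7, 9), col = c(5, 5, 5, 2, 2, 1))
  th <- thin_one_per_pixel(pts, g)
  expect_equal(nrow(th), 3)
  expect_equal(attr(th, "source_count"), 6)
  # brute-force dedup oracle on random input
  set.seed(1)
  pts2 <- tibble::tibble(row = sample(40, 300, TRUE), col = sample(40, 300, TRUE))
  th2 <- thin_one_per_pixel(pts2, g)
  expect_equal(nrow(th2), nrow(unique(pts2[, c("row", "col")])))
  # distinct cells pass through unchanged
  pts3 <- tibble::tibble(row = 1:10, col = 1:10)
  expect_equal(nrow(thin_one_per_pixel(pts3, g)), 10)
})

test_that("background sampling draws distinct valid cells, deterministically", {
  w <- small_world(4)
  g <- w$grids[[1]]
  bg <- sample_background(g, 500, seed = 9)
  expect_equal(nrow(bg), 500)
  expect_equal(nrow(unique(bg)), 500)
  expect_identical(bg, sample_background(g, 500, seed = 9))
  all_cells <- sample_background(g, sum(g$mask), seed = 1)
  expect_equal(nrow(all_cells), sum(g$mask))
  expect_error(sample_background(g, sum(g$mask) + 1, seed = 1), "exceeds")
})

test_that("null presences shrink weights and flatten the suitability surface", {
  w <- small_world(5)
  g <- w$grids[[1]]
  set.seed(2)
  bg <- sample_background(g, 1500, seed = 2)
  pres <- bg[sample.int(1500, 800), ]
  fit <- fit_maxent(pres, bg, g)
  expect_lt(max(abs(fit$weights)), 0.1)
  s <- project_suitability(fit, g)
  expect_lt(max(s, na.rm = TRUE) / min(s, na.rm = TRUE), 1.5)
})

test_that("presences in the warmest decile raise suitability there", {
  w <- small_world(6)
  g <- w$grids[[1]]
  warm_cut <- stats::quantile(g$mat[g$mask], 0.9)
  warm <- which(g$mat >= warm_cut & g$mask, arr.ind = TRUE)
  set.seed(3)
  pres <- tibble::tibble(row = warm[, 1], col = warm[, 2])[
    sample(nrow(warm), min(120, nrow(warm))), ]
  bg <- sample_background(g, 1000, seed = 3)
  fit <- fit_maxent(pres, bg, g)
  s <- project_suitability(fit, g)
  expect_gt(mean(s[cbind(pres$row, pres$col)]), mean(s, na.rm = TRUE))
})

test_that("the penalized objective trace is monotone non-increasing", {
  w <- small_world(7)
  g <- w$grids[[1]]
  occ <- simulate_taxon_occurrences(g, w$cfg)
  th <- thin_one_per_pixel(occ, g)
  bg <- sample_background(g, 800, seed = 7)
  fit <- fit_maxent(th, bg, g)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
})

test_that("projection reproduces training-cell suitabilities and keeps masks", {
  w <- small_world(8)
  g <- w$grids[[1]]
  g$mask[3, 3] <- FALSE
  occ <- simulate_taxon_occurrences(g, w$cfg)
  th <- thin_one_per_pixel(occ, g)
  bg <- sample_background(g, 700, seed = 8)
  fit <- fit_maxent(th, bg, g)
  s <- project_suitability(fit, g)
  expect_true(is.na(s[3, 3]))
  expect_equal(suitability_at(fit, g, th), s[cbind(th$row, th$col)])
})

test_that("maxSSS threshold equals the brute-force candidate search", {
  expect_equal(maxsss_threshold(c(0.9, 0.8), c(0.1, 0.2)), 0.8)
  expect_equal(maxsss_threshold(0.5, rep(0.5, 4)), 0.5)
  for (seed in 1:6) {
    set.seed(seed)
    pres <- stats::runif(40)
    bg <- stats::runif(150)
    brute <- function(pres, bg) {
      cand <- sort(unique(pres))
      sc <- vapply(cand, function(th) mean(pres >= th) + mean(bg < th), 0)
      best <- max(sc)
      min(cand[sc == best])  # lowest maximizer
    }
    expect_equal(maxsss_threshold(pres, bg), brute(pres, bg))
    expect_equal(maxsss_threshold(pres, pres), brute(pres, pres))
  }
  expect_error(maxsss_threshold(numeric(0), 1), "empty")
})

test_that("binarization is monotone and matches direct comparison", {
  set.seed(4)
  m <- matrix(stats::runif(100), 10, 10)
  m[1, 1] <- NA
  b1 <- binarize(m, 0)
  expect_true(all(b1[!is.na(b1)] == 1))
  expect_true(is.na(b1[1, 1]))
  expect_true(all(binarize(m, 1.0)[!is.na(m)] %in% c(0, 1)))
  expect_equal(sum(binarize(m, 0.6) == 1, na.rm = TRUE),
               sum(m >= 0.6, na.rm = TRUE))
  prev <- binarize(m, 0.2)
  for (th in c(0.4, 0.6, 0.8)) {
    cur <- binarize(m, th)
    expect_true(all(cur[!is.na(cur)] <= prev[!is.na(prev)]))
    prev <- cur
  }
})

test_that("co-occurrence is the logical AND of its inputs", {
  set.seed(5)
  maps <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.6), 8, 8))
  co <- cooccurrence(maps)
  oracle <- (maps[[1]] & maps[[2]] & maps[[3]] & maps[[4]]) * 1L
  expect_equal(co, oracle)
  expect_true(all(cooccurrence(list(matrix(1, 2, 2), matrix(1, 2, 2))) == 1))
  expect_error(cooccurrence(list(matrix(1, 2, 2))), "two maps")
  expect_error(cooccurrence(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "geometry")
})

test_that("period combination rules match their oracles", {
  a <- matrix(c(1, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(combine_period(list(a, b), "union"),
               matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_equal(combine_period(list(a, a), "intersection"),
               matrix(as.integer(a), 2, 2))
  set.seed(6)
  slices <- lapply(1:4, function(i) matrix(rbinom(36, 1, 0.5), 6, 6))
  maj <- combine_period(slices, "frequency", f = 0.5)
  oracle <- (Reduce(`+`, slices) >= 2) * 1L
  expect_equal(maj, oracle)
  expect_error(combine_period(list()), "empty")
})

test_that("co-occurrence area shrinks as taxa accumulate; nested ranges recovered", {
  w <- small_world(9)
  g <- w$grids[[1]]
  cfg <- w$cfg
  cfg$species$n_presences <- 500L
  maps <- list()
  true_maps <- list()
  for (i in 1:3) {
    sp <- cfg
    sp$species$widths$mat <- cfg$species$widths$mat / i  # nested true ranges
    occ <- simulate_taxon_occurrences(g, sp, taxon = paste0("t", i))
    th <- thin_one_per_pixel(occ, g)
    bg <- sample_background(g, 1000, seed = 100 + i)
    fit <- fit_maxent(th, bg, g)
    thr <- maxsss_threshold(suitability_at(fit, g, th),
                            suitability_at(fit, g, bg))
    maps[[i]] <- binarize(project_suitability(fit, g), thr)
    tru <- true_suitability(g, sp$species)
    thr_t <- maxsss_threshold(tru[cbind(th$row, th$col)],
                              tru[cbind(bg$row, bg$col)])
    true_maps[[i]] <- binarize(tru, thr_t)
  }
  areas <- c(sum(maps[[1]]), sum(cooccurrence(maps[1:2])),
             sum(cooccurrence(maps)))
  expect_true(all(diff(areas) <= 0))
  co <- cooccurrence(maps)
  co_true <- cooccurrence(true_maps)
  jaccard <- sum(co == 1 & co_true == 1) / sum(co == 1 | co_true == 1)
  expect_gte(jaccard, 0.5)
})

test_that("maxent models survive a JSON round trip", {
  w <- small_world(10)
  g <- w$grids[[1]]
  occ <- simulate_taxon_occurrences(g, w$cfg)
  th <- thin_one_per_pixel(occ, g)
  bg <- sample_background(g, 500, seed = 10)
  fit <- fit_maxent(th, bg, g)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(fit, path)
  fit2 <- read_maxent(path)
  expect_equal(project_suitability(fit2, g), project_suitability(fit, g),
               tolerance = 1e-8)
})
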