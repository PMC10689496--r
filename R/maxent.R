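#' Thin occurrences to one point per pixel
#'
#' @param points tibble of occurrence points with `row`/`col` cell indices
#'   (or `x`/`y` coordinates to be snapped to `grid` cells)
#' @param grid a [climate_grid()]
#' @return the input with at most one point per grid cell; retention is
#'   deterministic (the first point in sorted row/col/input order wins). The
#'   pre-thinning count is attached as attribute `source_count`.
#' @export
thin_one_per_pixel <- function(points, grid) {
  pts <- snap_to_grid(points, grid)
  if (!nrow(pts)) stop("all points fall off the grid", call. = FALSE)
  ord <- order(pts$row, pts$col, seq_len(nrow(pts)))
  pts <- pts[ord, ]
  keep <- !duplicated(pts[, c("row", "col")])
  out <- pts[keep, ]
  attr(out, "source_count") <- nrow(points)
  out
}

snap_to_grid <- function(points, grid) {
  d <- dim(grid$mat)
  if (!all(c("row", "col") %in% names(points))) {
    col <- floor((points$x - grid$origin[1]) / grid$cellsize) + 1
    row <- d[1] - floor((points$y - grid$origin[2]) / grid$cellsize)
    points$row <- row; points$col <- col
  }
  ok <- points$row >= 1 & points$row <= d[1] &
    points$col >= 1 & points$col <= d[2]
  ok[ok] <- grid$mask[cbind(points$row[ok], points$col[ok])]
  points[ok, ]
}

#' Sample background cells
#'
#' @param grid a [climate_grid()]
#' @param n number of background points, at most the number of valid cells
#' @param seed integer seed
#' @return tibble of `n` distinct valid cells (`row`, `col`).
#' @export
sample_background <- function(grid, n, seed = 1L) {
  valid <- which(grid$mask)
  if (n > length(valid)) stop("n exceeds the number of valid cells",
                              call. = FALSE)
  set.seed(seed)
  cells <- sort(sample(valid, n))
  rc <- arrayInd(cells, dim(grid$mat))
  tibble::tibble(row = rc[, 1], col = rc[, 2])
}

# feature expansion: per variable linear + quadratic + forward/reverse hinges
maxent_features <- function(mat, ap, spec) {
  one_var <- function(x, rng, knots) {
    x <- pmin(pmax(x, rng[1]), rng[2])  # clamp to training background range
    fwd <- outer(x, knots, function(v, k) pmax(0, (v - k) / (rng[2] - k)))
    rev <- outer(x, knots, function(v, k) pmax(0, (k - v) / (k - rng[1])))
    cbind(lin = x, quad = x^2, fwd, rev)
  }
  cbind(one_var(mat, spec$mat_range, spec$mat_knots),
        one_var(ap, spec$ap_range, spec$ap_knots))
}

#' Fit a maximum-entropy habitat suitability model
#'
#' Maximizes the L1-penalized maximum-entropy (Gibbs-over-background)
#' log-likelihood of the presence points, with quadratic and hinge features
#' only: per climate variable, linear and squared terms plus forward and
#' reverse hinges on `n_knots` evenly spaced knots over the background range.
#' Features are standardized over the background. Per-feature penalties
#' follow the published defaults of the reference MaxEnt implementation
#' (quadratic multiplier interpolated from 1.0 at 10 presences to 0.25 at
#' 100+, hinge 0.5, each scaled by `1/sqrt(n_presences)`), times `reg_mult`.
#' Optimization is proximal-gradient with backtracking line search, so the
#' penalized objective is non-increasing by construction; iteration stops at
#' `tol` relative objective change or `max_iter`.
#'
#' @param presences thinned occurrence tibble (`row`, `col`)
#' @param background background cell tibble from [sample_background()]
#' @param grid the training [climate_grid()]
#' @param max_iter iteration cap (default 2500)
#' @param reg_mult global regularization multiplier
#' @param n_knots hinge knots per variable per direction
#' @param tol relative objective-change convergence tolerance
#' @return object of class `maxent_model` with weights, feature definitions,
#'   normalizer, entropy of the fitted raw distribution, and the per-iteration
#'   penalized objective trace.
#' @export
fit_maxent <- function(presences, background, grid, max_iter = 2500,
                       reg_mult = 1, n_knots = 30, tol = 1e-7) {
  if (nrow(presences) < 5) stop("need at least 5 thinned presences",
                                call. = FALSE)
  bg_mat <- grid$mat[cbind(background$row, background$col)]
  bg_ap <- grid$ap[cbind(background$row, background$col)]
  if (stats::sd(bg_mat) < 1e-12 || stats::sd(bg_ap) < 1e-12) {
    stop("degenerate (constant) predictor layer", call. = FALSE)
  }
  spec <- list(
    mat_range = range(bg_mat), ap_range = range(bg_ap),
    mat_knots = seq(min(bg_mat), max(bg_mat),
                    length.out = n_knots + 2)[2:(n_knots + 1)],
    ap_knots = seq(min(bg_ap), max(bg_ap),
                   length.out = n_knots + 2)[2:(n_knots + 1)]
  )
  Fb <- maxent_features(bg_mat, bg_ap, spec)
  mu <- colMeans(Fb)
  sg <- apply(Fb, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  spec$center <- mu; spec$scale <- sg
  Fb <- sweep(sweep(Fb, 2, mu, `-`), 2, sg, `/`)
  pr_mat <- grid$mat[cbind(presences$row, presences$col)]
  pr_ap <- grid$ap[cbind(presences$row, presences$col)]
  Fp <- maxent_features(pr_mat, pr_ap, spec)
  Fp <- sweep(sweep(Fp, 2, mu, `-`), 2, sg, `/`)

  m <- nrow(Fp)
  # per-feature penalty: quadratic-class features (linear+square), hinge class
  n_feat_per_var <- 2 + 2 * n_knots
  is_quad <- rep(c(rep(TRUE, 2), rep(FALSE, 2 * n_knots)), 2)
  beta_quad <- stats::approx(x = c(0, 10, 17, 30, 100),
                             y = c(1.0, 1.0, 0.6, 0.5, 0.25),
                             xout = min(m, 100), rule = 2)$y
  lambda <- ifelse(is_quad, beta_quad, 0.5) * reg_mult / sqrt(m)

  mean_pres <- colMeans(Fp)
  w <- rep(0, ncol(Fb))
  obj_fn <- function(w) {
    eta <- drop(Fb %*% w)
    lse <- log_sum_exp(eta)
    -sum(mean_pres * w) + lse - log(nrow(Fb))
  }
  objective <- function(w) obj_fn(w) + sum(lambda * abs(w))
  step <- 1
  obj <- objective(w)
  trace <- obj
  for (it in seq_len(max_iter)) {
    eta <- drop(Fb %*% w)
    q <- exp(eta - log_sum_exp(eta))
    grad <- -mean_pres + drop(crossprod(Fb, q))
    repeat {
      w_new <- soft_threshold(w - step * grad, step * lambda)
      f_new <- obj_fn(w_new)
      dw <- w_new - w
      quad_bound <- obj_fn(w) + sum(grad * dw) + sum(dw^2) / (2 * step)
      if (f_new <= quad_bound + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    w <- w_new
    obj_new <- f_new + sum(lambda * abs(w))
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < tol * (abs(obj) + 1)) { obj <- obj_new; break }
    obj <- obj_new
    step <- min(step * 1.5, 1e3)
  }
  eta <- drop(Fb %*% w)
  log_z <- log_sum_exp(eta)
  raw <- exp(eta - log_z)
  entropy <- -sum(raw * log(pmax(raw, 1e-300)))
  structure(list(
    weights = w, feature_spec = spec, lambda = lambda,
    log_z = log_z, entropy = entropy, n_presences = m,
    n_background = nrow(Fb), objective_trace = trace
  ), class = "maxent_model")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

maxent_eta <- function(model, mat, ap) {
  Fm <- maxent_features(mat, ap, model$feature_spec)
  Fm <- sweep(sweep(Fm, 2, model$feature_spec$center, `-`), 2,
              model$feature_spec$scale, `/`)
  drop(Fm %*% model$weights)
}

#' Project habitat suitability over a grid
#'
#' Evaluates the fitted Gibbs model on every valid cell and applies the
#' complementary log-log output transform
#' `1 - exp(-exp(eta - logZ + H))` (`H` the entropy of the fitted raw
#' distribution); `type = "logistic"` uses `plogis(eta - logZ + H)` instead.
#' Feature values outside the training background range are clamped.
#'
#' @param model a [fit_maxent()] model
#' @param grid a [climate_grid()]
#' @param type `"cloglog"` (default) or `"logistic"`
#' @return suitability matrix in `[0, 1]`, `NA` on masked cells.
#' @export
project_suitability <- function(model, grid, type = c("cloglog", "logistic")) {
  type <- match.arg(type)
  idx <- which(grid$mask)
  eta <- maxent_eta(model, grid$mat[idx], grid$ap[idx])
  link <- eta - model$log_z + model$entropy
  suit <- if (type == "cloglog") 1 - exp(-exp(link)) else stats::plogis(link)
  out <- matrix(NA_real_, nrow(grid$mat), ncol(grid$mat))
  out[idx] <- pmin(pmax(suit, 0), 1)
  out
}

#' Suitability at specific cells
#' @param model a [fit_maxent()] model
#' @param grid a [climate_grid()]
#' @param cells tibble with `row`, `col`
#' @param type output transform, see [project_suitability()]
#' @return numeric vector of suitabilities.
#' @export
suitability_at <- function(model, grid, cells, type = "cloglog") {
  s <- project_suitability(model, grid, type = type)
  s[cbind(cells$row, cells$col)]
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Among the distinct presence suitabilities, returns the threshold
#' maximizing sensitivity plus specificity, with background points standing
#' in for absences and cells at the threshold predicted present. Ties break
#' to the lowest maximizing threshold, so binary ranges err inclusive.
#'
#' @param presence_suit suitabilities at presence points
#' @param background_suit suitabilities at background points
#' @return scalar threshold.
#' @export
maxsss_threshold <- function(presence_suit, background_suit) {
  if (!length(presence_suit) || !length(background_suit)) {
    stop("empty suitability series", call. = FALSE)
  }
  cand <- sort(unique(presence_suit))
  score <- vapply(cand, function(thr) {
    mean(presence_suit >= thr) + mean(background_suit < thr)
  }, 0)
  cand[which.max(score)]  # which.max returns the first (lowest) maximizer
}

#' Binarize a suitability map
#' @param map suitability matrix
#' @param threshold cutoff in `[0, 1]`; cells at or above it become 1
#' @return integer presence/absence matrix, `NA` preserved.
#' @export
binarize <- function(map, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- ifelse(map >= threshold, 1L, 0L)
  out
}

#' Multi-taxon co-occurrence map
#' @param maps list of binary maps of identical dimension
#' @return per-cell product (1 only where every taxon is present).
#' @export
cooccurrence <- function(maps) {
  if (length(maps) < 2) stop("need at least two maps", call. = FALSE)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) all(dim(m) == d), TRUE))) {
    stop("map geometry mismatch", call. = FALSE)
  }
  Reduce(`*`, maps)
}

#' Combine co-occurrence slices within a time period
#' @param slices list of binary maps
#' @param rule `"union"` (default), `"intersection"`, or `"frequency"`
#' @param f minimum fraction of slices for `rule = "frequency"`
#' @return combined binary map.
#' @export
combine_period <- function(slices, rule = c("union", "intersection",
                                            "frequency"), f = 0.5) {
  rule <- match.arg(rule)
  if (!length(slices)) stop("empty slice list", call. = FALSE)
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(m) all(dim(m) == d), TRUE))) {
    stop("map geometry mismatch", call. = FALSE)
  }
  s <- Reduce(`+`, slices)
  k <- length(slices)
  switch(rule,
    union = ifelse(s >= 1, 1L, 0L),
    intersection = ifelse(s == k, 1L, 0L),
    frequency = ifelse(s / k >= f, 1L, 0L)
  )
}

#' Serialize a MaxEnt model to JSON
#' @param model a [fit_maxent()] model
#' @param path output path
#' @return the path, invisibly.
#' @export
write_maxent <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$feature_spec <- lapply(m$feature_spec, unlist)
  structure(m, class = "maxent_model")
}
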