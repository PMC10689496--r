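#' Biome class labels
#'
#' The eight biome classes used throughout the biome stage: four low-arboreal
#' classes (`< 5%` arboreal pollen: Desert, Steppe, Tundra, Glacier) and four
#' arboreal-pollen bins.
#'
#' @return character vector of the 8 class labels.
#' @export
biome_classes <- function() {
  c("Desert", "Steppe", "Tundra", "Glacier",
    "5-25% AP", "25-50% AP", "50-75% AP", ">75% AP")
}

#' Default true biome-climate coefficients for the pollen simulator
#'
#' An 8 x 3 softmax coefficient matrix (columns: intercept, standardized
#' temperature, standardized precipitation) encoding a plausible climate
#' ordering: glaciers and tundra in the cold tail, deserts and steppe in the
#' dry tail, and increasing forest density (arboreal-pollen bins) with
#' precipitation. Slope sharpness is set so that a multinomial classifier
#' fitted to sites drawn from this model lands in the mid-seventies percent
#' accuracy regime typical of real pollen-biome classifications.
#'
#' @return numeric matrix with `biome_classes()` rownames.
#' @export
default_biome_coefficients <- function() {
  m <- rbind(
    Desert       = c(-1.0,  3.0, -10.0),
    Steppe       = c( 0.5,  1.0,  -4.0),
    Tundra       = c(-1.0, -8.0,   1.0),
    Glacier      = c(-2.0, -12.0,  0.0),
    `5-25% AP`   = c( 1.0,  1.0,   0.0),
    `25-50% AP`  = c( 1.0,  1.0,   2.0),
    `50-75% AP`  = c( 0.5,  1.0,   4.0),
    `>75% AP`    = c( 0.0,  1.0,   6.0)
  )
  colnames(m) <- c("intercept", "mat_z", "ap_z")
  m[biome_classes(), ]
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

# standardization stats shared by the pollen simulator and its consumers
climate_standardization <- function(grids) {
  v_mat <- unlist(lapply(grids, function(g) g$mat[g$mask]))
  v_ap <- unlist(lapply(grids, function(g) g$ap[g$mask]))
  list(mat_mean = mean(v_mat), mat_sd = stats::sd(v_mat),
       ap_mean = mean(v_ap), ap_sd = stats::sd(v_ap))
}

#' Simulate dated, biome-labelled pollen sites
#'
#' Sites fall uniformly over valid cells and time slices; each site reads the
#' climate of its cell, draws a biome label from the true softmax
#' biome-climate model, and receives an arboreal-pollen percentage consistent
#' with that label (uniform within the label's bin; below 5% for the four
#' low-arboreal classes, which then carry their class as `low_ap_label`).
#'
#' @param grids list of [climate_grid()] slices
#' @param cfg a [sim_config()]; `cfg$pollen$true_coefficients` may override
#'   [default_biome_coefficients()]
#' @return tibble with `x`, `y`, `row`, `col`, `date_bp`, `mat`, `ap`,
#'   `ap_percent`, `low_ap_label`, `biome`. The true coefficient matrix and
#'   standardization stats are attached as attributes `true_coefficients` and
#'   `standardization`.
#' @export
simulate_pollen_sites <- function(grids, cfg) {
  set.seed(derive_seed(cfg$seed, "pollen"))
  coefs <- cfg$pollen$true_coefficients %||% default_biome_coefficients()
  if (!is.matrix(coefs) || nrow(coefs) != 8 || ncol(coefs) != 3) {
    stop("true_coefficients must be an 8 x 3 matrix", call. = FALSE)
  }
  n <- cfg$pollen$n_sites
  std <- climate_standardization(grids)
  slice_times <- vapply(grids, `[[`, 0, "time_bp")
  slice <- sample.int(length(grids), n, replace = TRUE)
  half_gap <- if (length(grids) > 1) {
    abs(stats::median(diff(slice_times))) / 2
  } else {
    500
  }
  rows <- integer(n); cols <- integer(n)
  mats <- numeric(n); aps <- numeric(n)
  for (i in seq_len(n)) {
    g <- grids[[slice[i]]]
    cell <- sample(which(g$mask), 1)
    rc <- arrayInd(cell, dim(g$mat))
    rows[i] <- rc[1]; cols[i] <- rc[2]
    mats[i] <- g$mat[cell]; aps[i] <- g$ap[cell]
  }
  date_bp <- slice_times[slice] + stats::runif(n, -half_gap, half_gap)
  X <- cbind(1, (mats - std$mat_mean) / std$mat_sd,
             (aps - std$ap_mean) / std$ap_sd)
  p <- softmax_rows(X %*% t(coefs))
  biome <- vapply(seq_len(n), function(i) {
    sample(biome_classes(), 1, prob = p[i, ])
  }, "")
  low <- biome %in% biome_classes()[1:4]
  ap_percent <- numeric(n)
  ap_percent[low] <- stats::runif(sum(low), 0, 5)
  bins <- list(`5-25% AP` = c(5, 25), `25-50% AP` = c(25, 50),
               `50-75% AP` = c(50, 75), `>75% AP` = c(75, 100))
  for (b in names(bins)) {
    k <- biome == b
    ap_percent[k] <- stats::runif(sum(k), bins[[b]][1] + 1e-6, bins[[b]][2])
  }
  g1 <- grids[[1]]
  out <- tibble::tibble(
    x = g1$origin[1] + (cols - 0.5) * g1$cellsize,
    y = g1$origin[2] + (nrow(g1$mat) - rows + 0.5) * g1$cellsize,
    row = rows, col = cols,
    date_bp = round(date_bp),
    mat = mats, ap = aps,
    ap_percent = ap_percent,
    low_ap_label = ifelse(low, biome, NA_character_),
    biome = biome
  )
  attr(out, "true_coefficients") <- coefs
  attr(out, "standardization") <- std
  out
}

#' Simulate dated archaeological culture sites
#'
#' Places sites of the five cultures (HG, N, CA, BA, IA) according to a
#' society-biome association table: a site's date picks a time window, a
#' culture active in that window is drawn, and a cell is drawn among cells
#' whose true biome (argmax of the true biome-climate model on the nearest
#' climate slice) belongs to the culture's associated biome set.
#'
#' @param grids list of [climate_grid()] slices
#' @param cfg a [sim_config()]
#' @param table association table from [society_biome_table()]
#' @return tibble with `x`, `y`, `row`, `col`, `date_bp`, `culture`.
#' @export
simulate_culture_sites <- function(grids, cfg, table = society_biome_table()) {
  set.seed(derive_seed(cfg$seed, "cultures"))
  coefs <- cfg$pollen$true_coefficients %||% default_biome_coefficients()
  std <- climate_standardization(grids)
  slice_times <- vapply(grids, `[[`, 0, "time_bp")
  biome_of <- lapply(grids, function(g) {
    idx <- which(g$mask)
    X <- cbind(1, (g$mat[idx] - std$mat_mean) / std$mat_sd,
               (g$ap[idx] - std$ap_mean) / std$ap_sd)
    cls <- biome_classes()[max.col(X %*% t(coefs))]
    list(idx = idx, biome = cls)
  })
  windows <- unique(table[, c("window_start", "window_end")])
  n <- cfg$cultures$n_sites
  out <- vector("list", n)
  g1 <- grids[[1]]
  for (i in seq_len(n)) {
    repeat {
      w <- windows[sample.int(nrow(windows), 1), ]
      date <- stats::runif(1, w$window_end, w$window_start)
      active <- society_associations(table, date)
      active <- active[lengths(active) > 0]
      if (!length(active)) next
      culture <- sample(names(active), 1)
      si <- which.min(abs(slice_times - date))
      ok <- biome_of[[si]]$biome %in% active[[culture]]
      if (!any(ok)) next
      cell <- biome_of[[si]]$idx[sample(which(ok), 1)]
      rc <- arrayInd(cell, dim(g1$mat))
      out[[i]] <- tibble::tibble(
        x = g1$origin[1] + (rc[2] - 0.5) * g1$cellsize,
        y = g1$origin[2] + (nrow(g1$mat) - rc[1] + 0.5) * g1$cellsize,
        row = rc[1], col = rc[2],
        date_bp = round(date), culture = culture
      )
      break
    }
  }
  dplyr::bind_rows(out)
}
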