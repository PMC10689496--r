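#' Two-layer climate grid
#'
#' A raster stack for one time slice: mean annual temperature (`mat`,
#' degrees C) and annual precipitation (`ap`, mm) on a shared rectangular
#' grid, plus a validity mask and a nominal date in years BP.
#'
#' @param mat,ap numeric matrices of identical dimension
#' @param time_bp slice date, years BP
#' @param origin `c(x, y)` of the lower-left corner
#' @param cellsize cell edge length (arbitrary map units)
#' @param mask logical matrix, `TRUE` where cells hold data; defaults to all
#'   cells valid
#' @return object of class `climate_grid`
#' @export
climate_grid <- function(mat, ap, time_bp = 0, origin = c(0, 0), cellsize = 1,
                         mask = NULL) {
  stopifnot(is.matrix(mat), is.matrix(ap), all(dim(mat) == dim(ap)))
  if (is.null(mask)) mask <- !is.na(mat) & !is.na(ap)
  stopifnot(all(dim(mask) == dim(mat)))
  structure(list(mat = mat, ap = ap, time_bp = time_bp, origin = origin,
                 cellsize = cellsize, mask = mask),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %dx%d cells, %d valid, %s BP\n",
              nrow(x$mat), ncol(x$mat), sum(x$mask),
              format(x$time_bp, big.mark = ",")))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$mat)

#' Tabular view of a climate grid
#' @param x a [climate_grid()]
#' @param ... unused
#' @return tibble with `row`, `col`, `x`, `y`, `mat`, `ap` for valid cells.
#' @export
as_tibble.climate_grid <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    x = x$origin[1] + (idx[, 2] - 0.5) * x$cellsize,
    y = x$origin[2] + (nrow(x$mat) - idx[, 1] + 0.5) * x$cellsize,
    mat = x$mat[idx], ap = x$ap[idx]
  )
}

#' Read and write climate layers as ESRI ASCII grids
#'
#' Each layer goes to `<prefix>_mat.asc` / `<prefix>_ap.asc` with the usual
#' six-line ASCII-grid header; nodata cells use -9999.
#'
#' @param grid a [climate_grid()]
#' @param prefix file path prefix
#' @return `read_climate_grid()` returns a [climate_grid()];
#'   `write_climate_grid()` the prefix, invisibly.
#' @export
write_climate_grid <- function(grid, prefix) {
  for (layer in c("mat", "ap")) {
    m <- grid[[layer]]
    m[!grid$mask] <- -9999
    hdr <- c(
      sprintf("ncols %d", ncol(m)),
      sprintf("nrows %d", nrow(m)),
      sprintf("xllcorner %.10g", grid$origin[1]),
      sprintf("yllcorner %.10g", grid$origin[2]),
      sprintf("cellsize %.10g", grid$cellsize),
      "NODATA_value -9999"
    )
    body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    writeLines(c(hdr, body), paste0(prefix, "_", layer, ".asc"))
  }
  invisible(prefix)
}

#' @rdname write_climate_grid
#' @param time_bp slice date to attach on read
#' @export
read_climate_grid <- function(prefix, time_bp = 0) {
  layers <- lapply(c("mat", "ap"), function(layer) {
    lines <- readLines(paste0(prefix, "_", layer, ".asc"))
    hdr <- strsplit(lines[1:6], "\\s+")
    vals <- stats::setNames(
      as.numeric(vapply(hdr, `[`, "", 2)),
      tolower(vapply(hdr, `[`, "", 1))
    )
    body <- lapply(lines[-(1:6)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    m <- do.call(rbind, body)
    m[m == vals[["nodata_value"]]] <- NA
    list(m = m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
         cellsize = vals[["cellsize"]])
  })
  climate_grid(layers[[1]]$m, layers[[2]]$m, time_bp = time_bp,
               origin = layers[[1]]$origin, cellsize = layers[[1]]$cellsize)
}

# gaussian blur with edge renormalization; sd in cells
gauss_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  h <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-h:h, 0, sd)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    full <- stats::convolve(c(rep(0, h), v, rep(0, h)), rev(k), type = "filter")
    wt <- stats::convolve(c(rep(0, h), rep(1, length(v)), rep(0, h)), rev(k),
                          type = "filter")
    full / wt
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Simulate a series of smooth climate grids
#'
#' Layers are Gaussian random fields (spatially smoothed white noise) that
#' drift between consecutive time slices through an AR(1) blend, then are
#' mapped into the configured temperature and precipitation ranges.
#'
#' @param cfg a [sim_config()]
#' @return list of [climate_grid()] objects, oldest slice first, with
#'   `time_bp` spaced evenly over 15000..1500 BP (or a single slice at
#'   15000 BP).
#' @export
simulate_climate_series <- function(cfg) {
  cl <- cfg$climate
  set.seed(derive_seed(cfg$seed, "climate"))
  nr <- cl$grid_rows; nc <- cl$grid_cols; ns <- cl$n_time_slices
  times <- if (ns == 1) 15000 else round(seq(15000, 1500, length.out = ns))
  make_series <- function() {
    fields <- vector("list", ns)
    if (cl$smoothness >= max(nr, nc)) {
      # kernel spans the whole grid: the field is flat at the range midpoint
      return(replicate(ns, matrix(0, nr, nc), simplify = FALSE))
    }
    f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), cl$smoothness)
    fields[[1]] <- f
    for (i in seq_len(ns - 1)) {
      eps <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), cl$smoothness)
      f <- cl$drift * f + sqrt(1 - cl$drift^2) * eps
      fields[[i + 1]] <- f
    }
    all_v <- unlist(fields)
    mu <- mean(all_v); sg <- stats::sd(all_v)
    lapply(fields, function(x) if (sg < 1e-12) x * 0 else (x - mu) / sg)
  }
  to_range <- function(z, rng) {
    mid <- mean(rng); half <- diff(rng) / 2
    pmin(pmax(mid + z * half / 3, rng[1]), rng[2])
  }
  mats <- make_series()
  aps <- make_series()
  lapply(seq_len(ns), function(i) {
    climate_grid(
      to_range(mats[[i]], cl$temp_range),
      to_range(aps[[i]], cl$precip_range),
      time_bp = times[i]
    )
  })
}

#' True Gaussian-response suitability of a taxon on a grid
#'
#' @param grid a [climate_grid()]
#' @param species list with `optima` and `widths`, each holding `mat` and
#'   `ap` entries (see [sim_config()])
#' @return matrix of suitabilities in `[0, 1]`; masked cells are `NA`.
#' @export
true_suitability <- function(grid, species) {
  s <- exp(-0.5 * ((grid$mat - species$optima$mat) / species$widths$mat)^2
           - 0.5 * ((grid$ap - species$optima$ap) / species$widths$ap)^2)
  s[!grid$mask] <- NA
  s
}

#' Simulate taxon occurrence points
#'
#' Samples presence points (with replacement, i.e. before any thinning) with
#' probability proportional to the true Gaussian-response suitability of the
#' taxon over the grid.
#'
#' @param grid a [climate_grid()]
#' @param cfg a [sim_config()]; `cfg$species` holds optima, widths and
#'   `n_presences`
#' @param taxon taxon label for the output
#' @return tibble of occurrence points: `taxon`, `row`, `col`, `x`, `y`.
#' @export
simulate_taxon_occurrences <- function(grid, cfg, taxon = "taxon1") {
  set.seed(derive_seed(cfg$seed, paste0("species:", taxon)))
  s <- true_suitability(grid, cfg$species)
  idx <- which(grid$mask)
  w <- s[idx]
  if (all(w == 0 | is.na(w))) stop("true suitability is zero everywhere",
                                   call. = FALSE)
  pick <- sample(idx, cfg$species$n_presences, replace = TRUE, prob = w)
  rc <- arrayInd(pick, dim(grid$mat))
  tibble::tibble(
    taxon = taxon, row = rc[, 1], col = rc[, 2],
    x = grid$origin[1] + (rc[, 2] - 0.5) * grid$cellsize,
    y = grid$origin[2] + (nrow(grid$mat) - rc[, 1] + 0.5) * grid$cellsize
  )
}
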