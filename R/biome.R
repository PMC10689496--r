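#' Society-biome association table
#'
#' The culture x time-window x biome association lookup used to map past
#' societies from biome rasters: which biomes each of the five cultures
#' (hunter-gatherers HG, Neolithic N, Copper Age CA, Bronze Age BA, Iron Age
#' IA) occupied in each of the five time windows between 15,000 and 2,000
#' years BP. Returned tidy: one row per (window, culture, biome) association;
#' a culture absent from a window simply has no rows there.
#'
#' @param extend_to_1500 if `TRUE`, the final window runs to 1500 BP instead
#'   of 2000 BP.
#' @return tibble with `window_start`, `window_end` (years BP, start > end),
#'   `culture`, `biome`.
#' @export
society_biome_table <- function(extend_to_1500 = FALSE) {
  forests <- c("5-25% AP", "25-50% AP", "50-75% AP", ">75% AP")
  lt50 <- c("Steppe", "5-25% AP", "25-50% AP")
  lt75 <- c("Steppe", "5-25% AP", "25-50% AP", "50-75% AP")
  all_open <- c("Steppe", forests)
  assoc <- list(
    list(15000, 11000, list(HG = c("Steppe", forests))),
    list(11000, 8000, list(HG = forests, N = lt50)),
    list(8000, 6000, list(HG = ">75% AP", N = lt50, CA = lt75)),
    list(6000, 4000, list(HG = ">75% AP", CA = lt75, BA = lt75)),
    list(4000, if (extend_to_1500) 1500 else 2000,
         list(BA = all_open, IA = all_open))
  )
  dplyr::bind_rows(lapply(assoc, function(w) {
    dplyr::bind_rows(lapply(names(w[[3]]), function(cu) {
      tibble::tibble(window_start = w[[1]], window_end = w[[2]],
                     culture = cu, biome = w[[3]][[cu]])
    }))
  }))
}

#' Look up the biome associations active at a date
#'
#' @param table a [society_biome_table()]-shaped tibble
#' @param date_bp date in years BP; a window covers `(end, start]`
#' @return named list culture -> character vector of biomes (cultures with no
#'   association in the window map to empty vectors).
#' @export
society_associations <- function(table, date_bp) {
  w <- table[table$window_start >= date_bp & table$window_end < date_bp, ]
  out <- stats::setNames(
    lapply(c("HG", "N", "CA", "BA", "IA"),
           function(cu) unique(w$biome[w$culture == cu])),
    c("HG", "N", "CA", "BA", "IA")
  )
  if (!nrow(w)) stop("date ", date_bp, " BP outside every table window",
                     call. = FALSE)
  out
}

#' Bin a pollen site into a biome class
#'
#' Sites with at least 5% arboreal pollen (AP) fall into four AP bins
#' (lower-inclusive at 5/25/50; 75 belongs to the 50-75% bin and only
#' strictly greater values to the top class). Sites under 5% AP take their
#' supplied low-arboreal label (Desert, Steppe, Tundra or Glacier).
#'
#' @param ap_percent arboreal pollen percentage, in `[0, 100]`
#' @param low_ap_label label for sites under 5% AP; may be `NA` for sites at
#'   or above 5%
#' @return character vector of biome classes.
#' @export
assign_biome <- function(ap_percent, low_ap_label = NA_character_) {
  if (any(ap_percent < 0 | ap_percent > 100)) {
    stop("ap_percent outside [0, 100]", call. = FALSE)
  }
  low_ap_label <- rep_len(low_ap_label, length(ap_percent))
  low <- ap_percent < 5
  if (any(low & (is.na(low_ap_label) |
                 !low_ap_label %in% biome_classes()[1:4]))) {
    stop("sites under 5% AP need a low-AP label ",
         "(Desert, Steppe, Tundra or Glacier)", call. = FALSE)
  }
  out <- character(length(ap_percent))
  out[low] <- low_ap_label[low]
  out[!low & ap_percent < 25] <- "5-25% AP"
  out[!low & ap_percent >= 25 & ap_percent < 50] <- "25-50% AP"
  out[!low & ap_percent >= 50 & ap_percent <= 75] <- "50-75% AP"
  out[ap_percent > 75] <- ">75% AP"
  out
}

#' Fit the multinomial biome-climate model
#'
#' Multinomial logistic regression of biome class on standardized mean annual
#' temperature and annual precipitation, fitted by maximum likelihood.
#' Coefficients whose magnitude exceeds 30 on the standardized scale indicate
#' (quasi-)separation and are capped with a warning.
#'
#' @param sites tibble with `biome`, `mat`, `ap` columns (e.g. from
#'   [simulate_pollen_sites()])
#' @return object of class `biome_model`: softmax coefficient matrix (class x
#'   intercept/mat_z/ap_z, reference class row all zero) plus the
#'   standardization constants.
#' @export
fit_biome_model <- function(sites) {
  cls <- sort(unique(sites$biome))
  if (length(cls) < 2) stop("need at least two observed biome classes",
                            call. = FALSE)
  std <- list(mat_mean = mean(sites$mat), mat_sd = stats::sd(sites$mat),
              ap_mean = mean(sites$ap), ap_sd = stats::sd(sites$ap))
  df <- data.frame(
    biome = factor(sites$biome, levels = cls),
    mat_z = (sites$mat - std$mat_mean) / std$mat_sd,
    ap_z = (sites$ap - std$ap_mean) / std$ap_sd
  )
  fit <- nnet::multinom(biome ~ mat_z + ap_z, data = df, trace = FALSE,
                        maxit = 1000, reltol = 1e-12)
  co <- stats::coef(fit)
  if (length(cls) == 2) co <- matrix(co, 1, 3,
                                     dimnames = list(cls[2],
                                                     c("(Intercept)", "mat_z",
                                                       "ap_z")))
  coefs <- rbind(0, co)
  rownames(coefs) <- cls
  colnames(coefs) <- c("intercept", "mat_z", "ap_z")
  if (any(abs(coefs) > 30)) {
    warning("separation suspected; coefficients capped at |30|")
    coefs <- pmin(pmax(coefs, -30), 30)
  }
  structure(list(classes = cls, coefficients = coefs, standardization = std,
                 loglik = -fit$value, n = nrow(df)),
            class = "biome_model")
}

#' Predicted biome probabilities
#' @param object a [fit_biome_model()] fit
#' @param newdata tibble with `mat` and `ap`
#' @param ... unused
#' @return matrix of per-site class probabilities (rows sum to one).
#' @export
predict_biome_prob <- function(object, newdata, ...) {
  std <- object$standardization
  X <- cbind(1, (newdata$mat - std$mat_mean) / std$mat_sd,
             (newdata$ap - std$ap_mean) / std$ap_sd)
  p <- softmax_rows(X %*% t(object$coefficients))
  colnames(p) <- object$classes
  p
}

#' @export
predict.biome_model <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  p <- predict_biome_prob(object, newdata)
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Classification performance of a biome model
#'
#' Hard-assigns each site to its most probable class and reports overall
#' accuracy, Cohen's kappa (chance agreement from marginal products),
#' per-class accuracy and the confusion matrix.
#'
#' @param model a [fit_biome_model()] fit
#' @param sites tibble with `biome`, `mat`, `ap`
#' @return list with `accuracy`, `kappa`, `per_class` (tibble) and
#'   `confusion` (observed x predicted matrix).
#' @export
classification_metrics <- function(model, sites) {
  pred <- predict(model, sites)
  lv <- union(model$classes, unique(sites$biome))
  confusion <- table(observed = factor(sites$biome, lv),
                     predicted = factor(pred, lv))
  metrics_from_confusion(confusion)
}

#' Accuracy and Cohen's kappa from a confusion matrix
#' @param confusion square contingency table, observed rows x predicted cols
#' @return list with `accuracy`, `kappa`, `per_class`, `confusion`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.table(confusion)
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  per_class <- tibble::tibble(
    class = rownames(confusion),
    n = as.numeric(rowSums(confusion)),
    accuracy = ifelse(rowSums(confusion) > 0,
                      diag(confusion) / rowSums(confusion), NA_real_)
  )
  list(accuracy = po, kappa = kappa, per_class = per_class,
       confusion = confusion)
}

#' Project a biome model over a climate grid
#'
#' @param model a [fit_biome_model()] fit (or any object with `classes`,
#'   `coefficients`, `standardization` in the same layout)
#' @param grid a [climate_grid()]
#' @return integer matrix of class codes (indices into
#'   `attr(, "classes")`), `NA` on masked cells.
#' @export
project_biome_map <- function(model, grid) {
  idx <- which(grid$mask)
  p <- predict_biome_prob(model,
                          tibble::tibble(mat = grid$mat[idx],
                                         ap = grid$ap[idx]))
  out <- matrix(NA_integer_, nrow(grid$mat), ncol(grid$mat))
  out[idx] <- max.col(p, ties.method = "first")
  attr(out, "classes") <- model$classes
  out
}

#' Map a past society from a biome raster
#'
#' @param biomes integer biome raster from [project_biome_map()]
#' @param time_bp date of the raster, years BP
#' @param culture one of `"HG"`, `"N"`, `"CA"`, `"BA"`, `"IA"`
#' @param table a [society_biome_table()]
#' @return binary matrix (1 where the cell's biome is associated with the
#'   culture in the window containing `time_bp`), `NA` on masked cells.
#' @export
society_map <- function(biomes, time_bp, culture, table = society_biome_table()) {
  assoc <- society_associations(table, time_bp)[[culture]]
  classes <- attr(biomes, "classes")
  out <- matrix(0L, nrow(biomes), ncol(biomes))
  out[is.na(biomes)] <- NA_integer_
  if (length(assoc)) {
    out[!is.na(biomes) & matrix(classes[biomes] %in% assoc,
                                nrow(biomes))] <- 1L
  }
  out
}

#' Per-cell mode across raster slices
#'
#' @param slices list of integer/binary matrices of identical dimension
#' @return matrix of the per-cell modal value; ties resolved to the value of
#'   the earliest slice among the tied values.
#' @export
aggregate_mode <- function(slices) {
  if (!length(slices)) stop("empty slice list", call. = FALSE)
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) all(dim(s) == d), TRUE))) {
    stop("slice geometry mismatch", call. = FALSE)
  }
  if (length(slices) == 1) return(slices[[1]])
  arr <- vapply(slices, identity, slices[[1]])
  out <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    counts <- table(v)
    best <- max(counts)
    v[match(TRUE, counts[as.character(v)] == best)]
  })
  attr(out, "classes") <- attr(slices[[1]], "classes")
  out
}

#' Cross-tabulate archaeological sites against inferred biomes
#'
#' Each site is dated into a table window and located on the nearest climate
#' slice's biome raster; counts and within-(window, culture) fractions are
#' tabulated and an association is declared where the fraction reaches
#' `cutoff`, yielding a derived society-biome table.
#'
#' @param sites tibble with `row`, `col`, `date_bp`, `culture`
#' @param rasters list of biome rasters (one per slice)
#' @param slice_times numeric vector of the rasters' dates (years BP)
#' @param table window definitions (a [society_biome_table()])
#' @param cutoff association threshold on the within-culture fraction
#' @return list: `crosstab` (tibble window/culture/biome/n/fraction/associated),
#'   `derived_table` (rows with `associated`), `n_skipped` (off-grid sites).
#' @export
culture_biome_crosstab <- function(sites, rasters, slice_times,
                                   table = society_biome_table(),
                                   cutoff = 0.05) {
  d <- dim(rasters[[1]])
  classes <- attr(rasters[[1]], "classes")
  windows <- unique(table[, c("window_start", "window_end")])
  on_grid <- sites$row >= 1 & sites$row <= d[1] &
    sites$col >= 1 & sites$col <= d[2]
  n_skipped <- sum(!on_grid)
  s <- sites[on_grid, ]
  si <- vapply(s$date_bp, function(t) which.min(abs(slice_times - t)), 0L)
  code <- vapply(seq_len(nrow(s)), function(i) {
    rasters[[si[i]]][s$row[i], s$col[i]]
  }, 0L)
  wi <- vapply(s$date_bp, function(t) {
    w <- which(windows$window_start >= t & windows$window_end < t)
    if (!length(w)) NA_integer_ else w[1]
  }, 0L)
  keep <- !is.na(wi) & !is.na(code)
  n_skipped <- n_skipped + sum(!keep)
  s <- s[keep, ]; code <- code[keep]; wi <- wi[keep]
  crosstab <- tibble::tibble(
    window_start = windows$window_start[wi],
    window_end = windows$window_end[wi],
    culture = s$culture,
    biome = classes[code]
  ) |>
    dplyr::count(.data$window_start, .data$window_end, .data$culture,
                 .data$biome, name = "n") |>
    dplyr::group_by(.data$window_start, .data$window_end, .data$culture) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(associated = .data$fraction >= cutoff)
  list(
    crosstab = crosstab,
    derived_table = dplyr::select(
      dplyr::filter(crosstab, .data$associated),
      "window_start", "window_end", "culture", "biome"
    ),
    n_skipped = n_skipped
  )
}

#' @export
tidy.biome_model <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    class = rep(rownames(co), ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co)
  )
}

#' @export
glance.biome_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_sites = x$n,
                 log_likelihood = x$loglik)
}
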