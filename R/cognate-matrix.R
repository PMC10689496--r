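#' Binary cognate matrix
#'
#' The central data container for the linguistic stage: a languages-by-cognate
#' set matrix of presence (1) / absence (0) / uncertain (`?`, stored as `NA`)
#' codings, partitioned into meaning concepts, with one sampling date per
#' language (years BP; 0 for languages spoken today).
#'
#' @param cells integer matrix (languages x cognate sets) with values 0, 1 or
#'   `NA` (uncertain). Row names are the language names.
#' @param columns data frame with one row per matrix column: `concept_id`,
#'   `cognate_id` and logical `is_ascertainment`. Ascertainment columns are the
#'   all-absent dummy characters used to condition the likelihood on cognate
#'   sets being observable; see [add_ascertainment_columns()].
#' @param tip_dates named numeric vector of sampling dates in years BP, one
#'   per language, all `>= 0`.
#'
#' @return An object of class `cognate_matrix`.
#' @seealso [read_cognate_matrix()], [merge_concepts()], [matrix_summary()]
#' @export
cognate_matrix <- function(cells, columns, tip_dates) {
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  storage.mode(cells) <- "integer"
  columns <- tibble::as_tibble(columns)
  if (!all(c("concept_id", "cognate_id") %in% names(columns))) {
    stop("`columns` needs concept_id and cognate_id", call. = FALSE)
  }
  if (is.null(columns[["is_ascertainment"]])) columns$is_ascertainment <- FALSE
  obj <- structure(
    list(
      cells = cells,
      columns = columns,
      tip_dates = tip_dates
    ),
    class = "cognate_matrix"
  )
  validate_cognate_matrix(obj)
}

validate_cognate_matrix <- function(m) {
  cells <- m$cells
  langs <- rownames(cells)
  if (is.null(langs) || anyDuplicated(langs)) {
    stop("languages (row names) must be present and unique", call. = FALSE)
  }
  bad <- which(!(cells %in% c(0L, 1L, NA_integer_)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(cells))
    stop(sprintf(
      "cell value outside {1,0,?} at language '%s', column %d (value %s)",
      langs[i[1]], i[2], cells[bad[1]]
    ), call. = FALSE)
  }
  if (nrow(m$columns) != ncol(cells)) {
    stop("`columns` must describe every matrix column", call. = FALSE)
  }
  if (!setequal(names(m$tip_dates), langs) || any(m$tip_dates < 0)) {
    stop("tip_dates must name every language and be >= 0 years BP", call. = FALSE)
  }
  m$tip_dates <- m$tip_dates[langs]
  asc_per_concept <- tapply(m$columns$is_ascertainment, m$columns$concept_id, sum)
  if (any(asc_per_concept > 1)) {
    stop("at most one ascertainment column per concept", call. = FALSE)
  }
  real_per_concept <- tapply(!m$columns$is_ascertainment, m$columns$concept_id, sum)
  if (any(real_per_concept < 1)) {
    stop("every concept needs at least one non-ascertainment column", call. = FALSE)
  }
  m
}

#' @export
print.cognate_matrix <- function(x, ...) {
  s <- matrix_summary(x)
  cat(sprintf(
    "<cognate_matrix> %d languages, %d concepts, %d cognate sets (%d ascertainment), %.1f%% '?'\n",
    s$n_languages, s$n_concepts, s$n_cognate_sets, s$n_ascertainment,
    100 * s$missing_fraction
  ))
  invisible(x)
}

#' Languages of a cognate matrix
#' @param m a [cognate_matrix()]
#' @return character vector of language names, in matrix order.
#' @export
languages <- function(m) rownames(m$cells)

#' Concept ids of a cognate matrix
#' @param m a [cognate_matrix()]
#' @return character vector of distinct concept ids, in first-appearance order.
#' @export
concepts <- function(m) unique(m$columns$concept_id)

#' Summarize a cognate matrix
#'
#' @param m a [cognate_matrix()]
#' @return A one-row tibble with language/concept/cognate-set counts,
#'   per-language presence counts (list column) and the fraction of uncertain
#'   cells among non-ascertainment columns.
#' @export
matrix_summary <- function(m) {
  real <- !m$columns$is_ascertainment
  cells <- m$cells[, real, drop = FALSE]
  tibble::tibble(
    n_languages = nrow(m$cells),
    n_concepts = length(concepts(m)),
    n_cognate_sets = sum(real),
    n_ascertainment = sum(!real),
    missing_fraction = if (length(cells)) mean(is.na(cells)) else 0,
    presence_per_language = list(rowSums(cells == 1L, na.rm = TRUE))
  )
}

#' Merge meaning concepts
#'
#' Reassigns the cognate-set columns of several source concepts to a single
#' target concept, the bookkeeping step used when semantically inseparable
#' concepts (e.g. generic motion verbs sharing roots) are collapsed before
#' analysis. Cell codings are untouched; only the concept partition changes.
#'
#' @param m a [cognate_matrix()]
#' @param rules list of rules, each `list(sources = <chr>, target = <chr>)`.
#'   Sources must exist in `m` and be disjoint across rules.
#' @return The matrix with `length(sources) - 1` fewer concepts per rule.
#' @export
merge_concepts <- function(m, rules) {
  if (!length(rules)) return(m)
  all_sources <- unlist(lapply(rules, `[[`, "sources"))
  if (anyDuplicated(all_sources)) stop("rule sources must be disjoint", call. = FALSE)
  known <- concepts(m)
  missing <- setdiff(all_sources, known)
  if (length(missing)) {
    stop("merge rule references unknown concept(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cid <- m$columns$concept_id
  for (r in rules) {
    cid[cid %in% r$sources] <- r$target
  }
  m$columns$concept_id <- cid
  # a merged concept may have inherited several ascertainment dummies
  dup_asc <- m$columns$is_ascertainment &
    duplicated(paste(m$columns$concept_id, m$columns$is_ascertainment))
  if (any(dup_asc)) {
    keep <- !dup_asc
    m$cells <- m$cells[, keep, drop = FALSE]
    m$columns <- m$columns[keep, , drop = FALSE]
  }
  validate_cognate_matrix(m)
}

#' Append per-concept ascertainment columns
#'
#' Adds one all-absent dummy cognate set per meaning concept, flagged
#' `is_ascertainment`. The likelihood uses these columns to condition on the
#' fact that cognate sets absent from every sampled language can never be
#' observed (latent cognates).
#'
#' @param m a [cognate_matrix()] without ascertainment columns
#' @return The matrix with `n_concepts` extra flagged all-zero columns.
#' @export
add_ascertainment_columns <- function(m) {
  if (any(m$columns$is_ascertainment)) {
    stop("ascertainment columns already present", call. = FALSE)
  }
  cps <- concepts(m)
  extra <- matrix(0L, nrow = nrow(m$cells), ncol = length(cps),
                  dimnames = list(rownames(m$cells), NULL))
  m$cells <- cbind(m$cells, extra)
  m$columns <- dplyr::bind_rows(
    m$columns,
    tibble::tibble(
      concept_id = cps,
      cognate_id = paste0(cps, ".asc"),
      is_ascertainment = TRUE
    )
  )
  # keep columns of one concept contiguous
  ord <- order(match(m$columns$concept_id, cps), m$columns$is_ascertainment)
  m$cells <- m$cells[, ord, drop = FALSE]
  m$columns <- m$columns[ord, , drop = FALSE]
  validate_cognate_matrix(m)
}

#' @export
#' @importFrom generics glance
glance.cognate_matrix <- function(x, ...) {
  dplyr::select(matrix_summary(x), -"presence_per_language")
}
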