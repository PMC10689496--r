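#' Read and write cognate matrices
#'
#' Two on-disk dialects are supported. The CSV layout has languages as rows
#' and cognate sets as columns, with three header lines (concept ids, cognate
#' ids, ascertainment flags) and a `tip_date_bp` column. The NEXUS layout is a
#' standard-datatype DATA block (symbols "01", missing `?`) followed by a SETS
#' block with one charset per concept plus an `ascertainment` charset; this is
#' the layout tip-dating engines consume.
#'
#' @param path file path
#' @param format `"csv"` or `"nexus"`; the default guesses from the extension.
#' @return A [cognate_matrix()].
#' @export
read_cognate_matrix <- function(path, format = c("auto", "csv", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(format, csv = read_cognate_csv(path), nexus = read_cognate_nexus(path))
}

#' @rdname read_cognate_matrix
#' @param m a [cognate_matrix()]
#' @export
write_cognate_matrix <- function(m, path, format = c("auto", "csv", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  }
  switch(format, csv = write_cognate_csv(m, path), nexus = write_cognate_nexus(m, path))
  invisible(path)
}

cell_to_symbol <- function(x) ifelse(is.na(x), "?", as.character(x))

symbol_to_cell <- function(s, where) {
  out <- rep(NA_integer_, length(s))
  out[s == "0"] <- 0L
  out[s == "1"] <- 1L
  bad <- !(s %in% c("0", "1", "?"))
  if (any(bad)) {
    stop(sprintf("unknown symbol '%s' at %s", s[which(bad)[1]], where[which(bad)[1]]),
         call. = FALSE)
  }
  out
}

write_cognate_csv <- function(m, path) {
  hdr1 <- c("concept", "", m$columns$concept_id)
  hdr2 <- c("cognate", "", m$columns$cognate_id)
  hdr3 <- c("ascertainment", "", as.integer(m$columns$is_ascertainment))
  body <- cbind(
    rownames(m$cells),
    format(m$tip_dates[rownames(m$cells)], trim = TRUE, scientific = FALSE),
    apply(m$cells, 2, cell_to_symbol)
  )
  lines <- apply(rbind(hdr1, hdr2, hdr3, c("language", "tip_date_bp",
                                           rep("", ncol(m$cells))), body),
                 1, paste, collapse = ",")
  # the 4th header line only labels the two leading columns
  lines[4] <- "language,tip_date_bp"
  writeLines(lines, path)
}

read_cognate_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5) stop("malformed cognate CSV: too few lines", call. = FALSE)
  split1 <- strsplit(lines, ",", fixed = TRUE)
  # strsplit drops trailing empty fields; pad every row to the widest
  width <- max(lengths(split1))
  split1 <- lapply(split1, function(x) c(x, rep("", width - length(x))))
  grab <- function(i, tag) {
    x <- split1[[i]]
    if (x[1] != tag) stop("malformed cognate CSV: expected '", tag, "' header", call. = FALSE)
    x[-(1:2)]
  }
  concept_id <- grab(1, "concept")
  cognate_id <- grab(2, "cognate")
  asc <- as.logical(as.integer(grab(3, "ascertainment")))
  body <- split1[-(1:4)]
  langs <- vapply(body, `[`, "", 1)
  dates <- as.numeric(vapply(body, `[`, "", 2))
  ncols <- length(concept_id)
  cells <- matrix(NA_integer_, length(langs), ncols, dimnames = list(langs, NULL))
  for (i in seq_along(body)) {
    vals <- body[[i]][-(1:2)]
    if (length(vals) != ncols) {
      stop("row for language '", langs[i], "' has ", length(vals),
           " cells, expected ", ncols, call. = FALSE)
    }
    cells[i, ] <- symbol_to_cell(
      vals, sprintf("language '%s', column %d", langs[i], seq_len(ncols)))
  }
  if (anyDuplicated(langs)) stop("duplicate language name in CSV", call. = FALSE)
  if (any(concept_id == "")) stop("column with no concept id", call. = FALSE)
  cognate_matrix(
    cells,
    tibble::tibble(concept_id = concept_id, cognate_id = cognate_id,
                   is_ascertainment = asc),
    stats::setNames(dates, langs)
  )
}

write_cognate_nexus <- function(m, path) {
  seqs <- lapply(seq_len(nrow(m$cells)),
                 function(i) cell_to_symbol(m$cells[i, ]))
  names(seqs) <- rownames(m$cells)
  ape::write.nexus.data(seqs, path, format = "standard", interleaved = FALSE)
  # rewrite symbols to the binary alphabet, then append SETS + date metadata
  txt <- readLines(path)
  txt <- sub('symbols="0123456789"', 'symbols="01"', txt, fixed = TRUE)
  txt <- txt[!grepl("^\\[Data written by", txt)]  # drop the timestamp comment
  cps <- concepts(m)
  charsets <- vapply(cps, function(cp) {
    idx <- which(m$columns$concept_id == cp)
    sprintf("    charset '%s' = %s;", cp, paste(idx, collapse = " "))
  }, "")
  asc_idx <- which(m$columns$is_ascertainment)
  sets <- c("BEGIN SETS;", charsets,
            if (length(asc_idx)) {
              sprintf("    charset 'ascertainment' = %s;",
                      paste(asc_idx, collapse = " "))
            },
            "END;")
  dates <- sprintf("[tipdate %s = %s]", rownames(m$cells),
                   format(m$tip_dates[rownames(m$cells)], trim = TRUE,
                          scientific = FALSE))
  writeLines(c(txt, sets, dates), path)
}

read_cognate_nexus <- function(path) {
  seqs <- ape::read.nexus.data(path)
  langs <- names(seqs)
  cells <- do.call(rbind, lapply(seqs, function(s) {
    symbol_to_cell(toupper(s), sprintf("position %d", seq_along(s)))
  }))
  rownames(cells) <- langs
  txt <- readLines(path)
  cs <- regmatches(txt, regexec("charset '([^']+)' = ([0-9 ]+);", txt))
  cs <- cs[vapply(cs, length, 0L) == 3]
  concept_id <- rep(NA_character_, ncol(cells))
  asc <- rep(FALSE, ncol(cells))
  for (entry in cs) {
    idx <- as.integer(strsplit(entry[3], " ")[[1]])
    if (entry[2] == "ascertainment") asc[idx] <- TRUE else concept_id[idx] <- entry[2]
  }
  if (anyNA(concept_id)) stop("column with no concept charset", call. = FALSE)
  td <- regmatches(txt, regexec("\\[tipdate (\\S+) = ([0-9.eE+-]+)\\]", txt))
  td <- td[vapply(td, length, 0L) == 3]
  dates <- stats::setNames(
    vapply(td, function(x) as.numeric(x[3]), 0),
    vapply(td, `[`, "", 2)
  )
  if (!length(dates)) dates <- stats::setNames(rep(0, length(langs)), langs)
  cognate_matrix(
    cells,
    tibble::tibble(
      concept_id = concept_id,
      cognate_id = ifelse(asc, paste0(concept_id, ".asc"),
                          paste0(concept_id, ".", stats::ave(seq_along(asc),
                                                             concept_id,
                                                             FUN = seq_along))),
      is_ascertainment = asc
    ),
    dates
  )
}
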