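# Plain-text I/O: line-record visit files, delimited rating triples, and
# sparse coordinate (MatrixMarket) export of rating matrices.
#
# Visit record format, one record per line, space-separated key:value
# fields, UTF-8:
#
#   patient:p00001 true_dept:2 dept:2 doctor:doc0012 rating:5 tokens:s0010x3,s0042x1
#
# `true_dept` is optional (real corpora have no planted labels); `tokens`
# is a comma-separated list of term x count pairs.

format_tokens <- function(tc) {
  paste0(names(tc), "x", as.integer(tc), collapse = ",")
}

parse_tokens <- function(s, line) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*)x([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad) || length(parts) == 0L) {
    abort_data(paste0("line ", line, ": malformed tokens field '", s, "'"), line = line)
  }
  counts <- as.integer(vapply(m, `[[`, character(1), 3L))
  terms <- vapply(m, `[[`, character(1), 2L)
  if (any(counts < 1L)) {
    abort_data(paste0("line ", line, ": token counts must be positive"), line = line)
  }
  stats::setNames(counts, terms)
}

#' Write visit records to a line-record text file
#'
#' @param x A `clinic`, a `symptom_corpus`, or a visits tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  visits <- if (inherits(x, "clinic") || inherits(x, "symptom_corpus")) x$visits else x
  validate_visits(visits)
  has_truth <- "true_department_id" %in% names(visits)
  lines <- vapply(seq_len(nrow(visits)), function(i) {
    v <- visits[i, ]
    paste0(
      "patient:", v$patient_id,
      if (has_truth) paste0(" true_dept:", v$true_department_id) else "",
      " dept:", v$visited_department_id,
      " doctor:", v$doctor_id,
      " rating:", v$rating,
      " tokens:", format_tokens(v$tokens[[1]])
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read visit records from a line-record text file
#'
#' Malformed records raise a data error naming the offending line; an empty
#' file yields an empty visits tibble.
#'
#' @param path Input file path.
#' @return A visits tibble (see [symptom_corpus()] for the columns).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort_data(paste0("corpus file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(
    patient_id = character(), true_department_id = integer(),
    visited_department_id = integer(), doctor_id = character(),
    rating = integer(), tokens = list()
  )
  if (length(lines) == 0L) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], " ", fixed = TRUE)[[1]]
    kv <- regmatches(fields, regexec("^([a-z_]+):(.*)$", fields))
    if (any(vapply(kv, length, integer(1)) != 3L)) {
      abort_data(paste0("line ", i, ": malformed field in record"), line = i)
    }
    keys <- vapply(kv, `[[`, character(1), 2L)
    vals <- stats::setNames(vapply(kv, `[[`, character(1), 3L), keys)
    need <- c("patient", "dept", "doctor", "rating", "tokens")
    if (!all(need %in% keys)) {
      abort_data(paste0("line ", i, ": missing field(s) ",
                        paste(setdiff(need, keys), collapse = ", ")), line = i)
    }
    rating <- suppressWarnings(as.integer(vals[["rating"]]))
    if (is.na(rating) || rating < 1L || rating > 5L) {
      abort_data(paste0("line ", i, ": rating must be an integer in [1, 5], got '",
                        vals[["rating"]], "'"), line = i)
    }
    list(
      patient_id = vals[["patient"]],
      true_department_id = if ("true_dept" %in% keys)
        as.integer(vals[["true_dept"]]) else NA_integer_,
      visited_department_id = as.integer(vals[["dept"]]),
      doctor_id = vals[["doctor"]],
      rating = rating,
      tokens = list(parse_tokens(vals[["tokens"]], i))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$true_department_id))) out$true_department_id <- NULL
  # keep canonical column order
  cols <- intersect(
    c("patient_id", "true_department_id", "visited_department_id",
      "doctor_id", "rating", "tokens"),
    names(out)
  )
  out[cols]
}

#' Write rating triples as delimited text
#'
#' One `patient,doctor,rating` triple per line with a header row.
#'
#' @param ratings Tibble with columns `patient_id`, `doctor_id`, `rating`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(all(c("patient_id", "doctor_id", "rating") %in% names(ratings)))
  if (nrow(ratings) > 0 &&
      (any(ratings$rating < 1) || any(ratings$rating > 5))) {
    abort_data("ratings must lie in [1, 5]")
  }
  utils::write.csv(ratings[c("patient_id", "doctor_id", "rating")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read rating triples from delimited text
#' @param path Input file path.
#' @return Tibble with columns `patient_id`, `doctor_id`, `rating`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort_data(paste0("ratings file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "integer"))
  names(df) <- c("patient_id", "doctor_id", "rating")
  if (nrow(df) > 0) {
    bad <- which(is.na(df$rating) | df$rating < 1L | df$rating > 5L)
    if (length(bad) > 0L) {
      abort_data(paste0("line ", bad[1] + 1L, ": rating out of [1, 5]"),
                 line = bad[1] + 1L)
    }
  }
  tibble::as_tibble(df)
}

#' Build a (sparse) rating matrix from rating triples
#'
#' Rows are patients, columns are doctors, unobserved cells are `NA`.
#' Patients or doctors without any observation are dropped so every retained
#' row and column has at least one rating.
#'
#' @param ratings Tibble of `patient_id`, `doctor_id`, `rating` triples.
#' @return Dense numeric matrix with `NA` for unobserved entries.
#' @export
rating_matrix <- function(ratings) {
  if (nrow(ratings) == 0L) abort_data("no ratings to build a matrix from")
  ratings <- dplyr::distinct(ratings, .data$patient_id, .data$doctor_id,
                             .keep_all = TRUE)
  pats <- sort(unique(ratings$patient_id))
  docs <- sort(unique(ratings$doctor_id))
  R <- matrix(NA_real_, length(pats), length(docs), dimnames = list(pats, docs))
  R[cbind(match(ratings$patient_id, pats), match(ratings$doctor_id, docs))] <-
    ratings$rating
  R
}

#' Export / import a rating matrix in sparse coordinate exchange format
#'
#' Writes the observed entries of the patient-by-doctor matrix in
#' MatrixMarket coordinate format (via the Matrix package), with row and
#' column ids in sidecar `<path>.rows` / `<path>.cols` files.
#'
#' @param R Rating matrix with `NA` for unobserved entries.
#' @param path Output `.mtx` file path.
#' @return `path`, invisibly.
#' @export
write_rating_mtx <- function(R, path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    abort_data("the Matrix package is required for sparse coordinate export")
  }
  obs <- which(!is.na(R), arr.ind = TRUE)
  S <- Matrix::sparseMatrix(i = obs[, 1], j = obs[, 2], x = R[obs],
                            dims = dim(R))
  Matrix::writeMM(S, path)
  writeLines(rownames(R), paste0(path, ".rows"))
  writeLines(colnames(R), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_rating_mtx
#' @export
read_rating_mtx <- function(path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    abort_data("the Matrix package is required for sparse coordinate import")
  }
  S <- as(Matrix::readMM(path), "CsparseMatrix")
  R <- matrix(NA_real_, nrow(S), ncol(S))
  obs <- Matrix::which(S != 0, arr.ind = TRUE)
  R[obs] <- S[obs]
  rownames(R) <- readLines(paste0(path, ".rows"))
  colnames(R) <- readLines(paste0(path, ".cols"))
  R
}
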