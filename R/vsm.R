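# Symptom vector space model: TF-IDF patient vectors and score-weighted
# department profiles.

#' Term frequency of a tokenized chief complaint
#'
#' The weight of a symptom token within one complaint is its count divided by
#' the total token count of that complaint, so frequencies sum to one per
#' complaint.
#'
#' @param token_counts Named numeric vector of positive token counts.
#' @return Named numeric vector of frequencies in `[0, 1]` summing to 1.
#' @export
#' @examples
#' term_frequency(c(cough = 2, fever = 1, chills = 1))
term_frequency <- function(token_counts) {
  if (length(token_counts) == 0L) {
    abort_data("empty complaint: at least one token with a positive count is required")
  }
  if (is.null(names(token_counts)) || any(!nzchar(names(token_counts)))) {
    abort_data("`token_counts` must be a named vector of symptom-term counts")
  }
  if (any(!is.finite(token_counts)) || any(token_counts <= 0)) {
    abort_data("token counts must be finite and positive")
  }
  token_counts / sum(token_counts)
}

#' Smoothed inverse document frequency
#'
#' `IDF_i = log(N / D_i + 1)` with the natural logarithm, where `N` is the
#' number of complaint documents and `D_i` the number of documents containing
#' term `i`. The additive one is applied after the ratio, so a term appearing
#' in every document still gets the strictly positive weight `log(2)`.
#'
#' @param n_documents Total number of complaint documents (`N >= 1`).
#' @param doc_freq Document frequency of the term(s); each in `[1, N]`.
#'   Vectorized.
#' @return Strictly positive IDF value(s).
#' @export
#' @examples
#' inverse_document_frequency(100, 9)
inverse_document_frequency <- function(n_documents, doc_freq) {
  if (!is_count(n_documents)) {
    abort_data("`n_documents` must be a single integer >= 1")
  }
  if (length(doc_freq) == 0L || any(!is.finite(doc_freq)) ||
      any(doc_freq < 1) || any(doc_freq > n_documents) ||
      any(doc_freq != as.integer(doc_freq))) {
    abort_data("`doc_freq` must be integer document frequencies in [1, n_documents]")
  }
  log(n_documents / doc_freq + 1)
}

validate_visits <- function(visits) {
  required <- c("patient_id", "visited_department_id", "doctor_id", "rating", "tokens")
  missing <- setdiff(required, names(visits))
  if (length(missing) > 0L) {
    abort_data(paste0("`visits` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(visits) > 0L) {
    bad <- which(!vapply(visits$tokens, function(tc) {
      length(tc) > 0L && !is.null(names(tc)) && all(tc > 0)
    }, logical(1)))
    if (length(bad) > 0L) {
      abort_data(paste0("visit row(s) ", paste(utils::head(bad, 5), collapse = ", "),
                        " have an empty or unnamed token-count map"))
    }
    r <- visits$rating
    if (any(!is.finite(r)) || any(r < 1) || any(r > 5) || any(r != as.integer(r))) {
      abort_data("ratings must be integers in [1, 5]")
    }
  }
  invisible(visits)
}

#' Fit a symptom corpus from visit records
#'
#' Collects the vocabulary (stable lexicographic order), the number of
#' complaint documents `N` (one visit = one document) and per-term document
#' frequencies. The same document unit is shared by patient and department
#' vector construction so the two vector spaces are directly comparable.
#'
#' @param visits Tibble of visit records with columns `patient_id`,
#'   `visited_department_id`, `doctor_id`, `rating` (integer 1-5) and
#'   `tokens` (list column of named positive counts).
#' @return An object of class `symptom_corpus` with elements `visits`,
#'   `vocabulary`, `n_documents` and `doc_freq`.
#' @export
symptom_corpus <- function(visits) {
  visits <- tibble::as_tibble(visits)
  validate_visits(visits)
  if (nrow(visits) == 0L) {
    abort_data("cannot fit a corpus from zero visits")
  }
  vocabulary <- sort(unique(unlist(lapply(visits$tokens, names), use.names = FALSE)))
  doc_freq <- vapply(
    stats::setNames(vocabulary, vocabulary),
    function(term) sum(vapply(visits$tokens, function(tc) term %in% names(tc), logical(1))),
    integer(1)
  )
  structure(
    list(
      visits = visits,
      vocabulary = vocabulary,
      n_documents = nrow(visits),
      doc_freq = doc_freq
    ),
    class = "symptom_corpus"
  )
}

#' @export
print.symptom_corpus <- function(x, ...) {
  cat("<symptom_corpus>\n")
  cat("  documents:  ", x$n_documents, "\n", sep = "")
  cat("  vocabulary: ", length(x$vocabulary), " terms\n", sep = "")
  cat("  departments:", length(unique(x$visits$visited_department_id)), "\n")
  invisible(x)
}

corpus_idf <- function(corpus) {
  inverse_document_frequency(corpus$n_documents, corpus$doc_freq)
}

#' TF-IDF vector for a single patient complaint
#'
#' Coordinates are term frequency within the complaint times corpus IDF.
#' Tokens absent from the corpus vocabulary are dropped; if nothing remains
#' the zero vector is returned with attribute `oov = TRUE` and a warning
#' (cold-start text cannot be triaged by content).
#'
#' @param token_counts Named counts of one complaint, or a one-row slice of
#'   the corpus `visits` tibble.
#' @param corpus A fitted [symptom_corpus()].
#' @return Named numeric vector over the corpus vocabulary.
#' @export
patient_vector <- function(token_counts, corpus) {
  stopifnot(inherits(corpus, "symptom_corpus"))
  if (is.data.frame(token_counts)) {
    stopifnot(nrow(token_counts) == 1L)
    token_counts <- token_counts$tokens[[1L]]
  }
  tf_all <- term_frequency(token_counts)
  keep <- names(tf_all) %in% corpus$vocabulary
  w <- stats::setNames(numeric(length(corpus$vocabulary)), corpus$vocabulary)
  if (!any(keep)) {
    warning("complaint contains no in-vocabulary tokens; returning a zero vector",
            call. = FALSE)
    return(structure(w, oov = TRUE))
  }
  tf <- tf_all[keep]
  idf <- corpus_idf(corpus)[names(tf)]
  w[names(tf)] <- tf * idf
  w
}

#' TF-IDF vectors for all (or selected) visits, as a matrix
#'
#' @param corpus A fitted [symptom_corpus()].
#' @param visits Visit records to vectorize; defaults to the corpus's own.
#' @return Numeric matrix, one row per visit (rownames = patient ids),
#'   one column per vocabulary term.
#' @export
patient_vectors <- function(corpus, visits = corpus$visits) {
  stopifnot(inherits(corpus, "symptom_corpus"))
  visits <- tibble::as_tibble(visits)
  validate_visits(visits)
  idf <- corpus_idf(corpus)
  X <- matrix(0, nrow = nrow(visits), ncol = length(corpus$vocabulary),
              dimnames = list(visits$patient_id, corpus$vocabulary))
  for (r in seq_len(nrow(visits))) {
    tf <- term_frequency(visits$tokens[[r]])
    tf <- tf[names(tf) %in% corpus$vocabulary]
    if (length(tf) > 0L) X[r, names(tf)] <- tf * idf[names(tf)]
  }
  X
}

#' Score-weighted term frequency of a department
#'
#' Pools the complaints of all patients of one department, multiplying each
#' patient's token counts by their post-visit rating `r_k` (1-5) before
#' normalizing:
#' `TF_i = sum_k n_ik * r_k / sum_k n_*k * r_k`.
#' High-rated visits therefore contribute more to the department's symptom
#' description; with all ratings equal this reduces to the plain pooled term
#' frequency.
#'
#' @param visits Visit records of one department.
#' @param vocabulary Optional character vector; if given, the result is a
#'   vector over exactly these terms (zeros elsewhere, out-of-vocabulary
#'   counts dropped).
#' @return Named numeric vector of weighted frequencies summing to 1.
#' @export
score_weighted_tf <- function(visits, vocabulary = NULL) {
  visits <- tibble::as_tibble(visits)
  validate_visits(visits)
  if (nrow(visits) == 0L) {
    abort_data("cannot compute a department term frequency from zero visits")
  }
  num <- new.env(parent = emptyenv())
  denom <- 0
  for (r in seq_len(nrow(visits))) {
    tc <- visits$tokens[[r]]
    rk <- visits$rating[[r]]
    if (!is.null(vocabulary)) tc <- tc[names(tc) %in% vocabulary]
    if (length(tc) == 0L) next
    denom <- denom + sum(tc) * rk
    for (term in names(tc)) {
      num[[term]] <- (if (is.null(num[[term]])) 0 else num[[term]]) + tc[[term]] * rk
    }
  }
  if (denom == 0) {
    abort_data("no in-vocabulary tokens in this department's visits")
  }
  terms <- sort(ls(num))
  tf <- vapply(terms, function(t) num[[t]] / denom, numeric(1))
  if (is.null(vocabulary)) {
    return(tf)
  }
  out <- stats::setNames(numeric(length(vocabulary)), sort(vocabulary))
  out[names(tf)] <- tf
  out
}

#' Score-weighted TF-IDF profile of one department
#'
#' @param visits Visit records of one department.
#' @param corpus The fitted corpus providing vocabulary and IDF.
#' @return Named numeric weight vector over the corpus vocabulary.
#' @export
department_profile <- function(visits, corpus) {
  stopifnot(inherits(corpus, "symptom_corpus"))
  tf <- score_weighted_tf(visits, vocabulary = corpus$vocabulary)
  tf <- tf[corpus$vocabulary]
  tf * corpus_idf(corpus)
}

#' Score-weighted TF-IDF profiles of every department
#'
#' @param corpus A fitted [symptom_corpus()].
#' @param weighting `"score"` uses rating-weighted pooling; `"unweighted"`
#'   pools counts ignoring ratings (baseline for the weighting comparison).
#' @return Numeric matrix, one row per department (rownames = department
#'   ids, sorted), one column per vocabulary term.
#' @export
department_profiles <- function(corpus, weighting = c("score", "unweighted")) {
  stopifnot(inherits(corpus, "symptom_corpus"))
  weighting <- match.arg(weighting)
  visits <- corpus$visits
  if (weighting == "unweighted") {
    visits <- dplyr::mutate(visits, rating = 1L)
  }
  depts <- sort(unique(visits$visited_department_id))
  P <- matrix(0, nrow = length(depts), ncol = length(corpus$vocabulary),
              dimnames = list(as.character(depts), corpus$vocabulary))
  for (d in depts) {
    dv <- dplyr::filter(visits, .data$visited_department_id == d)
    P[as.character(d), ] <- department_profile(dv, corpus)
  }
  P
}

#' Serialize a weight vector (or profile matrix) to JSON
#'
#' The on-disk form is `{"vocabulary": [...], "weights": {term: value}}` with
#' deterministic (vocabulary) key order; only nonzero weights are stored.
#'
#' @param x Named numeric vector, or a matrix whose rows are vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vector_json <- function(x, path) {
  to_doc <- function(v) {
    nz <- v[v != 0]
    list(vocabulary = names(v), weights = as.list(nz))
  }
  doc <- if (is.matrix(x)) {
    lapply(stats::setNames(rownames(x), rownames(x)), function(r) to_doc(x[r, ]))
  } else {
    to_doc(x)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a weight vector or profile matrix written by [write_vector_json()]
#'
#' @param path Input file path.
#' @return Named numeric vector, or matrix if the file holds several.
#' @export
read_vector_json <- function(path) {
  doc <- jsonlite::read_json(path)
  from_doc <- function(d) {
    v <- stats::setNames(numeric(length(d$vocabulary)), unlist(d$vocabulary))
    w <- unlist(d$weights)
    if (length(w) > 0) v[names(w)] <- w
    v
  }
  if (!is.null(doc$vocabulary)) {
    return(from_doc(doc))
  }
  rows <- lapply(doc, from_doc)
  do.call(rbind, rows)
}
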