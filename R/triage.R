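# Department triage by similarity between patient vectors and department
# profiles.

#' Modified (mean-centered) cosine similarity
#'
#' Each vector is centered by its own mean over all vocabulary coordinates
#' (zeros included) before the standard cosine is taken. Centering removes
#' per-vector offset effects, which is what distinguishes this from the plain
#' cosine; over a common full coordinate set it coincides numerically with
#' the Pearson correlation of the two vectors.
#'
#' If either centered vector has zero norm (a constant vector) the similarity
#' is defined as 0 and the result carries attribute `degenerate = TRUE`, so
#' rankings never fail on degenerate input.
#'
#' @param u,v Numeric vectors over the same vocabulary (same length).
#' @return Similarity in `[-1, 1]`.
#' @export
#' @examples
#' modified_cosine(c(1, 0), c(0, 1))  # -1: opposite after centering
modified_cosine <- function(u, v) {
  if (length(u) != length(v)) {
    abort_data("`u` and `v` must be vectors over the same vocabulary")
  }
  plain_cosine(u - mean(u), v - mean(v))
}

#' Plain (uncentered) cosine similarity
#' @rdname modified_cosine
#' @export
plain_cosine <- function(u, v) {
  if (length(u) != length(v)) {
    abort_data("`u` and `v` must be vectors over the same vocabulary")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(u * v) / (nu * nv)
}

similarity_fun <- function(similarity = c("modified", "plain", "pearson")) {
  similarity <- match.arg(similarity)
  switch(similarity,
    modified = modified_cosine,
    plain = plain_cosine,
    pearson = function(u, v) {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) {
        return(structure(0, degenerate = TRUE))
      }
      stats::cor(u, v)
    }
  )
}

#' Rank departments for one patient vector
#'
#' Scores the patient vector against every department profile and returns
#' the full ranking; the top-ranked department is the triage prediction.
#' Equal similarities are broken in favor of the lowest department id so the
#' ranking is deterministic.
#'
#' @param p Patient weight vector over the corpus vocabulary.
#' @param profiles Matrix of department profiles (rows = departments, as
#'   produced by [department_profiles()]).
#' @param similarity Similarity mode: `"modified"` (mean-centered cosine,
#'   default), `"plain"`, or `"pearson"`.
#' @param patient_id Identifier copied into the result.
#' @return A tibble with columns `patient_id`, `rank`, `department_id`,
#'   `similarity`, sorted by rank.
#' @export
triage_patient <- function(p, profiles, similarity = "modified",
                           patient_id = NA_character_) {
  if (is.null(dim(profiles)) || nrow(profiles) < 1L) {
    abort_data("`profiles` must be a matrix with at least one department row")
  }
  if (all(p == 0)) {
    abort_data("zero patient vector: content triage impossible (cold start)",
               reason = "cold_start")
  }
  sim_fun <- similarity_fun(similarity)
  sims <- vapply(seq_len(nrow(profiles)), function(i) as.numeric(sim_fun(p, profiles[i, ])),
                 numeric(1))
  dept_ids <- rownames(profiles)
  if (is.null(dept_ids)) dept_ids <- as.character(seq_len(nrow(profiles)))
  # order by similarity desc, then department id asc (ties deterministic)
  ord <- order(-sims, dept_ids)
  tibble::tibble(
    patient_id = patient_id,
    rank = seq_along(ord),
    department_id = dept_ids[ord],
    similarity = sims[ord]
  )
}

#' Triage every patient of a corpus (or visit set)
#'
#' @param corpus A fitted [symptom_corpus()].
#' @param profiles Department profile matrix; defaults to score-weighted
#'   profiles of the corpus.
#' @param visits Visits to triage; defaults to the corpus's own.
#' @param similarity Similarity mode, see [triage_patient()].
#' @param top Keep only the best `top` departments per patient (`Inf` keeps
#'   the full ranking).
#' @return A tibble with one row per (patient, ranked department).
#' @export
triage <- function(corpus, profiles = department_profiles(corpus),
                   visits = corpus$visits, similarity = "modified", top = Inf) {
  X <- patient_vectors(corpus, visits)
  res <- purrr::map(seq_len(nrow(X)), function(i) {
    triage_patient(X[i, ], profiles, similarity = similarity,
                   patient_id = rownames(X)[i])
  })
  out <- dplyr::bind_rows(res)
  if (is.finite(top)) out <- dplyr::filter(out, .data$rank <= top)
  out
}

#' Top-1 triage accuracy against reference labels
#'
#' @param triage_result Output of [triage()].
#' @param truth Tibble with columns `patient_id` and a department label
#'   column (`true_department_id` by default).
#' @param label Name of the label column in `truth`.
#' @return Fraction of patients whose rank-1 department matches the label.
#' @export
triage_accuracy <- function(triage_result, truth, label = "true_department_id") {
  top1 <- dplyr::filter(triage_result, .data$rank == 1L)
  joined <- dplyr::inner_join(top1, truth, by = "patient_id")
  if (nrow(joined) == 0L) abort_data("no patients in common between result and truth")
  mean(joined$department_id == as.character(joined[[label]]))
}
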