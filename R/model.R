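# Fitted clinic model: the trained state of the two-stage pipeline
# (profiles for triage, per-department cluster models, historical vectors
# and ratings for the recommender).

#' Fit the full triage-and-recommendation model on historical visits
#'
#' Trains every stage the recommender needs: fits the symptom corpus,
#' builds score-weighted department profiles, vectorizes all historical
#' patients, and clusters each department's patients with trust-weighted
#' K-means (fixed `k` or elbow-selected over `k_range`).
#'
#' @param visits Historical visit records (see [symptom_corpus()]).
#' @param ratings Historical `patient_id`, `doctor_id`, `rating` triples.
#' @param k Clusters per department; ignored when `k_range` is given.
#' @param k_range Optional integer vector; if supplied, `k` is chosen per
#'   department by [elbow_select()] on its SSE curve.
#' @param weighting Profile weighting, see [department_profiles()].
#' @param trust_mode See [trust()].
#' @param seed Master seed; the clustering stage derives its own seed via
#'   [split_seed()].
#' @return An object of class `clinic_model` with elements `corpus`,
#'   `profiles`, `vectors`, `membership`, `clusters` (named list of
#'   [kmeans_trust()] models), `chosen_k`, `seed`.
#' @export
clinic_model <- function(visits, ratings, k = 4, k_range = NULL,
                         weighting = "score", trust_mode = "as_printed",
                         seed = 1) {
  corpus <- symptom_corpus(visits)
  profiles <- department_profiles(corpus, weighting = weighting)
  vectors <- patient_vectors(corpus)
  keep <- rowSums(vectors) > 0
  vectors <- vectors[keep, , drop = FALSE]
  membership <- tibble::tibble(
    patient_id = corpus$visits$patient_id,
    department_id = as.character(corpus$visits$visited_department_id)
  )[keep, ]

  cl_seed <- split_seed(seed, "clustering")
  depts <- sort(unique(membership$department_id))
  clusters <- list()
  chosen_k <- stats::setNames(integer(length(depts)), depts)
  for (d in depts) {
    ids <- membership$patient_id[membership$department_id == d]
    Xd <- vectors[ids, , drop = FALSE]
    kd <- if (!is.null(k_range)) {
      usable <- k_range[k_range <= nrow(Xd)]
      if (length(usable) >= 3L) {
        elbow_select(sse_curve(Xd, usable, seed = cl_seed, trust_mode = trust_mode))
      } else {
        min(k, nrow(Xd))
      }
    } else {
      k
    }
    chosen_k[d] <- kd
    clusters[[d]] <- kmeans_trust(Xd, kd, seed = cl_seed, trust_mode = trust_mode)
  }

  structure(
    list(
      corpus = corpus,
      profiles = profiles,
      vectors = vectors,
      membership = membership,
      clusters = clusters,
      chosen_k = chosen_k,
      ratings = tibble::as_tibble(ratings),
      seed = seed
    ),
    class = "clinic_model"
  )
}

#' @export
print.clinic_model <- function(x, ...) {
  cat("<clinic_model>\n")
  cat("  departments:", nrow(x$profiles),
      " patients:", nrow(x$vectors),
      " ratings:", nrow(x$ratings), "\n")
  cat("  clusters per department:",
      paste(names(x$chosen_k), x$chosen_k, sep = "=", collapse = " "), "\n")
  invisible(x)
}
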