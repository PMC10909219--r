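# Doctor recommendation: neighbor selection by symptom similarity, ALS
# densification of the neighbor rating submatrix, and mean-centered
# user-based collaborative filtering on the dense reconstruction.

#' Select the m most symptom-similar neighbors of a target patient
#'
#' @param a Target patient weight vector.
#' @param members Matrix of candidate patient vectors (rownames = patient
#'   ids), typically the members of the target's assigned cluster.
#' @param m Number of neighbors (all candidates if fewer).
#' @param similarity Similarity mode, see [triage_patient()].
#' @return Tibble `patient_id`, `similarity`, sorted by decreasing
#'   similarity with ties broken by patient id.
#' @export
neighbor_select <- function(a, members, m, similarity = "modified") {
  if (is.null(dim(members)) || nrow(members) == 0L) {
    abort_data("the candidate cluster is empty")
  }
  sim_fun <- similarity_fun(similarity)
  sims <- vapply(seq_len(nrow(members)),
                 function(i) as.numeric(sim_fun(a, members[i, ])), numeric(1))
  ids <- rownames(members)
  ord <- order(-sims, ids)
  keep <- utils::head(ord, m)
  tibble::tibble(patient_id = ids[keep], similarity = sims[keep])
}

#' Alternating-least-squares factorization of a sparse rating matrix
#'
#' Approximates the observed entries of the patient-by-doctor matrix `R`
#' by a rank-`rank` product, alternately solving ridge regressions for the
#' patient factors and the doctor factors against observed entries only
#' (explicit-feedback ALS). The dense reconstruction replaces the sparse
#' matrix downstream, so every (patient, doctor) cell has a value.
#'
#' Factors are initialized from a seeded RNG (doctor factors: first latent
#' dimension at the doctor's observed mean, remaining dimensions small
#' noise), making the fit deterministic given the seed. The observed-entry
#' RMSE is recorded after every sweep.
#'
#' @param R Numeric matrix with `NA` for unobserved entries; at least one
#'   observation.
#' @param rank Latent dimension, `1 <= rank <= min(dim(R))`.
#' @param lambda Ridge regularization, `> 0` (guards singular solves).
#' @param sweeps Number of alternating sweeps.
#' @param seed RNG seed for the factor initialization.
#' @return An object of class `factor_model`: `P` (rank x m patient
#'   factors), `Q` (n x rank doctor factors), `reconstruction` (m x n dense
#'   matrix `t(P) %*% t(Q)`), `rmse_path`, plus the call parameters.
#' @export
als_factorize <- function(R, rank = 10, lambda = 0.1, sweeps = 15, seed = 1) {
  if (is.null(dim(R))) abort_data("`R` must be a matrix")
  m <- nrow(R)
  n <- ncol(R)
  obs <- !is.na(R)
  if (!any(obs)) abort_data("`R` has no observed entries")
  if (!is_count(rank) || rank > min(m, n)) {
    abort_data(paste0("`rank` must be an integer in [1, ", min(m, n), "]"))
  }
  if (!is_scalar_number(lambda) || lambda <= 0) {
    abort_data("`lambda` must be a positive number")
  }
  if (!is_count(sweeps)) abort_data("`sweeps` must be a positive integer")

  with_local_seed(seed, {
    col_means <- vapply(seq_len(n), function(j) {
      v <- R[obs[, j], j]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    # U: m x rank patient factors, V: n x rank doctor factors
    V <- matrix(stats::rnorm(n * rank, 0, 0.05), n, rank)
    V[, 1L] <- col_means + V[, 1L]
    U <- matrix(0, m, rank)
    Ik <- diag(lambda, rank)

    solve_side <- function(Fixed, obs_rows, values) {
      # one ridge solve: factors of a single row against its observed entries
      idx <- which(obs_rows)
      Fj <- Fixed[idx, , drop = FALSE]
      solve(crossprod(Fj) + Ik, crossprod(Fj, values[idx]))
    }

    rmse_path <- numeric(sweeps)
    for (s in seq_len(sweeps)) {
      for (i in seq_len(m)) {
        if (any(obs[i, ])) U[i, ] <- solve_side(V, obs[i, ], R[i, ])
      }
      for (j in seq_len(n)) {
        if (any(obs[, j])) V[j, ] <- solve_side(U, obs[, j], R[, j])
      }
      resid <- (U %*% t(V) - R)[obs]
      rmse_path[s] <- sqrt(mean(resid^2))
    }

    reconstruction <- U %*% t(V)
    dimnames(reconstruction) <- dimnames(R)
    structure(
      list(
        P = t(U),                 # rank x m
        Q = V,                    # n x rank
        reconstruction = reconstruction,
        rank = rank, lambda = lambda, sweeps = sweeps, seed = seed,
        rmse_path = rmse_path
      ),
      class = "factor_model"
    )
  })
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> rank =", x$rank,
      " lambda =", x$lambda,
      " sweeps =", x$sweeps,
      " final observed RMSE =", format(utils::tail(x$rmse_path, 1), digits = 6), "\n")
  invisible(x)
}

#' Predict a target patient's score for one doctor
#'
#' Mean-centered user-based collaborative filtering over the dense
#' (ALS-reconstructed) neighbor matrix:
#' `r_ai = rbar_i + sum_j sim(a, j) (r_ji - rbar_j) / sum_j sim(a, j)`,
#' where `rbar_i` is doctor `i`'s average score in the dense matrix (column
#' mean over all its rows) and `rbar_j` neighbor `j`'s row mean, both taken
#' from the dense reconstruction. If the similarity mass is not positive
#' the prediction falls back to `rbar_i` (attribute `fallback = TRUE`).
#'
#' @param doctor_id Column name in `R_dense`.
#' @param neighbors Tibble `patient_id`, `similarity` ([neighbor_select()]).
#' @param R_dense Dense neighbor-by-doctor score matrix.
#' @return Unclipped predicted score; clip to `[1, 5]` for reporting.
#' @export
predict_score <- function(doctor_id, neighbors, R_dense) {
  if (nrow(neighbors) == 0L) abort_data("at least one neighbor is required")
  if (!doctor_id %in% colnames(R_dense)) {
    abort_data(paste0("doctor '", doctor_id, "' not present in the score matrix"))
  }
  rows <- match(neighbors$patient_id, rownames(R_dense))
  if (anyNA(rows)) abort_data("all neighbors must be rows of the score matrix")
  rbar_i <- mean(R_dense[, doctor_id])
  rbar_j <- rowMeans(R_dense[rows, , drop = FALSE])
  sim <- neighbors$similarity
  denom <- sum(sim)
  if (denom <= 0) {
    return(structure(rbar_i, fallback = TRUE))
  }
  rbar_i + sum(sim * (R_dense[rows, doctor_id] - rbar_j)) / denom
}

#' Recommend the top-N doctors for a target patient
#'
#' Full second-stage pipeline given a fitted [clinic_model()]: triage the
#' patient's complaint to a department, assign it to that department's
#' nearest patient cluster, select the `m` most similar cluster members,
#' densify their rating submatrix with ALS, predict a score for every
#' doctor rated by at least one neighbor, and return the top `N`.
#'
#' @param model A fitted [clinic_model()].
#' @param tokens Named token counts of the target complaint (or a one-row
#'   visits slice).
#' @param n_top Number of doctors to return.
#' @param m Neighbor count.
#' @param rank,lambda,sweeps ALS parameters.
#' @param seed Seed for the ALS initialization.
#' @param scope `"cluster"` restricts the neighbor search to the assigned
#'   cluster (default); `"department"` searches the whole department
#'   (the no-clustering baseline).
#' @param similarity Similarity mode for triage and neighbor selection.
#' @return An object of class `recommendation`: tibble `rank`, `doctor_id`,
#'   `score` (clipped to `[1, 5]`; ranking by the unclipped value, ties by
#'   doctor id), with attributes `department_id`, `cluster`,
#'   `candidate_set_size` and `reason` (set when empty).
#' @export
recommend <- function(model, tokens, n_top = 5, m = 10,
                      rank = 10, lambda = 0.1, sweeps = 15, seed = 1,
                      scope = c("cluster", "department"),
                      similarity = "modified") {
  scope <- match.arg(scope)
  stopifnot(inherits(model, "clinic_model"))
  a <- patient_vector(tokens, model$corpus)

  tri <- triage_patient(a, model$profiles, similarity = similarity)
  dept <- tri$department_id[1L]

  dept_ids <- model$membership$patient_id[model$membership$department_id == dept]
  cl <- NA_integer_
  if (scope == "cluster" && !is.null(model$clusters[[dept]])) {
    cl <- as.integer(assign_cluster(a, model$clusters[[dept]]))
    members <- names(model$clusters[[dept]]$assignments)[
      model$clusters[[dept]]$assignments == cl]
  } else {
    members <- dept_ids
  }
  empty_rec <- function(reason) {
    structure(
      tibble::tibble(rank = integer(), doctor_id = character(), score = numeric()),
      department_id = dept, cluster = cl, candidate_set_size = length(members),
      reason = reason, class = c("recommendation", "tbl_df", "tbl", "data.frame")
    )
  }
  members <- intersect(members, rownames(model$vectors))
  if (length(members) == 0L) return(empty_rec("no historical patients in scope"))

  neighbors <- neighbor_select(a, model$vectors[members, , drop = FALSE], m,
                               similarity = similarity)
  rated <- dplyr::filter(model$ratings, .data$patient_id %in% neighbors$patient_id)
  if (nrow(rated) == 0L) return(empty_rec("no doctor rated by any neighbor"))

  R <- rating_matrix(rated)
  neighbors <- dplyr::filter(neighbors, .data$patient_id %in% rownames(R))
  fit_rank <- min(rank, dim(R))
  fm <- als_factorize(R, rank = fit_rank, lambda = lambda, sweeps = sweeps,
                      seed = seed)
  scores <- vapply(colnames(R), function(doc) {
    as.numeric(predict_score(doc, neighbors, fm$reconstruction))
  }, numeric(1))

  ord <- order(-scores, names(scores))
  keep <- utils::head(ord, n_top)
  structure(
    tibble::tibble(
      rank = seq_along(keep),
      doctor_id = names(scores)[keep],
      score = clip(scores[keep], 1, 5)
    ),
    department_id = dept, cluster = cl,
    candidate_set_size = length(members), reason = NULL,
    class = c("recommendation", "tbl_df", "tbl", "data.frame")
  )
}
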