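# Top-N evaluation: precision/recall, the before/after-clustering
# comparison harness, and mean-gain arithmetic on comparison tables.

#' Precision and recall of a top-N recommendation list
#'
#' `precision = |top-N intersect relevant| / N`,
#' `recall = |top-N intersect relevant| / |relevant|`.
#'
#' @param recommended Ordered character vector of recommended item ids.
#' @param relevant Character set of relevant item ids (non-empty).
#' @param n Cut-off `N >= 1`.
#' @return One-row tibble `precision`, `recall`, `hits`.
#' @export
#' @examples
#' precision_recall_at_n(c("d1", "d2", "d3"), c("d2", "d4"), 3)
precision_recall_at_n <- function(recommended, relevant, n) {
  if (!is_count(n)) abort_data("`n` must be a positive integer")
  relevant <- unique(relevant)
  if (length(relevant) == 0L) {
    abort_data("recall is undefined for an empty relevant set",
               reason = "empty_relevant")
  }
  top <- utils::head(recommended, n)
  hits <- length(intersect(top, relevant))
  tibble::tibble(precision = hits / n, recall = hits / length(relevant),
                 hits = as.integer(hits))
}

#' Mean before/after gain in percentage points
#'
#' `100 * mean(after - before)` over the comparison rows; linear, so
#' duplicating the rows leaves it unchanged.
#'
#' @param before,after Numeric rates in `[0, 1]`, same length, >= 1 row.
#' @return Gain in percentage points.
#' @export
#' @examples
#' mean_gain(c(0.71, 0.61, 0.60, 0.51), c(0.74, 0.66, 0.63, 0.53))
mean_gain <- function(before, after) {
  if (length(before) == 0L || length(before) != length(after)) {
    abort_data("`before` and `after` must be non-empty vectors of equal length")
  }
  if (any(before < 0 | before > 1 | after < 0 | after > 1)) {
    abort_data("rates must lie in [0, 1]")
  }
  100 * mean(after - before)
}

# -- internal: one algorithm's top-N list from a neighbor submatrix ---------

# Densify-then-CF variants share the CF step and differ in the densifier;
# "CF" skips densification and runs the classic observed-only variant.
recommend_from_neighbors <- function(algorithm, neighbors, ratings, n_top,
                                     rank, lambda, sweeps, seed) {
  rated <- dplyr::filter(ratings, .data$patient_id %in% neighbors$patient_id)
  if (nrow(rated) == 0L) return(character(0))
  R <- rating_matrix(rated)
  neighbors <- dplyr::filter(neighbors, .data$patient_id %in% rownames(R))
  fit_rank <- min(rank, dim(R))

  scores <- switch(algorithm,
    ALS_User_CF = {
      fm <- als_factorize(R, rank = fit_rank, lambda = lambda, sweeps = sweeps,
                          seed = seed)
      vapply(colnames(R), function(doc) {
        as.numeric(predict_score(doc, neighbors, fm$reconstruction))
      }, numeric(1))
    },
    SVD_User_CF = {
      # column-mean imputation then truncated SVD: a rank-k densifier
      # baseline standing in for classic SVD recommenders (reimplementation,
      # not a reference system)
      Rimp <- R
      for (j in seq_len(ncol(R))) {
        cm <- mean(R[, j], na.rm = TRUE)
        Rimp[is.na(R[, j]), j] <- cm
      }
      sv <- svd(Rimp)
      r <- min(fit_rank, length(sv$d))
      dense <- sv$u[, seq_len(r), drop = FALSE] %*%
        diag(sv$d[seq_len(r)], r) %*% t(sv$v[, seq_len(r), drop = FALSE])
      dimnames(dense) <- dimnames(R)
      vapply(colnames(R), function(doc) {
        as.numeric(predict_score(doc, neighbors, dense))
      }, numeric(1))
    },
    CF = {
      # classic user CF on the raw sparse matrix: means and deviations over
      # observed entries only
      sub <- R[match(neighbors$patient_id, rownames(R)), , drop = FALSE]
      row_means <- rowMeans(sub, na.rm = TRUE)
      vapply(colnames(sub), function(doc) {
        col <- sub[, doc]
        has <- !is.na(col)
        if (!any(has)) return(NA_real_)
        rbar_i <- mean(col[has])
        sim <- neighbors$similarity[has]
        if (sum(sim) <= 0) return(rbar_i)
        rbar_i + sum(sim * (col[has] - row_means[has])) / sum(sim)
      }, numeric(1))
    },
    abort_config(paste0("unknown algorithm '", algorithm, "'"), field = "algorithms")
  )
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) return(character(0))
  names(scores)[utils::head(order(-scores, names(scores)), n_top)]
}

#' Before/after-clustering comparison of recommender algorithms
#'
#' Mirrors the evaluation design of the pipeline: hold out a fraction of
#' patients, fit the model on the rest, and score each algorithm's top-N
#' doctor list for every held-out patient twice — once with the neighbor
#' search over the whole triaged department ("before" clustering) and once
#' restricted to the assigned patient cluster ("after"). A held-out
#' patient's relevant doctors are those they rated at or above
#' `relevance_threshold`; patients with no relevant doctor are skipped.
#'
#' @param clinic A [generate_clinic()] result (or a list with `visits` and
#'   `ratings` tibbles).
#' @param algorithms Character subset of
#'   `c("ALS_User_CF", "SVD_User_CF", "CF")`.
#' @param seed Master seed (split into hold-out, clustering and ALS seeds).
#' @param test_fraction Fraction of patients held out.
#' @param n_top Recommendation cut-off N.
#' @param m Neighbor count.
#' @param k Clusters per department for the fitted model.
#' @param rank,lambda,sweeps ALS parameters.
#' @param relevance_threshold Minimum held-out rating that marks a doctor
#'   relevant.
#' @return An object of class `eval_report`: tibble with one row per
#'   algorithm (`accuracy_before`, `accuracy_after`, `recall_before`,
#'   `recall_after`) and attributes `mean_accuracy_gain`,
#'   `mean_recall_gain` (percentage points), `candidate_sizes` (mean
#'   candidate-set size before/after), `n_test`, `seed`.
#' @export
before_after_comparison <- function(clinic,
                                    algorithms = c("ALS_User_CF", "SVD_User_CF", "CF"),
                                    seed = 1, test_fraction = 0.2, n_top = 5,
                                    m = 10, k = 4, rank = 8, lambda = 0.1,
                                    sweeps = 10, relevance_threshold = 4) {
  visits <- tibble::as_tibble(clinic$visits)
  ratings <- tibble::as_tibble(clinic$ratings)
  algorithms <- match.arg(algorithms, several.ok = TRUE)

  split_s <- split_seed(seed, "split")
  ids <- visits$patient_id
  n_test <- max(1L, round(test_fraction * length(ids)))
  test_ids <- with_local_seed(split_s, sample(ids, n_test))
  train_visits <- dplyr::filter(visits, !.data$patient_id %in% test_ids)
  train_ratings <- dplyr::filter(ratings, !.data$patient_id %in% test_ids)
  model <- clinic_model(train_visits, train_ratings, k = k, seed = seed)
  als_seed <- split_seed(seed, "als")

  acc <- list()
  sizes <- c(before = 0, after = 0)
  n_used <- 0L
  for (pid in test_ids) {
    vrow <- visits[visits$patient_id == pid, ]
    relevant <- ratings$doctor_id[ratings$patient_id == pid &
                                    ratings$rating >= relevance_threshold]
    if (length(relevant) == 0L) next
    a <- suppressWarnings(patient_vector(vrow$tokens[[1]], model$corpus))
    if (all(a == 0)) next

    dept <- triage_patient(a, model$profiles)$department_id[1L]
    dept_ids <- model$membership$patient_id[model$membership$department_id == dept]
    dept_ids <- intersect(dept_ids, rownames(model$vectors))
    if (length(dept_ids) == 0L) next
    cl <- as.integer(assign_cluster(a, model$clusters[[dept]]))
    cl_ids <- names(model$clusters[[dept]]$assignments)[
      model$clusters[[dept]]$assignments == cl]
    cl_ids <- intersect(cl_ids, rownames(model$vectors))
    if (length(cl_ids) == 0L) cl_ids <- dept_ids

    nb_before <- neighbor_select(a, model$vectors[dept_ids, , drop = FALSE], m)
    nb_after <- neighbor_select(a, model$vectors[cl_ids, , drop = FALSE], m)
    sizes <- sizes + c(before = length(dept_ids), after = length(cl_ids))
    n_used <- n_used + 1L

    for (alg in algorithms) {
      for (phase in c("before", "after")) {
        nb <- if (phase == "before") nb_before else nb_after
        top <- recommend_from_neighbors(alg, nb, train_ratings, n_top,
                                        rank, lambda, sweeps, als_seed)
        pr <- if (length(top) == 0L) {
          tibble::tibble(precision = 0, recall = 0)
        } else {
          precision_recall_at_n(top, relevant, n_top)
        }
        key <- paste(alg, phase, sep = ".")
        acc[[key]] <- rbind(acc[[key]], c(pr$precision, pr$recall))
      }
    }
  }
  if (n_used == 0L) abort_data("no held-out patient had a relevant doctor")

  rows <- lapply(algorithms, function(alg) {
    b <- acc[[paste0(alg, ".before")]]
    a_ <- acc[[paste0(alg, ".after")]]
    tibble::tibble(
      algorithm = alg,
      accuracy_before = mean(b[, 1]), accuracy_after = mean(a_[, 1]),
      recall_before = mean(b[, 2]), recall_after = mean(a_[, 2])
    )
  })
  report <- dplyr::bind_rows(rows)
  structure(
    report,
    mean_accuracy_gain = mean_gain(report$accuracy_before, report$accuracy_after),
    mean_recall_gain = mean_gain(report$recall_before, report$recall_after),
    candidate_sizes = sizes / n_used,
    n_test = n_used,
    seed = seed,
    class = c("eval_report", class(report))
  )
}

#' Write / read an evaluation report as delimited text
#'
#' The table round-trips unchanged; the derived mean-gain cells are
#' recomputed on read.
#'
#' @param report An `eval_report` (or compatible data frame).
#' @param path File path.
#' @return `path` invisibly / the report tibble.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  structure(
    df,
    mean_accuracy_gain = mean_gain(df$accuracy_before, df$accuracy_after),
    mean_recall_gain = mean_gain(df$recall_before, df$recall_after),
    class = c("eval_report", class(df))
  )
}
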