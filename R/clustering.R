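# Trust-weighted K-means over patient symptom vectors, with elbow selection
# of k from the SSE curve.

#' Trust between two symptom sets
#'
#' The trust multiplier between two patients is
#' `sqrt(|I(u) union I(v)|) / |I(u) intersect I(v)|` over their symptom
#' (support) sets: the more symptoms two complaints share, the smaller the
#' multiplier and hence the smaller the trust-weighted distance. Disjoint
#' sets return `Inf` (maximally distant).
#'
#' With `mode = "jaccard_inverse"` the square root is dropped
#' (`|union| / |intersection|`), a plain inverse-Jaccard reading of the same
#' quantity.
#'
#' @param symptoms_u,symptoms_v Non-empty character vectors of symptom terms.
#' @param mode `"as_printed"` (default) or `"jaccard_inverse"`.
#' @return Positive real, or `Inf` for disjoint sets.
#' @export
#' @examples
#' trust(c("a", "b", "c", "d"), c("a", "b", "c", "d"))  # sqrt(4)/4 = 0.5
trust <- function(symptoms_u, symptoms_v, mode = c("as_printed", "jaccard_inverse")) {
  mode <- match.arg(mode)
  if (length(symptoms_u) == 0L || length(symptoms_v) == 0L) {
    abort_data("symptom sets must be non-empty")
  }
  u <- unique(symptoms_u)
  v <- unique(symptoms_v)
  n_int <- length(intersect(u, v))
  n_uni <- length(union(u, v))
  if (n_int == 0L) return(Inf)
  if (mode == "as_printed") sqrt(n_uni) / n_int else n_uni / n_int
}

support_of <- function(w, threshold = 1e-9) names(w)[w > threshold]

#' Trust-weighted distance between two patient vectors
#'
#' Euclidean distance restricted to the common support (symptoms both
#' patients report), multiplied by the [trust()] of their symptom sets:
#' `D(u, v) = T(u, v) * sqrt(sum_{i in I(u, v)} (W_ui - W_vi)^2)`.
#' Disjoint supports give `Inf`.
#'
#' @param u,v Named weight vectors over the same vocabulary with non-empty
#'   support.
#' @param mode Trust mode, see [trust()].
#' @param support_threshold Weights above this count as support.
#' @return Non-negative real or `Inf`.
#' @export
trust_distance <- function(u, v, mode = "as_printed", support_threshold = 1e-9) {
  su <- support_of(u, support_threshold)
  sv <- support_of(v, support_threshold)
  if (length(su) == 0L || length(sv) == 0L) {
    abort_data("vectors must have non-empty support")
  }
  common <- intersect(su, sv)
  if (length(common) == 0L) return(Inf)
  t_uv <- trust(su, sv, mode = mode)
  t_uv * sqrt(sum((u[common] - v[common])^2))
}

# Vectorized trust distances from every row of X (patients x vocab) to one
# centroid. S is the logical support matrix of X.
trust_distance_rows <- function(X, S, centroid, centroid_support, mode) {
  cs <- centroid_support
  inter <- as.vector(S %*% cs)
  uni <- rowSums(S) + sum(cs) - inter
  t_mult <- if (mode == "as_printed") sqrt(uni) / inter else uni / inter
  t_mult[inter == 0] <- Inf
  diff2 <- sweep(X, 2L, centroid)^2
  diff2[!S | matrix(!cs, nrow(X), ncol(X), byrow = TRUE)] <- 0
  eu <- sqrt(rowSums(diff2))
  d <- t_mult * eu
  d[inter == 0] <- Inf
  d
}

plain_euclidean_rows <- function(X, centroid) {
  sqrt(rowSums(sweep(X, 2L, centroid)^2))
}

# distance matrix n x k plus fallback bookkeeping
cluster_distances <- function(X, S, centroids, supports, mode) {
  k <- nrow(centroids)
  D <- vapply(seq_len(k), function(j) {
    trust_distance_rows(X, S, centroids[j, ], supports[j, ], mode)
  }, numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X), ncol = k)
  fallback <- rowSums(is.finite(D)) == 0L
  if (any(fallback)) {
    Dfb <- vapply(seq_len(k), function(j) plain_euclidean_rows(X[fallback, , drop = FALSE],
                                                               centroids[j, ]),
                  numeric(sum(fallback)))
    D[fallback, ] <- matrix(Dfb, nrow = sum(fallback), ncol = k)
  }
  list(D = D, fallback = fallback)
}

assign_rows <- function(D) apply(D, 1L, which.min)  # which.min: ties -> lowest index

# farthest-point initialization from a seeded RNG
init_centroids <- function(X, S, k, mode) {
  n <- nrow(X)
  chosen <- sample.int(n, 1L)
  min_d <- trust_distance_rows(X, S, X[chosen, ], S[chosen, ], mode)
  min_d[!is.finite(min_d)] <- sqrt(ncol(X)) * (max(abs(X)) + 1)  # beyond any finite distance
  while (length(chosen) < k) {
    min_d[chosen] <- -Inf
    nxt <- which.max(min_d)
    chosen <- c(chosen, nxt)
    d_new <- trust_distance_rows(X, S, X[nxt, ], S[nxt, ], mode)
    d_new[!is.finite(d_new)] <- sqrt(ncol(X)) * (max(abs(X)) + 1)
    min_d <- pmin(min_d, d_new)
  }
  chosen
}

#' Trust-weighted K-means over patient vectors
#'
#' Lloyd-style iteration using [trust_distance()] for assignment and the
#' coordinate-wise mean of members as the centroid update; a centroid's
#' symptom set is the set of coordinates above `support_threshold`. Because
#' the trust-weighted distance is not a metric, the mean update is not
#' guaranteed to lower the trust-weighted SSE, so the fitter iterates to an
#' assignment fixpoint (or `max_iter`) while keeping the best-SSE state
#' seen, which it returns; `sse_path` records only accepted improvements
#' and is therefore non-increasing.
#'
#' Patients sharing no symptom with any centroid are assigned by plain
#' Euclidean distance and flagged. An emptied cluster is re-seeded with the
#' patient farthest from its centroid.
#'
#' @param X Patient-by-vocabulary weight matrix (rownames = patient ids),
#'   e.g. from [patient_vectors()]; every row must have non-empty support.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed Seed for the farthest-point initialization.
#' @param max_iter,tol Iteration cap and SSE-change tolerance.
#' @param patience Stop after this many consecutive iterations without an
#'   SSE improvement.
#' @param n_start Number of restarts; the best-SSE fit is returned
#'   (restart seeds are derived deterministically from `seed`).
#' @param trust_mode See [trust()].
#' @param support_threshold Coordinates above this value count as symptoms.
#' @return An object of class `cluster_model`: `k`, `centroids`,
#'   `assignments` (named integer), `sse`, `sse_path`, `iterations_run`,
#'   `fallback` (patients assigned by the Euclidean fallback), `seed`,
#'   `trust_mode`, `support_threshold`.
#' @export
kmeans_trust <- function(X, k, seed = 1, max_iter = 100, tol = 1e-6,
                         patience = 10, n_start = 5,
                         trust_mode = c("as_printed", "jaccard_inverse"),
                         support_threshold = 1e-9) {
  trust_mode <- match.arg(trust_mode)
  if (is.null(dim(X)) || nrow(X) < 1L) abort_data("`X` must be a patient-by-term matrix")
  n <- nrow(X)
  if (!is_count(k) || k > n) {
    abort_data(paste0("`k` must be an integer in [1, ", n, "]"))
  }
  if (!is_count(n_start)) abort_data("`n_start` must be a positive integer")
  S <- X > support_threshold
  if (any(rowSums(S) == 0L)) {
    abort_data("every patient vector must have non-empty support")
  }
  # canonical row order: the seeded initialization then depends on the set
  # of patients, not on their input order (permutation equivariance)
  if (!is.null(rownames(X)) && !anyDuplicated(rownames(X))) {
    X <- X[order(rownames(X)), , drop = FALSE]
    S <- S[order(rownames(S)), , drop = FALSE]
  }
  if (n_start > 1L) {
    # best of n_start restarts (seeds derived deterministically from `seed`)
    fits <- lapply(seq_len(n_start), function(r) {
      kmeans_trust(X, k, seed = seed + (r - 1L) * 131L, max_iter = max_iter,
                   tol = tol, patience = patience, n_start = 1L,
                   trust_mode = trust_mode, support_threshold = support_threshold)
    })
    best_fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
    best_fit$seed <- seed
    return(best_fit)
  }

  return(with_local_seed(seed, {
    idx <- init_centroids(X, S, k, trust_mode)
    centroids <- X[idx, , drop = FALSE]
    rownames(centroids) <- NULL
    supports <- centroids > support_threshold

    assign_prev <- rep(0L, n)
    best <- NULL
    stall <- 0L
    sse_path <- numeric(0)
    iterations <- 0L

    for (it in seq_len(max_iter)) {
      cd <- cluster_distances(X, S, centroids, supports, trust_mode)
      assignment <- assign_rows(cd$D)

      # re-seed emptied clusters with the globally farthest patient
      for (j in setdiff(seq_len(k), unique(assignment))) {
        d_here <- cd$D[cbind(seq_len(n), assignment)]
        far <- which.max(ifelse(is.finite(d_here), d_here, -Inf))
        centroids[j, ] <- X[far, ]
        supports[j, ] <- S[far, ]
        cd <- cluster_distances(X, S, centroids, supports, trust_mode)
        assignment <- assign_rows(cd$D)
      }

      # candidate state: this assignment with its member-mean centroids
      # (a model's centroids are always means of its members)
      new_centroids <- centroids
      for (j in seq_len(k)) {
        members <- which(assignment == j)
        if (length(members) > 0L) {
          new_centroids[j, ] <- colMeans(X[members, , drop = FALSE])
        }
      }
      new_supports <- new_centroids > support_threshold
      cd_new <- cluster_distances(X, S, new_centroids, new_supports, trust_mode)
      sse <- sum(cd_new$D[cbind(seq_len(n), assignment)]^2)

      iterations <- it
      improved <- is.null(best) || sse < best$sse - tol
      if (improved) {
        sse_path <- c(sse_path, sse)
        best <- list(centroids = new_centroids, assignment = assignment,
                     fallback = cd$fallback, sse = sse)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      # assignment fixpoint, or no improvement for `patience` iterations
      # (the trust-weighted update can cycle without converging)
      if (identical(assignment, assign_prev) || stall >= patience) break
      assign_prev <- assignment
      centroids <- new_centroids
      supports <- new_supports
    }

    structure(
      list(
        k = k,
        centroids = best$centroids,
        assignments = stats::setNames(best$assignment, rownames(X)),
        sse = best$sse,
        sse_path = sse_path,
        iterations_run = iterations,
        fallback = stats::setNames(best$fallback, rownames(X)),
        seed = seed,
        trust_mode = trust_mode,
        support_threshold = support_threshold
      ),
      class = "cluster_model"
    )
  }))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k,
      " n =", length(x$assignments),
      " SSE =", format(x$sse, digits = 6),
      " iterations =", x$iterations_run, "\n")
  invisible(x)
}

#' Assign a patient vector to its nearest cluster
#'
#' Trust-weighted distance to every centroid; if the patient shares no
#' symptom with any centroid, plain Euclidean distance is used instead and
#' the result carries attribute `fallback = TRUE`. Ties go to the lowest
#' cluster index.
#'
#' @param p Named weight vector (same vocabulary as the model's centroids).
#' @param model A fitted [kmeans_trust()] model.
#' @return Cluster index (integer).
#' @export
assign_cluster <- function(p, model) {
  stopifnot(inherits(model, "cluster_model"))
  X <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  S <- X > model$support_threshold
  if (sum(S) == 0L) abort_data("patient vector has empty support")
  supports <- model$centroids > model$support_threshold
  cd <- cluster_distances(X, S, model$centroids, supports, model$trust_mode)
  structure(assign_rows(cd$D)[1L], fallback = unname(cd$fallback[1L]))
}

#' SSE as a function of k
#'
#' Fits [kmeans_trust()] for each k in `k_range` (same seed) and returns the
#' curve used by the elbow rule.
#'
#' @param X Patient-by-term weight matrix.
#' @param k_range Integer vector of candidate k (at least 3 values).
#' @param seed Seed passed to each fit.
#' @param n_start Restarts per fit; the curve needs well-converged SSE
#'   values at every k, so the default is higher than [kmeans_trust()]'s.
#' @param ... Further arguments to [kmeans_trust()].
#' @return A tibble of class `sse_curve` with columns `k`, `sse`.
#' @export
sse_curve <- function(X, k_range, seed = 1, n_start = 10, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) {
    abort_data("`k_range` must contain at least 3 distinct values")
  }
  out <- tibble::tibble(
    k = k_range,
    sse = vapply(k_range, function(k) {
      kmeans_trust(X, k, seed = seed, n_start = n_start, ...)$sse
    }, numeric(1))
  )
  class(out) <- c("sse_curve", class(out))
  out
}

#' Select k at the elbow of an SSE curve
#'
#' The elbow is the interior point maximizing the discrete second forward
#' difference of the curve on the log scale,
#' `log SSE(k-1) - 2 log SSE(k) + log SSE(k+1)` (maximum curvature of the
#' decreasing curve, assuming a contiguous k grid); ties resolve to the
#' smallest k. The log scale makes the rule exact at the slope change of a
#' two-regime curve while staying neutral on a geometric decay, which is
#' how the trust-weighted SSE behaves while centroids still merge several
#' true clusters; the linear-scale second difference degenerates to the
#' smallest k on such convex decays. A curve with no knee (constant slope
#' or constant ratio) returns the smallest interior k with a warning.
#'
#' @param curve A tibble with columns `k`, `sse` ([sse_curve()] output).
#' @return Selected `k` (integer).
#' @export
elbow_select <- function(curve) {
  if (nrow(curve) < 3L) abort_data("the SSE curve needs at least 3 points")
  curve <- dplyr::arrange(curve, .data$k)
  s <- curve$sse
  n <- length(s)
  d2_lin <- s[1:(n - 2)] - 2 * s[2:(n - 1)] + s[3:n]
  ls <- log(pmax(s, 1e-12 * max(s, 1)))
  d2 <- ls[1:(n - 2)] - 2 * ls[2:(n - 1)] + ls[3:n]
  flat_lin <- max(d2_lin) - min(d2_lin) < 1e-12 * max(abs(s), 1)
  flat_log <- max(d2) - min(d2) < 1e-12 * max(abs(ls), 1)
  if (flat_lin || flat_log) {
    warning("SSE curve has no knee (constant curvature); returning smallest interior k",
            call. = FALSE)
    return(curve$k[2L])
  }
  curve$k[1L + which.max(d2)]
}

#' Small chance-corrected partition agreement (adjusted Rand index)
#'
#' Used by the evaluation harness to score planted-cluster recovery.
#'
#' @param labels_a,labels_b Two partitions of the same elements.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort_data("partitions must cover the same elements")
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
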