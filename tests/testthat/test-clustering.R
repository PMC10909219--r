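# Trust metric, trust-weighted K-means, elbow selection, assignment.

test_that("trust reproduces its forced set arithmetic", {
  expect_equal(trust(letters[1:4], letters[1:4]), sqrt(4) / 4)
  expect_equal(trust(letters[1:6], letters[4:9]), sqrt(9) / 3)
  expect_equal(trust(c("a"), c("b")), Inf)
  expect_error(trust(character(0), "a"), class = "triagerec_data_error")
  # prose-reading variant drops the square root
  expect_equal(trust(letters[1:6], letters[4:9], mode = "jaccard_inverse"), 3)
})

test_that("trust distance matches its hand-computed case", {
  u <- c(a = 0.6, b = 0.8, c = 0.1)
  v <- c(a = 0.3, b = 0.4, c = 0)
  # |union| = 3, |intersection| = 2, restricted Euclid = 0.5
  expect_equal(trust_distance(u, v), 0.433012701892219, tolerance = 1e-12)
  expect_equal(trust_distance(u, u), 0)
  expect_equal(trust_distance(c(a = 1, b = 0), c(a = 0, b = 1)), Inf)
})

test_that("trust distance is symmetric and agrees with the loop oracle", {
  set.seed(19)
  vocab <- sprintf("t%02d", 1:10)
  for (i in 1:25) {
    u <- stats::setNames(stats::rbinom(10, 1, 0.5) * stats::runif(10), vocab)
    v <- stats::setNames(stats::rbinom(10, 1, 0.5) * stats::runif(10), vocab)
    if (all(u <= 1e-9) || all(v <= 1e-9)) next
    expect_equal(trust_distance(u, v), trust_distance(v, u))
    expect_equal(trust_distance(u, v), oracle_trust_distance(u, v),
                 tolerance = 1e-12)
  }
})

test_that("degenerate k choices behave as limits", {
  set.seed(8)
  visits <- random_visits(12, vocab_size = 10)
  X <- patient_vectors(symptom_corpus(visits))
  X <- X[!duplicated(X), ]
  km_n <- kmeans_trust(X, nrow(X), seed = 1)
  expect_equal(km_n$sse, 0)
  expect_equal(length(unique(km_n$assignments)), nrow(X))

  km_1 <- kmeans_trust(X, 1, seed = 1)
  expect_equal(unname(km_1$centroids[1, ]), unname(colMeans(X)))
  expect_error(kmeans_trust(X, nrow(X) + 1), class = "triagerec_data_error")
})

test_that("the SSE path never increases and the stored SSE is recomputable", {
  set.seed(12)
  visits <- random_visits(40, vocab_size = 15)
  X <- patient_vectors(symptom_corpus(visits))
  km <- kmeans_trust(X, 3, seed = 5)
  expect_true(all(diff(km$sse_path) <= 0))
  # recompute SSE from assignments and centroids
  sse <- 0
  for (i in seq_len(nrow(X))) {
    j <- km$assignments[i]
    d <- tryCatch(
      trust_distance(X[i, ], stats::setNames(km$centroids[j, ], colnames(X))),
      error = function(e) Inf
    )
    if (!is.finite(d)) d <- sqrt(sum((X[i, ] - km$centroids[j, ])^2))
    sse <- sse + d^2
  }
  expect_equal(km$sse, sse, tolerance = 1e-8)
})

test_that("fits are deterministic and order-equivariant", {
  set.seed(33)
  visits <- random_visits(30, vocab_size = 12)
  X <- patient_vectors(symptom_corpus(visits))
  km_a <- kmeans_trust(X, 3, seed = 9)
  km_b <- kmeans_trust(X, 3, seed = 9)
  expect_identical(km_a$assignments, km_b$assignments)

  perm <- sample(nrow(X))
  km_p <- kmeans_trust(X[perm, ], 3, seed = 9)
  # same partition up to label renaming
  common <- rownames(X)
  expect_equal(
    adjusted_rand_index(km_a$assignments[common], km_p$assignments[common]), 1
  )
})

test_that("planted subclusters are recovered on a separated department", {
  clinic <- generate_clinic(clinic_config(
    n_departments = 1, vocab_size = 80, n_patients = 200,
    clusters_per_department = 4, dept_concentration = 0.05, seed = 3
  ))
  X <- patient_vectors(symptom_corpus(clinic$visits))
  km <- kmeans_trust(X, 4, seed = 3)
  truth <- clinic$truth$subcluster[match(rownames(X), clinic$truth$patient_id)]
  ari <- adjusted_rand_index(km$assignments, truth)
  expect_gte(ari, 0.9)
  # cross-check the ARI helper against an established implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(km$assignments, truth),
               tolerance = 1e-12)
})

test_that("elbow selection finds a constructed knee and flags flat curves", {
  k <- 2:30
  sse <- ifelse(k <= 20, 1000 - 40 * (k - 2), 1000 - 40 * 18 - 2 * (k - 20))
  expect_equal(elbow_select(tibble::tibble(k = k, sse = sse)), 20)

  linear <- tibble::tibble(k = 2:10, sse = 100 - 5 * (2:10))
  expect_warning(k_star <- elbow_select(linear), "no knee")
  expect_equal(k_star, 3)

  expect_error(elbow_select(tibble::tibble(k = 1:2, sse = c(2, 1))),
               class = "triagerec_data_error")
})

test_that("elbow selection finds the curvature maximum of random two-slope curves", {
  set.seed(44)
  for (i in 1:20) {
    knee <- sample(5:15, 1)
    s1 <- stats::runif(1, 20, 60)
    s2 <- stats::runif(1, 0.1, 2)
    k <- 2:20
    sse <- ifelse(k <= knee, 1000 - s1 * (k - 2),
                  1000 - s1 * (knee - 2) - s2 * (k - knee))
    expect_equal(elbow_select(tibble::tibble(k = k, sse = sse)), knee)
  }
})

test_that("the elbow recovers the planted subcluster count in the modal case", {
  selected <- vapply(1:5, function(s) {
    clinic <- generate_clinic(clinic_config(
      n_departments = 1, vocab_size = 120, n_patients = 150,
      clusters_per_department = 6, dept_concentration = 0.05, seed = s
    ))
    X <- patient_vectors(symptom_corpus(clinic$visits))
    suppressWarnings(elbow_select(sse_curve(X, 2:15, seed = s)))
  }, integer(1))
  modal <- as.integer(names(which.max(table(selected))))
  expect_equal(modal, 6)
})

test_that("held-out patients are assigned to their source subcluster", {
  clinic <- generate_clinic(clinic_config(
    n_departments = 1, vocab_size = 80, n_patients = 250,
    clusters_per_department = 4, dept_concentration = 0.05, seed = 5
  ))
  corpus <- symptom_corpus(clinic$visits[1:200, ])
  X <- patient_vectors(corpus)
  km <- kmeans_trust(X, 4, seed = 5)
  truth <- clinic$truth$subcluster[match(rownames(X), clinic$truth$patient_id)]
  label_of <- vapply(1:4, function(j) {
    as.integer(names(which.max(table(truth[km$assignments == j]))))
  }, integer(1))
  held <- patient_vectors(corpus, clinic$visits[201:250, ])
  ok <- vapply(seq_len(nrow(held)), function(i) {
    label_of[assign_cluster(held[i, ], km)] == clinic$truth$subcluster[200 + i]
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("a patient disjoint from every centroid takes the Euclidean fallback", {
  vocab <- letters[1:6]
  X <- rbind(
    p1 = stats::setNames(c(1, 1, 0, 0, 0, 0), vocab),
    p2 = stats::setNames(c(0.9, 1.1, 0, 0, 0, 0), vocab),
    p3 = stats::setNames(c(0, 0, 1, 1, 0, 0), vocab),
    p4 = stats::setNames(c(0, 0, 1.1, 0.9, 0, 0), vocab)
  )
  km <- kmeans_trust(X, 2, seed = 1)
  q <- stats::setNames(c(0, 0, 0, 0, 1, 1), vocab)
  idx <- assign_cluster(q, km)
  expect_true(isTRUE(attr(idx, "fallback")))
  expect_true(as.integer(idx) %in% 1:2)
  # a patient equal to a centroid belongs to that centroid's cluster
  cm <- stats::setNames(km$centroids[2, ], vocab)
  expect_equal(as.integer(assign_cluster(cm, km)), 2L)
})
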