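# TF-IDF vector space construction: term frequencies, smoothed IDF,
# patient vectors and score-weighted department profiles.

test_that("term frequency normalizes counts within one complaint", {
  tf <- term_frequency(c(cough = 2, fever = 1, chills = 1))
  expect_equal(tf, c(cough = 0.5, fever = 0.25, chills = 0.25))
  expect_equal(term_frequency(c(rash = 3)), c(rash = 1))
  expect_error(term_frequency(c()), class = "triagerec_data_error")
  expect_error(term_frequency(c(a = 0)), class = "triagerec_data_error")
})

test_that("IDF follows the smoothed natural-log form log(N/D + 1)", {
  expect_equal(inverse_document_frequency(7, 7), log(2))
  expect_equal(inverse_document_frequency(100, 9), 2.494123304892924,
               tolerance = 1e-12)
  expect_error(inverse_document_frequency(10, 0), class = "triagerec_data_error")
  expect_error(inverse_document_frequency(10, 11), class = "triagerec_data_error")
})

test_that("patient vectors compose TF and IDF over the corpus vocabulary", {
  visits <- toy_visits(list(
    visit_row("p1", c(cough = 1, fever = 1)),
    visit_row("p2", c(cough = 4))
  ))
  corpus <- symptom_corpus(visits)
  v <- patient_vector(c(cough = 4), corpus)
  expect_equal(unname(v["cough"]), 1 * log(2))

  # three-document toy corpus against the brute-force oracle
  visits3 <- toy_visits(list(
    visit_row("p1", c(a = 1, b = 1)),
    visit_row("p2", c(a = 1)),
    visit_row("p3", c(b = 1, c = 2))
  ))
  corpus3 <- symptom_corpus(visits3)
  X <- patient_vectors(corpus3)
  expect_equal(X, oracle_patient_vectors(visits3), tolerance = 1e-12)
})

test_that("out-of-vocabulary complaints yield a flagged zero vector", {
  corpus <- symptom_corpus(toy_visits(list(visit_row("p1", c(cough = 1)))))
  expect_warning(v <- patient_vector(c(nausea = 2), corpus), "no in-vocabulary")
  expect_true(all(v == 0))
  expect_true(isTRUE(attr(v, "oov")))
})

test_that("score-weighted TF reproduces the forced two-patient arithmetic", {
  visits <- toy_visits(list(
    visit_row("pA", c(cough = 2, fever = 2), rating = 5),
    visit_row("pB", c(cough = 1, rash = 1), rating = 1)
  ))
  tf <- score_weighted_tf(visits)
  expect_equal(unname(tf["cough"]), 11 / 22)
  expect_equal(unname(tf["fever"]), 10 / 22)
  expect_equal(unname(tf["rash"]), 1 / 22)
  expect_equal(sum(tf), 1)
})

test_that("equal ratings reduce score weighting to pooled term frequency", {
  set.seed(42)
  visits <- random_visits(8)
  visits$rating <- 4L
  tf_w <- score_weighted_tf(visits)
  pooled <- unlist(visits$tokens)
  pooled <- tapply(pooled, names(pooled), sum)
  nms <- sort(names(pooled))
  expect_equal(unname(tf_w[nms]),
               as.numeric(pooled[nms] / sum(pooled)))
})

test_that("department profiles match the brute-force oracle", {
  set.seed(7)
  visits <- random_visits(12, n_dept = 2)
  corpus <- symptom_corpus(visits)
  P <- department_profiles(corpus)
  for (d in c("1", "2")) {
    dv <- visits[visits$visited_department_id == as.integer(d), ]
    expect_equal(P[d, ], oracle_department_profile(dv, visits),
                 tolerance = 1e-12)
  }
})

test_that("raising a patient's rating raises the weight of their unique term", {
  base <- list(
    visit_row("p1", c(shared = 2, unique1 = 3), rating = 1),
    visit_row("p2", c(shared = 3), rating = 4)
  )
  lo <- score_weighted_tf(toy_visits(base))
  base[[1]]$rating <- 5L
  hi <- score_weighted_tf(toy_visits(base))
  expect_gt(hi[["unique1"]], lo[["unique1"]])
})

test_that("weighted TF sums to one per department and weights stay finite", {
  set.seed(11)
  for (rep in 1:5) {
    visits <- random_visits(10, n_dept = 3)
    corpus <- symptom_corpus(visits)
    for (d in unique(visits$visited_department_id)) {
      tf <- score_weighted_tf(visits[visits$visited_department_id == d, ],
                              vocabulary = corpus$vocabulary)
      expect_equal(sum(tf), 1, tolerance = 1e-9)
    }
    X <- patient_vectors(corpus)
    expect_true(all(is.finite(X)) && all(X >= 0))
  }
})

test_that("vocabulary order does not depend on input order", {
  set.seed(3)
  visits <- random_visits(9)
  shuffled <- visits[sample(nrow(visits)), ]
  c1 <- symptom_corpus(visits)
  c2 <- symptom_corpus(shuffled)
  expect_identical(c1$vocabulary, c2$vocabulary)
  X1 <- patient_vectors(c1)
  X2 <- patient_vectors(c2)
  expect_equal(X1[sort(rownames(X1)), ], X2[sort(rownames(X2)), ])
})

test_that("profile vectors round-trip through the JSON serialization", {
  set.seed(5)
  visits <- random_visits(8, n_dept = 2)
  corpus <- symptom_corpus(visits)
  P <- department_profiles(corpus)
  path <- withr::local_tempfile(fileext = ".json")
  write_vector_json(P, path)
  expect_equal(read_vector_json(path), P, tolerance = 1e-12)
})
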