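# Synthetic clinic generator: determinism, validation, planted structure,
# and text round-trips.

test_that("invalid configuration fields are rejected by name", {
  expect_error(clinic_config(n_departments = 0), "n_departments",
               class = "triagerec_config_error")
  expect_error(clinic_config(vocab_size = 3, n_departments = 5), "vocab_size",
               class = "triagerec_config_error")
  expect_error(clinic_config(rating_sparsity = 0), "rating_sparsity",
               class = "triagerec_config_error")
  expect_error(clinic_config(dept_concentration = -1), "dept_concentration",
               class = "triagerec_config_error")
})

test_that("the same seed reproduces a byte-identical corpus", {
  cfg <- clinic_config(n_patients = 60, seed = 123)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_corpus(generate_clinic(cfg), f1)
  write_corpus(generate_clinic(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and ratings too
  r1 <- generate_clinic(cfg)$ratings
  r2 <- generate_clinic(cfg)$ratings
  expect_identical(r1, r2)
})

test_that("near-zero concentration makes the top token department-diagnostic", {
  clinic <- generate_clinic(clinic_config(
    n_patients = 200, dept_concentration = 1e-6,
    clusters_per_department = 1, seed = 9
  ))
  top_tok <- vapply(clinic$visits$tokens,
                    function(tc) names(tc)[which.max(tc)], character(1))
  lut <- tapply(top_tok, clinic$truth$true_department_id,
                function(x) names(which.max(table(x))))
  pred <- vapply(top_tok, function(tok) {
    hit <- names(lut)[vapply(lut, identical, logical(1), tok)]
    if (length(hit)) as.integer(hit[1]) else NA_integer_
  }, integer(1))
  expect_equal(mean(pred == clinic$truth$true_department_id), 1)
})

test_that("lower concentration never decreases department separation", {
  seps <- vapply(c(0.5, 0.1, 0.02), function(conc) {
    department_separation(generate_clinic(clinic_config(
      n_patients = 200, dept_concentration = conc, seed = 31
    )))
  }, numeric(1))
  expect_true(all(diff(seps) >= 0))
})

test_that("matched visits are rated higher than mismatched ones", {
  clinic <- generate_clinic(clinic_config(
    n_patients = 1000, mismatch_rate = 0.3, match_bonus = 1.5, seed = 17
  ))
  v <- clinic$visits
  matched <- v$rating[v$visited_department_id == v$true_department_id]
  mismatched <- v$rating[v$visited_department_id != v$true_department_id]
  expect_gte(mean(matched) - mean(mismatched), 1.5 / 2)
})

test_that("ratings are integers on the 1-5 scale at configured sparsity", {
  cfg <- clinic_config(n_patients = 120, rating_sparsity = 0.5, seed = 2)
  clinic <- generate_clinic(cfg)
  expect_true(all(clinic$ratings$rating %in% 1:5))
  per_patient <- table(clinic$ratings$patient_id)
  expect_true(all(per_patient == round(0.5 * cfg$doctors_per_department)))
})

test_that("visit files round-trip through the line-record format", {
  clinic <- generate_clinic(clinic_config(n_patients = 40, seed = 4))
  path <- withr::local_tempfile()
  write_corpus(clinic, path)
  back <- read_corpus(path)
  expect_equal(back, clinic$visits)

  rpath <- withr::local_tempfile(fileext = ".csv")
  write_ratings(clinic$ratings, rpath)
  expect_equal(read_ratings(rpath), clinic$ratings)
})

test_that("malformed records are rejected with their line number", {
  path <- withr::local_tempfile()
  writeLines(c(
    "patient:p1 dept:1 doctor:d1 rating:5 tokens:ax2",
    "patient:p2 dept:1 doctor:d1 rating:6 tokens:ax1"
  ), path)
  expect_error(read_corpus(path), "line 2", class = "triagerec_data_error")

  writeLines("patient:p1 dept:1 doctor:d1 rating:3 tokens:", path)
  expect_error(read_corpus(path), "line 1", class = "triagerec_data_error")
})

test_that("an empty file reads as an empty corpus", {
  path <- withr::local_tempfile()
  writeLines(character(0), path)
  corpus <- read_corpus(path)
  expect_s3_class(corpus, "tbl_df")
  expect_equal(nrow(corpus), 0)
})

test_that("rating matrices round-trip through sparse coordinate files", {
  skip_if_not_installed("Matrix")
  clinic <- generate_clinic(clinic_config(n_patients = 30, seed = 6))
  R <- rating_matrix(clinic$ratings)
  path <- withr::local_tempfile(fileext = ".mtx")
  write_rating_mtx(R, path)
  expect_equal(read_rating_mtx(path), R)
})
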