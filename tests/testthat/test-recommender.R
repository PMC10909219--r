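# Neighbor selection, ALS densification, and the CF score prediction.

test_that("neighbor selection returns the exact brute-force top-m", {
  set.seed(50)
  vocab <- sprintf("t%02d", 1:12)
  members <- matrix(stats::runif(50 * 12), 50, 12,
                    dimnames = list(sprintf("p%02d", 1:50), vocab))
  a <- stats::runif(12)
  nb <- neighbor_select(a, members, 10)
  sims <- vapply(rownames(members),
                 function(id) oracle_modified_cosine(a, members[id, ]),
                 numeric(1))
  want <- names(sims)[order(-sims, names(sims))][1:10]
  expect_equal(nb$patient_id, want)
  expect_equal(nb$similarity, unname(sims[want]), tolerance = 1e-12)

  # m larger than the cluster returns everyone; an identical member leads
  all_nb <- neighbor_select(a, members, 100)
  expect_equal(nrow(all_nb), 50)
  members2 <- rbind(members, self = a)
  expect_equal(neighbor_select(a, members2, 3)$patient_id[1], "self")
})

test_that("ALS exactly recovers a fully observed rank-1 matrix", {
  R <- outer(c(1, 2), c(2, 1, 3))
  dimnames(R) <- list(c("p1", "p2"), c("d1", "d2", "d3"))
  fm <- als_factorize(R, rank = 1, lambda = 1e-6, sweeps = 25, seed = 1)
  expect_lte(max(abs(fm$reconstruction - R)), 1e-3)
  # independent oracle: the best rank-1 approximation from the SVD is R itself
  sv <- svd(R)
  oracle <- sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1])
  expect_lte(max(abs(fm$reconstruction - oracle)), 1e-3)

  # constant matrices are rank 1 as well
  C <- matrix(3.5, 4, 5)
  fmc <- als_factorize(C, rank = 1, lambda = 1e-6, sweeps = 25, seed = 2)
  expect_lte(max(abs(fmc$reconstruction - 3.5)), 1e-3)
})

test_that("ALS generalizes on a noisy partially observed rank-3 matrix", {
  set.seed(60)
  U0 <- matrix(stats::rnorm(20 * 3, 0, 1), 20, 3)
  V0 <- matrix(stats::rnorm(15 * 3, 0, 1), 15, 3)
  R0 <- U0 %*% t(V0)
  mask <- matrix(stats::runif(20 * 15) < 0.6, 20, 15)
  R <- R0 + matrix(stats::rnorm(20 * 15, 0, 0.1), 20, 15)
  R[!mask] <- NA
  fm <- als_factorize(R, rank = 3, lambda = 0.05, sweeps = 30, seed = 3)
  heldout <- sqrt(mean((fm$reconstruction[!mask] - R0[!mask])^2))
  expect_lte(heldout, 0.2)
})

test_that("observed-entry RMSE never increases across sweeps", {
  set.seed(61)
  for (s in 1:3) {
    R <- matrix(stats::runif(12 * 9, 1, 5), 12, 9)
    R[stats::runif(12 * 9) < 0.5] <- NA
    fm <- als_factorize(R, rank = 3, lambda = 0.1, sweeps = 15, seed = s)
    expect_true(all(diff(fm$rmse_path) <= 1e-10))
  }
})

test_that("ALS validates its inputs", {
  R <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(als_factorize(R, rank = 3), class = "triagerec_data_error")
  expect_error(als_factorize(R, rank = 1, lambda = 0), class = "triagerec_data_error")
  expect_error(als_factorize(matrix(NA_real_, 2, 2), rank = 1),
               class = "triagerec_data_error")
})

test_that("score prediction reproduces its closed-form cases", {
  # zero deviations: every neighbor rates doctor i at their own row mean
  Rd <- rbind(n1 = c(d1 = 4, d2 = 4), n2 = c(d1 = 3, d2 = 3))
  nb <- tibble::tibble(patient_id = c("n1", "n2"), similarity = c(0.9, 0.4))
  expect_equal(as.numeric(predict_score("d1", nb, Rd)), mean(Rd[, "d1"]))

  # single neighbor: rbar_i = 4.0 (column mean), neighbor value 4.5,
  # neighbor row mean 4.0, sim 0.5 -> 4.0 + 0.5 * 0.5 / 0.5 = 4.5
  Rd2 <- rbind(n1 = c(d1 = 4.5, d2 = 3.5), other = c(d1 = 3.5, d2 = 2.5))
  nb2 <- tibble::tibble(patient_id = "n1", similarity = 0.5)
  expect_equal(as.numeric(predict_score("d1", nb2, Rd2)), 4.5)

  # two neighbors with sims 0.8 / 0.2 and deviations +1 / -1:
  # prediction = rbar_i + (0.8 - 0.2) / 1.0 = rbar_i + 0.6
  Rd3 <- rbind(n1 = c(d1 = 4, d2 = 2), n2 = c(d1 = 2, d2 = 4))
  rbar_i <- mean(Rd3[, "d1"])
  nb3 <- tibble::tibble(patient_id = c("n1", "n2"), similarity = c(0.8, 0.2))
  expect_equal(as.numeric(predict_score("d1", nb3, Rd3)), rbar_i + 0.6)
})

test_that("score prediction is a weighted mean with the documented bounds", {
  set.seed(70)
  for (i in 1:10) {
    Rd <- matrix(stats::runif(5 * 4, 1, 5), 5, 4,
                 dimnames = list(sprintf("n%d", 1:5), sprintf("d%d", 1:4)))
    nb <- tibble::tibble(patient_id = rownames(Rd),
                         similarity = stats::runif(5, 0.1, 1))
    p <- as.numeric(predict_score("d2", nb, Rd))
    dev <- Rd[, "d2"] - rowMeans(Rd)
    rbar <- mean(Rd[, "d2"])
    expect_gte(p, rbar + min(dev) - 1e-12)
    expect_lte(p, rbar + max(dev) + 1e-12)

    # duplicating a neighbor with its similarity split in half changes nothing
    nb_dup <- dplyr::bind_rows(
      nb,
      dplyr::mutate(nb[1, ], similarity = .data$similarity / 2)
    )
    nb_dup$similarity[1] <- nb_dup$similarity[1] / 2
    expect_equal(as.numeric(predict_score("d2", nb_dup, Rd)), p,
                 tolerance = 1e-12)
  }
})

test_that("non-positive similarity mass falls back to the doctor mean", {
  Rd <- rbind(n1 = c(d1 = 4, d2 = 2))
  nb <- tibble::tibble(patient_id = "n1", similarity = -0.2)
  p <- predict_score("d1", nb, Rd)
  expect_equal(as.numeric(p), 4)
  expect_true(isTRUE(attr(p, "fallback")))
})

test_that("a doctor holding every 5 among the neighbors is recommended first", {
  clinic <- generate_clinic(clinic_config(n_patients = 120, seed = 11))
  model <- clinic_model(clinic$visits, clinic$ratings, k = 2, seed = 1)
  target <- clinic$visits$tokens[[1]]
  # the target triages into some department; make one of its rated doctors
  # hold every 5-rating while all other doctors hold 1s
  a <- patient_vector(target, model$corpus)
  dept <- triage_patient(a, model$profiles)$department_id[1]
  dept_docs <- clinic$doctors$doctor_id[
    clinic$doctors$department_id == as.integer(dept)]
  rated_dept_docs <- intersect(dept_docs, model$ratings$doctor_id)
  planted <- rated_dept_docs[1]
  model$ratings$rating <- ifelse(model$ratings$doctor_id == planted, 5L, 1L)
  rec <- recommend(model, target, n_top = 3, seed = 1)
  expect_equal(rec$doctor_id[1], planted)
  expect_true(all(diff(rec$score) <= 1e-9))
  expect_true(all(rec$score >= 1 & rec$score <= 5))
})

test_that("recommendation lists are deterministic and respect availability", {
  clinic <- generate_clinic(clinic_config(n_patients = 100, seed = 14))
  model <- clinic_model(clinic$visits, clinic$ratings, k = 2, seed = 2)
  target <- clinic$visits$tokens[[5]]
  r1 <- recommend(model, target, n_top = 50, m = 8, seed = 5)
  r2 <- recommend(model, target, n_top = 50, m = 8, seed = 5)
  expect_identical(r1$doctor_id, r2$doctor_id)
  expect_identical(r1$score, r2$score)
  # n_top larger than the rateable pool returns everything available, ordered
  expect_lte(nrow(r1), length(unique(model$ratings$doctor_id)))
  expect_equal(r1$rank, seq_len(nrow(r1)))
})
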