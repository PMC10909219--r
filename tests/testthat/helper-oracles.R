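# Independent brute-force oracles and tiny fixture builders. These
# deliberately re-derive every quantity with plain loops, separate from the
# package's vectorized implementations.

# one visit record
visit_row <- function(patient_id, tokens, dept = 1L, doctor = "d1", rating = 3L,
                      true_dept = NULL) {
  tibble::tibble(
    patient_id = patient_id,
    true_department_id = if (is.null(true_dept)) dept else true_dept,
    visited_department_id = dept,
    doctor_id = doctor,
    rating = as.integer(rating),
    tokens = list(tokens)
  )
}

toy_visits <- function(rows) dplyr::bind_rows(rows)

# random small visit set over an abstract vocabulary
random_visits <- function(n, vocab_size = 12, n_dept = 2, max_count = 4) {
  vocab <- sprintf("t%02d", seq_len(vocab_size))
  rows <- lapply(seq_len(n), function(i) {
    n_terms <- sample(1:min(5, vocab_size), 1)
    terms <- sample(vocab, n_terms)
    visit_row(sprintf("p%03d", i),
              stats::setNames(sample(1:max_count, n_terms, TRUE), terms),
              dept = sample(seq_len(n_dept), 1),
              doctor = sprintf("d%02d", sample(1:5, 1)),
              rating = sample(1:5, 1))
  })
  toy_visits(rows)
}

# --- oracles ---------------------------------------------------------------

# direct evaluation of TF, IDF and the patient TF-IDF vector with loops
oracle_patient_vectors <- function(visits) {
  vocab <- sort(unique(unlist(lapply(visits$tokens, names))))
  N <- nrow(visits)
  D <- sapply(vocab, function(term) {
    sum(sapply(visits$tokens, function(tc) term %in% names(tc)))
  })
  X <- matrix(0, N, length(vocab), dimnames = list(visits$patient_id, vocab))
  for (j in seq_len(N)) {
    tc <- visits$tokens[[j]]
    total <- sum(tc)
    for (term in names(tc)) {
      tf <- tc[[term]] / total
      idf <- log(N / D[[term]] + 1)
      X[j, term] <- tf * idf
    }
  }
  X
}

# score-weighted department profile, direct double loop
oracle_department_profile <- function(dept_visits, all_visits) {
  vocab <- sort(unique(unlist(lapply(all_visits$tokens, names))))
  N <- nrow(all_visits)
  D <- sapply(vocab, function(term) {
    sum(sapply(all_visits$tokens, function(tc) term %in% names(tc)))
  })
  num <- stats::setNames(numeric(length(vocab)), vocab)
  denom <- 0
  for (j in seq_len(nrow(dept_visits))) {
    tc <- dept_visits$tokens[[j]]
    r <- dept_visits$rating[[j]]
    denom <- denom + sum(tc) * r
    for (term in names(tc)) num[[term]] <- num[[term]] + tc[[term]] * r
  }
  sapply(vocab, function(term) (num[[term]] / denom) * log(N / D[[term]] + 1))
}

oracle_modified_cosine <- function(u, v) {
  uc <- u - sum(u) / length(u)
  vc <- v - sum(v) / length(v)
  den <- sqrt(sum(uc^2)) * sqrt(sum(vc^2))
  if (den == 0) return(0)
  sum(uc * vc) / den
}

oracle_trust_distance <- function(u, v) {
  su <- names(u)[u > 1e-9]
  sv <- names(v)[v > 1e-9]
  common <- intersect(su, sv)
  if (length(common) == 0) return(Inf)
  t_uv <- sqrt(length(union(su, sv))) / length(common)
  s <- 0
  for (term in common) s <- s + (u[[term]] - v[[term]])^2
  t_uv * sqrt(s)
}

# triple-loop valid 1-D convolution
oracle_conv <- function(x, kernels) {
  n <- dim(x)[1]; t_len <- dim(x)[2]; d <- dim(x)[3]
  hmax <- max(sapply(kernels, function(k) dim(k$weights)[1]))
  L <- t_len - hmax + 1
  csum <- sum(sapply(kernels, function(k) dim(k$weights)[3]))
  out <- array(0, c(n, L, csum))
  ch <- 0
  for (k in kernels) {
    h <- dim(k$weights)[1]; cks <- dim(k$weights)[3]
    for (cc in seq_len(cks)) {
      for (i in seq_len(n)) for (s in seq_len(L)) {
        acc <- 0
        for (u in seq_len(h)) for (j in seq_len(d)) {
          acc <- acc + k$weights[u, j, cc] * x[i, s + u - 1, j]
        }
        out[i, s, ch + cc] <- acc + k$bias[cc]
      }
    }
    ch <- ch + cks
  }
  out
}
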