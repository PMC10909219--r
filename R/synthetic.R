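# Synthetic clinic simulator. Generates departments with distinct symptom
# distributions, planted within-department patient subclusters, doctors with
# fixed quality offsets, and ratings that are higher when the visited
# department matches the patient's true condition. Every downstream stage of
# the pipeline is testable against the planted ground truth.

#' Configuration of a synthetic clinic
#'
#' @param n_departments Number of departments (>= 1).
#' @param vocab_size Number of abstract symptom terms (`"s0001"`, ...);
#'   must be at least `n_departments`.
#' @param n_patients Number of patients; one visit each.
#' @param doctors_per_department Doctors staffing each department.
#' @param complaint_length_mean Expected token count of a complaint
#'   (length is `1 + Poisson(mean - 1)`, so every complaint is non-empty).
#' @param dept_concentration Dirichlet concentration of each subcluster's
#'   symptom distribution over its vocabulary sub-block. Low values give
#'   spiky, well-separated distributions; in the limit each subcluster is
#'   dominated by a single diagnostic token.
#' @param clusters_per_department Planted subclusters per department.
#' @param match_bonus Additive rating uplift when the visited department
#'   equals the patient's true department.
#' @param rating_noise_sd Standard deviation of the rating noise.
#' @param rating_sparsity Fraction in `(0, 1]` of the visited department's
#'   doctors each patient rates (at least one).
#' @param mismatch_rate Probability a visit is routed to a wrong department,
#'   emulating historical triage errors (these visits earn no match bonus).
#' @param seed Integer RNG seed; the whole clinic is a deterministic
#'   function of the configuration.
#' @return A validated object of class `clinic_config`.
#' @export
clinic_config <- function(n_departments = 5, vocab_size = 200, n_patients = 500,
                          doctors_per_department = 8, complaint_length_mean = 8,
                          dept_concentration = 0.05, clusters_per_department = 4,
                          match_bonus = 1.5, rating_noise_sd = 0.5,
                          rating_sparsity = 0.3, mismatch_rate = 0.1, seed = 1) {
  cfg <- list(
    n_departments = n_departments, vocab_size = vocab_size,
    n_patients = n_patients, doctors_per_department = doctors_per_department,
    complaint_length_mean = complaint_length_mean,
    dept_concentration = dept_concentration,
    clusters_per_department = clusters_per_department,
    match_bonus = match_bonus, rating_noise_sd = rating_noise_sd,
    rating_sparsity = rating_sparsity, mismatch_rate = mismatch_rate,
    seed = seed
  )
  for (f in c("n_departments", "vocab_size", "n_patients",
              "doctors_per_department", "clusters_per_department")) {
    if (!is_count(cfg[[f]])) {
      abort_config(paste0("`", f, "` must be a single integer >= 1"), field = f)
    }
  }
  if (cfg$vocab_size < cfg$n_departments) {
    abort_config("`vocab_size` must be at least `n_departments`", field = "vocab_size")
  }
  if (cfg$vocab_size < cfg$n_departments * cfg$clusters_per_department) {
    abort_config(
      "`vocab_size` must allow a distinct sub-block per (department, subcluster)",
      field = "vocab_size"
    )
  }
  if (!is_scalar_number(cfg$complaint_length_mean) || cfg$complaint_length_mean <= 0) {
    abort_config("`complaint_length_mean` must be a positive number",
                 field = "complaint_length_mean")
  }
  if (!is_scalar_number(cfg$dept_concentration) || cfg$dept_concentration <= 0) {
    abort_config("`dept_concentration` must be a positive number",
                 field = "dept_concentration")
  }
  if (!is_scalar_number(cfg$match_bonus)) {
    abort_config("`match_bonus` must be a finite number", field = "match_bonus")
  }
  if (!is_scalar_number(cfg$rating_noise_sd) || cfg$rating_noise_sd < 0) {
    abort_config("`rating_noise_sd` must be a non-negative number",
                 field = "rating_noise_sd")
  }
  if (!is_scalar_number(cfg$rating_sparsity) || cfg$rating_sparsity <= 0 ||
      cfg$rating_sparsity > 1) {
    abort_config("`rating_sparsity` must lie in (0, 1]", field = "rating_sparsity")
  }
  if (!is_scalar_number(cfg$mismatch_rate) || cfg$mismatch_rate < 0 ||
      cfg$mismatch_rate >= 1) {
    abort_config("`mismatch_rate` must lie in [0, 1)", field = "mismatch_rate")
  }
  if (!is_count(cfg$seed, min = 0L)) {
    abort_config("`seed` must be a single non-negative integer", field = "seed")
  }
  structure(cfg, class = "clinic_config")
}

# Dirichlet draw; in the small-concentration limit the mass collapses onto a
# single uniformly chosen coordinate (the analytic limit of the Dirichlet).
rdirichlet1 <- function(len, concentration) {
  g <- stats::rgamma(len, shape = concentration)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    g <- numeric(len)
    g[sample.int(len, 1L)] <- 1
    return(g)
  }
  g / s
}

#' Generate a synthetic clinic
#'
#' Draws, in documented order from one RNG stream seeded by `config$seed`:
#' (1) one symptom distribution per (department, subcluster) — a 90/10
#' mixture of a Dirichlet over the subcluster's private vocabulary sub-block
#' and a uniform background over the full vocabulary; (2) doctor quality
#' offsets `Normal(0, 0.5)` fixed per doctor; (3) per patient: true
#' department (uniform), subcluster (uniform), complaint length, multinomial
#' token counts, visited department (wrong with probability
#' `mismatch_rate`), the subset of that department's doctors they rate, and
#' integer ratings
#' `clip(round(3 + match_bonus * matched + quality + noise), 1, 5)`.
#'
#' @param config A [clinic_config()].
#' @return An object of class `clinic`: list with tibbles `visits` (one row
#'   per patient: ids, true/visited department, doctor, rating, token
#'   counts), `ratings` (patient, doctor, rating triples), `doctors`
#'   (id, department, quality), `truth` (patient, true department, planted
#'   subcluster), plus `vocabulary` and `config`.
#' @export
#' @examples
#' clinic <- generate_clinic(clinic_config(n_patients = 50, seed = 1))
#' clinic$visits
generate_clinic <- function(config) {
  if (!inherits(config, "clinic_config")) {
    abort_config("`config` must be created by clinic_config()", field = "config")
  }
  with_local_seed(config$seed, {
    V <- config$vocab_size
    nd <- config$n_departments
    nc <- config$clusters_per_department
    vocabulary <- sprintf("s%04d", seq_len(V))

    # contiguous department blocks, then subcluster sub-blocks within each
    block_of <- sort(rep_len(seq_len(nd), V))
    cluster_dist <- vector("list", nd)
    for (d in seq_len(nd)) {
      block_idx <- which(block_of == d)
      sub_of <- sort(rep_len(seq_len(nc), length(block_idx)))
      # subclusters are distinct mixtures within the department's block:
      # 90% private sub-block signal plus a 10% clinic-wide uniform
      # background that makes complaints overlap across subclusters
      cluster_dist[[d]] <- lapply(seq_len(nc), function(cc) {
        sub_idx <- block_idx[sub_of == cc]
        p <- rep(0.1 / V, V)
        p[sub_idx] <- p[sub_idx] + 0.9 * rdirichlet1(length(sub_idx), config$dept_concentration)
        p
      })
    }

    doctors <- tibble::tibble(
      doctor_id = sprintf("doc%04d", seq_len(nd * config$doctors_per_department)),
      department_id = rep(seq_len(nd), each = config$doctors_per_department),
      quality = stats::rnorm(nd * config$doctors_per_department, 0, 0.5)
    )

    n <- config$n_patients
    patient_id <- sprintf("p%05d", seq_len(n))
    true_dept <- sample.int(nd, n, replace = TRUE)
    subcluster <- sample.int(nc, n, replace = TRUE)
    lens <- 1L + stats::rpois(n, max(config$complaint_length_mean - 1, 0))
    tokens <- vector("list", n)
    for (i in seq_len(n)) {
      p <- cluster_dist[[true_dept[i]]][[subcluster[i]]]
      cnt <- as.integer(stats::rmultinom(1, lens[i], p))
      nz <- cnt > 0L
      tokens[[i]] <- stats::setNames(cnt[nz], vocabulary[nz])
    }

    mism <- stats::runif(n) < config$mismatch_rate & nd > 1L
    visited <- true_dept
    for (i in which(mism)) {
      visited[i] <- sample(setdiff(seq_len(nd), true_dept[i]), 1L)
    }

    n_rated <- max(1L, round(config$rating_sparsity * config$doctors_per_department))
    rated <- vector("list", n)
    for (i in seq_len(n)) {
      pool <- doctors$doctor_id[doctors$department_id == visited[i]]
      rated[[i]] <- sample(pool, min(n_rated, length(pool)))
    }

    quality_of <- stats::setNames(doctors$quality, doctors$doctor_id)
    ratings <- tibble::tibble(
      patient_id = rep(patient_id, lengths(rated)),
      doctor_id = unlist(rated, use.names = FALSE)
    )
    matched <- rep(visited == true_dept, lengths(rated))
    noise <- stats::rnorm(nrow(ratings), 0, config$rating_noise_sd)
    raw <- 3 + config$match_bonus * matched + quality_of[ratings$doctor_id] + noise
    ratings$rating <- as.integer(clip(round(raw), 1L, 5L))

    first_doc <- vapply(rated, `[[`, character(1), 1L)
    first_rating <- ratings$rating[match(paste(patient_id, first_doc),
                                         paste(ratings$patient_id, ratings$doctor_id))]
    visits <- tibble::tibble(
      patient_id = patient_id,
      true_department_id = true_dept,
      visited_department_id = visited,
      doctor_id = first_doc,
      rating = first_rating,
      tokens = tokens
    )

    structure(
      list(
        visits = visits,
        ratings = ratings,
        doctors = doctors,
        truth = tibble::tibble(patient_id = patient_id,
                               true_department_id = true_dept,
                               subcluster = subcluster),
        vocabulary = vocabulary,
        config = config
      ),
      class = "clinic"
    )
  })
}

#' @export
print.clinic <- function(x, ...) {
  cat("<clinic>\n")
  cat("  departments:", x$config$n_departments,
      " patients:", nrow(x$visits),
      " doctors:", nrow(x$doctors),
      " ratings:", nrow(x$ratings), "\n")
  invisible(x)
}

#' Average between-department separation of a clinic
#'
#' Mean pairwise Euclidean distance between the departments' empirical
#' term-frequency profiles (computed from true-department visits). Used to
#' check that lowering `dept_concentration` produces spikier, more separated
#' departments.
#'
#' @param clinic A [generate_clinic()] result.
#' @return Non-negative scalar.
#' @export
department_separation <- function(clinic) {
  stopifnot(inherits(clinic, "clinic"))
  V <- length(clinic$vocabulary)
  depts <- sort(unique(clinic$visits$true_department_id))
  prof <- t(vapply(depts, function(d) {
    rows <- clinic$visits$tokens[clinic$visits$true_department_id == d]
    counts <- stats::setNames(numeric(V), clinic$vocabulary)
    for (tc in rows) counts[names(tc)] <- counts[names(tc)] + tc
    counts / sum(counts)
  }, numeric(V)))
  if (length(depts) < 2L) return(0)
  mean(stats::dist(prof))
}
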