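# Pipeline configuration and the end-to-end driver used by the command-line
# front end: generate (or read) a corpus, fit the model, triage, evaluate,
# and persist artifacts with a manifest.

pipeline_defaults <- function() {
  list(
    corpus = "",            # path to a visit file; empty -> synthetic clinic
    ratings = "",           # path to rating triples; empty -> synthetic
    out_dir = "triagerec-out",
    similarity = "modified",
    trust_mode = "as_printed",
    k = 4L,
    k_range = "",           # e.g. "2:10"; overrides k when set
    neighbors = 10L,
    rank = 8L,
    lambda = 0.1,
    sweeps = 10L,
    top_n = 5L,
    test_fraction = 0.2,
    seed = 1L,
    # synthetic clinic knobs (used when no corpus path is given)
    n_departments = 5L, vocab_size = 200L, n_patients = 500L,
    doctors_per_department = 8L, complaint_length_mean = 8,
    dept_concentration = 0.05, clusters_per_department = 4L,
    match_bonus = 1.5, rating_noise_sd = 0.5, rating_sparsity = 0.3,
    mismatch_rate = 0.1
  )
}

validate_pipeline_config <- function(cfg) {
  for (f in c("k", "neighbors", "rank", "sweeps", "top_n", "n_departments",
              "vocab_size", "n_patients", "doctors_per_department",
              "clusters_per_department")) {
    if (!is_count(cfg[[f]])) {
      abort_config(paste0("`", f, "` must be a positive integer"), field = f)
    }
  }
  if (!is_scalar_number(cfg$lambda) || cfg$lambda <= 0) {
    abort_config("`lambda` must be a positive number", field = "lambda")
  }
  if (!is_scalar_number(cfg$test_fraction) || cfg$test_fraction <= 0 ||
      cfg$test_fraction >= 1) {
    abort_config("`test_fraction` must lie in (0, 1)", field = "test_fraction")
  }
  if (!cfg$similarity %in% c("modified", "plain", "pearson")) {
    abort_config("`similarity` must be one of modified, plain, pearson",
                 field = "similarity")
  }
  if (!cfg$trust_mode %in% c("as_printed", "jaccard_inverse")) {
    abort_config("`trust_mode` must be as_printed or jaccard_inverse",
                 field = "trust_mode")
  }
  if (nzchar(cfg$k_range) && !grepl("^[0-9]+:[0-9]+$", cfg$k_range)) {
    abort_config("`k_range` must have the form 'lo:hi'", field = "k_range")
  }
  cfg
}

#' Load / save a flat key-value pipeline configuration
#'
#' The file format is one `key = value` pair per line (`#` comments
#' allowed). Unknown keys are rejected with the list of valid keys;
#' omitted keys take their documented defaults.
#'
#' @param path Configuration file path.
#' @return A validated named list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  defaults <- pipeline_defaults()
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) abort_config(paste0("malformed config line: '", ln, "'"))
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(defaults)) {
      abort_config(paste0("unknown config key '", key, "'; valid keys: ",
                          paste(names(defaults), collapse = ", ")), field = key)
    }
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.integer(proto)) {
      iv <- suppressWarnings(as.integer(val))
      if (is.na(iv)) abort_config(paste0("`", key, "` must be an integer"), field = key)
      iv
    } else if (is.numeric(proto)) {
      nv <- suppressWarnings(as.numeric(val))
      if (is.na(nv)) abort_config(paste0("`", key, "` must be numeric"), field = key)
      nv
    } else {
      val
    }
  }
  structure(validate_pipeline_config(cfg), class = "pipeline_config")
}

#' @rdname load_config
#' @param config A `pipeline_config` (or plain named list using the same keys).
#' @export
save_config <- function(config, path) {
  defaults <- pipeline_defaults()
  cfg <- utils::modifyList(defaults, config[names(config) %in% names(defaults)])
  writeLines(
    vapply(names(cfg), function(k) paste0(k, " = ", format(cfg[[k]], scientific = FALSE)),
           character(1)),
    path
  )
  invisible(path)
}

#' Default pipeline configuration
#' @return A `pipeline_config` populated with the documented defaults.
#' @export
default_config <- function() {
  structure(validate_pipeline_config(pipeline_defaults()), class = "pipeline_config")
}

#' Run the full pipeline and persist its artifacts
#'
#' Generates (or reads) a corpus, fits the triage-and-recommendation model,
#' evaluates triage accuracy and the before/after-clustering comparison,
#' and writes everything under `config$out_dir`: the corpus and rating
#' files, department profiles (JSON), the evaluation report (CSV) and a
#' JSON manifest with the effective parameters, derived seeds and MD5
#' hashes of every artifact. Rerunning with the same configuration
#' reproduces identical artifacts.
#'
#' @param config A `pipeline_config` from [load_config()] or
#'   [default_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(
    utils::modifyList(pipeline_defaults(), unclass(config))
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (nzchar(cfg$corpus)) {
    visits <- read_corpus(cfg$corpus)
    if (!nzchar(cfg$ratings)) {
      abort_config("`ratings` path is required when `corpus` is given",
                   field = "ratings")
    }
    ratings <- read_ratings(cfg$ratings)
    clinic <- list(visits = visits, ratings = ratings)
  } else {
    gen_cfg <- clinic_config(
      n_departments = cfg$n_departments, vocab_size = cfg$vocab_size,
      n_patients = cfg$n_patients,
      doctors_per_department = cfg$doctors_per_department,
      complaint_length_mean = cfg$complaint_length_mean,
      dept_concentration = cfg$dept_concentration,
      clusters_per_department = cfg$clusters_per_department,
      match_bonus = cfg$match_bonus, rating_noise_sd = cfg$rating_noise_sd,
      rating_sparsity = cfg$rating_sparsity, mismatch_rate = cfg$mismatch_rate,
      seed = split_seed(cfg$seed, "generate")
    )
    clinic <- generate_clinic(gen_cfg)
  }

  corpus_path <- file.path(cfg$out_dir, "corpus.txt")
  ratings_path <- file.path(cfg$out_dir, "ratings.csv")
  write_corpus(clinic$visits, corpus_path)
  write_ratings(clinic$ratings, ratings_path)

  k_range <- NULL
  if (nzchar(cfg$k_range)) {
    parts <- as.integer(strsplit(cfg$k_range, ":", fixed = TRUE)[[1]])
    k_range <- seq(parts[1], parts[2])
  }
  model <- clinic_model(clinic$visits, clinic$ratings, k = cfg$k,
                        k_range = k_range, trust_mode = cfg$trust_mode,
                        seed = cfg$seed)

  profiles_path <- file.path(cfg$out_dir, "profiles.json")
  write_vector_json(model$profiles, profiles_path)

  tri <- triage(model$corpus, model$profiles, similarity = cfg$similarity, top = 1)
  triage_path <- file.path(cfg$out_dir, "triage.csv")
  utils::write.csv(
    dplyr::mutate(tri, similarity = round(.data$similarity, 6)),
    triage_path, row.names = FALSE, quote = FALSE
  )
  tri_acc <- if ("true_department_id" %in% names(clinic$visits)) {
    triage_accuracy(tri, clinic$visits[c("patient_id", "true_department_id")])
  } else {
    NA_real_
  }

  report <- before_after_comparison(
    clinic, seed = cfg$seed, test_fraction = cfg$test_fraction,
    n_top = cfg$top_n, m = cfg$neighbors, k = cfg$k, rank = cfg$rank,
    lambda = cfg$lambda, sweeps = cfg$sweeps
  )
  report_path <- file.path(cfg$out_dir, "eval_report.csv")
  write_eval_report(report, report_path)

  artifacts <- c(corpus_path, ratings_path, profiles_path, triage_path, report_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("triagerec")),
    parameters = cfg,
    seeds = list(
      master = cfg$seed,
      generate = split_seed(cfg$seed, "generate"),
      split = split_seed(cfg$seed, "split"),
      clustering = split_seed(cfg$seed, "clustering"),
      als = split_seed(cfg$seed, "als")
    ),
    triage_accuracy = tri_acc,
    mean_accuracy_gain = attr(report, "mean_accuracy_gain"),
    mean_recall_gain = attr(report, "mean_recall_gain"),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(artifacts)),
                                        basename(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
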