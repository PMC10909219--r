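# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster model into per-patient assignments
#'
#' @param x A [kmeans_trust()] model.
#' @param ... Unused.
#' @return Tibble `patient_id`, `cluster`, `fallback`.
#' @exportS3Method generics::tidy
tidy.cluster_model <- function(x, ...) {
  tibble::tibble(
    patient_id = names(x$assignments),
    cluster = as.integer(x$assignments),
    fallback = unname(x$fallback)
  )
}

#' @rdname tidy.cluster_model
#' @exportS3Method generics::glance
glance.cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$assignments),
    sse = x$sse,
    iterations_run = x$iterations_run,
    seed = x$seed,
    trust_mode = x$trust_mode
  )
}

#' Tidy an ALS factor model into its per-sweep fit path
#'
#' @param x An [als_factorize()] model.
#' @param ... Unused.
#' @return Tibble `sweep`, `rmse` (observed-entry RMSE after each sweep).
#' @exportS3Method generics::tidy
tidy.factor_model <- function(x, ...) {
  tibble::tibble(sweep = seq_along(x$rmse_path), rmse = x$rmse_path)
}

#' @rdname tidy.factor_model
#' @exportS3Method generics::glance
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, lambda = x$lambda, sweeps = x$sweeps,
    rmse = utils::tail(x$rmse_path, 1), seed = x$seed
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report` from [before_after_comparison()].
#' @param ... Unused.
#' @return Tibble with the mean accuracy/recall gains (percentage points)
#'   and the mean candidate-set sizes before and after clustering.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  sizes <- attr(x, "candidate_sizes")
  tibble::tibble(
    mean_accuracy_gain = attr(x, "mean_accuracy_gain"),
    mean_recall_gain = attr(x, "mean_recall_gain"),
    candidates_before = unname(sizes["before"]),
    candidates_after = unname(sizes["after"]),
    n_test = attr(x, "n_test")
  )
}

#' Elbow plot of an SSE curve
#'
#' @param object An [sse_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot: SSE against k with the elbow-selected k marked.
#' @exportS3Method ggplot2::autoplot
autoplot.sse_curve <- function(object, ...) {
  k_star <- tryCatch(elbow_select(object), warning = function(w) NA_integer_)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "sum of squared errors (SSE)")
  if (!is.na(k_star)) {
    p <- p + ggplot2::geom_vline(xintercept = k_star, linetype = "dashed") +
      ggplot2::annotate("text", x = k_star, y = max(object$sse),
                        label = paste0("elbow k = ", k_star),
                        hjust = -0.1, vjust = 1)
  }
  p
}

#' Before/after-clustering comparison plot
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of precision and recall, before vs after clustering,
#'   per algorithm.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = -"algorithm",
    names_to = c("metric", "phase"), names_sep = "_",
    values_to = "rate"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm, y = .data$rate,
                                     fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "rate", fill = "clustering")
}
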