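#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_hline geom_tile
#'   geom_histogram geom_line labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' @export
tidy.vc_pauc_report <- function(x, ...) x$scores

#' @export
glance.vc_pauc_report <- function(x, ...) {
  bind_cols(x$summary, tibble(n_folds = nrow(x$scores), sens_lo = x$sens_lo))
}

#' @export
tidy.vc_dag <- function(x, ...) x$edges

#' @export
glance.vc_dag <- function(x, ...) {
  tibble(nodes = length(x$nodes), edges = nrow(x$edges),
         score = x$score, algorithm = x$algorithm)
}

#' @export
tidy.discrete_bn <- function(x, ...) bn_edges(x)

#' @export
glance.discrete_bn <- function(x, ...) {
  tibble(nodes = length(x$nodes), edges = sum(lengths(x$parents)),
         alpha = x$alpha %||% NA_real_)
}

#' @export
tidy.vc_edge_confidence <- function(x, ...) x$edges

#' @export
glance.vc_edge_confidence <- function(x, ...) {
  tibble(B = x$B, edges = nrow(x$edges))
}

#' @export
tidy.vc_cv <- function(x, ...) x$scores

#' @export
glance.vc_cv <- function(x, ...) {
  tibble(best = x$best,
         best_neg_loglik = x$summary$mean_neg_loglik[1])
}

#' @export
tidy.vc_imputation <- function(x, ...) x$convergence

#' @export
glance.vc_imputation <- function(x, ...) tibble(iterations = x$iterations)

#' @export
glance.vc_cohort <- function(x, ...) {
  tibble(n = nrow(x), accepted = sum(x$.accepted),
         mean_confidence = mean(x$.confidence))
}

#' Boxplot of cross-validated pAUC values
#'
#' One box per cross-validation repeat, with the chance level (0.5) marked.
#'
#' @param object a [pauc_cv()] report.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vc_pauc_report <- function(object, ...) {
  ggplot(object$scores, aes(x = factor(.data$rep), y = .data$pauc)) +
    geom_boxplot(fill = "grey85") +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "firebrick") +
    labs(x = "cross-validation repeat", y = "standardized pAUC",
         title = "Real-vs-virtual discrimination (0.5 = chance)") +
    theme_minimal()
}

#' Heatmap of bootstrap edge frequencies
#'
#' @param object a [bootstrap_edges()] result.
#' @param min_frequency edges below this frequency are dropped from the plot.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vc_edge_confidence <- function(object, min_frequency = 0, ...) {
  d <- filter(object$edges, .data$frequency >= min_frequency)
  ggplot(d, aes(x = .data$to, y = .data$from, fill = .data$frequency)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "child", y = "parent", fill = "frequency",
         title = paste0("Edge stability over ", object$B, " bootstrap replicates")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of virtual-patient confidence scores
#'
#' @param object a `vc_cohort` from [conservative_filter()]/[generate_vc()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vc_cohort <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$.confidence, fill = .data$.accepted)) +
    geom_histogram(bins = 30, boundary = 0) +
    labs(x = "probability of falling into the real-patient distribution",
         y = "virtual patients", fill = "accepted") +
    theme_minimal()
}

#' Imputation convergence trace
#'
#' @param object a [rf_impute()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vc_imputation <- function(object, ...) {
  d <- tidyr::pivot_longer(object$convergence, c("continuous", "categorical"),
                           names_to = "part", values_to = "statistic")
  ggplot(d, aes(x = .data$iteration, y = .data$statistic,
                colour = .data$part)) +
    geom_line() +
    labs(x = "iteration", y = "convergence statistic") +
    theme_minimal()
}
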