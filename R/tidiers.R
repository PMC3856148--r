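#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per node, per pathway, per permutation) as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A netpharm result object.
#' @param ... Unused.
#' @return A tibble.
#' @name netpharm-tidiers
NULL

#' @rdname netpharm-tidiers
#' @exportS3Method generics::tidy
tidy.propagation_result <- function(x, ...) {
  tibble(node = x$node, score = x$score)
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::glance
glance.propagation_result <- function(x, ...) {
  tibble(r = attr(x, "r"), iterations = attr(x, "iterations"),
         residual = attr(x, "residual"), seed_sum = attr(x, "seed_sum"),
         n_nodes = nrow(x), n_dropped_seeds = length(attr(x, "dropped_seeds")))
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) as_tibble(unclass(x))

#' @rdname netpharm-tidiers
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(N = attr(x, "N"), K = attr(x, "K"), alpha = attr(x, "alpha"),
         n_pathways = nrow(x), n_significant = sum(x$significant),
         n_targets_not_in_universe = length(attr(x, "targets_not_in_universe")))
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::tidy
tidy.null_distribution <- function(x, ...) {
  tibble(permutation = seq_along(x$scores), score = x$scores)
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::tidy
tidy.zscore_report <- function(x, ...) {
  tibble(E = x$E, z = x$z, null_mean = x$null$mean, null_sd = x$null$sd,
         n_perm = x$null$n_perm, rng_seed = x$null$rng_seed,
         significant = x$significant)
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::glance
glance.zscore_report <- function(x, ...) tidy.zscore_report(x, ...)

#' @rdname netpharm-tidiers
#' @exportS3Method generics::tidy
tidy.topology_report <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$targeted_by <- vapply(out$targeted_by, paste, "", collapse = ",")
  out
}

#' @rdname netpharm-tidiers
#' @exportS3Method generics::glance
glance.topology_report <- function(x, ...) {
  as_tibble(attr(x, "summary"))
}

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' top propagated nodes, the enrichment volcano of -log10 P against overlap,
#' and the permutation null with the observed score marked.
#'
#' @param object A netpharm result object.
#' @param n_top How many top-scoring nodes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @name netpharm-autoplot
NULL

#' @rdname netpharm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.propagation_result <- function(object, n_top = 25, ...) {
  df <- dplyr::slice_max(tidy(object), .data$score, n = n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score, y = stats::reorder(.data$node, .data$score))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "propagation score", y = NULL,
                  title = sprintf("Top %d nodes by %s effect score",
                                  nrow(df), attr(object, "role") %||% "seed")) +
    ggplot2::theme_minimal()
}

#' @rdname netpharm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "targets in pathway (k)", y = "-log10 P",
                  colour = sprintf("P < %g", attr(object, "alpha")),
                  title = "Pathway enrichment of target set") +
    ggplot2::theme_minimal()
}

#' @rdname netpharm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.zscore_report <- function(object, ...) {
  df <- tidy(object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$E, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "effect score of random target sets", y = "count",
                  title = sprintf("Permutation null (z = %.2f, %d sets)",
                                  object$z, object$null$n_perm)) +
    ggplot2::theme_minimal()
}

#' @rdname netpharm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.topology_report <- function(object, ...) {
  df <- tidy(object)
  df$targeted <- df$n_components_targeting > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$betweenness,
                                   colour = .data$targeted,
                                   shape = .data$is_disease_gene)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "degree", y = "betweenness",
                  title = "Disease-subnetwork centrality",
                  colour = "targeted by formula", shape = "disease gene") +
    ggplot2::theme_minimal()
}
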