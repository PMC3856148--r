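#' Extract the top-scoring disease subnetwork
#'
#' Sorts the propagation scores and keeps the `floor(fraction * n)` highest-
#' scoring nodes (ties broken by score descending then symbol ascending, so
#' the selection is deterministic), then takes the subgraph they induce on
#' the parent network. This is the disease-associated subnetwork on which
#' topology is analysed.
#'
#' @param network A `ppi_network`.
#' @param scores A `propagation_result` on that network (typically from
#'   [disease_effect()]).
#' @param fraction Fraction of nodes to keep, in (0, 1); default 0.03.
#' @param disease_genes Optional disease gene symbols; if given, the count
#'   and percentage retained on the subnetwork are reported.
#' @param drop_zero_scores Exclude zero-score nodes before taking the
#'   fraction.
#'
#' @return A `subnetwork` (a `ppi_network` that may contain isolated
#'   members) with attributes `members`, `selection_fraction`, and — when
#'   `disease_genes` is supplied — `disease_coverage` (list: `n_total`,
#'   `n_on_subnetwork`, `percent`).
#' @export
extract_top_fraction <- function(network, scores, fraction = 0.03,
                                 disease_genes = NULL,
                                 drop_zero_scores = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  if (!identical(scores$node, network$nodes)) {
    abort("scores were not computed on this network")
  }
  pool <- scores
  if (drop_zero_scores) pool <- pool[pool$score > 0, , drop = FALSE]
  n_keep <- floor(fraction * n_nodes(network))
  if (n_keep < 1L || nrow(pool) == 0L) {
    abort("selection empty: fraction too small for this network")
  }
  n_keep <- min(n_keep, nrow(pool))
  ord <- order(-pool$score, pool$node)
  members <- sort(pool$node[ord[seq_len(n_keep)]])
  sub_edges <- network$edges[network$edges$from %in% members &
                               network$edges$to %in% members, , drop = FALSE]
  if (nrow(sub_edges) == 0L) {
    # an edgeless selection is still a valid (degenerate) subnetwork
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(members)
    sub <- structure(list(edges = tibble(from = character(), to = character(),
                                         weight = numeric()),
                          nodes = members, graph = g),
                     class = "ppi_network")
  } else {
    sub <- new_ppi_network(sub_edges, allow_isolates = TRUE, nodes = members)
  }
  class(sub) <- c("subnetwork", class(sub))
  attr(sub, "members") <- members
  attr(sub, "selection_fraction") <- fraction
  if (!is.null(disease_genes)) {
    disease_genes <- unique(toupper(trimws(disease_genes)))
    on_sub <- intersect(disease_genes, members)
    attr(sub, "disease_coverage") <- list(
      n_total = length(disease_genes),
      n_on_subnetwork = length(on_sub),
      percent = 100 * length(on_sub) / length(disease_genes)
    )
  }
  sub
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> top %.3g%% of parent: %d nodes, %d edges\n",
              100 * attr(x, "selection_fraction"), length(x$nodes),
              nrow(x$edges)))
  cov <- attr(x, "disease_coverage")
  if (!is.null(cov)) {
    cat(sprintf("  disease genes retained: %d/%d (%.2f%%)\n",
                cov$n_on_subnetwork, cov$n_total, cov$percent))
  }
  invisible(x)
}

#' Node degrees of a (sub)network
#'
#' Simple-graph degree: the number of connections a node has to other
#' nodes, ignoring weights.
#'
#' @param network A `ppi_network` or `subnetwork`.
#' @return A tibble with columns `node`, `degree`.
#' @export
node_degrees <- function(network) {
  d <- igraph::degree(network$graph, loops = FALSE)
  tibble(node = names(d), degree = as.integer(d)) |>
    dplyr::arrange(.data$node)
}

#' k-core decomposition
#'
#' The coreness of a node is the largest `k` such that it survives the
#' recursive deletion of all nodes of degree `< k` — membership in the
#' maximal subgraph where every vertex keeps at least `k` neighbours.
#' Computed on the unweighted simple graph.
#'
#' @param network A `ppi_network` or `subnetwork`.
#' @return A tibble with columns `node`, `coreness`.
#' @export
kcore_decomposition <- function(network) {
  cs <- igraph::coreness(network$graph)
  tibble(node = names(cs), coreness = as.integer(cs)) |>
    dplyr::arrange(.data$node)
}

#' Betweenness centrality
#'
#' Exact betweenness `g(v) = sum_{s != v != t} sigma_st(v) / sigma_st` on
#' the unweighted simple graph over unordered source-target pairs; pairs in
#' different components contribute zero. Normalized (default) by
#' `(n - 1)(n - 2) / 2`, the number of pairs a node could lie between.
#'
#' @param network A `ppi_network` or `subnetwork`.
#' @param normalized Scale into \[0, 1\]; default `TRUE`.
#' @return A tibble with columns `node`, `betweenness`.
#' @export
betweenness_centrality <- function(network, normalized = TRUE) {
  g <- network$graph
  # weights = NA: shortest paths are hop counts, not weighted distances
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  n <- igraph::vcount(g)
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    b <- if (denom > 0) b / denom else b * 0
  }
  tibble(node = names(b), betweenness = as.numeric(b)) |>
    dplyr::arrange(.data$node)
}

#' Per-node topology report with target annotation
#'
#' Joins degree, betweenness and coreness with disease-gene membership and
#' the list of drugs/components targeting each node, and summarises how
#' central the targeted nodes are: the fraction of target nodes with degree
#' above the subnetwork mean, betweenness above the mean, and coreness equal
#' to the maximum core index.
#'
#' @param network A `ppi_network` or `subnetwork`.
#' @param disease_genes Character vector of disease gene symbols.
#' @param drug_table Drug-target tibble ([drug_target_table()]); only rows
#'   whose target is on the network are used. May be `NULL`.
#'
#' @return A `topology_report` tibble with columns `node`, `degree`,
#'   `betweenness`, `coreness`, `is_disease_gene`, `targeted_by` (list
#'   column) and `n_components_targeting`, sorted by degree descending. The
#'   `"summary"` attribute holds the mean degree, mean betweenness, max
#'   coreness and the target-centrality fractions (`NA` when no target is
#'   on the network).
#' @export
topology_report <- function(network, disease_genes = character(),
                            drug_table = NULL) {
  disease_genes <- unique(toupper(trimws(disease_genes)))
  rep <- node_degrees(network) |>
    dplyr::left_join(betweenness_centrality(network), by = "node") |>
    dplyr::left_join(kcore_decomposition(network), by = "node") |>
    dplyr::mutate(is_disease_gene = .data$node %in% disease_genes)
  if (!is.null(drug_table) && nrow(drug_table) > 0L) {
    by_target <- drug_table |>
      dplyr::filter(.data$target %in% rep$node) |>
      dplyr::group_by(.data$target) |>
      dplyr::summarise(targeted_by = list(sort(unique(.data$drug_id))),
                       .groups = "drop")
    rep <- dplyr::left_join(rep, by_target, by = c(node = "target"))
    rep$targeted_by[vapply(rep$targeted_by, is.null, TRUE)] <- list(character(0))
  } else {
    rep$targeted_by <- replicate(nrow(rep), character(0), simplify = FALSE)
  }
  rep$n_components_targeting <- lengths(rep$targeted_by)
  rep <- dplyr::arrange(rep, dplyr::desc(.data$degree), .data$node)

  mean_deg <- mean(rep$degree)
  mean_btw <- mean(rep$betweenness)
  max_core <- max(rep$coreness)
  tgt <- rep[rep$n_components_targeting > 0, , drop = FALSE]
  summary <- list(
    mean_degree = mean_deg, mean_betweenness = mean_btw,
    max_coreness = max_core, n_targets_on_network = nrow(tgt),
    frac_targets_degree_above_mean =
      if (nrow(tgt)) mean(tgt$degree > mean_deg) else NA_real_,
    frac_targets_betweenness_above_mean =
      if (nrow(tgt)) mean(tgt$betweenness > mean_btw) else NA_real_,
    frac_targets_in_max_core =
      if (nrow(tgt)) mean(tgt$coreness == max_core) else NA_real_
  )
  structure(rep, summary = summary,
            class = c("topology_report", class(tibble())))
}

#' @export
print.topology_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<topology_report> mean degree %.2f, mean betweenness %.4g, max k-core %d\n",
              s$mean_degree, s$mean_betweenness, s$max_coreness))
  if (!is.na(s$frac_targets_degree_above_mean)) {
    cat(sprintf("  targets: %d on network; %.0f%% above mean degree, %.0f%% in max core\n",
                s$n_targets_on_network,
                100 * s$frac_targets_degree_above_mean,
                100 * s$frac_targets_in_max_core))
  }
  NextMethod()
}

#' Write a topology report as TSV
#' @param report A `topology_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(report, path) {
  df <- as.data.frame(report[, c("node", "degree", "betweenness", "coreness",
                                 "is_disease_gene")])
  df$betweenness <- format_num(df$betweenness)
  df$targeted_by <- vapply(report$targeted_by, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
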