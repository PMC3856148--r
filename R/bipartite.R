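#' Build a drug-target bipartite network
#'
#' Two disjoint node sets — drugs and the proteins they target — with a link
#' wherever a protein is targeted by a drug. Internally drug and protein
#' identifiers live in separate namespaces (`drug:`, `prot:`) so a drug name
#' colliding with a gene symbol can never merge the two modes.
#'
#' @param table A drug-target tibble (columns `drug_id`, `drug_class`,
#'   `target`), e.g. from [read_drug_targets()] or [drug_target_table()].
#'
#' @return A `bipartite_net` with elements `drugs` (tibble `drug_id`,
#'   `drug_class`), `targets` (character) and `links` (tibble `drug_id`,
#'   `target`).
#' @export
#' @examples
#' tb <- drug_target_table(
#'   c("etanercept", "celecoxib"), c("biological", "NSAID"), c("TNF", "PTGS2")
#' )
#' build_bipartite(tb)
build_bipartite <- function(table) {
  if (is.null(table) || nrow(table) == 0L) {
    abort("empty drug-target table", class = "netpharm_empty_table")
  }
  drugs <- dplyr::distinct(table, .data$drug_id, .data$drug_class)
  if (anyDuplicated(drugs$drug_id)) {
    abort("a drug_id appears with more than one drug_class")
  }
  links <- dplyr::distinct(table, .data$drug_id, .data$target)
  structure(list(
    drugs = dplyr::arrange(drugs, .data$drug_id),
    targets = sort(unique(links$target)),
    links = dplyr::arrange(links, .data$drug_id, .data$target)
  ), class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("<bipartite_net> %d drugs, %d targets, %d links\n",
              nrow(x$drugs), length(x$targets), nrow(x$links)))
  invisible(x)
}

#' Target overlap between a formula and each drug class
#'
#' For each drug class in the bipartite network, intersects the formula's
#' target set with the union of that class's targets — the map of which
#' established drug classes the multi-component formula shares pharmacology
#' with.
#'
#' @param formula_targets Character vector of the formula's target symbols.
#' @param net A [build_bipartite()] result.
#'
#' @return A tibble with columns `drug_class`, `shared` (list column of
#'   shared symbols) and `n_shared`, sorted by class. The `"overall"`
#'   attribute holds the union of all shared symbols and the
#'   `"n_classes_hit"` attribute the number of classes with nonempty
#'   overlap.
#' @export
shared_targets <- function(formula_targets, net) {
  formula_targets <- unique(toupper(trimws(formula_targets)))
  by_class <- net$links |>
    dplyr::left_join(net$drugs, by = "drug_id") |>
    dplyr::group_by(.data$drug_class) |>
    dplyr::summarise(
      shared = list(sort(intersect(formula_targets, unique(.data$target)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_shared = lengths(.data$shared)) |>
    dplyr::arrange(.data$drug_class)
  structure(by_class,
            overall = sort(unique(unlist(by_class$shared))),
            n_classes_hit = sum(by_class$n_shared > 0),
            class = c("shared_target_report", class(by_class)))
}

#' @export
print.shared_target_report <- function(x, ...) {
  cat(sprintf("Shared targets with %d drug class(es): %s\n",
              attr(x, "n_classes_hit"),
              paste(attr(x, "overall"), collapse = ", ")))
  NextMethod()
}

#' Write the bipartite network for generic graph viewers
#'
#' Writes an edge TSV (`source`, `target`) and a node-attribute TSV (`id`,
#' `kind`, `class`), with drug and protein identifiers prefixed `drug:` /
#' `prot:` to keep the two modes disjoint.
#'
#' @param net A `bipartite_net`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bipartite <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- data.frame(
    source = paste0("drug:", net$links$drug_id),
    target = paste0("prot:", net$links$target)
  )
  nodes <- rbind(
    data.frame(id = paste0("drug:", net$drugs$drug_id), kind = "drug",
               class = net$drugs$drug_class),
    data.frame(id = paste0("prot:", net$targets), kind = "protein",
               class = "")
  )
  utils::write.table(edges, file.path(dir, "bipartite_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nodes, file.path(dir, "bipartite_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
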