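#' Weighted interactome objects
#'
#' A `ppi_network` is an undirected, simple, weighted graph over gene/protein
#' symbols: no self-loops, no duplicate edges, every weight in (0, 1], and no
#' isolated nodes. It is the substrate for random-walk propagation and for
#' topological analysis. Internally it stores a canonical edge tibble
#' (`from < to`, sorted) together with an [igraph::igraph] view.
#'
#' @param edges A data frame with columns `from`, `to`, `weight`.
#' @param allow_isolates Keep nodes of degree zero (used for induced
#'   subnetworks, where isolated members are meaningful).
#' @param nodes Optional explicit node set (superset of edge endpoints);
#'   only honoured when `allow_isolates = TRUE`.
#'
#' @return A `ppi_network` object.
#' @keywords internal
new_ppi_network <- function(edges, allow_isolates = FALSE, nodes = NULL) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- tibble(
    from = toupper(as.character(pmin(edges$from, edges$to))),
    to = toupper(as.character(pmax(edges$from, edges$to))),
    weight = as.numeric(edges$weight)
  )
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  # conflicting duplicate weights resolve to the maximum (confidence bound)
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  if (nrow(edges) == 0L) {
    abort("network has no edges", class = "netpharm_empty_network")
  }
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    abort("edge weights must lie in (0, 1]", class = "netpharm_bad_weight")
  }
  node_set <- sort(unique(c(edges$from, edges$to)))
  if (allow_isolates && !is.null(nodes)) {
    node_set <- sort(unique(c(node_set, toupper(nodes))))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = node_set)
  structure(
    list(edges = edges, nodes = node_set, graph = g),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  weight range: [%.3g, %.3g]\n",
              min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.ppi_network <- function(x, ...) x$edges

#' Number of nodes and edges of a network
#' @param network A `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Read a STRING-style weighted edge list
#'
#' Parses a tab- or whitespace-separated file with at least three columns
#' (symbol A, symbol B, interaction score). A header line is detected by a
#' non-numeric third field and skipped. Scores are divided by `weight_scale`
#' (1000 for raw STRING combined scores, 1 for scores already in \[0, 1\]),
#' and the scaled weight must fall in (0, 1\].
#'
#' @param path Path to the edge-list file.
#' @param weight_scale Positive divisor applied to the score column.
#'
#' @return A tibble with columns `from`, `to`, `weight`; symbols are
#'   uppercased and stripped of surrounding whitespace. This is the raw edge
#'   list: pass it to [build_network()] to obtain an analysis-ready
#'   `ppi_network`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("TNF\tIL6\t900", "IL6\tIL1B\t850"), f)
#' read_edge_list(f, weight_scale = 1000)
read_edge_list <- function(path, weight_scale = 1) {
  stopifnot(is.numeric(weight_scale), weight_scale > 0)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort("empty edge-list file")
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  first <- fields[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  if (has_header) {
    fields <- fields[-1L]
    idx <- idx[-1L]
  }
  if (length(fields) == 0L) abort("edge-list file contains a header but no data rows")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("malformed edge-list row at line %d: expected >= 3 columns, got %d",
                  idx[which(nf < 3L)[1L]], nf[which(nf < 3L)[1L]]))
  }
  a <- toupper(trimws(vapply(fields, `[`, "", 1L)))
  b <- toupper(trimws(vapply(fields, `[`, "", 2L)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(score)) {
    abort(sprintf("non-numeric score at line %d", idx[which(is.na(score))[1L]]))
  }
  w <- score / weight_scale
  bad <- w <= 0 | w > 1
  if (any(bad)) {
    abort(sprintf("weight out of range (0, 1] at line %d: %g",
                  idx[which(bad)[1L]], w[which(bad)[1L]]))
  }
  tibble(from = a, to = b, weight = w)
}

#' Build the analysis-ready weighted network
#'
#' Keeps every interaction at or above the high-confidence threshold, then
#' rescues focus genes (disease genes and drug targets) that fall below it:
#' for each focus gene present in the raw edge list but absent from the
#' high-confidence subnetwork, its incident interactions with the highest
#' sub-threshold weight are added (all ties at that weight are kept).
#' Self-loops are dropped; duplicate edges keep their maximum weight;
#' isolated nodes are removed so that the transition operator of the random
#' walk has no zero columns.
#'
#' @param edges Raw edge tibble from [read_edge_list()] (columns `from`,
#'   `to`, `weight`).
#' @param focus_genes Character vector of symbols that must be retained if
#'   at all present in the raw edge list (typically the union of disease
#'   genes and all drug/component targets).
#' @param high_conf Confidence threshold in (0, 1]; default 0.9.
#'
#' @return A `ppi_network`. Focus genes with no usable raw interactions are
#'   recorded in the `"unmapped"` attribute.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   from = c("A", "C", "C", "C"), to = c("B", "A", "B", "D"),
#'   weight = c(0.95, 0.8, 0.8, 0.4)
#' )
#' net <- build_network(raw, focus_genes = "C")
#' as_tibble(net)  # C rescued at its maximal sub-threshold weight, ties kept
build_network <- function(edges, focus_genes = character(), high_conf = 0.9) {
  stopifnot(is.numeric(high_conf), high_conf > 0, high_conf <= 1)
  focus_genes <- toupper(trimws(focus_genes))
  edges <- tibble(
    from = toupper(as.character(pmin(edges$from, edges$to))),
    to = toupper(as.character(pmax(edges$from, edges$to))),
    weight = as.numeric(edges$weight)
  )
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")

  kept <- edges[edges$weight >= high_conf, , drop = FALSE]
  present <- unique(c(kept$from, kept$to))
  raw_nodes <- unique(c(edges$from, edges$to))

  missing <- setdiff(focus_genes, present)
  unmapped <- setdiff(missing, raw_nodes)
  rescue <- character(0)
  extra <- list()
  for (g in intersect(missing, raw_nodes)) {
    inc <- edges[(edges$from == g | edges$to == g) & edges$weight < high_conf, ,
                 drop = FALSE]
    if (nrow(inc) == 0L) {
      unmapped <- c(unmapped, g)
      next
    }
    wmax <- max(inc$weight)
    extra[[g]] <- inc[inc$weight == wmax, , drop = FALSE]
    rescue <- c(rescue, g)
  }
  out <- dplyr::distinct(dplyr::bind_rows(c(list(kept), unname(extra))))
  if (nrow(out) == 0L) {
    abort("no edges survive threshold", class = "netpharm_empty_network")
  }
  net <- new_ppi_network(out)
  attr(net, "unmapped") <- sort(unique(unmapped))
  attr(net, "rescued") <- sort(rescue)
  net
}

#' Read a pathway collection in GMT format
#'
#' Standard GMT: one gene set per tab-separated line, fields
#' `name`, `description`, then member symbols. Duplicate members within a
#' line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a tibble with columns `pathway_id`,
#'   `name`, `members` (list column of uppercase symbols) and `n` (set
#'   size); the `"universe"` attribute holds the union of all members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3L)[1L]))
  }
  sets <- tibble(
    pathway_id = vapply(fields, `[`, "", 1L),
    name = vapply(fields, `[`, "", 2L),
    members = lapply(fields, function(f) unique(toupper(trimws(f[-(1:2)]))))
  )
  sets$n <- lengths(sets$members)
  new_gene_set_collection(sets)
}

new_gene_set_collection <- function(sets) {
  stopifnot(all(lengths(sets$members) >= 1L))
  universe <- sort(unique(unlist(sets$members)))
  structure(sets, universe = universe,
            class = c("gene_set_collection", class(tibble())))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              nrow(x), length(attr(x, "universe"))))
  NextMethod()
}

#' Universe of a gene-set collection
#' @param pathways A `gene_set_collection`.
#' @return Character vector: the union of all member symbols.
#' @export
set_universe <- function(pathways) attr(pathways, "universe")

drug_classes <- c("NSAID", "DMARD", "glucocorticoid", "biological",
                  "herbal_component")

normalize_drug_class <- function(x) {
  m <- match(tolower(x), tolower(drug_classes))
  if (anyNA(m)) {
    abort(sprintf("unknown drug class '%s'; allowed: %s",
                  x[which(is.na(m))[1L]], paste(drug_classes, collapse = ", ")))
  }
  drug_classes[m]
}

#' Read a drug-to-target table
#'
#' Tab-separated with header `drug_id`, `drug_class`, `target`. Classes are
#' matched case-insensitively against NSAID, DMARD, glucocorticoid,
#' biological and herbal_component; duplicate (drug, target) pairs collapse
#' to one record.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `drug_id`, `drug_class`, `target`.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("drug_id", "drug_class", "target")
  if (!all(need %in% names(df))) {
    abort(sprintf("drug-target table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  drug_target_table(df$drug_id, df$drug_class, df$target)
}

#' Construct a drug-target table from vectors
#'
#' @param drug_id,drug_class,target Parallel vectors of records.
#' @return A deduplicated tibble with columns `drug_id`, `drug_class`,
#'   `target`; targets uppercase, classes normalized.
#' @export
drug_target_table <- function(drug_id, drug_class, target) {
  drug_id <- trimws(as.character(drug_id))
  if (any(drug_id == "")) abort("drug_id must be nonempty")
  tb <- tibble(
    drug_id = drug_id,
    drug_class = normalize_drug_class(trimws(drug_class)),
    target = toupper(trimws(target))
  )
  dplyr::distinct(tb, .data$drug_id, .data$target, .keep_all = TRUE)
}

#' Read a gene list (one symbol per line)
#'
#' Lines starting with `#` are comments; symbols are uppercased.
#'
#' @param path Path to the file.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^(#|$)", lines)]
  unique(toupper(sub("\\s*#.*$", "", lines)))
}

#' Write a network as an edge-list TSV
#' @param network A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  df <- as.data.frame(as_tibble(network))
  df$weight <- format_num(df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-set collection as GMT
#' @param pathways A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$name[i],
            pathways$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# fixed-width numeric formatting so repeated runs are byte-identical
format_num <- function(x) formatC(x, format = "g", digits = 17)
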