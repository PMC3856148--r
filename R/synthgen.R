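#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a sparse weighted interactome with heavy-tailed degrees (preferential
#' attachment), a connected planted disease module, drug target sets at
#' controlled graph proximity to the module, and pathway collections with a
#' controlled fraction of drug targets.
#'
#' @param n_nodes Number of network nodes (>= 10).
#' @param edges_per_node Preferential-attachment parameter m: each new node
#'   attaches to this many existing nodes chosen with probability
#'   proportional to current degree. `m = 1` grows a tree.
#' @param weight_low,weight_high Edge weights are drawn uniformly from
#'   `[weight_low, weight_high]`, both in (0, 1].
#' @param disease_module_size Size of the planted connected disease module;
#'   defaults to a tenth of the network (at least 2).
#' @param n_pathways Number of synthetic pathway gene sets.
#' @param pathway_size_range Integer pair: pathway sizes are uniform in this
#'   range (each size >= 2).
#' @param rng_seed Integer seed; every generator is a pure function of its
#'   config and seed.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nodes = 200, edges_per_node = 3,
                         weight_low = 0.5, weight_high = 1,
                         disease_module_size = NULL, n_pathways = 50,
                         pathway_size_range = c(10, 40), rng_seed = 1L) {
  disease_module_size <- disease_module_size %||% max(2L, n_nodes %/% 10L)
  stopifnot(
    n_nodes >= 10, edges_per_node >= 1,
    weight_low > 0, weight_low <= weight_high, weight_high <= 1,
    disease_module_size >= 2, disease_module_size < n_nodes,
    length(pathway_size_range) == 2L, pathway_size_range[1] >= 2,
    pathway_size_range[1] <= pathway_size_range[2]
  )
  structure(list(
    n_nodes = as.integer(n_nodes),
    edges_per_node = as.integer(edges_per_node),
    weight_low = weight_low, weight_high = weight_high,
    disease_module_size = as.integer(disease_module_size),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

synth_symbols <- function(n) sprintf("G%04d", seq_len(n))

# a node set plus its first neighbours, as symbols
closed_neighbourhood <- function(g, nodes) {
  sort(unique(unlist(lapply(igraph::ego(g, order = 1, nodes = nodes), names))))
}

#' Generate a weighted scale-free network
#'
#' Grows a connected undirected graph by preferential attachment: the seed
#' graph is a clique on `edges_per_node` nodes (a single node for m = 1, a
#' triangle for m = 3), and each subsequent node attaches to m distinct
#' existing nodes with probability proportional to their current degree.
#' Edge weights are i.i.d. uniform on `[weight_low, weight_high]`. The edge
#' count is therefore exactly `choose(m, 2) + (n_nodes - m) * m`.
#'
#' @param config A [synth_config()].
#' @return A `ppi_network`; deterministic given `config$rng_seed`.
#' @export
generate_network <- function(config) {
  n <- config$n_nodes
  m <- config$edges_per_node
  withr::with_seed(config$rng_seed, {
    from <- integer(0); to <- integer(0)
    if (m >= 2) {
      clique <- utils::combn(m, 2L)
      from <- clique[1L, ]; to <- clique[2L, ]
    }
    deg <- integer(n)
    if (m >= 2) for (k in seq_along(from)) {
      deg[from[k]] <- deg[from[k]] + 1L
      deg[to[k]] <- deg[to[k]] + 1L
    }
    for (v in (m + 1L):n) {
      existing <- seq_len(v - 1L)
      prob <- deg[existing]
      if (sum(prob) == 0) prob <- rep(1, length(existing))
      k <- min(m, length(existing))
      tgt <- sample(existing, k, replace = FALSE, prob = prob)
      from <- c(from, rep.int(v, k)); to <- c(to, tgt)
      deg[v] <- deg[v] + k
      deg[tgt] <- deg[tgt] + 1L
    }
    sym <- synth_symbols(n)
    w <- stats::runif(length(from), config$weight_low, config$weight_high)
    new_ppi_network(tibble(from = sym[from], to = sym[to], weight = w))
  })
}

#' Plant a connected disease module
#'
#' Picks a random high-degree anchor (uniform among the top decile of
#' degree) and grows a connected node set of the requested size by
#' breadth-first expansion from it, emulating disease genes clustering in a
#' neighbourhood of the interactome.
#'
#' @param network A `ppi_network`.
#' @param size Module size, `2 <= size < n_nodes(network)`.
#' @param rng_seed Integer seed.
#' @return Character vector of module symbols; the induced subgraph is
#'   connected.
#' @export
plant_disease_module <- function(network, size, rng_seed = 1L) {
  stopifnot(size >= 2, size < n_nodes(network))
  deg <- igraph::degree(network$graph)
  withr::with_seed(rng_seed, {
    hubs <- names(deg)[deg >= quantile(deg, 0.9)]
    anchor <- sample(hubs, 1L)
    ord <- igraph::bfs(network$graph, root = anchor, unreachable = FALSE)$order
    ord <- names(ord)[!is.na(names(ord))]
    if (length(ord) < size) {
      abort(sprintf("only %d nodes reachable from anchor %s; cannot plant module of size %d",
                    length(ord), anchor, size))
    }
    sort(ord[seq_len(size)])
  })
}

#' Plant drug target sets at controlled proximity to the disease module
#'
#' Returns a drug-target table containing one "effective" drug whose targets
#' are drawn from the disease module and its first neighbours, one "random"
#' drug whose targets are drawn uniformly from all nodes, and a three-
#' component herbal formula whose components draw targets from the effective
#' drug's neighbourhood (so components overlap the disease vicinity, as the
#' formula's on-module pharmacology assumes).
#'
#' @param network A `ppi_network`.
#' @param disease_genes Symbols of the planted module.
#' @param n_targets_effective,n_targets_random Target counts for the two
#'   reference drugs.
#' @param n_targets_component Targets per herbal component.
#' @param rng_seed Integer seed.
#' @return A drug-target tibble (see [drug_target_table()]); the effective
#'   drug is classed DMARD, the random drug NSAID, components
#'   herbal_component.
#' @export
plant_drugs <- function(network, disease_genes, n_targets_effective = 5,
                        n_targets_random = 5, n_targets_component = 4,
                        rng_seed = 1L) {
  g <- network$graph
  disease_genes <- intersect(network$nodes, toupper(disease_genes))
  module_nbhd <- closed_neighbourhood(g, disease_genes)
  if (n_targets_effective > length(module_nbhd)) {
    abort("n_targets_effective exceeds the disease neighbourhood size")
  }
  if (n_targets_random > n_nodes(network)) {
    abort("n_targets_random exceeds the number of network nodes")
  }
  withr::with_seed(rng_seed, {
    # an effective drug hits the disease proteins themselves, preferring the
    # well-connected ones (drug targets are typically hub proteins); first
    # neighbours are used only when the module is smaller than the request
    deg <- igraph::degree(g)
    if (n_targets_effective <= length(disease_genes)) {
      eff <- sample(disease_genes, n_targets_effective,
                    prob = deg[disease_genes])
    } else {
      eff <- c(disease_genes,
               sample(setdiff(module_nbhd, disease_genes),
                      n_targets_effective - length(disease_genes)))
    }
    rnd <- sample(network$nodes, n_targets_random)
    eff_nbhd <- closed_neighbourhood(g, eff)
    if (n_targets_component > length(eff_nbhd)) {
      abort("n_targets_component exceeds the effective drug's neighbourhood size")
    }
    comp <- lapply(1:3, function(i) sample(eff_nbhd, n_targets_component))
    drug_target_table(
      drug_id = c(rep("drug_effective", length(eff)),
                  rep("drug_random", length(rnd)),
                  rep(sprintf("component_%d", 1:3), lengths(comp))),
      drug_class = c(rep("DMARD", length(eff)), rep("NSAID", length(rnd)),
                     rep("herbal_component", sum(lengths(comp)))),
      target = c(eff, rnd, unlist(comp))
    )
  })
}

#' Plant a pathway collection with one enriched set
#'
#' Generates `n_pathways` gene sets with sizes uniform in `size_range`. One
#' designated set is enriched: a fraction `enriched_fraction` of its members
#' are drug targets; all other sets sample members uniformly from the
#' network nodes.
#'
#' @param network A `ppi_network`.
#' @param drug_targets Character vector of target symbols (on the network).
#' @param n_pathways Number of sets.
#' @param size_range Integer pair of set sizes.
#' @param enriched_fraction Fraction of the enriched set made of drug
#'   targets, in \[0, 1\].
#' @param enriched_size Size of the enriched set; by default drawn from
#'   `size_range` like the others. Set it explicitly when the target pool is
#'   small, since `round(enriched_fraction * enriched_size)` targets must be
#'   available.
#' @param rng_seed Integer seed.
#' @return A `gene_set_collection`; the enriched set's id is in the
#'   `"enriched_id"` attribute.
#' @export
plant_pathways <- function(network, drug_targets, n_pathways = 50,
                           size_range = c(10, 40), enriched_fraction = 0.5,
                           enriched_size = NULL, rng_seed = 1L) {
  stopifnot(enriched_fraction >= 0, enriched_fraction <= 1)
  nodes <- network$nodes
  drug_targets <- intersect(toupper(drug_targets), nodes)
  withr::with_seed(rng_seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    enriched_i <- sample(n_pathways, 1L)
    if (!is.null(enriched_size)) sizes[enriched_i] <- as.integer(enriched_size)
    n_hit <- round(enriched_fraction * sizes[enriched_i])
    if (n_hit > length(drug_targets)) {
      abort(sprintf("enriched set needs %d drug targets but only %d are available",
                    n_hit, length(drug_targets)))
    }
    members <- lapply(seq_len(n_pathways), function(i) {
      if (i == enriched_i) {
        hits <- sample(drug_targets, n_hit)
        rest <- sample(setdiff(nodes, hits), sizes[i] - n_hit)
        sort(c(hits, rest))
      } else {
        sort(sample(nodes, sizes[i]))
      }
    })
    sets <- tibble(
      pathway_id = sprintf("PW%03d", seq_len(n_pathways)),
      name = sprintf("synthetic pathway %d", seq_len(n_pathways)),
      members = members, n = lengths(members)
    )
    out <- new_gene_set_collection(sets)
    attr(out, "enriched_id") <- sets$pathway_id[enriched_i]
    out
  })
}

#' Generate a full synthetic analysis bundle
#'
#' Convenience wrapper producing every input of the pipeline: the network, a
#' planted disease module, the drug-target table (effective drug, random
#' drug, three-component formula) and a pathway collection enriched for the
#' effective drug's targets, plus a `truth` record of the planted structure.
#'
#' @param config A [synth_config()].
#' @param enriched_fraction Passed to [plant_pathways()].
#' @return A `synth_bundle` list with elements `network`, `disease_genes`,
#'   `drugs`, `pathways`, `truth`.
#' @export
generate_bundle <- function(config = synth_config(), enriched_fraction = 0.5) {
  net <- generate_network(config)
  module <- plant_disease_module(net, config$disease_module_size,
                                 rng_seed = derive_seed(config$rng_seed, "module"))
  drugs <- plant_drugs(net, module,
                       rng_seed = derive_seed(config$rng_seed, "drugs"))
  # the enriched set draws from every planted target (effective drug plus
  # formula components), sized so the requested fraction always fits
  pool <- unique(drugs$target[drugs$drug_class %in% c("DMARD", "herbal_component")])
  enriched_size <- if (enriched_fraction > 0) {
    max(config$pathway_size_range[1],
        min(config$pathway_size_range[2],
            floor(length(pool) / enriched_fraction)))
  } else NULL
  pathways <- plant_pathways(
    net, pool, n_pathways = config$n_pathways,
    size_range = config$pathway_size_range,
    enriched_fraction = enriched_fraction,
    enriched_size = enriched_size,
    rng_seed = derive_seed(config$rng_seed, "pathways")
  )
  structure(list(
    network = net, disease_genes = module, drugs = drugs, pathways = pathways,
    truth = list(effective_drug = "drug_effective",
                 random_drug = "drug_random",
                 enriched_pathway = attr(pathways, "enriched_id"),
                 config = config, enriched_fraction = enriched_fraction)
  ), class = "synth_bundle")
}

#' Write a synthetic bundle to standard input files
#'
#' Writes the four standard inputs (edge-list TSV, gene list, drug-target
#' TSV, GMT) plus a `truth.json` of planted parameters into a directory.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(bundle$network, file.path(dir, "network.tsv"))
  writeLines(bundle$disease_genes, file.path(dir, "disease_genes.txt"))
  df <- as.data.frame(bundle$drugs)
  utils::write.table(df, file.path(dir, "drug_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
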