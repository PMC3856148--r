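#' Pipeline configuration
#'
#' Bundles the file paths and tuning parameters of the five-stage analysis.
#' Defaults are the canonical study values: restart probability `r = 0.3`,
#' component seed strength 0.01, approved-drug strength 1, enrichment
#' `alpha = 0.01`, 3000 permutations, top-3% subnetwork, 0.9 confidence
#' threshold.
#'
#' @param network_file Edge-list TSV (see [read_edge_list()]).
#' @param disease_file Gene list, one symbol per line.
#' @param drug_file Drug-target TSV.
#' @param pathway_file GMT file.
#' @param r,tol,max_iter Random-walk parameters (see [rwr()]).
#' @param drug_strength,component_strength Seed strengths by drug kind.
#' @param alpha Enrichment significance level.
#' @param n_perm Permutations for the null model.
#' @param top_fraction Subnetwork selection fraction.
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @param weight_scale Edge-score divisor (see [read_edge_list()]).
#' @param high_conf Confidence threshold for [build_network()].
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network_file, disease_file, drug_file,
                            pathway_file, r = 0.3, tol = 1e-10,
                            max_iter = 10000L, drug_strength = 1,
                            component_strength = 0.01, alpha = 0.01,
                            n_perm = 3000L, top_fraction = 0.03,
                            rng_seed = 1L, weight_scale = 1,
                            high_conf = 0.9) {
  stopifnot(r > 0, r <= 1, tol > 0, drug_strength > 0,
            component_strength > 0, alpha > 0, alpha < 1, n_perm >= 2,
            top_fraction > 0, top_fraction < 1, weight_scale > 0,
            high_conf > 0, high_conf <= 1)
  structure(list(
    network_file = network_file, disease_file = disease_file,
    drug_file = drug_file, pathway_file = pathway_file,
    r = r, tol = tol, max_iter = as.integer(max_iter),
    drug_strength = drug_strength, component_strength = component_strength,
    alpha = alpha, n_perm = as.integer(n_perm),
    top_fraction = top_fraction, rng_seed = as.integer(rng_seed),
    weight_scale = weight_scale, high_conf = high_conf
  ), class = "pipeline_config")
}

#' Run the full network-pharmacology pipeline
#'
#' Sequences the five stages — network construction, drug-target bipartite
#' mapping with class overlaps, pathway enrichment of the formula's
#' targets, per-drug effect scores with permutation z-scores (plus the
#' whole-formula union score), and disease-subnetwork topology — and writes
#' every result under `output_dir` together with a manifest (all
#' parameters, derived seeds and input checksums) that suffices to re-run
#' the analysis bit-identically.
#'
#' The disease propagation is computed once and reused for every drug and
#' every permutation; each drug's null draws its seed from the master seed
#' keyed by the drug id, so adding or removing a drug leaves every other
#' drug's output unchanged.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for outputs (created if absent).
#' @return Invisibly, a list with the in-memory results: `network`,
#'   `bipartite`, `shared`, `enrichment`, `scores` (tibble of per-drug E
#'   and z), `formula_score`, `subnetwork`, `topology`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_edge_list(config$network_file, weight_scale = config$weight_scale)
  disease_genes <- read_gene_list(config$disease_file)
  drugs <- read_drug_targets(config$drug_file)
  pathways <- read_gmt(config$pathway_file)

  herbal <- drugs[drugs$drug_class == "herbal_component", , drop = FALSE]
  focus <- unique(c(disease_genes, drugs$target))
  network <- build_network(raw, focus_genes = focus,
                           high_conf = config$high_conf)
  write_edge_list(network, file.path(output_dir, "network.tsv"))

  bip <- build_bipartite(drugs[drugs$drug_class != "herbal_component", ,
                               drop = FALSE])
  shared <- shared_targets(unique(herbal$target), bip)
  write_bipartite(bip, output_dir)
  shared_df <- data.frame(
    drug_class = shared$drug_class,
    shared = vapply(shared$shared, paste, "", collapse = ","),
    n_shared = shared$n_shared
  )
  utils::write.table(shared_df, file.path(output_dir, "shared_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enr <- enrich_targets(unique(herbal$target), pathways, alpha = config$alpha)
  write_enrichment(enr, file.path(output_dir, "enrichment.tsv"))

  disease <- suppressWarnings(disease_effect(
    network, disease_genes, r = config$r, tol = config$tol,
    max_iter = config$max_iter))
  write_scores(disease, file.path(output_dir, "disease_propagation.tsv"))

  per_drug <- dplyr::distinct(drugs, .data$drug_id, .data$drug_class)
  reports <- lapply(seq_len(nrow(per_drug)), function(i) {
    id <- per_drug$drug_id[i]
    cls <- per_drug$drug_class[i]
    strength <- if (cls == "herbal_component") config$component_strength
                else config$drug_strength
    suppressWarnings(drug_significance(
      network, disease, drugs$target[drugs$drug_id == id],
      strength = strength, n_perm = config$n_perm,
      rng_seed = derive_seed(config$rng_seed, paste0("null:", id)),
      r = config$r, tol = config$tol, max_iter = config$max_iter,
      role = if (cls == "herbal_component") "component" else "drug"))
  })
  scores <- tibble(
    drug_id = per_drug$drug_id, drug_class = per_drug$drug_class,
    n_targets = vapply(per_drug$drug_id, function(id)
      length(intersect(unique(drugs$target[drugs$drug_id == id]),
                       network$nodes)), 0L),
    E = vapply(reports, function(x) x$E, 0),
    z = vapply(reports, function(x) x$z, 0),
    null_mean = vapply(reports, function(x) x$null$mean, 0),
    null_sd = vapply(reports, function(x) x$null$sd, 0),
    significant = vapply(reports, function(x) x$significant, TRUE)
  )

  formula_report <- NULL
  if (nrow(herbal) > 0L) {
    comp_sets <- split(herbal$target, herbal$drug_id)
    fs <- formula_seeds(comp_sets, strength = config$component_strength)
    fs <- fs[fs$node %in% network$nodes, , drop = FALSE]
    formula_report <- suppressWarnings(drug_significance(
      network, disease, fs$node, strength = config$component_strength,
      n_perm = config$n_perm,
      rng_seed = derive_seed(config$rng_seed, "null:formula"),
      r = config$r, tol = config$tol, max_iter = config$max_iter,
      role = "formula"))
    scores <- dplyr::bind_rows(scores, tibble(
      drug_id = "formula", drug_class = "herbal_component",
      n_targets = nrow(fs), E = formula_report$E, z = formula_report$z,
      null_mean = formula_report$null$mean,
      null_sd = formula_report$null$sd,
      significant = formula_report$significant
    ))
  }
  sc_df <- as.data.frame(scores)
  for (col in c("E", "z", "null_mean", "null_sd")) {
    sc_df[[col]] <- format_num(sc_df[[col]])
  }
  utils::write.table(sc_df, file.path(output_dir, "effect_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sub <- extract_top_fraction(network, disease,
                              fraction = config$top_fraction,
                              disease_genes = disease_genes)
  write_edge_list(sub, file.path(output_dir, "subnetwork.tsv"))
  topo <- topology_report(sub, disease_genes = disease_genes,
                          drug_table = herbal)
  write_topology(topo, file.path(output_dir, "topology.tsv"))

  manifest <- list(
    parameters = unclass(config),
    derived_seeds = setNames(
      lapply(c(per_drug$drug_id, "formula"),
             function(id) derive_seed(config$rng_seed, paste0("null:", id))),
      c(per_drug$drug_id, "formula")),
    inputs = as.list(tools::md5sum(c(
      network = config$network_file, disease = config$disease_file,
      drugs = config$drug_file, pathways = config$pathway_file))),
    network = list(nodes = n_nodes(network), edges = n_edges(network),
                   unmapped_focus_genes = attr(network, "unmapped")),
    subnetwork = list(nodes = length(sub$nodes), edges = nrow(sub$edges),
                      disease_coverage = attr(sub, "disease_coverage"))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(network = network, bipartite = bip, shared = shared,
                 enrichment = enr, disease = disease, scores = scores,
                 formula_score = formula_report, subnetwork = sub,
                 topology = topo, manifest = manifest))
}

#' Write a propagation result as TSV
#' @param result A `propagation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path) {
  df <- data.frame(node = result$node, score = format_num(result$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
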