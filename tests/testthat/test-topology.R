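test_that("top-fraction extraction floors, breaks ties lexicographically, and reports coverage", {
  net <- generate_network(synth_config(n_nodes = 100, rng_seed = 3))
  d <- suppressWarnings(disease_effect(net, net$nodes[1:10]))
  sub <- extract_top_fraction(net, d, fraction = 0.5)
  expect_equal(length(sub$nodes), 50L)

  # all-equal scores select the lexicographically first half
  flat <- d
  flat$score <- rep(1, nrow(flat))
  sub2 <- extract_top_fraction(net, flat, fraction = 0.5)
  expect_equal(sub2$nodes, sort(net$nodes)[1:50])

  sub3 <- extract_top_fraction(net, d, fraction = 0.1,
                               disease_genes = net$nodes[1:10])
  cov <- attr(sub3, "disease_coverage")
  expect_equal(cov$n_total, 10L)
  expect_equal(cov$percent, 100 * cov$n_on_subnetwork / 10)

  expect_error(extract_top_fraction(net, d, fraction = 0.001), "empty")
})

test_that("subnetwork edges are exactly the induced parent edges", {
  net <- generate_network(synth_config(n_nodes = 120, rng_seed = 5))
  d <- suppressWarnings(disease_effect(net, net$nodes[1:12]))
  sub <- extract_top_fraction(net, d, fraction = 0.2)
  members <- attr(sub, "members")
  parent <- as_tibble(net)
  induced <- parent[parent$from %in% members & parent$to %in% members, ]
  expect_identical(as_tibble(sub), induced)
  expect_true(all(members %in% net$nodes))
})

test_that("selections at nested fractions are nested", {
  net <- generate_network(synth_config(n_nodes = 100, rng_seed = 7))
  d <- suppressWarnings(disease_effect(net, net$nodes[1:10]))
  sub <- extract_top_fraction(net, d, fraction = 0.3)
  # a smaller fraction of the subnetwork's own scores is a prefix of the
  # same ranking, so it must lie inside the larger selection
  keep <- d[d$node %in% sub$nodes, ]
  inner <- extract_top_fraction(sub, keep, fraction = 0.5)
  expect_true(all(inner$nodes %in% sub$nodes))
  smaller <- extract_top_fraction(net, d, fraction = 0.15)
  expect_true(all(smaller$nodes %in% sub$nodes))
})

test_that("degrees satisfy closed forms and the handshake lemma", {
  tri <- cycle_network(3)
  expect_true(all(node_degrees(tri)$degree == 2L))
  star <- star_network(4)
  ds <- node_degrees(star)
  expect_equal(ds$degree[ds$node == "HUB"], 4L)
  expect_true(all(ds$degree[ds$node != "HUB"] == 1L))

  net <- generate_network(synth_config(n_nodes = 80, rng_seed = 2))
  expect_equal(mean(node_degrees(net)$degree), 2 * n_edges(net) / n_nodes(net))
})

test_that("coreness matches the recursive-deletion brute force", {
  expect_true(all(kcore_decomposition(cycle_network(3))$coreness == 2L))
  expect_true(all(kcore_decomposition(star_network(5))$coreness == 1L))

  for (s in 1:3) {
    net <- generate_network(synth_config(n_nodes = 100, edges_per_node = 3,
                                         rng_seed = s))
    got <- kcore_decomposition(net)
    want <- oracle_coreness(net)
    expect_equal(setNames(got$coreness, got$node), want[got$node])
  }
})

test_that("betweenness matches closed forms and BFS path-counting brute force", {
  pth <- path_network(c("A", "B", "C"))
  b <- betweenness_centrality(pth, normalized = FALSE)
  expect_equal(b$betweenness[b$node == "B"], 1)
  bn <- betweenness_centrality(pth, normalized = TRUE)
  expect_equal(bn$betweenness[bn$node == "B"], 1)

  star <- star_network(6)
  bs <- betweenness_centrality(star, normalized = FALSE)
  expect_equal(bs$betweenness[bs$node == "HUB"], choose(6, 2))
  expect_true(all(bs$betweenness[bs$node != "HUB"] == 0))
  bsn <- betweenness_centrality(star, normalized = TRUE)
  expect_equal(bsn$betweenness[bsn$node == "HUB"], 1)

  # cycle symmetry: all nodes equal
  bc <- betweenness_centrality(cycle_network(5), normalized = FALSE)
  expect_true(all(abs(bc$betweenness - bc$betweenness[1]) < 1e-12))

  for (s in 1:3) {
    net <- generate_network(synth_config(n_nodes = 40, edges_per_node = 2,
                                         rng_seed = s))
    got <- betweenness_centrality(net, normalized = FALSE)
    want <- oracle_betweenness(net)
    expect_equal(setNames(got$betweenness, got$node), want[got$node],
                 tolerance = 1e-10)
  }
})

test_that("coreness never exceeds degree", {
  net <- generate_network(synth_config(n_nodes = 150, rng_seed = 9))
  j <- dplyr::inner_join(node_degrees(net), kcore_decomposition(net), by = "node")
  expect_true(all(j$coreness <= j$degree))
})

test_that("topology report annotates disease genes and targets with summaries", {
  b <- generate_bundle(synth_config(rng_seed = 19))
  d <- disease_effect(b$network, b$disease_genes)
  sub <- extract_top_fraction(b$network, d, fraction = 0.2,
                              disease_genes = b$disease_genes)
  herbal <- b$drugs[b$drugs$drug_class == "herbal_component", ]
  rep <- topology_report(sub, disease_genes = b$disease_genes,
                         drug_table = herbal)
  expect_setequal(rep$node, sub$nodes)
  expect_true(all(rep$coreness <= rep$degree))
  s <- attr(rep, "summary")
  expect_equal(s$mean_degree, mean(rep$degree))
  hub <- rep$node[1]  # sorted by degree descending
  expect_equal(rep$degree[1], max(rep$degree))

  # no targets on the subnetwork: summary fractions are NA
  rep0 <- topology_report(sub, disease_genes = b$disease_genes,
                          drug_table = NULL)
  expect_true(is.na(attr(rep0, "summary")$frac_targets_degree_above_mean))
})

test_that("effective-drug targets are more central than random node sets", {
  # a quarter of a 200-node network keeps the subnetwork large enough for
  # coreness to vary; the production default (top 3%) is meant for
  # interactome-scale inputs
  hits <- 0L
  for (s in 1:10) {
    b <- generate_bundle(synth_config(rng_seed = 100 + s))
    d <- disease_effect(b$network, b$disease_genes)
    sub <- extract_top_fraction(b$network, d, fraction = 0.25)
    cores <- kcore_decomposition(sub)
    core_of <- setNames(cores$coreness, cores$node)
    eff <- intersect(b$drugs$target[b$drugs$drug_id == "drug_effective"],
                     sub$nodes)
    obs <- mean(core_of[eff])
    null <- withr::with_seed(s, replicate(100, {
      mean(core_of[sample(sub$nodes, length(eff))])
    }))
    hits <- hits + (obs > mean(null))
  }
  expect_gte(hits, 8L)
})
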