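test_that("edge lists parse with scaling, case normalization and header detection", {
  f <- write_tmp(c("TNF\tIL6\t900", "il6\til1b\t850"))
  e <- read_edge_list(f, weight_scale = 1000)
  expect_equal(e$from, c("TNF", "IL6"))
  expect_equal(e$to, c("IL6", "IL1B"))
  expect_equal(e$weight, c(0.9, 0.85))

  f2 <- write_tmp(c("node_a\tnode_b\tweight", "tnf il6 0.9"))
  e2 <- read_edge_list(f2, weight_scale = 1)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$weight, 0.9)

  expect_error(read_edge_list(write_tmp("A B 1500"), weight_scale = 1000),
               "out of range")
  expect_error(read_edge_list(write_tmp(c("A B 0.5", "A B")), 1),
               "line 2")
  expect_error(read_edge_list(write_tmp(c("A B 0.5", "C D x")), 1),
               "non-numeric")
  # a lone non-numeric third field reads as a header over an empty body
  expect_error(read_edge_list(write_tmp("A B x"), 1), "no data")
})

test_that("build_network keeps high-confidence edges and rescues focus genes with ties", {
  raw <- tibble::tibble(from = c("A", "C", "C", "C"),
                        to = c("B", "A", "B", "D"),
                        weight = c(0.95, 0.8, 0.8, 0.4))
  net <- build_network(raw, focus_genes = "C", high_conf = 0.9)
  expect_setequal(net$nodes, c("A", "B", "C"))
  edges <- as_tibble(net)
  expect_equal(nrow(edges), 3L)
  # both edges tied at C's maximal sub-threshold weight are rescued
  expect_equal(sort(edges$weight[edges$from == "C" | edges$to == "C"]),
               c(0.8, 0.8))

  # threshold-only when no focus gene needs rescue
  raw2 <- tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                         weight = c(0.95, 0.5))
  net2 <- build_network(raw2, focus_genes = "A", high_conf = 0.9)
  expect_setequal(net2$nodes, c("A", "B"))

  # a focus gene with no raw edges cannot be rescued and is reported
  net3 <- build_network(raw2, focus_genes = "Z", high_conf = 0.9)
  expect_equal(attr(net3, "unmapped"), "Z")

  expect_error(build_network(raw2, high_conf = 0.99), "no edges survive")
})

test_that("build_network is order-invariant and rescue-complete", {
  set.seed(11)
  sym <- sprintf("N%02d", 1:20)
  raw <- tibble::tibble(from = sample(sym, 60, TRUE),
                        to = sample(sym, 60, TRUE),
                        weight = round(runif(60, 0.1, 1), 3))
  raw <- raw[raw$from != raw$to, ]
  focus <- sample(sym, 6)
  a <- build_network(raw, focus, high_conf = 0.9)
  b <- build_network(raw[sample(nrow(raw)), ], focus, high_conf = 0.9)
  expect_identical(as_tibble(a), as_tibble(b))
  # every focus gene present in the raw list ends up on the network
  raw_nodes <- unique(c(raw$from, raw$to))
  expect_true(all(intersect(focus, raw_nodes) %in% a$nodes))
  # no isolated nodes, weights in (0, 1], self-loops dropped
  deg <- igraph::degree(a$graph)
  expect_true(all(deg >= 1))
  expect_true(all(a$edges$weight > 0 & a$edges$weight <= 1))
  expect_true(all(a$edges$from != a$edges$to))
})

test_that("duplicate edges with conflicting weights keep the maximum", {
  raw <- tibble::tibble(from = c("A", "B"), to = c("B", "A"),
                        weight = c(0.91, 0.97))
  net <- build_network(raw, high_conf = 0.9)
  expect_equal(as_tibble(net)$weight, 0.97)
})

test_that("GMT files read with dedup and a correct universe", {
  f <- write_tmp(c("P1\tdesc\tA\tB\tA", "P2\tdesc\tB\tC"))
  gs <- read_gmt(f)
  expect_equal(gs$members[[1]], c("A", "B"))
  expect_equal(set_universe(gs), c("A", "B", "C"))
  expect_error(read_gmt(write_tmp(c("P1\tdesc\tA", "P2\tonlydesc"))), "line 2")
  expect_error(read_gmt(write_tmp(character(0))), "empty")
})

test_that("drug-target tables dedupe and normalize classes", {
  f <- write_tmp(c("drug_id\tdrug_class\ttarget",
                   "etanercept\tbiological\tTNF",
                   "etanercept\tbiological\tTNF",
                   "x\tnsaid\tptgs2"))
  tb <- read_drug_targets(f)
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$drug_class[tb$drug_id == "x"], "NSAID")
  expect_equal(tb$target[tb$drug_id == "x"], "PTGS2")
  expect_error(
    read_drug_targets(write_tmp(c("drug_id\tdrug_class\ttarget",
                                  "y\tpainkiller\tTNF"))),
    "allowed")
})

test_that("gene lists skip comments and uppercase symbols", {
  f <- write_tmp(c("# disease genes", "tnf", "IL6", "", "il6"))
  expect_equal(read_gene_list(f), c("TNF", "IL6"))
})
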