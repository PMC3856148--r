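test_that("transition operator is column-stochastic with reliability-proportional moves", {
  tri <- new_net(tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "A"),
                                weight = c(0.5, 0.5, 0.5)))
  W <- transition_matrix(tri)
  off <- as.matrix(W)[as.matrix(W) > 0]
  expect_true(all(abs(off - 0.5) < 1e-15))

  net <- new_net(tibble::tibble(from = c("V", "V"), to = c("U1", "U2"),
                                weight = c(0.9, 0.3)))
  W2 <- as.matrix(transition_matrix(net))
  expect_equal(W2["U1", "V"], 0.75)
  expect_equal(W2["U2", "V"], 0.25)

  rnd <- generate_network(synth_config(n_nodes = 80, rng_seed = 12))
  expect_equal(max(abs(Matrix::colSums(transition_matrix(rnd)) - 1)), 0,
               tolerance = 1e-12)
})

test_that("restart probability one returns the seed vector unchanged", {
  net <- new_net(tibble::tibble(from = "A", to = "B", weight = 1))
  res <- rwr(net, c(A = 1), r = 1)
  expect_equal(res$score[res$node == "A"], 1)
  expect_equal(res$score[res$node == "B"], 0)
})

test_that("propagation is linear in the seed vector", {
  net <- generate_network(synth_config(n_nodes = 60, rng_seed = 5))
  s1 <- setNames(c(1, 2), net$nodes[c(3, 10)])
  s2 <- setNames(c(0.5, 1), net$nodes[c(10, 40)])
  a <- rwr(net, s1, tol = 1e-13)$score
  b <- rwr(net, s2, tol = 1e-13)$score
  both <- c(s1[1], s1[2] + 2 * s2[1], 2 * s2[2])
  names(both) <- net$nodes[c(3, 10, 40)]
  ab <- rwr(net, both, tol = 1e-13)$score
  expect_equal(ab, a + 2 * b, tolerance = 1e-8)

  # scaling seeds by c scales every score by c
  sc <- rwr(net, s1 * 0.01, tol = 1e-13)$score
  expect_equal(sc, 0.01 * a, tolerance = 1e-10)
})

test_that("iterative walk matches the dense linear solve on a three-node path", {
  net <- path_network(c("A", "B", "C"), weight = 1)
  res <- rwr(net, c(A = 1), r = 0.3, tol = 1e-13)
  exact <- oracle_rwr(net, c(A = 1), r = 0.3)
  expect_equal(res$score, exact, tolerance = 1e-8)
})

test_that("disease effect conserves mass and respects symmetry", {
  net <- generate_network(synth_config(n_nodes = 50, rng_seed = 2))
  all_seed <- suppressWarnings(disease_effect(net, net$nodes))
  expect_equal(sum(all_seed$score), n_nodes(net), tolerance = 1e-8)

  cyc <- cycle_network(5)
  res <- disease_effect(cyc, "A")
  s <- setNames(res$score, res$node)
  expect_equal(s[["B"]], s[["E"]])  # neighbours of the seed are equivalent
  expect_equal(s[["C"]], s[["D"]])

  expect_error(disease_effect(cyc, "ZZ"), "disease gene")
})

test_that("module members score higher than the background", {
  for (s in 1:10) {
    b <- generate_bundle(synth_config(n_nodes = 150, rng_seed = s))
    d <- disease_effect(b$network, b$disease_genes)
    in_mod <- d$node %in% b$disease_genes
    expect_gt(mean(d$score[in_mod]), mean(d$score[!in_mod]))
  }
})

test_that("drug effect validates strengths and reports off-network targets", {
  net <- path_network()
  expect_error(drug_effect(net, "A", strength = 0), "positive")
  expect_error(drug_effect(net, c("ZZ", "YY")), "ZZ")
  expect_warning(res <- drug_effect(net, c("A", "ZZ")), "ZZ")
  expect_equal(attr(res, "dropped_seeds"), "ZZ")

  # component strength 0.01 is an exact rescaling of the unit-strength run
  net2 <- generate_network(synth_config(n_nodes = 60, rng_seed = 9))
  t5 <- net2$nodes[1:5]
  full <- drug_effect(net2, t5, strength = 1, tol = 1e-13)
  comp <- drug_effect(net2, t5, strength = 0.01, tol = 1e-13)
  expect_equal(comp$score, 0.01 * full$score, tolerance = 1e-10)
})

test_that("formula seeds implement union and additive conventions", {
  comps <- list(c1 = c("A", "B"), c2 = c("B", "C"), c3 = "D")
  fs <- formula_seeds(comps, strength = 0.01)
  expect_equal(fs$node, c("A", "B", "C", "D"))
  expect_equal(fs$strength, rep(0.01, 4))
  fa <- formula_seeds(comps, strength = 0.01, mode = "additive")
  expect_equal(fa$strength[fa$node == "B"], 0.02)

  # union formula run is bounded above by the sum of component runs
  net <- generate_network(synth_config(n_nodes = 80, rng_seed = 3))
  comp_sets <- list(net$nodes[1:4], net$nodes[3:6], net$nodes[c(5, 9)])
  fs2 <- formula_seeds(comp_sets, 0.01)
  u <- rwr(net, fs2, tol = 1e-13)$score
  parts <- lapply(comp_sets, function(tg)
    drug_effect(net, tg, strength = 0.01, tol = 1e-13)$score)
  expect_true(all(u <= Reduce(`+`, parts) + 1e-10))
})

test_that("effect score is the inner product with the documented edge cases", {
  # disconnected two-component network: disjoint supports give E = 0
  net <- new_net(tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                                weight = c(1, 1)))
  d <- disease_effect(net, "A")
  g <- drug_effect(net, "C")
  expect_equal(effect_score(d, g)$E, 0)
  expect_equal(effect_score(d, d)$E, sum(d$score^2))

  net2 <- path_network()
  expect_error(effect_score(disease_effect(net2, "A"), g), "node set")
})

test_that("the planted effective drug outscores the random drug", {
  wins <- 0L
  for (s in 1:10) {
    b <- generate_bundle(synth_config(n_nodes = 50, disease_module_size = 8,
                                      rng_seed = s))
    d <- disease_effect(b$network, b$disease_genes)
    Ee <- effect_score(d, drug_effect(
      b$network, b$drugs$target[b$drugs$drug_id == "drug_effective"]))$E
    Er <- effect_score(d, drug_effect(
      b$network, b$drugs$target[b$drugs$drug_id == "drug_random"]))$E
    wins <- wins + (Ee > Er)
  }
  expect_gte(wins, 9L)
})
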