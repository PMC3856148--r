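# Independent oracles used across the suite. Each one recomputes a quantity
# by a different route than the package (dense linear algebra, exhaustive
# enumeration, brute-force graph search) and stays free of the code it checks.

# Direct linear solve of the restart walk: x = r (I - (1-r) W)^-1 x0, with W
# rebuilt densely from the edge tibble (own normalization, no package code).
oracle_rwr <- function(network, seeds, r) {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    A[e$from[i], e$to[i]] <- e$weight[i]
    A[e$to[i], e$from[i]] <- e$weight[i]
  }
  W <- sweep(A, 2, colSums(A), "/")
  x0 <- numeric(n)
  names(x0) <- nodes
  x0[names(seeds)] <- seeds
  as.numeric(r * solve(diag(n) - (1 - r) * W, x0))
}

# Exhaustive hypergeometric pmf: enumerate every size-n draw from a universe
# of N items of which the first K carry the feature; returns P(X = i) for
# i = 0..n.
oracle_hyper_pmf <- function(N, K, n) {
  if (n == 0) return(c(1, rep(0, 0)))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  counts <- tabulate(hits + 1L, nbins = n + 1L)
  counts / ncol(draws)
}

# Brute-force betweenness by breadth-first path counting: sigma_s(v) shortest
# path counts from every source, then the pair-dependency identity
# sigma_s(v) * sigma_t(v) when v lies on a shortest s-t path.
oracle_betweenness <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(network$edges$to[network$edges$from == v],
      network$edges$from[network$edges$to == v])
  })
  bfs_counts <- function(s) {
    dist <- setNames(rep(Inf, n), nodes)
    sigma <- setNames(rep(0, n), nodes)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
        if (dist[u] == dist[v] + 1) sigma[u] <- sigma[u] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(setNames(nodes, nodes), bfs_counts)
  g <- setNames(rep(0, n), nodes)
  for (si in seq_len(n - 1)) for (ti in (si + 1):n) {
    s <- nodes[si]; t <- nodes[ti]
    if (is.infinite(sp[[s]]$dist[t])) next
    d <- sp[[s]]$dist[t]
    for (v in nodes) {
      if (v == s || v == t) next
      if (sp[[s]]$dist[v] + sp[[t]]$dist[v] == d) {
        g[v] <- g[v] + sp[[s]]$sigma[v] * sp[[t]]$sigma[v] / sp[[s]]$sigma[t]
      }
    }
  }
  g
}

# Brute-force coreness: for each k, repeatedly delete nodes of degree < k
# from the edge list until stable; coreness is the last k a node survives.
oracle_coreness <- function(network) {
  nodes <- network$nodes
  core <- setNames(rep(0L, length(nodes)), nodes)
  e0 <- network$edges[, c("from", "to")]
  k <- 1L
  repeat {
    alive <- nodes
    e <- e0
    repeat {
      deg <- table(factor(c(e$from, e$to), levels = alive))
      drop <- names(deg)[deg < k]
      if (length(drop) == 0) break
      alive <- setdiff(alive, drop)
      e <- e[e$from %in% alive & e$to %in% alive, , drop = FALSE]
    }
    if (length(alive) == 0) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Small deterministic fixtures ------------------------------------------------

path_network <- function(symbols = c("A", "B", "C"), weight = 1) {
  new_net(tibble::tibble(
    from = symbols[-length(symbols)], to = symbols[-1],
    weight = rep(weight, length(symbols) - 1)
  ))
}

cycle_network <- function(n = 5, weight = 1) {
  sym <- LETTERS[seq_len(n)]
  new_net(tibble::tibble(
    from = sym, to = c(sym[-1], sym[1]), weight = rep(weight, n)
  ))
}

star_network <- function(n_leaves = 4, weight = 1) {
  new_net(tibble::tibble(
    from = rep("HUB", n_leaves), to = paste0("L", seq_len(n_leaves)),
    weight = rep(weight, n_leaves)
  ))
}

# build a ppi_network from an edge tibble without going through file IO
new_net <- function(edges) build_network(edges, high_conf = min(edges$weight))

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
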