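#' Column-stochastic transition operator of a weighted network
#'
#' The random walker at node `v` moves to neighbour `u` with probability
#' proportional to the reliability of the interaction:
#' `W[u, v] = w(u, v) / sum_{u'} w(u', v)`. Every column sums to one, which
#' requires the network to have no isolated nodes.
#'
#' @param network A `ppi_network`.
#' @return A sparse [Matrix::dgCMatrix-class] with rows/columns named by the
#'   network's node symbols.
#' @export
transition_matrix <- function(network) {
  nodes <- network$nodes
  e <- network$edges
  i <- match(c(e$from, e$to), nodes)
  j <- match(c(e$to, e$from), nodes)
  w <- rep(e$weight, 2L)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  colsum <- Matrix::colSums(A)
  if (any(colsum == 0)) {
    abort("network has isolated nodes; cannot form a stochastic operator")
  }
  W <- A %*% Matrix::Diagonal(x = 1 / colsum)
  dimnames(W) <- list(nodes, nodes)
  W
}

# power iteration of x <- (1 - r) W x + r x0, shared by all entry points
rwr_iterate <- function(W, x0, r, tol, max_iter) {
  x <- x0
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x_new <- (1 - r) * as.numeric(W %*% x) + r * x0
    resid <- sum(abs(x_new - x))
    x <- x_new
    if (resid < tol) break
  }
  list(x = x, iterations = it, residual = resid)
}

as_seed_vector <- function(network, seeds, role = "drug") {
  if (is.data.frame(seeds)) {
    strengths <- setNames(as.numeric(seeds$strength), toupper(seeds$node))
  } else if (!is.null(names(seeds))) {
    strengths <- setNames(as.numeric(seeds), toupper(names(seeds)))
  } else {
    abort("seeds must be a named numeric vector or a tibble(node, strength)")
  }
  if (any(strengths < 0)) abort("seed strengths must be nonnegative")
  off <- setdiff(names(strengths), network$nodes)
  if (length(off) > 0L) {
    warn(sprintf("%d seed symbol(s) not on the network were dropped: %s",
                 length(off), paste(off, collapse = ", ")))
    strengths <- strengths[setdiff(names(strengths), off)]
  }
  strengths <- strengths[strengths > 0]
  if (length(strengths) == 0L) {
    abort("no seed with positive strength on the network",
          class = "netpharm_empty_seeds")
  }
  structure(list(strengths = strengths, role = role, dropped = sort(off)),
            class = "seed_vector")
}

#' Random walk with restart on a weighted network
#'
#' Iterates `x_{t+1} = (1 - r) W x_t + r x_0` from the seed vector `x_0`
#' until the L1 change between successive iterates falls below `tol`, where
#' `W` is the column-normalized weight matrix of [transition_matrix()] and
#' `r` is the restart probability. The steady state `x_inf` measures the
#' association of every node with the seed set; its total mass equals the
#' total seed strength.
#'
#' @param network A `ppi_network`.
#' @param seeds Named numeric vector or tibble with columns `node`,
#'   `strength`; nonnegative, at least one positive. Symbols absent from the
#'   network are dropped with a warning and recorded.
#' @param r Restart probability in (0, 1]; default 0.3.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @param .W Optional precomputed [transition_matrix()] of `network`, so
#'   callers running many propagations on one network (permutation nulls)
#'   build it once.
#'
#' @return A `propagation_result`: tibble with columns `node`, `score` (all
#'   network nodes, in node order). Attributes: `r`, `iterations`,
#'   `residual`, `seed_sum`, `dropped_seeds`.
#' @export
#' @examples
#' net <- generate_network(synth_config(n_nodes = 50, rng_seed = 7))
#' res <- rwr(net, c(G0001 = 1), r = 0.3)
#' sum(res$score)  # equals the seed mass
rwr <- function(network, seeds, r = 0.3, tol = 1e-10, max_iter = 10000L,
                .W = NULL) {
  stopifnot(r > 0, r <= 1, tol > 0, max_iter >= 1)
  sv <- if (inherits(seeds, "seed_vector")) seeds else as_seed_vector(network, seeds)
  W <- .W %||% transition_matrix(network)
  nodes <- network$nodes
  x0 <- numeric(length(nodes))
  names(x0) <- nodes
  x0[names(sv$strengths)] <- sv$strengths
  it_res <- rwr_iterate(W, x0, r, tol, max_iter)
  x <- it_res$x
  it <- it_res$iterations
  resid <- it_res$residual
  if (resid >= tol) {
    abort(sprintf("random walk did not converge in %d iterations (residual %.3g)",
                  max_iter, resid),
          class = "netpharm_no_convergence")
  }
  structure(
    tibble(node = nodes, score = as.numeric(x)),
    r = r, iterations = it, residual = resid, seed_sum = sum(sv$strengths),
    dropped_seeds = sv$dropped, role = sv$role,
    class = c("propagation_result", class(tibble()))
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> role = %s; r = %g; %d iterations (residual %.2g)\n",
              attr(x, "role") %||% "?", attr(x, "r"), attr(x, "iterations"),
              attr(x, "residual")))
  NextMethod()
}

#' Disease effect vector
#'
#' Propagates the disease gene set with unit strength on every on-network
#' disease gene; the steady state is the disease effect vector, scoring each
#' protein's association with the disease seed set.
#'
#' @param network A `ppi_network`.
#' @param disease_genes Character vector of disease-associated symbols.
#' @inheritParams rwr
#' @return A `propagation_result`.
#' @export
disease_effect <- function(network, disease_genes, r = 0.3, tol = 1e-10,
                           max_iter = 10000L) {
  disease_genes <- unique(toupper(trimws(disease_genes)))
  if (length(intersect(disease_genes, network$nodes)) == 0L) {
    abort("no disease gene on the network")
  }
  sv <- as_seed_vector(network, setNames(rep(1, length(disease_genes)),
                                         disease_genes), role = "disease")
  rwr(network, sv, r = r, tol = tol, max_iter = max_iter)
}

#' Drug (or component) effect vector
#'
#' Propagates a drug's target set at a uniform seed strength: 1 for
#' approved single-target drugs, 0.01 for natural-compound components whose
#' inhibition potency is roughly two orders of magnitude weaker.
#'
#' @param network A `ppi_network`.
#' @param targets Character vector of target symbols.
#' @param strength Positive uniform seed strength.
#' @inheritParams rwr
#' @param role Label stored on the result (`"drug"`, `"component"`,
#'   `"formula"`).
#' @return A `propagation_result`.
#' @export
drug_effect <- function(network, targets, strength = 1, r = 0.3, tol = 1e-10,
                        max_iter = 10000L, role = "drug", .W = NULL) {
  if (!is.numeric(strength) || strength <= 0) {
    abort("seed strength must be strictly positive")
  }
  targets <- unique(toupper(trimws(targets)))
  off <- setdiff(targets, network$nodes)
  if (length(off) == length(targets)) {
    abort(sprintf("no target on the network; off-network targets: %s",
                  paste(off, collapse = ", ")))
  }
  sv <- as_seed_vector(network, setNames(rep(strength, length(targets)),
                                         targets), role = role)
  rwr(network, sv, r = r, tol = tol, max_iter = max_iter, .W = .W)
}

#' Whole-formula seed set from component target sets
#'
#' The formula-level seed vector places `strength` on the union of the
#' component target sets (a target shared by several components is seeded
#' once). The `"additive"` mode instead sums the per-component strengths on
#' shared targets.
#'
#' @param component_targets Named list of character vectors, one per
#'   component.
#' @param strength Per-component seed strength; default 0.01.
#' @param mode `"union"` (default) or `"additive"`.
#' @return A tibble with columns `node`, `strength`, usable as the `seeds`
#'   argument of [rwr()].
#' @export
formula_seeds <- function(component_targets, strength = 0.01,
                          mode = c("union", "additive")) {
  mode <- match.arg(mode)
  stopifnot(is.list(component_targets), length(component_targets) >= 1L)
  all_t <- toupper(trimws(unlist(component_targets, use.names = FALSE)))
  if (mode == "union") {
    tibble(node = sort(unique(all_t)), strength = strength)
  } else {
    counts <- table(unlist(lapply(component_targets,
                                  function(x) unique(toupper(trimws(x))))))
    tibble(node = sort(names(counts)),
           strength = strength * as.numeric(counts[sort(names(counts))]))
  }
}

#' Inner-product effect score of a drug on a disease
#'
#' `E = sum_v x_disease(v) * x_drug(v)`: large when the drug's propagated
#' influence is concentrated where the disease's influence is. Both vectors
#' must come from the same network.
#'
#' @param disease,drug `propagation_result` objects on the same node set.
#' @return An `effect_score` with elements `E`, `disease`, `drug`.
#' @export
effect_score <- function(disease, drug) {
  if (!identical(disease$node, drug$node)) {
    abort("propagation results computed on different node sets")
  }
  structure(list(E = sum(disease$score * drug$score),
                 disease = disease, drug = drug),
            class = "effect_score")
}

#' @export
print.effect_score <- function(x, ...) {
  cat(sprintf("<effect_score> E = %.6g (role %s vs %s)\n", x$E,
              attr(x$disease, "role") %||% "?", attr(x$drug, "role") %||% "?"))
  invisible(x)
}
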