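#' Random target sets for the permutation null
#'
#' Draws `n_perm` target sets of the given size uniformly without
#' replacement from all network nodes — the random counterparts against
#' which a drug's effect score is standardized.
#'
#' @param network A `ppi_network`.
#' @param set_size Targets per random set, `<=` number of nodes.
#' @param n_perm Number of sets; default 3000.
#' @param rng_seed Integer seed; the list is a pure function of it.
#' @return List of `n_perm` character vectors.
#' @export
random_target_sets <- function(network, set_size, n_perm = 3000L,
                               rng_seed = 1L) {
  if (set_size > n_nodes(network)) {
    abort(sprintf("set_size %d exceeds the %d network nodes",
                  set_size, n_nodes(network)))
  }
  stopifnot(set_size >= 1, n_perm >= 1)
  withr::with_seed(rng_seed, {
    lapply(seq_len(n_perm), function(i) sample(network$nodes, set_size))
  })
}

new_null_distribution <- function(scores, rng_seed) {
  structure(list(scores = as.numeric(scores), mean = mean(scores),
                 sd = sd(scores), n_perm = length(scores),
                 rng_seed = rng_seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations: mean %.4g, sd %.4g\n",
              x$n_perm, x$mean, x$sd))
  invisible(x)
}

#' Standardize an effect score against its permutation null
#'
#' `z = (E - mean(null)) / sd(null)` with the sample (n - 1) standard
#' deviation; `|z| > 3` is flagged as a significant deviation from the
#' random counterparts.
#'
#' @param E Observed effect score (or an `effect_score` object).
#' @param null A `null_distribution`.
#' @return A `zscore_report` with elements `E`, `z`, `null`, `significant`.
#' @export
zscore <- function(E, null) {
  if (inherits(E, "effect_score")) E <- E$E
  stopifnot(inherits(null, "null_distribution"), null$n_perm >= 2)
  if (null$sd == 0) abort("degenerate null: zero standard deviation")
  z <- (E - null$mean) / null$sd
  structure(list(E = E, z = z, null = null, significant = abs(z) > 3),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat(sprintf("<zscore_report> E = %.6g, z = %.2f (%ssignificant at |z| > 3; %d permutations)\n",
              x$E, x$z, if (x$significant) "" else "not ", x$null$n_perm))
  invisible(x)
}

#' Permutation significance of a drug's antirheumatic-style effect score
#'
#' Computes the drug's effect score against a cached disease propagation,
#' then the scores of `n_perm` random target sets of the same size (the
#' number of the drug's on-network targets) at the same seed strength, and
#' standardizes. The z-score is invariant to the seed strength, since both
#' the observed and null scores scale linearly with it.
#'
#' @param network A `ppi_network`.
#' @param disease A `propagation_result` for the disease seeds (computed
#'   once and reused across drugs and permutations).
#' @param targets The drug's target symbols.
#' @param strength Uniform seed strength (1 for approved drugs, 0.01 for
#'   herbal components).
#' @param n_perm Number of random target sets; default 3000.
#' @param rng_seed Integer seed for the random sets.
#' @inheritParams rwr
#' @param role Label for the drug propagation.
#' @return A `zscore_report`; the observed propagation is attached as the
#'   `"drug_result"` attribute.
#' @export
drug_significance <- function(network, disease, targets, strength = 1,
                              n_perm = 3000L, rng_seed = 1L, r = 0.3,
                              tol = 1e-10, max_iter = 10000L, role = "drug") {
  W <- transition_matrix(network)
  obs <- drug_effect(network, targets, strength = strength, r = r, tol = tol,
                     max_iter = max_iter, role = role, .W = W)
  E <- effect_score(disease, obs)$E
  set_size <- length(intersect(unique(toupper(trimws(targets))),
                               network$nodes))
  sets <- random_target_sets(network, set_size, n_perm = n_perm,
                             rng_seed = rng_seed)
  null_scores <- vapply(sets, function(s) {
    res <- drug_effect(network, s, strength = strength, r = r, tol = tol,
                       max_iter = max_iter, role = "null", .W = W)
    sum(disease$score * res$score)
  }, 0)
  rep <- zscore(E, new_null_distribution(null_scores, rng_seed))
  attr(rep, "drug_result") <- obs
  rep
}
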