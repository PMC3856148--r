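#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `i` feature items when `n` items are drawn
#' without replacement from a universe of `N` items of which `K` carry the
#' feature: `C(K,i) C(N-K,n-i) / C(N,n)`. Computed in log space via
#' `lchoose` so large universes do not overflow; zero outside the support
#' `[max(0, n-N+K), min(n, K)]`.
#'
#' @param N Universe size.
#' @param K Feature items in the universe, `0 <= K <= N`.
#' @param n Draw size, `0 <= n <= N`.
#' @param i Number of feature items drawn (vectorized).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' hypergeom_pmf(20, 5, 6, 0:5)
hypergeom_pmf <- function(N, K, n, i) {
  check_hyper_args(N, K, n)
  i <- as.numeric(i)
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  out <- numeric(length(i))
  ok <- i >= lo & i <= hi & i == floor(i)
  out[ok] <- exp(lchoose(K, i[ok]) + lchoose(N - K, n - i[ok]) - lchoose(N, n))
  out
}

#' Hypergeometric upper-tail P value
#'
#' Probability of drawing at least `k` feature items, the enrichment P value
#' for a pathway containing `k` of the `K` targets among its `n` members in
#' a universe of `N` genes. Computed as the direct log-space sum of the pmf
#' over `i = k .. min(n, K)` (not as one minus the lower tail), which keeps
#' precision for very small P; returns 1 when `k <= max(0, n - N + K)`.
#'
#' @inheritParams hypergeom_pmf
#' @param k Minimum number of feature items, `k >= 0`.
#' @return Upper-tail probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_pvalue(1000, 30, 20, 10)
hypergeom_pvalue <- function(N, K, n, k) {
  check_hyper_args(N, K, n)
  stopifnot(length(k) == 1L, k >= 0)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- seq(max(k, max(0, n - (N - K))), hi)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  # log-sum-exp; the sum is a probability so clamp rounding excursions at 1
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

check_hyper_args <- function(N, K, n) {
  if (!(length(N) == 1L && length(K) == 1L && length(n) == 1L &&
        N >= 0 && K >= 0 && n >= 0 && K <= N && n <= N)) {
    abort("require 0 <= K <= N and 0 <= n <= N")
  }
  invisible(TRUE)
}

#' Hypergeometric pathway enrichment of a target set
#'
#' Tests every pathway for over-representation of the target set. The
#' universe is the union of all pathway members; `K` is the number of
#' targets inside that universe, and for each pathway of size `n` containing
#' `k` targets the upper-tail hypergeometric P value is computed. Pathways
#' are flagged significant at raw `p < alpha` (no multiple-testing
#' correction, matching the original analysis); Benjamini-Hochberg q-values
#' are reported alongside for users who want them.
#'
#' @param targets Character vector of target symbols.
#' @param pathways A `gene_set_collection` (see [read_gmt()]).
#' @param alpha Significance level on the raw P value; default 0.01.
#'
#' @return An `enrichment_result`: a tibble with columns `pathway_id`,
#'   `name`, `n`, `k`, `p_value`, `q_value`, `significant`, sorted by
#'   ascending `p_value` (ties by id). Attributes: `N`, `K`, `alpha`, and
#'   `targets_not_in_universe`.
#' @export
enrich_targets <- function(targets, pathways, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  targets <- unique(toupper(trimws(targets)))
  universe <- set_universe(pathways)
  in_univ <- intersect(targets, universe)
  if (length(in_univ) == 0L) {
    abort("no targets in pathway universe", class = "netpharm_no_targets")
  }
  N <- length(universe)
  K <- length(in_univ)
  rows <- tibble(
    pathway_id = pathways$pathway_id,
    name = pathways$name,
    n = lengths(pathways$members),
    k = vapply(pathways$members, function(m) length(intersect(in_univ, m)), 0L)
  )
  rows$p_value <- vapply(seq_len(nrow(rows)), function(j) {
    hypergeom_pvalue(N, K, rows$n[j], rows$k[j])
  }, 0)
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$p_value < alpha
  rows <- dplyr::arrange(rows, .data$p_value, .data$pathway_id)
  structure(rows, N = N, K = K, alpha = alpha,
            targets_not_in_universe = sort(setdiff(targets, universe)),
            class = c("enrichment_result", class(tibble())))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> N = %d, K = %d, alpha = %g; %d/%d pathways significant\n",
    attr(x, "N"), attr(x, "K"), attr(x, "alpha"), sum(x$significant), nrow(x)))
  NextMethod()
}

#' Write an enrichment result as TSV
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  df <- as.data.frame(result)
  df$p_value <- format_num(df$p_value)
  df$q_value <- format_num(df$q_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
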