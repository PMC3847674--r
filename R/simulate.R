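# Hardy-Weinberg simulator of pooled genotype data, and locus-wise collapsing.

#' Simulate pooled genotype data under Hardy-Weinberg equilibrium
#'
#' Draws n * 2k haplotypes independently from `dist` (all 2nk chromosome
#' copies i.i.d. from the population haplotype distribution), groups them into
#' n pools of k individuals, and records the per-pool, per-locus minor-allele
#' totals -- the quantities a pooled genotyping assay reports.
#'
#' @param dist A [hap_freq] distribution to sample from.
#' @param n Number of pools.
#' @param k Pool size (individuals per pool; each contributes 2 haplotypes).
#' @param seed Optional integer seed; when supplied the dataset is a
#'   deterministic function of (`dist`, `n`, `k`, `seed`) and the caller's RNG
#'   state is left untouched.
#' @param keep_haplotypes If `TRUE`, the latent haplotype draws are retained in
#'   attribute `"haplotypes"` (an n x 2k character matrix) for diagnostics.
#' @return A tibble of class `pooled_data` with column `pool` and integer
#'   columns `locus_1` .. `locus_L` (each entry in 0..2k), and attributes `k`
#'   and `L`.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' simulate_pools(d, n = 5, k = 2, seed = 1)
#' @export
simulate_pools <- function(dist, n, k, seed = NULL, keep_haplotypes = FALSE) {
  dist <- as_hap_freq(dist)
  k <- check_pool_size(k)
  if (length(n) != 1L || n < 1 || n != round(n)) abort("n must be an integer >= 1")
  n <- as.integer(n)
  K <- 2L * k
  draw <- function() sample.int(nrow(dist), n * K, replace = TRUE, prob = dist$freq)
  idx <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  hm <- hap_to_matrix(dist$haplotype)
  pool_of <- rep(seq_len(n), each = K)
  totals <- rowsum(hm[idx, , drop = FALSE], pool_of)
  out <- new_pooled(totals, k = k, collapsed = FALSE)
  if (keep_haplotypes) {
    attr(out, "haplotypes") <- matrix(dist$haplotype[idx], nrow = n, ncol = K,
                                      byrow = TRUE)
  }
  out
}

new_pooled <- function(totals, k, collapsed) {
  totals <- as.matrix(totals)
  storage.mode(totals) <- "integer"
  L <- ncol(totals)
  colnames(totals) <- paste0("locus_", seq_len(L))
  out <- tibble(pool = seq_len(nrow(totals)), as_tibble(totals))
  cls <- if (collapsed) "collapsed_data" else "pooled_data"
  structure(out, k = k, L = L, class = c(cls, class(out)))
}

#' Extract the totals matrix from a pooled or collapsed dataset
#'
#' @param x A `pooled_data` or `collapsed_data` tibble.
#' @return The n x L integer matrix of per-pool totals (0/1 indicators for
#'   collapsed data), without the `pool` column.
#' @export
pooled_totals <- function(x) {
  unname(pooled_matrix(x))
}

# extract the n x L integer matrix from a pooled/collapsed tibble
pooled_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  cols <- grep("^locus_", names(x), value = TRUE)
  if (length(cols) == 0) abort("no locus_* columns found")
  m <- as.matrix(x[, cols])
  storage.mode(m) <- "integer"
  m
}

pooled_k <- function(x) {
  k <- attr(x, "k", exact = TRUE)
  if (is.null(k)) abort("pool size attribute 'k' is missing")
  as.integer(k)
}

validate_pooled <- function(x) {
  m <- pooled_matrix(x)
  k <- pooled_k(x)
  if (any(is.na(m)) || any(m < 0L) || any(m > 2L * k))
    abort(sprintf("pool totals must be integers in 0..%d", 2L * k))
  invisible(x)
}

#' Collapse pooled totals to zero / at-least-one indicators
#'
#' Collapses each per-locus minor-allele total to an indicator of "zero"
#' versus "at least one", as in classical group testing. The distinct rows of
#' the collapsed matrix are the raw material of the internal candidate
#' haplotype list.
#'
#' @param pooled A `pooled_data` tibble from [simulate_pools()] or
#'   [read_pooled()]. Collapsing an already collapsed dataset is a no-op.
#' @return A tibble of class `collapsed_data` with 0/1 entries and the same
#'   layout and attributes as the input.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' collapse_pools(simulate_pools(d, n = 5, k = 2, seed = 1))
#' @export
collapse_pools <- function(pooled) {
  validate_pooled(pooled)
  z <- pooled_matrix(pooled) >= 1L
  storage.mode(z) <- "integer"
  new_pooled(z, k = pooled_k(pooled), collapsed = TRUE)
}
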