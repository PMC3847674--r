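# Collapsed-data maximum likelihood estimation by inclusion-exclusion over
# empirical zero-pattern fractions.

#' Empirical zero fraction of collapsed pools
#'
#' The collapsed-data MLE of g0(Lambda) = P(Z_l = 0, l in Lambda) is the plain
#' fraction n_Z0(Lambda)/n of pools with no minor allele at any locus in
#' `loci` (no smoothing).
#'
#' @param collapsed A `collapsed_data` tibble.
#' @param loci Integer vector of 1-based locus indices (may be empty).
#' @return A probability (exact count ratio).
#' @export
zero_fraction <- function(collapsed, loci) {
  if (!inherits(collapsed, "collapsed_data"))
    abort("expected a collapsed_data object; run collapse_pools() first")
  z <- pooled_matrix(collapsed)
  if (nrow(z) == 0) abort("empty dataset")
  loci <- as.integer(loci)
  if (length(loci) && (any(loci < 1L) || any(loci > ncol(z))))
    abort(sprintf("locus indices must lie in 1..%d", ncol(z)))
  if (length(loci) == 0L) return(1)
  mean(rowSums(z[, loci, drop = FALSE]) == 0L)
}

# Inclusion-exclusion estimate for one target haplotype with variant set
# `ones`: sum over subsets S of ones of (-1)^|S| (n_Z0(zeros U S)/n)^(1/K).
# Rows relevant to any term are those whose support lies inside `ones`;
# such a row is counted in the S-term iff its support avoids S.
cdmle_one <- function(row_supp, ones, n, K, max_ones = 20L) {
  if (length(ones) > max_ones)
    abort(sprintf(
      "haplotype has %d variant alleles; inclusion-exclusion is limited to %d (2^%d subsets)",
      length(ones), max_ones, max_ones))
  keep <- vapply(row_supp, function(s) all(s %in% ones), logical(1))
  supp <- row_supp[keep]
  total <- 0
  for (S in all_subsets(ones)) {
    cnt <- sum(vapply(supp, function(s) !any(s %in% S), logical(1)))
    total <- total + (-1)^length(S) * (cnt / n)^(1 / K)
  }
  total
}

#' Collapsed-data MLE of haplotype frequencies
#'
#' Closed-form estimator of f(y) from collapsed pools, obtained by Mobius
#' inversion of the empirical zero-pattern fractions:
#' f_CD(y) = sum over subsets S of the variant positions of y of
#' (-1)^|S| (n_Z0(zeros(y) U S)/n)^(1/K), with K = 2k. The estimate is
#' positive only for haplotypes coinciding with an observed collapsed row,
#' which is why the observed CD list is the default target set. Sampling
#' noise can push individual raw values negative; these are clipped to zero
#' by default (and counted in the `clipped` attribute). Estimates are
#' reported unnormalized.
#'
#' @param collapsed A `collapsed_data` tibble.
#' @param targets Haplotypes at which to evaluate the estimator: a
#'   `hap_list`, character vector, or `NULL` (default) for the CD list of the
#'   data (ancestral haplotype included).
#' @param clip_negative Replace negative raw values by 0 (default `TRUE`).
#' @param renormalize Rescale clipped estimates to sum to 1 (default `FALSE`,
#'   matching the estimator's definition).
#' @return A tibble with columns `haplotype`, `positions`, `estimate` and
#'   attributes `clipped` (count of negative raw values clipped) and
#'   `g0_ancestral` (the benchmark value `cd_benchmark_f0()` is based on).
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' z <- collapse_pools(simulate_pools(d, n = 50, k = 2, seed = 1))
#' cdmle(z)
#' @export
cdmle <- function(collapsed, targets = NULL, clip_negative = TRUE,
                  renormalize = FALSE) {
  if (!inherits(collapsed, "collapsed_data"))
    abort("expected a collapsed_data object; run collapse_pools() first")
  z <- pooled_matrix(collapsed)
  n <- nrow(z)
  if (n == 0) abort("empty dataset")
  K <- 2L * pooled_k(collapsed)
  if (is.null(targets)) targets <- cd_list(collapsed)
  targets <- as_hap_list(targets)
  if (hap_list_L(targets) != ncol(z))
    abort("target haplotype length does not match the data")
  row_supp <- lapply(seq_len(n), function(i) which(z[i, ] == 1L))
  tm <- hap_to_matrix(targets$haplotype)
  raw <- vapply(seq_len(nrow(tm)), function(i) {
    cdmle_one(row_supp, which(tm[i, ] == 1L), n, K)
  }, numeric(1))
  est <- raw
  clipped <- 0L
  if (clip_negative) {
    clipped <- sum(raw < 0)
    est <- pmax(raw, 0)
  }
  if (renormalize && sum(est) > 0) est <- est / sum(est)
  out <- tibble(haplotype = targets$haplotype,
                positions = hap_positions(targets$haplotype),
                estimate = est)
  attr(out, "raw") <- raw
  attr(out, "clipped") <- clipped
  attr(out, "g0_ancestral") <- zero_fraction(collapsed, seq_len(ncol(z)))
  attr(out, "k") <- pooled_k(collapsed)
  out
}

#' Collapsed-data benchmark estimate of the ancestral frequency
#'
#' The special case of [cdmle()] at the all-zero haplotype,
#' f_CD(0) = (n_Z0(all loci)/n)^(1/2k). It anchors the adaptive trimming
#' threshold: among candidate thresholds, the one whose EM estimate of f(0)
#' lands closest to this benchmark is selected.
#'
#' @param collapsed A `collapsed_data` tibble.
#' @return A probability.
#' @export
cd_benchmark_f0 <- function(collapsed) {
  K <- 2L * pooled_k(collapsed)
  L <- length(grep("^locus_", names(collapsed)))
  zero_fraction(collapsed, seq_len(L))^(1 / K)
}
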