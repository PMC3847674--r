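# Analytic layer: zero-pattern probabilities, the induced collapsed-data
# distribution for a given pool size, the sufficient rarity condition for
# frequency amplification, and capture probabilities for list design.

#' Probability of zero minor alleles at a set of loci
#'
#' For a single haplotype drawn from `dist`, `zero_pattern_prob()` computes
#' f0(Lambda) = P(Y_l = 0 for all l in Lambda), the total frequency of support
#' haplotypes carrying no variant at any locus in `loci`. With pools of `k`
#' individuals (K = 2k independent haplotypes under Hardy-Weinberg
#' equilibrium), the probability that the pooled totals are all zero on those
#' loci is `collapsed_zero_prob()` = f0(Lambda)^K.
#'
#' @param dist A [hap_freq] distribution.
#' @param loci Integer vector of 1-based locus indices (may be empty).
#' @param k Pool size (individuals per pool), so each pool holds 2k haplotypes.
#' @return A probability.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' zero_pattern_prob(d, 1)        # 0.94
#' collapsed_zero_prob(d, 1:2, k = 2)  # 0.9^4
#' @export
zero_pattern_prob <- function(dist, loci) {
  dist <- as_hap_freq(dist)
  L <- hap_freq_L(dist)
  loci <- as.integer(loci)
  if (length(loci) && (any(loci < 1L) || any(loci > L)))
    abort(sprintf("locus indices must lie in 1..%d", L))
  if (length(loci) == 0L) return(1)
  m <- hap_to_matrix(dist$haplotype)
  sum(dist$freq[rowSums(m[, loci, drop = FALSE]) == 0L])
}

#' @rdname zero_pattern_prob
#' @export
collapsed_zero_prob <- function(dist, loci, k) {
  check_pool_size(k)
  zero_pattern_prob(dist, loci)^(2L * as.integer(k))
}

check_pool_size <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    abort("pool size k must be a single integer >= 1")
  invisible(as.integer(k))
}

# inclusion-exclusion core: g(y) = sum_{S subset of ones(y)} (-1)^|S| f0(zeros(y) U S)^K
# f0 over augmented patterns is evaluated by restriction: a support haplotype h
# contributes to f0(zeros(y) U S) iff supp(h) is a subset of ones(y) and
# supp(h) avoids S.
collapsed_mass_one <- function(hsupp, hfreq, ones, K, max_ones = 25L) {
  m <- length(ones)
  if (m > max_ones)
    abort(sprintf(
      "haplotype has %d variant alleles; subset enumeration is limited to %d",
      m, max_ones))
  keep <- vapply(hsupp, function(s) all(s %in% ones), logical(1))
  supp <- hsupp[keep]
  fr <- hfreq[keep]
  total <- 0
  for (S in all_subsets(ones)) {
    f0 <- sum(fr[vapply(supp, function(s) !any(s %in% S), logical(1))])
    total <- total + (-1)^length(S) * f0^K
  }
  total
}

#' Induced collapsed-data haplotype frequencies
#'
#' When pools of `k` individuals are collapsed locus-wise to indicators of
#' "zero" versus "at least one" minor allele, the collapsed vector Z of a pool
#' follows an induced distribution g over haplotype patterns. `collapsed_freq()`
#' evaluates g(y) by inclusion-exclusion over subsets S of the variant
#' positions of y: g(y) = sum_S (-1)^|S| f0(zeros(y) U S)^(2k). Pooling and
#' collapsing redistributes mass away from the ancestral haplotype
#' (g(0) = f(0)^(2k)) and amplifies the frequencies of rare non-ancestral
#' haplotypes, which is what makes the collapsed rows a useful internal
#' candidate list.
#'
#' @inheritParams zero_pattern_prob
#' @param haplotypes 0/1 strings at which to evaluate g; defaults to the
#'   support of `dist`.
#' @return A tibble with columns `haplotype`, `positions` (variant-position
#'   notation) and `g`.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' collapsed_freq(d, k = 2)
#' @export
collapsed_freq <- function(dist, k, haplotypes = NULL) {
  dist <- as_hap_freq(dist)
  k <- check_pool_size(k)
  L <- hap_freq_L(dist)
  if (is.null(haplotypes)) haplotypes <- dist$haplotype
  hap_validate_strings(haplotypes, L)
  K <- 2L * k
  hm <- hap_to_matrix(dist$haplotype)
  hsupp <- lapply(seq_len(nrow(hm)), function(i) which(hm[i, ] == 1L))
  qm <- hap_to_matrix(haplotypes)
  g <- vapply(seq_len(nrow(qm)), function(i) {
    collapsed_mass_one(hsupp, dist$freq, which(qm[i, ] == 1L), K)
  }, numeric(1))
  tibble(haplotype = haplotypes, positions = hap_positions(haplotypes), g = g)
}

#' @rdname collapsed_freq
#' @param haplotype A single 0/1 string.
#' @export
collapsed_mass <- function(dist, haplotype, k) {
  stopifnot(length(haplotype) == 1L)
  collapsed_freq(dist, k, haplotypes = haplotype)$g
}

#' Rarity condition for collapsed-data frequency amplification
#'
#' For a non-ancestral haplotype y with f(y) > 0, collapsing pooled data
#' increases its apparent frequency (g(y) > f(y)) whenever the ancestral
#' frequency satisfies f(0) > (1/(2k))^(1/(2k-1)). `lemma1_threshold()` returns
#' that lower threshold on f(0); it is strictly increasing in the pool size k.
#'
#' @param k Pool size(s); vectorized.
#' @return Threshold value(s) in (0, 1).
#' @examples
#' lemma1_threshold(1:5)
#' @export
lemma1_threshold <- function(k) {
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k)))
    abort("pool size k must be integer >= 1")
  K <- 2 * k
  (1 / K)^(1 / (K - 1))
}

#' Capture probability of a haplotype by the collapsed-data list
#'
#' The CD list built from n pools captures a haplotype whose induced
#' collapsed-data frequency is g with probability 1 - (1 - g)^n, approximately
#' 1 - exp(-n g) for small g (Poisson approximation). `min_pools_for_capture()`
#' inverts the Poisson form: the smallest n with capture probability at least
#' 1 - epsilon, i.e. n >= -log(epsilon)/g.
#'
#' @param g Induced collapsed-data frequency (probability), vectorized.
#' @param n Number of pools.
#' @param method `"exact"` or `"poisson"`.
#' @param epsilon Allowed miss probability, in (0, 1).
#' @return `capture_prob()`: probability; `min_pools_for_capture()`: integer.
#' @examples
#' capture_prob(0.0097, 200)                       # 0.8577
#' capture_prob(0.0097, 200, method = "poisson")   # 0.8563
#' min_pools_for_capture(0.01, exp(-2))            # 200
#' @export
capture_prob <- function(g, n, method = c("exact", "poisson")) {
  method <- match.arg(method)
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    abort("g must lie in [0, 1]")
  if (any(n < 1)) abort("n must be >= 1")
  switch(method,
    exact = 1 - (1 - g)^n,
    poisson = 1 - exp(-n * g)
  )
}

#' @rdname capture_prob
#' @export
min_pools_for_capture <- function(g, epsilon) {
  if (any(g <= 0)) abort("g must be positive to reach a capture target")
  if (any(epsilon <= 0) || any(epsilon >= 1)) abort("epsilon must be in (0, 1)")
  n <- ceiling(-log(epsilon) / g)
  # guard against a ceiling landing one short through floating error
  n <- ifelse(1 - exp(-(n - 1) * g) >= 1 - epsilon - 1e-12, n - 1, n)
  pmax(as.integer(n), 1L)
}
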