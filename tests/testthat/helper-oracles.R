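# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: ordered-tuple enumeration and
# direct formula evaluation only.

# random sparse haplotype distribution on L loci
rand_dist <- function(L, n_support, seed, f0 = NULL) {
  withr::with_seed(seed, {
    all_haps <- apply(expand.grid(rep(list(0:1), L)), 1, paste0, collapse = "")
    anc <- paste(rep("0", L), collapse = "")
    others <- sample(setdiff(all_haps, anc), n_support - 1)
    w <- stats::runif(n_support - 1)
    if (is.null(f0)) f0 <- stats::runif(1, 0.3, 0.9)
    hap_freq(c(anc, others), c(f0, (1 - f0) * w / sum(w)))
  })
}

# ordered K-tuple enumeration of the induced collapsed-data mass g(y)
oracle_collapsed_mass <- function(dist, y, K) {
  hm <- matrix(as.integer(unlist(strsplit(dist$haplotype, ""))),
               nrow = nrow(dist), byrow = TRUE)
  yv <- as.integer(strsplit(y, "")[[1]])
  idx <- expand.grid(rep(list(seq_len(nrow(dist))), K))
  total <- 0
  for (r in seq_len(nrow(idx))) {
    tup <- as.integer(idx[r, ])
    z <- as.integer(colSums(hm[tup, , drop = FALSE]) >= 1)
    if (all(z == yv)) total <- total + prod(dist$freq[tup])
  }
  total
}

# direct inclusion-exclusion evaluation of the collapsed-data MLE at y
oracle_cdmle <- function(zmat, y, K) {
  yv <- as.integer(strsplit(y, "")[[1]])
  ones <- which(yv == 1)
  zeros <- which(yv == 0)
  n <- nrow(zmat)
  subsets <- list(integer(0))
  for (e in ones) subsets <- c(subsets, lapply(subsets, function(s) c(s, e)))
  total <- 0
  for (S in subsets) {
    cols <- c(zeros, S)
    cnt <- if (length(cols) == 0) n else
      sum(rowSums(zmat[, cols, drop = FALSE]) == 0)
    total <- total + (-1)^length(S) * (cnt / n)^(1 / K)
  }
  total
}

# all multisets of K list rows summing to `total`, via ordered tuples
oracle_configs <- function(total, haps, K) {
  hm <- matrix(as.integer(unlist(strsplit(haps, ""))),
               nrow = length(haps), byrow = TRUE)
  idx <- expand.grid(rep(list(seq_along(haps)), K))
  seen <- character(0)
  out <- list()
  for (r in seq_len(nrow(idx))) {
    tup <- as.integer(idx[r, ])
    if (all(colSums(hm[tup, , drop = FALSE]) == total)) {
      cnt <- tabulate(tup, nbins = length(haps))
      key <- paste(cnt, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- cnt
      }
    }
  }
  if (length(out) == 0) return(matrix(0L, 0, length(haps)))
  do.call(rbind, out)
}

# independent genotype-data (K = 2) EM over an explicit candidate set:
# classical two-haplotype-resolution EM written directly on ordered pairs
oracle_genotype_em <- function(genotypes, haps, iter = 500) {
  hm <- matrix(as.integer(unlist(strsplit(haps, ""))),
               nrow = length(haps), byrow = TRUE)
  r <- length(haps)
  pairs <- expand.grid(a = seq_len(r), b = seq_len(r))
  f <- rep(1 / r, r)
  for (t in seq_len(iter)) {
    m <- rep(0, r)
    for (i in seq_len(nrow(genotypes))) {
      ok <- which(apply(pairs, 1, function(p)
        all(hm[p[1], ] + hm[p[2], ] == genotypes[i, ])))
      w <- f[pairs$a[ok]] * f[pairs$b[ok]]
      w <- w / sum(w)
      for (j in seq_along(ok)) {
        m[pairs$a[ok[j]]] <- m[pairs$a[ok[j]]] + w[j]
        m[pairs$b[ok[j]]] <- m[pairs$b[ok[j]]] + w[j]
      }
    }
    f <- m / (2 * nrow(genotypes))
  }
  stats::setNames(f, haps)
}

anc_of <- function(L) paste(rep("0", L), collapse = "")

est_of <- function(fit, hap) {
  j <- match(hap, fit$estimates$haplotype)
  if (is.na(j)) 0 else fit$estimates$estimate[j]
}
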