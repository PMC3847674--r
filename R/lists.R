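# Candidate haplotype lists: the collapsed-data (CD) list, single-variant
# augmentation, the perfect list, and union lists for hybrid workflows.

#' Candidate haplotype lists
#'
#' A `hap_list` is a tibble with columns `haplotype` (distinct 0/1 strings of
#' equal length) and `provenance` (one of `"cd"`, `"augmented"`, `"external"`,
#' `"protected"`), ordered with the ancestral haplotype first and then
#' lexicographically so downstream EM runs are deterministic. Members tagged
#' `"protected"` are never removed by trimming.
#'
#' @param haplotype Character vector of 0/1 strings.
#' @param provenance Provenance tag per member (recycled).
#' @return A tibble of class `hap_list` with attribute `L`.
#' @examples
#' hap_list(c("000", "110"))
#' @export
hap_list <- function(haplotype, provenance = "external") {
  L <- hap_validate_strings(haplotype)
  if (anyDuplicated(haplotype)) abort("list members must be distinct")
  provenance <- rep_len(as.character(provenance), length(haplotype))
  ok <- provenance %in% c("cd", "augmented", "external", "protected")
  if (!all(ok)) abort("unknown provenance tag")
  ord <- order(haplotype)
  out <- tibble(haplotype = haplotype[ord], provenance = provenance[ord])
  structure(out, L = L, class = c("hap_list", class(out)))
}

hap_list_L <- function(x) {
  L <- attr(x, "L", exact = TRUE)
  if (is.null(L)) L <- nchar(x$haplotype[1])
  L
}

as_hap_list <- function(x) {
  if (inherits(x, "hap_list")) return(x)
  if (is.character(x)) return(hap_list(x))
  stopifnot(is.data.frame(x), "haplotype" %in% names(x))
  hap_list(x$haplotype,
           if ("provenance" %in% names(x)) x$provenance else "external")
}

#' Build the collapsed-data (CD) candidate list
#'
#' The CD list consists of the distinct collapsed rows observed across pools:
#' for rare variants these patterns capture true haplotypes with amplified
#' probability (see [collapsed_freq()] and [lemma1_threshold()]). The
#' ancestral all-zero haplotype is force-included (tagged `"protected"`) by
#' default because the adaptive trimming rule benchmarks on an estimate of
#' f(0); for rare variants an all-zero pool is nearly always observed anyway.
#'
#' @param collapsed A `collapsed_data` tibble (see [collapse_pools()]).
#' @param include_ancestral Force-include the all-zero haplotype.
#' @return A `hap_list`.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' cd_list(collapse_pools(simulate_pools(d, n = 20, k = 2, seed = 1)))
#' @export
cd_list <- function(collapsed, include_ancestral = TRUE) {
  if (!inherits(collapsed, "collapsed_data"))
    abort("expected a collapsed_data object; run collapse_pools() first")
  z <- pooled_matrix(collapsed)
  haps <- unique(matrix_to_hap(z))
  anc <- ancestral_hap(ncol(z))
  prov <- rep("cd", length(haps))
  if (include_ancestral && !(anc %in% haps)) {
    haps <- c(anc, haps)
    prov <- c("protected", prov)
  }
  prov[haps == anc] <- "protected"
  hap_list(haps, prov)
}

#' Augment a list with all single-variant haplotypes
#'
#' Adds every unit haplotype (exactly one minor allele) not already present,
#' tagged `"augmented"` -- at most L additions. Rare-variant haplotypes with a
#' single '1' are the ones most plausibly present in the population yet missed
#' by the CD list, which motivates this augmentation before trimming.
#'
#' @param x A `hap_list` (or coercible).
#' @return A `hap_list` containing `x` plus the missing unit haplotypes.
#' @examples
#' augment_singletons(hap_list(c("000", "110")))
#' @export
augment_singletons <- function(x) {
  x <- as_hap_list(x)
  L <- hap_list_L(x)
  units <- hap_from_positions(as.list(seq_len(L)), L)
  add <- setdiff(units, x$haplotype)
  if (length(add) == 0) return(x)
  hap_list(c(x$haplotype, add), c(x$provenance, rep("augmented", length(add))))
}

#' Perfect list: the true support of a distribution
#'
#' Returns the haplotypes with positive frequency in `dist`. An EM run on
#' this list is the infeasible-in-practice gold standard (it presumes knowing
#' exactly which haplotypes exist).
#'
#' @param dist A [hap_freq] distribution.
#' @return A `hap_list` tagged `"external"` (ancestral member `"protected"`).
#' @export
perfect_list <- function(dist) {
  dist <- as_hap_freq(dist)
  haps <- dist$haplotype[dist$freq > 0]
  prov <- rep("external", length(haps))
  prov[haps == ancestral_hap(hap_freq_L(dist))] <- "protected"
  hap_list(haps, prov)
}

#' Union of two candidate lists
#'
#' Set union preserving provenance; where both lists contain a member, the
#' first list's tag wins (with `"protected"` dominating either way). Useful
#' for hybrid designs combining an external database list with the internal
#' CD list before augmenting and trimming.
#'
#' @param a,b `hap_list` objects over the same locus count.
#' @return A `hap_list`.
#' @export
union_lists <- function(a, b) {
  a <- as_hap_list(a); b <- as_hap_list(b)
  if (hap_list_L(a) != hap_list_L(b)) abort("lists have different locus counts")
  haps <- c(a$haplotype, setdiff(b$haplotype, a$haplotype))
  prov <- c(a$provenance, b$provenance[match(setdiff(b$haplotype, a$haplotype),
                                             b$haplotype)])
  prot <- union(a$haplotype[a$provenance == "protected"],
                b$haplotype[b$provenance == "protected"])
  prov[haps %in% prot] <- "protected"
  hap_list(haps, prov)
}
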