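#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# ---- internal haplotype string helpers ------------------------------------
# Haplotypes are serialized as 0/1 strings ("0100..."); internally we work
# with integer 0/1 matrices (rows = haplotypes). Locus indexing is 1-based
# everywhere a user sees it.

hap_validate_strings <- function(haplotype, L = NULL) {
  if (length(haplotype) == 0) abort("need at least one haplotype")
  if (!is.character(haplotype)) abort("haplotypes must be 0/1 strings")
  lens <- nchar(haplotype)
  if (length(unique(lens)) != 1L)
    abort("all haplotype strings must have the same length")
  if (!is.null(L) && lens[1] != L)
    abort(sprintf("haplotype length %d does not match L = %d", lens[1], L))
  if (any(grepl("[^01]", haplotype)))
    abort("haplotype strings may contain only '0' and '1'")
  invisible(lens[1])
}

hap_to_matrix <- function(haplotype) {
  L <- hap_validate_strings(haplotype)
  m <- matrix(
    as.integer(unlist(strsplit(haplotype, "", fixed = TRUE), use.names = FALSE)),
    nrow = length(haplotype), ncol = L, byrow = TRUE
  )
  m
}

matrix_to_hap <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

ancestral_hap <- function(L) strcollapse(rep("0", L))

strcollapse <- function(x) paste0(x, collapse = "")

#' Convert between 0/1 haplotype strings and variant-position notation
#'
#' Reports render haplotypes the way the field's tables do, as the 1-based
#' positions of the minor ('1') alleles; `hap_positions()` produces that
#' notation and `hap_from_positions()` inverts it.
#'
#' @param haplotype Character vector of 0/1 strings.
#' @param positions List of integer vectors of 1-based variant positions
#'   (empty vector = ancestral haplotype).
#' @param L Locus count for the output strings.
#' @return `hap_positions()`: a character vector like `"None"`, `"1, 3"`;
#'   `hap_from_positions()`: a character vector of 0/1 strings.
#' @examples
#' hap_positions(c("0000", "1010"))
#' hap_from_positions(list(integer(0), c(1, 3)), L = 4)
#' @export
hap_positions <- function(haplotype) {
  m <- hap_to_matrix(haplotype)
  vapply(seq_len(nrow(m)), function(i) {
    p <- which(m[i, ] == 1L)
    if (length(p) == 0) "None" else paste(p, collapse = ", ")
  }, character(1))
}

#' @rdname hap_positions
#' @export
hap_from_positions <- function(positions, L) {
  stopifnot(is.list(positions), L >= 1)
  vapply(positions, function(p) {
    v <- rep("0", L)
    if (length(p)) {
      p <- as.integer(p)
      if (any(p < 1 | p > L)) abort("variant position out of range")
      v[p] <- "1"
    }
    strcollapse(v)
  }, character(1))
}

# enumerate all subsets of an index vector as a list (safe for length 0/1)
all_subsets <- function(x) {
  out <- list(integer(0))
  for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
  out
}

# ---- haplotype frequency distributions ------------------------------------

#' Haplotype frequency distributions
#'
#' A `hap_freq` object is a tibble with columns `haplotype` (0/1 string, one
#' chromosome copy across L bi-allelic loci; 1 = minor/variant allele) and
#' `freq`, describing a probability distribution over haplotypes. Published
#' frequency tables are typically rounded, so by default frequencies summing
#' to 1 within `tol` are renormalized to sum exactly to 1.
#'
#' @param haplotype Character vector of distinct 0/1 strings of equal length.
#' @param freq Non-negative frequencies, one per haplotype.
#' @param renormalize If `TRUE` (default), rescale `freq` to sum to 1 provided
#'   the raw sum is within `tol` of 1; if `FALSE`, the raw sum must be within
#'   `1e-6` of 1.
#' @param tol Tolerance on the raw frequency sum when renormalizing.
#' @return A tibble of class `hap_freq` with attribute `L` (locus count),
#'   sorted so the ancestral (all-zero) haplotype, if present, comes first,
#'   then lexicographically.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' attr(d, "L")
#' @export
hap_freq <- function(haplotype, freq, renormalize = TRUE, tol = 1e-3) {
  L <- hap_validate_strings(haplotype)
  if (length(freq) != length(haplotype))
    abort("haplotype and freq must have the same length")
  if (anyDuplicated(haplotype)) abort("support haplotypes must be distinct")
  if (any(!is.finite(freq)) || any(freq < 0))
    abort("frequencies must be finite and non-negative")
  s <- sum(freq)
  if (renormalize) {
    if (abs(s - 1) > tol)
      abort(sprintf("frequencies sum to %.6f, outside renormalization tolerance %g", s, tol))
    freq <- freq / s
  } else if (abs(s - 1) > 1e-6) {
    abort(sprintf("frequencies sum to %.6f (renormalize is off)", s))
  }
  ord <- order(haplotype)
  out <- tibble(haplotype = haplotype[ord], freq = freq[ord])
  structure(out, L = L, class = c("hap_freq", class(out)))
}

hap_freq_L <- function(dist) {
  L <- attr(dist, "L", exact = TRUE)
  if (is.null(L)) L <- nchar(dist$haplotype[1])
  L
}

as_hap_freq <- function(x, renormalize = TRUE, tol = 1e-3) {
  if (inherits(x, "hap_freq")) return(x)
  stopifnot(is.data.frame(x), all(c("haplotype", "freq") %in% names(x)))
  hap_freq(x$haplotype, x$freq, renormalize = renormalize, tol = tol)
}

#' @export
print.hap_freq <- function(x, ...) {
  cat(sprintf("# Haplotype distribution: %d haplotypes, %d loci\n",
              nrow(x), hap_freq_L(x)))
  NextMethod()
}
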