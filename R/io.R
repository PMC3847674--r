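# TSV readers/writers for the package's three table dialects, plus the
# bundled example distributions.

read_tsv_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2) abort(sprintf("no data rows in %s", path))
  tbl <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character", check.names = FALSE)
  list(meta = meta, tbl = as_tibble(tbl))
}

meta_value <- function(meta, key) {
  hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
  if (length(hit) == 0) return(NULL)
  trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1]))
}

#' Read and write haplotype frequency tables
#'
#' Tab-separated with a header and columns `haplotype` (0/1 string) and
#' `freq`; lines starting with `#` are comments. Writers and readers
#' round-trip exactly.
#'
#' @param path File path.
#' @param renormalize,tol Passed to [hap_freq()].
#' @param x A [hap_freq] distribution.
#' @return `read_hap_freq()`: a [hap_freq]; `write_hap_freq()`: `path`,
#'   invisibly.
#' @export
read_hap_freq <- function(path, renormalize = TRUE, tol = 1e-3) {
  b <- read_tsv_body(path)
  if (!all(c("haplotype", "freq") %in% names(b$tbl)))
    abort(sprintf("%s must have 'haplotype' and 'freq' columns", path))
  freq <- suppressWarnings(as.numeric(b$tbl$freq))
  if (any(is.na(freq))) abort("non-numeric frequencies")
  hap_freq(b$tbl$haplotype, freq, renormalize = renormalize, tol = tol)
}

#' @rdname read_hap_freq
#' @export
write_hap_freq <- function(x, path) {
  x <- as_hap_freq(x)
  readr::write_tsv(tibble(haplotype = x$haplotype,
                          freq = format(x$freq, digits = 17)), path)
  invisible(path)
}

#' Read and write pooled (or collapsed) datasets
#'
#' Tab-separated with header `pool`, `locus_1` .. `locus_L`; the pool size is
#' recorded in a `# k=<int>` metadata line and collapsed data carry
#' `# collapsed=true`. Entries must be integers in 0..2k (0/1 when
#' collapsed).
#'
#' @param path File path.
#' @param x A `pooled_data` or `collapsed_data` tibble.
#' @return `read_pooled()`: a `pooled_data`/`collapsed_data` tibble;
#'   `write_pooled()`: `path`, invisibly.
#' @export
read_pooled <- function(path) {
  b <- read_tsv_body(path)
  k <- meta_value(b$meta, "k")
  if (is.null(k)) abort(sprintf("%s is missing the '# k=<int>' metadata line", path))
  k <- check_pool_size(as.numeric(k))
  collapsed <- identical(tolower(meta_value(b$meta, "collapsed") %||% "false"),
                         "true")
  cols <- grep("^locus_", names(b$tbl), value = TRUE)
  if (length(cols) == 0) abort("no locus_* columns found")
  m <- as.matrix(b$tbl[, cols])
  num <- suppressWarnings(as.numeric(m))
  if (any(is.na(num)) || any(num != round(num)))
    abort("pool totals must be integers")
  m <- matrix(as.integer(num), nrow = nrow(b$tbl))
  if (any(m < 0L) || any(m > 2L * k))
    abort(sprintf("pool totals must lie in 0..%d", 2L * k))
  if (collapsed && any(m > 1L)) abort("collapsed data must be 0/1")
  new_pooled(m, k = k, collapsed = collapsed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pooled
#' @export
write_pooled <- function(x, path) {
  validate_pooled(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d", pooled_k(x)), con)
  if (inherits(x, "collapsed_data")) writeLines("# collapsed=true", con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write candidate haplotype lists
#'
#' Tab-separated with a `haplotype` column and an optional `provenance`
#' column (defaulting to `"external"` on read).
#'
#' @param path File path.
#' @param x A [hap_list].
#' @return `read_hap_list()`: a [hap_list]; `write_hap_list()`: `path`,
#'   invisibly.
#' @export
read_hap_list <- function(path) {
  b <- read_tsv_body(path)
  if (!("haplotype" %in% names(b$tbl)))
    abort(sprintf("%s must have a 'haplotype' column", path))
  prov <- if ("provenance" %in% names(b$tbl)) b$tbl$provenance else "external"
  hap_list(b$tbl$haplotype, prov)
}

#' @rdname read_hap_list
#' @export
write_hap_list <- function(x, path) {
  x <- as_hap_list(x)
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Bundled example haplotype distributions
#'
#' Two rare-variant haplotype distributions ship with the package and drive
#' its examples and simulation studies: `"mgll25"`, 22 haplotypes over 25
#' loci in a region enriched in rare variants near the MGLL gene
#' (ancestral frequency 0.7995), and `"faah32"`, 32 haplotypes over 32 loci
#' near the FAAH gene (ancestral frequency 0.7113). Both are population
#' haplotype distributions estimated from the re-sequenced cases of an
#' obesity cohort and are used here as known truths for simulation.
#'
#' @param name `"mgll25"` or `"faah32"`.
#' @return `hap_example_path()`: path to the TSV; `hap_example()`: the
#'   [hap_freq] distribution.
#' @examples
#' hap_example("mgll25")
#' @export
hap_example <- function(name = c("mgll25", "faah32")) {
  read_hap_freq(hap_example_path(name))
}

#' @rdname hap_example
#' @export
hap_example_path <- function(name = c("mgll25", "faah32")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, "_true.tsv"), package = "haplopool",
              mustWork = TRUE)
}
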