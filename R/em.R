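# EM-with-a-list machinery: exact enumeration of within-pool haplotype
# configurations compatible with each observed total, vectorized E/M steps,
# per-iteration trimming with feasibility protection, and adaptive threshold
# selection benchmarked against the collapsed-data estimate of f(0).

#' EM control parameters
#'
#' @param tol Convergence tolerance: maximum absolute frequency change
#'   between successive iterations.
#' @param max_iter Iteration cap.
#' @param grid Trimming thresholds tried by the adaptive rule (ascending).
#' @param init `"uniform"` (default; reproducible and list-agnostic) or
#'   `"cdmle"` (start from clipped collapsed-data estimates, floored to keep
#'   all list members initially positive).
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol = 1e-6, max_iter = 2000L,
                       grid = seq(1e-4, 2e-3, by = 1e-4),
                       init = c("uniform", "cdmle")) {
  stopifnot(tol > 0, max_iter >= 1, length(grid) >= 1,
            all(grid > 0), all(grid < 1))
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 grid = sort(as.numeric(grid)), init = match.arg(init)),
            class = "em_control")
}

# ---- configuration enumeration --------------------------------------------

# All multisets of K rows of Rmat (with repetition) whose componentwise sum
# equals `total`. Depth-first search over members ordered by decreasing
# number of '1's (ancestral last), pruning on residual coverage. Returns an
# integer matrix (configurations x nrow(Rmat)); zero rows if infeasible.
enumerate_multisets <- function(total, Rmat, K) {
  r <- nrow(Rmat)
  L <- ncol(Rmat)
  stopifnot(length(total) == L)
  total <- as.integer(total)
  if (any(total < 0L) || any(total > K))
    abort("pool totals must lie in 0..K")
  compat <- which(apply(Rmat, 1L, function(h) all(h[total == 0L] == 0L)))
  out <- matrix(0L, 0L, r)
  if (length(compat) == 0L) return(out)
  ones_ct <- rowSums(Rmat[compat, , drop = FALSE])
  ordc <- compat[order(ones_ct, decreasing = TRUE)]
  M <- Rmat[ordc, , drop = FALSE]
  nc <- length(ordc)
  # suffix coverage: which loci can still receive a '1' from members i..nc
  suffix_cover <- matrix(FALSE, nc + 1L, L)
  for (i in nc:1) suffix_cover[i, ] <- suffix_cover[i + 1L, ] | (M[i, ] == 1L)
  acc <- vector("list", 64L); n_acc <- 0L
  counts <- integer(nc)
  dfs <- function(i, remaining, slots) {
    if (slots == 0L) {
      if (all(remaining == 0L)) {
        n_acc <<- n_acc + 1L
        if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
        acc[[n_acc]] <<- counts
      }
      return(invisible())
    }
    if (i > nc) return(invisible())
    pos <- remaining > 0L
    if (any(remaining > slots) || any(pos & !suffix_cover[i, ]))
      return(invisible())
    o <- which(M[i, ] == 1L)
    cmax <- if (length(o)) min(slots, min(remaining[o])) else slots
    for (cc in cmax:0L) {
      counts[i] <<- cc
      rem2 <- remaining
      if (length(o)) rem2[o] <- rem2[o] - cc
      dfs(i + 1L, rem2, slots - cc)
    }
    counts[i] <<- 0L
    invisible()
  }
  dfs(1L, total, as.integer(K))
  if (n_acc == 0L) return(out)
  cfg <- do.call(rbind, acc[seq_len(n_acc)])
  out <- matrix(0L, nrow(cfg), r)
  out[, ordc] <- cfg
  out
}

# Shared configuration system for one dataset + list: configurations for all
# distinct observed totals stacked into one matrix so each E-step is a single
# matrix product. Enumeration is done once and reused across trimming steps
# and across adaptive-threshold grid values (trimming only filters rows and
# columns), which is contract-identical to re-enumerating per reduced list.
config_system <- function(totals, Rmat, K) {
  n <- nrow(totals)
  key <- apply(totals, 1L, paste0, collapse = ",")
  uk <- unique(key)
  gidx <- match(key, uk)
  tw <- tabulate(gidx, nbins = length(uk))
  first <- match(uk, key)
  cfgs <- lapply(first, function(i) enumerate_multisets(totals[i, ], Rmat, K))
  feasible <- vapply(cfgs, nrow, integer(1)) > 0L
  bad_pools <- which(gidx %in% which(!feasible))
  keep_g <- which(feasible)
  if (length(keep_g) == 0L) {
    return(list(C = matrix(0L, 0L, nrow(Rmat)), logcoef = numeric(0),
                group = integer(0), tw = integer(0), G = 0L,
                K = K, n_eff = 0L, bad_pools = bad_pools))
  }
  cfgs <- cfgs[keep_g]
  C <- do.call(rbind, cfgs)
  group <- rep(seq_along(keep_g), vapply(cfgs, nrow, integer(1)))
  logcoef <- lgamma(K + 1) - rowSums(lgamma(C + 1))
  list(C = C, logcoef = logcoef, group = group, tw = tw[keep_g],
       G = length(keep_g), K = K, n_eff = sum(tw[keep_g]),
       bad_pools = bad_pools)
}

# drop list members (logical keep vector over columns of sys$C), retaining
# only configurations that avoid removed members; groups must stay covered.
filter_sys <- function(sys, keep) {
  if (all(keep)) return(sys)
  uses_removed <- rowSums(sys$C[, !keep, drop = FALSE]) > 0L
  ok <- !uses_removed
  sys$C <- sys$C[ok, keep, drop = FALSE]
  sys$logcoef <- sys$logcoef[ok]
  sys$group <- sys$group[ok]
  sys
}

groups_covered <- function(sys) {
  length(unique(sys$group)) == sys$G
}

# one E + M step; returns updated frequencies, log-likelihood, and expected
# counts (which sum to n_eff * K exactly)
em_iterate <- function(sys, f) {
  logf <- ifelse(f > 0, log(f), -1e6)
  w <- exp(sys$logcoef + drop(sys$C %*% logf))
  gs <- as.vector(rowsum(w, sys$group))
  ll <- sum(sys$tw * log(gs))
  wt <- w * (sys$tw / gs)[sys$group]
  m <- drop(crossprod(sys$C, wt))
  list(f = m / (sys$n_eff * sys$K), loglik = ll, counts = m)
}

init_freqs <- function(control, members, collapsed) {
  r <- length(members)
  if (control$init == "uniform" || is.null(collapsed)) return(rep(1 / r, r))
  tbl <- cdmle(collapsed, targets = hap_list(members))
  est <- tbl$estimate[match(members, tbl$haplotype)]
  est <- est + 1e-4  # floor keeps every member reachable
  est / sum(est)
}

# ---- low-level exported steps ---------------------------------------------

#' Enumerate within-pool haplotype configurations
#'
#' Finds every multiset of 2k list members whose componentwise sum equals the
#' observed pool total -- the latent configurations the E-step averages over.
#' Enumeration is exact and complete; the empty result signals an infeasible
#' total under the list.
#'
#' @param total Integer vector of per-locus minor-allele totals for one pool.
#' @param list A `hap_list` (or character vector of 0/1 strings).
#' @param k Pool size.
#' @return Integer matrix with one row per configuration and one column per
#'   list member (column names are the haplotype strings); entries are the
#'   multiplicities, each row summing to 2k.
#' @examples
#' enumerate_configurations(c(1, 1), c("00", "10", "01", "11"), k = 1)
#' @export
enumerate_configurations <- function(total, list, k) {
  list <- as_hap_list(list)
  k <- check_pool_size(k)
  Rmat <- hap_to_matrix(list$haplotype)
  out <- enumerate_multisets(total, Rmat, 2L * k)
  colnames(out) <- list$haplotype
  out
}

resolve_freqs <- function(freqs, members) {
  if (is.data.frame(freqs)) {
    stopifnot(all(c("haplotype", "freq") %in% names(freqs)))
    freqs <- stats::setNames(freqs$freq, freqs$haplotype)
  }
  if (!is.null(names(freqs))) {
    miss <- setdiff(members, names(freqs))
    if (length(miss)) abort("freqs missing for some list members")
    freqs <- unname(freqs[members])
  } else if (length(freqs) != length(members)) {
    abort("freqs must be named or aligned with the list")
  }
  if (any(freqs < 0) || sum(freqs) > 1 + 1e-8)
    abort("freqs must be non-negative with sum <= 1")
  freqs
}

#' Likelihood of one pool total under a restricted list
#'
#' P(T = total) = sum over compatible configurations of the multinomial
#' weight (2k)!/prod(c_y!) * prod f(y)^(c_y); zero iff no configuration
#' exists.
#'
#' @inheritParams enumerate_configurations
#' @param freqs Frequencies on the list: a named numeric vector, a
#'   `data.frame` with `haplotype`/`freq` columns, or a numeric vector in
#'   list order.
#' @return A probability.
#' @export
pool_likelihood <- function(total, list, freqs, k) {
  list <- as_hap_list(list)
  f <- resolve_freqs(freqs, list$haplotype)
  cfg <- enumerate_configurations(total, list, k)
  if (nrow(cfg) == 0L) return(0)
  logf <- ifelse(f > 0, log(f), -1e6)
  K <- 2L * check_pool_size(k)
  sum(exp(lgamma(K + 1) - rowSums(lgamma(cfg + 1)) + drop(cfg %*% logf)))
}

#' One E-step: expected haplotype counts given pool totals
#'
#' Conditional expectation of the latent haplotype counts m(y) given the
#' observed totals and current frequencies, restricted to the list. Counts
#' are conserved: they sum to (number of pools) * 2k.
#'
#' @param pooled A `pooled_data` tibble.
#' @inheritParams pool_likelihood
#' @return Named numeric vector of expected counts per list member.
#' @export
e_step <- function(pooled, list, freqs) {
  validate_pooled(pooled)
  list <- as_hap_list(list)
  f <- resolve_freqs(freqs, list$haplotype)
  k <- pooled_k(pooled)
  sys <- config_system(pooled_matrix(pooled), hap_to_matrix(list$haplotype),
                       2L * k)
  if (length(sys$bad_pools))
    abort(paste0("pool total(s) infeasible under the list: pools ",
                 paste(sys$bad_pools, collapse = ", ")))
  stats::setNames(em_iterate(sys, f)$counts, list$haplotype)
}

#' One M-step: complete-data frequency update
#'
#' The multinomial M-step in closed form: f(y) = m(y) / (n * 2k).
#'
#' @param counts Expected haplotype counts (from [e_step()]).
#' @param n Number of pools.
#' @param k Pool size.
#' @return Updated frequencies (same names as `counts`).
#' @export
m_step <- function(counts, n, k) {
  counts / (n * 2L * check_pool_size(k))
}

# ---- EM drivers ------------------------------------------------------------

new_em_fit <- function(members, provenance, f, loglik, iterations, converged,
                       method, threshold, k, n_pools, dropped, initial_size,
                       trim_iterations = integer(0), grid = NULL) {
  estimates <- tibble(haplotype = members,
                      positions = hap_positions(members),
                      estimate = f,
                      provenance = provenance)
  structure(list(estimates = estimates, loglik = loglik,
                 iterations = iterations, converged = converged,
                 method = method, threshold = threshold, k = k,
                 n_pools = n_pools, dropped_pools = dropped,
                 initial_list_size = initial_size,
                 final_list_size = length(members),
                 trim_iterations = trim_iterations, grid = grid),
            class = "hap_em_fit")
}

#' @export
print.hap_em_fit <- function(x, ...) {
  cat(sprintf(
    "EM haplotype frequency fit (%s): %d pools of k = %d, list %d -> %d members\n",
    x$method, x$n_pools, x$k, x$initial_list_size, x$final_list_size))
  cat(sprintf("  %d iterations, %sconverged, log-likelihood %.4f%s\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$loglik[length(x$loglik)],
              if (is.na(x$threshold)) "" else
                sprintf(", trim threshold %g", x$threshold)))
  if (length(x$dropped_pools))
    cat(sprintf("  %d infeasible pool(s) excluded from the likelihood\n",
                length(x$dropped_pools)))
  print(x$estimates[order(-x$estimates$estimate), ], ...)
  invisible(x)
}

# core loop shared by run_em / run_em_trimmed / em_adaptive; sys is already
# built for the full member set.
em_run_sys <- function(sys, members, provenance, control, threshold = NA,
                       method = "em_list", collapsed = NULL) {
  keep <- rep(TRUE, length(members))
  f <- init_freqs(control, members, collapsed)
  loglik <- numeric(0)
  trim_at <- integer(0)
  csys <- sys
  protected <- provenance == "protected" |
    members == ancestral_hap(nchar(members[1]))
  iter <- 0L
  converged <- FALSE
  while (iter < control$max_iter) {
    iter <- iter + 1L
    step <- em_iterate(csys, f)
    fn <- step$f
    loglik[iter] <- step$loglik
    removed <- FALSE
    if (!is.na(threshold)) {
      cand <- which(fn < threshold & !protected[keep][seq_along(fn)])
      if (length(cand)) {
        cand <- trim_protect(csys, fn, cand)
        if (length(cand)) {
          keep_local <- rep(TRUE, length(fn)); keep_local[cand] <- FALSE
          csys <- filter_sys(csys, keep_local)
          idx_keep <- which(keep)[keep_local]
          keep[] <- FALSE; keep[idx_keep] <- TRUE
          fn <- fn[keep_local]
          fn <- fn / sum(fn)
          removed <- TRUE
          trim_at <- c(trim_at, iter)
        }
      }
    }
    if (!removed && length(fn) == length(f)) {
      if (max(abs(fn - f)) < control$tol) {
        f <- fn
        converged <- TRUE
        break
      }
    }
    f <- fn
  }
  new_em_fit(members[keep], provenance[keep], f, loglik, iter, converged,
             method, threshold, k = NA_integer_, n_pools = NA_integer_,
             dropped = integer(0), initial_size = length(members),
             trim_iterations = trim_at)
}

# feasibility protection: among trim candidates (indices into current member
# set), iteratively restore the highest-frequency candidate whose removal
# leaves some observed pool total with no remaining configuration.
trim_protect <- function(sys, f, cand) {
  repeat {
    keep_local <- rep(TRUE, length(f)); keep_local[cand] <- FALSE
    trial <- filter_sys(sys, keep_local)
    if (groups_covered(trial)) return(cand)
    covered <- unique(trial$group)
    bad_groups <- setdiff(unique(sys$group), covered)
    in_bad <- sys$group %in% bad_groups
    used <- colSums(sys$C[in_bad, , drop = FALSE] > 0L) > 0L
    rescue <- cand[used[cand]]
    if (length(rescue) == 0L) return(integer(0))  # cannot trim safely
    restore <- rescue[which.max(f[rescue])]
    cand <- setdiff(cand, restore)
    if (length(cand) == 0L) return(integer(0))
  }
}

prepare_sys <- function(pooled, list, on_infeasible, method) {
  validate_pooled(pooled)
  list <- as_hap_list(list)
  k <- pooled_k(pooled)
  totals <- pooled_matrix(pooled)
  if (hap_list_L(list) != ncol(totals))
    abort("list haplotype length does not match the data")
  sys <- config_system(totals, hap_to_matrix(list$haplotype), 2L * k)
  if (length(sys$bad_pools)) {
    msg <- sprintf("%d pool(s) have totals infeasible under the %s list: %s",
                   length(sys$bad_pools), method,
                   paste(utils::head(sys$bad_pools, 10L), collapse = ", "))
    if (on_infeasible == "error") abort(msg)
    warn(paste0(msg, "; excluded from the likelihood"))
  }
  list(sys = sys, list = list, k = k, n = nrow(totals))
}

#' Run the EM algorithm restricted to a haplotype list
#'
#' Maximum likelihood estimation of haplotype frequencies from pooled totals
#' with the latent haplotypes restricted to `list`. `run_em()` iterates exact
#' E and closed-form M steps until the largest frequency change falls below
#' `control$tol`; `run_em_trimmed()` additionally removes, after each M-step,
#' members whose current frequency falls below `threshold` (the ancestral
#' haplotype and `"protected"` members are never removed, nor is a member
#' whose removal would leave an observed pool total with no compatible
#' configuration), renormalizes, and continues until convergence with no
#' further removals.
#'
#' @param pooled A `pooled_data` tibble.
#' @param list A `hap_list` (or coercible).
#' @param threshold Trimming threshold in (0, 1).
#' @param control An [em_control()].
#' @param on_infeasible What to do with pools whose totals admit no
#'   configuration under `list`: `"error"` (default) or `"drop"` (exclude
#'   from the likelihood with a warning; dropped pools are recorded in the
#'   fit).
#' @param method Label stored in the fit.
#' @return A `hap_em_fit` object; see [tidy.hap_em_fit()] and
#'   [glance.hap_em_fit()].
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' p <- simulate_pools(d, n = 50, k = 2, seed = 1)
#' run_em(p, perfect_list(d))
#' @export
run_em <- function(pooled, list, control = em_control(),
                   on_infeasible = c("error", "drop"), method = "em_list") {
  on_infeasible <- match.arg(on_infeasible)
  pr <- prepare_sys(pooled, list, on_infeasible, method)
  fit <- em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance, control,
                    threshold = NA, method = method,
                    collapsed = if (control$init == "cdmle")
                      collapse_pools(pooled) else NULL)
  fit$k <- pr$k; fit$n_pools <- pr$n; fit$dropped_pools <- pr$sys$bad_pools
  fit
}

#' @rdname run_em
#' @export
run_em_trimmed <- function(pooled, list, threshold, control = em_control(),
                           on_infeasible = c("error", "drop"),
                           method = "em_trimmed") {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  on_infeasible <- match.arg(on_infeasible)
  pr <- prepare_sys(pooled, list, on_infeasible, method)
  fit <- em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance, control,
                    threshold = threshold, method = method,
                    collapsed = if (control$init == "cdmle")
                      collapse_pools(pooled) else NULL)
  fit$k <- pr$k; fit$n_pools <- pr$n; fit$dropped_pools <- pr$sys$bad_pools
  fit
}

#' Adaptive threshold selection for trimmed EM
#'
#' Runs [run_em_trimmed()] from scratch for every threshold on
#' `control$grid` and keeps the fit whose estimate of the ancestral frequency
#' f(0) lies closest to the collapsed-data benchmark [cd_benchmark_f0()];
#' ties break toward the smaller threshold (least aggressive trimming).
#' Configuration enumeration is shared across the grid, so the sweep costs
#' little more than a single run on the full list.
#'
#' @inheritParams run_em
#' @return The selected `hap_em_fit`, with the grid diagnostics (threshold,
#'   f(0) estimate, distance to benchmark) in its `grid` element.
#' @export
em_adaptive <- function(pooled, list, control = em_control(),
                        on_infeasible = c("error", "drop"),
                        method = "em_adaptive") {
  on_infeasible <- match.arg(on_infeasible)
  pr <- prepare_sys(pooled, list, on_infeasible, method)
  collapsed <- collapse_pools(pooled)
  bench <- cd_benchmark_f0(collapsed)
  anc <- ancestral_hap(hap_list_L(pr$list))
  coll_init <- if (control$init == "cdmle") collapsed else NULL
  fits <- vector("list", length(control$grid))
  f0 <- rep(NA_real_, length(control$grid))
  for (i in seq_along(control$grid)) {
    fit <- tryCatch(
      em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance, control,
                 threshold = control$grid[i], method = method,
                 collapsed = coll_init),
      error = function(e) {
        warn(sprintf("threshold %g failed: %s", control$grid[i],
                     conditionMessage(e)))
        NULL
      })
    fits[[i]] <- fit
    if (!is.null(fit)) {
      j <- match(anc, fit$estimates$haplotype)
      f0[i] <- if (is.na(j)) 0 else fit$estimates$estimate[j]
    }
  }
  if (all(is.na(f0))) abort("every threshold on the grid failed")
  dist <- abs(f0 - bench)
  best <- which.min(dist)  # first minimum = smallest threshold
  fit <- fits[[best]]
  fit$k <- pr$k; fit$n_pools <- pr$n; fit$dropped_pools <- pr$sys$bad_pools
  fit$grid <- tibble(threshold = control$grid, f0_hat = f0,
                     benchmark = bench, distance = dist,
                     selected = seq_along(control$grid) == best)
  fit
}

#' Named haplotype-frequency estimators for pooled data
#'
#' Front-end dispatching the estimators compared in the accompanying
#' simulation study:
#' \describe{
#'   \item{`em_cdl`}{EM on the CD list (distinct collapsed rows).}
#'   \item{`em_acdl`}{EM on the CD list augmented with all single-variant
#'     haplotypes.}
#'   \item{`em_atcdl`}{EM on the augmented CD list with per-iteration
#'     trimming and adaptive threshold selection (the recommended
#'     estimator).}
#'   \item{`em_tcdl`}{Trimmed EM on the unaugmented CD list.}
#'   \item{`em_pl`}{EM on the perfect list (true support) -- a gold standard
#'     requiring `truth`.}
#'   \item{`em_list`}{EM on an externally supplied `list`.}
#' }
#' Pools whose totals are infeasible under the working list are excluded
#' from the likelihood with a warning.
#'
#' @param pooled A `pooled_data` tibble.
#' @param method Estimator name (see Details).
#' @param truth A [hap_freq] distribution (or `hap_list`) giving the true
#'   support; required for `em_pl`.
#' @param list External `hap_list`; required for `em_list`.
#' @param control An [em_control()].
#' @return A `hap_em_fit`.
#' @examples
#' d <- hap_freq(c("00", "10", "01"), c(0.9, 0.06, 0.04))
#' p <- simulate_pools(d, n = 50, k = 2, seed = 1)
#' estimate_haplotypes(p, "em_atcdl")
#' @export
estimate_haplotypes <- function(pooled,
                                method = c("em_atcdl", "em_cdl", "em_acdl",
                                           "em_tcdl", "em_pl", "em_list"),
                                truth = NULL, list = NULL,
                                control = em_control()) {
  method <- match.arg(method)
  validate_pooled(pooled)
  need_cd <- method %in% c("em_cdl", "em_acdl", "em_atcdl", "em_tcdl")
  cdl <- if (need_cd) cd_list(collapse_pools(pooled)) else NULL
  switch(method,
    em_cdl = run_em(pooled, cdl, control, on_infeasible = "drop",
                    method = method),
    em_acdl = run_em(pooled, augment_singletons(cdl), control,
                     on_infeasible = "drop", method = method),
    em_atcdl = em_adaptive(pooled, augment_singletons(cdl), control,
                           on_infeasible = "drop", method = method),
    em_tcdl = em_adaptive(pooled, cdl, control, on_infeasible = "drop",
                          method = method),
    em_pl = {
      if (is.null(truth)) abort("em_pl needs `truth` (distribution or list)")
      pl <- if (inherits(truth, "hap_list")) truth else
        perfect_list(as_hap_freq(truth))
      run_em(pooled, pl, control, on_infeasible = "drop", method = method)
    },
    em_list = {
      if (is.null(list)) abort("em_list needs an external `list`")
      run_em(pooled, as_hap_list(list), control, on_infeasible = "drop",
             method = method)
    })
}
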