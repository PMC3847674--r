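# Estimator comparison metrics and the simulation-study driver.

est_table <- function(x) {
  if (inherits(x, "hap_em_fit")) {
    return(tibble(haplotype = x$estimates$haplotype,
                  estimate = x$estimates$estimate))
  }
  if (inherits(x, "hap_freq")) {
    return(tibble(haplotype = x$haplotype, estimate = x$freq))
  }
  stopifnot(is.data.frame(x), "haplotype" %in% names(x))
  val <- if ("estimate" %in% names(x)) x$estimate else x$freq
  if (is.null(val)) abort("need an `estimate` or `freq` column")
  tibble(haplotype = x$haplotype, estimate = val)
}

#' Estimation error metrics against a known truth
#'
#' `sum_squared_errors()` is the full-support sum of (f_hat(y) - f(y))^2 over
#' the union of the estimate's support and the truth's support (all other
#' haplotypes contribute zero on both sides). `missed_mass()` is the total
#' true frequency of haplotypes absent from the estimate's final list, and
#' `remaining_mass()` the total estimated frequency assigned to haplotypes
#' with zero true frequency (false haplotypes).
#'
#' @param est An estimate: a `hap_em_fit`, a [cdmle()] table, or any data
#'   frame with `haplotype` and `estimate` (or `freq`) columns.
#' @param truth A [hap_freq] distribution.
#' @return A non-negative number (`missed_mass()` and `remaining_mass()` lie
#'   in [0, 1]).
#' @examples
#' truth <- hap_freq(c("00", "10"), c(0.9, 0.1))
#' est <- tibble::tibble(haplotype = c("00", "01"), estimate = c(0.95, 0.05))
#' sum_squared_errors(est, truth)
#' missed_mass(est, truth)
#' remaining_mass(est, truth)
#' @export
sum_squared_errors <- function(est, truth) {
  e <- est_table(est)
  truth <- as_hap_freq(truth)
  all <- dplyr::full_join(e, tibble(haplotype = truth$haplotype,
                                    true = truth$freq),
                          by = "haplotype")
  all$estimate[is.na(all$estimate)] <- 0
  all$true[is.na(all$true)] <- 0
  sum((all$estimate - all$true)^2)
}

#' @rdname sum_squared_errors
#' @export
missed_mass <- function(est, truth) {
  e <- est_table(est)
  truth <- as_hap_freq(truth)
  sum(truth$freq[!(truth$haplotype %in% e$haplotype) & truth$freq > 0])
}

#' @rdname sum_squared_errors
#' @export
remaining_mass <- function(est, truth) {
  e <- est_table(est)
  truth <- as_hap_freq(truth)
  on_support <- e$haplotype %in% truth$haplotype[truth$freq > 0]
  sum(e$estimate[!on_support])
}

# fit one estimator inside a study replicate, reusing prepared configuration
# systems across estimators that share a list
study_one <- function(method, pooled, collapsed, cdl, truth, control, cache) {
  anc <- ancestral_hap(hap_freq_L(truth))
  if (method == "cdmle") {
    tbl <- cdmle(collapsed, targets = cdl)
    j <- match(anc, tbl$haplotype)
    return(list(
      estimates = tibble(haplotype = tbl$haplotype, estimate = tbl$estimate),
      list_length = length(unique(matrix_to_hap(pooled_matrix(collapsed)))),
      f0_hat = if (is.na(j)) 0 else tbl$estimate[j],
      threshold = NA_real_, dropped = 0L))
  }
  get_pr <- function(name, list) {
    if (is.null(cache[[name]]))
      cache[[name]] <- suppressWarnings(prepare_sys(pooled, list, "drop",
                                                    method))
    cache[[name]]
  }
  pr <- switch(method,
    em_cdl = , em_tcdl = get_pr("cd", cdl),
    em_acdl = , em_atcdl = get_pr("acd", augment_singletons(cdl)),
    em_pl = get_pr("pl", perfect_list(truth)))
  fit <- if (method %in% c("em_atcdl", "em_tcdl")) {
    bench <- cd_benchmark_f0(collapsed)
    grid_fits <- lapply(control$grid, function(th)
      em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance, control,
                 threshold = th, method = method))
    f0 <- vapply(grid_fits, function(f) {
      j <- match(anc, f$estimates$haplotype)
      if (is.na(j)) 0 else f$estimates$estimate[j]
    }, numeric(1))
    best <- which.min(abs(f0 - bench))
    g <- grid_fits[[best]]
    g$threshold <- control$grid[best]
    g
  } else {
    em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance, control,
               threshold = NA, method = method)
  }
  j <- match(anc, fit$estimates$haplotype)
  list(estimates = tibble(haplotype = fit$estimates$haplotype,
                          estimate = fit$estimates$estimate),
       list_length = fit$final_list_size,
       f0_hat = if (is.na(j)) 0 else fit$estimates$estimate[j],
       threshold = fit$threshold, dropped = length(pr$sys$bad_pools))
}

#' Simulation study comparing pooled haplotype-frequency estimators
#'
#' Replicates the pipeline simulate -> collapse -> estimate -> score: each
#' replicate draws `n` pools of `k` individuals from `truth` under
#' Hardy-Weinberg equilibrium, runs each requested estimator, and records the
#' sum of squared errors, missed true mass, false-haplotype mass, final list
#' length, and the estimated ancestral frequency. Replicate seeds are derived
#' deterministically as `seed + replicate`, so any single replicate can be
#' re-run exactly.
#'
#' @param truth A [hap_freq] distribution to simulate from.
#' @param n Pools per replicate.
#' @param k Pool size.
#' @param replicates Number of simulation replicates.
#' @param estimators Subset of `c("cdmle", "em_cdl", "em_acdl", "em_atcdl",
#'   "em_tcdl", "em_pl")`.
#' @param seed Master integer seed.
#' @param control An [em_control()].
#' @return A `hap_study` object: list with `metrics` (one row per replicate x
#'   estimator), `estimates` (long per-haplotype estimates), and the study
#'   settings. See [summary.hap_study()], [tidy.hap_study()],
#'   [autoplot.hap_study()].
#' @examples
#' \donttest{
#' truth <- hap_freq(c("000", "100", "010"), c(0.9, 0.06, 0.04))
#' st <- run_study(truth, n = 50, k = 2, replicates = 3,
#'                 estimators = c("cdmle", "em_atcdl"), seed = 1)
#' summary(st)
#' }
#' @export
run_study <- function(truth, n, k,
                      replicates = 100,
                      estimators = c("cdmle", "em_cdl", "em_atcdl",
                                     "em_tcdl", "em_pl"),
                      seed = 1, control = em_control()) {
  truth <- as_hap_freq(truth)
  estimators <- match.arg(estimators,
                          c("cdmle", "em_cdl", "em_acdl", "em_atcdl",
                            "em_tcdl", "em_pl"), several.ok = TRUE)
  stopifnot(replicates >= 1)
  rows <- vector("list", replicates * length(estimators))
  ests <- vector("list", replicates * length(estimators))
  ii <- 0L
  for (rep_i in seq_len(replicates)) {
    rseed <- as.integer(seed) + rep_i
    pooled <- simulate_pools(truth, n, k, seed = rseed)
    collapsed <- collapse_pools(pooled)
    cdl <- cd_list(collapsed)
    cache <- new.env(parent = emptyenv())
    for (est in estimators) {
      ii <- ii + 1L
      res <- tryCatch(
        study_one(est, pooled, collapsed, cdl, truth, control, cache),
        error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("replicate %d, %s failed: %s", rep_i, est,
                     conditionMessage(res)))
        rows[[ii]] <- tibble(replicate = rep_i, estimator = est,
                             seed = rseed, sse = NA_real_, missed = NA_real_,
                             remaining = NA_real_, list_length = NA_real_,
                             f0_hat = NA_real_, threshold = NA_real_,
                             dropped_pools = NA_integer_)
        next
      }
      rows[[ii]] <- tibble(
        replicate = rep_i, estimator = est, seed = rseed,
        sse = sum_squared_errors(res$estimates, truth),
        missed = missed_mass(res$estimates, truth),
        remaining = remaining_mass(res$estimates, truth),
        list_length = as.numeric(res$list_length),
        f0_hat = res$f0_hat,
        threshold = if (is.null(res$threshold)) NA_real_ else res$threshold,
        dropped_pools = res$dropped)
      ests[[ii]] <- dplyr::mutate(res$estimates, replicate = rep_i,
                                  estimator = est, .before = 1)
    }
  }
  structure(list(metrics = dplyr::bind_rows(rows),
                 estimates = dplyr::bind_rows(ests),
                 truth = truth, n = n, k = k, replicates = replicates,
                 seed = seed, estimators = estimators),
            class = "hap_study")
}

#' @export
print.hap_study <- function(x, ...) {
  cat(sprintf(
    "Simulation study: %d replicates of n = %d pools, k = %d (%d loci)\n",
    x$replicates, x$n, x$k, hap_freq_L(x$truth)))
  print(summary(x)$summary, ...)
  invisible(x)
}

#' Summarise a simulation study
#'
#' @param object A `hap_study` from [run_study()].
#' @param ... Unused.
#' @return A list with `summary` (per-estimator means/SDs of the error
#'   metrics and list length) and `haplotypes` (per true-support haplotype,
#'   per estimator: mean and SD of the estimated frequency, with absent
#'   haplotypes counted as zero).
#' @export
summary.hap_study <- function(object, ...) {
  m <- object$metrics
  summ <- m |>
    dplyr::group_by(.data$estimator) |>
    dplyr::summarise(
      mean_f0 = mean(.data$f0_hat, na.rm = TRUE),
      mean_sse = mean(.data$sse, na.rm = TRUE),
      mean_missed = mean(.data$missed, na.rm = TRUE),
      mean_remaining = mean(.data$remaining, na.rm = TRUE),
      mean_length = mean(.data$list_length, na.rm = TRUE),
      sd_length = stats::sd(.data$list_length, na.rm = TRUE),
      failures = sum(is.na(.data$sse)), .groups = "drop")
  truth <- object$truth
  support <- truth$haplotype[truth$freq > 0]
  grid <- tidyr::expand_grid(replicate = seq_len(object$replicates),
                             estimator = object$estimators,
                             haplotype = support)
  haps <- grid |>
    dplyr::left_join(object$estimates,
                     by = c("replicate", "estimator", "haplotype")) |>
    dplyr::mutate(estimate = dplyr::coalesce(.data$estimate, 0)) |>
    dplyr::group_by(.data$estimator, .data$haplotype) |>
    dplyr::summarise(mean = mean(.data$estimate),
                     sd = stats::sd(.data$estimate), .groups = "drop") |>
    dplyr::mutate(positions = hap_positions(.data$haplotype),
                  true = truth$freq[match(.data$haplotype, truth$haplotype)],
                  .after = "haplotype")
  list(summary = summ, haplotypes = haps)
}

#' Sweep fixed trimming thresholds and compare with the adaptive rule
#'
#' For each threshold on `grid`, runs the augmented-and-trimmed EM at that
#' fixed threshold on every replicate and records the mean sum of squared
#' errors; alongside, it records the threshold the adaptive benchmarking rule
#' would select in each replicate. Plotting the result shows how close the
#' average adaptively chosen threshold sits to the SSE-optimal one.
#'
#' @inheritParams run_study
#' @param grid Thresholds to sweep (also used by the adaptive rule).
#' @return A `hap_sweep` object: list with `by_threshold` (threshold,
#'   mean/sd of SSE), `adaptive` (per replicate selected threshold),
#'   `mean_adaptive`, `optimal` (SSE-minimizing grid threshold), and the
#'   settings. See [autoplot.hap_sweep()].
#' @export
threshold_sweep <- function(truth, n, k, replicates = 100,
                            grid = seq(1e-4, 2e-3, by = 1e-4),
                            seed = 1, control = em_control()) {
  truth <- as_hap_freq(truth)
  control$grid <- sort(as.numeric(grid))
  anc <- ancestral_hap(hap_freq_L(truth))
  sse <- matrix(NA_real_, replicates, length(control$grid))
  chosen <- rep(NA_real_, replicates)
  for (rep_i in seq_len(replicates)) {
    rseed <- as.integer(seed) + rep_i
    pooled <- simulate_pools(truth, n, k, seed = rseed)
    collapsed <- collapse_pools(pooled)
    acd <- augment_singletons(cd_list(collapsed))
    pr <- suppressWarnings(prepare_sys(pooled, acd, "drop", "em_atcdl"))
    bench <- cd_benchmark_f0(collapsed)
    f0 <- rep(NA_real_, length(control$grid))
    for (j in seq_along(control$grid)) {
      fit <- em_run_sys(pr$sys, pr$list$haplotype, pr$list$provenance,
                        control, threshold = control$grid[j],
                        method = "em_atcdl")
      sse[rep_i, j] <- sum_squared_errors(fit$estimates, truth)
      jj <- match(anc, fit$estimates$haplotype)
      f0[j] <- if (is.na(jj)) 0 else fit$estimates$estimate[jj]
    }
    chosen[rep_i] <- control$grid[which.min(abs(f0 - bench))]
  }
  by_threshold <- tibble(threshold = control$grid,
                         mean_sse = colMeans(sse),
                         sd_sse = apply(sse, 2, stats::sd))
  structure(list(by_threshold = by_threshold,
                 adaptive = tibble(replicate = seq_len(replicates),
                                   threshold = chosen),
                 mean_adaptive = mean(chosen),
                 optimal = control$grid[which.min(by_threshold$mean_sse)],
                 truth = truth, n = n, k = k, replicates = replicates,
                 seed = seed),
            class = "hap_sweep")
}

#' @export
print.hap_sweep <- function(x, ...) {
  cat(sprintf(
    "Threshold sweep: %d replicates, n = %d, k = %d; SSE-optimal %.4g, mean adaptive %.4g\n",
    x$replicates, x$n, x$k, x$optimal, x$mean_adaptive))
  print(x$by_threshold, ...)
  invisible(x)
}
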