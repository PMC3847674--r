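# tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an EM haplotype-frequency fit
#'
#' @param x A `hap_em_fit`.
#' @param ... Unused.
#' @return `tidy()`: the estimates tibble (`haplotype`, `positions`,
#'   `estimate`, `provenance`); `glance()`: a one-row tibble with the fit
#'   diagnostics (method, iterations, convergence, final log-likelihood,
#'   list sizes, trimming threshold, dropped pools).
#' @method tidy hap_em_fit
#' @export
tidy.hap_em_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.hap_em_fit
#' @method glance hap_em_fit
#' @export
glance.hap_em_fit <- function(x, ...) {
  tibble(method = x$method,
         iterations = x$iterations,
         converged = x$converged,
         loglik = x$loglik[length(x$loglik)],
         threshold = x$threshold,
         initial_list_size = x$initial_list_size,
         final_list_size = x$final_list_size,
         n_pools = x$n_pools,
         k = x$k,
         dropped_pools = length(x$dropped_pools))
}

#' Tidy a simulation study
#'
#' @param x A `hap_study` from [run_study()].
#' @param ... Unused.
#' @return `tidy()`: the per-replicate, per-estimator metrics tibble;
#'   `glance()`: per-estimator means (one row per estimator).
#' @method tidy hap_study
#' @export
tidy.hap_study <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.hap_study
#' @method glance hap_study
#' @export
glance.hap_study <- function(x, ...) {
  summary(x)$summary
}

#' Tidy a threshold sweep
#'
#' @param x A `hap_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return The per-threshold mean SSE tibble.
#' @method tidy hap_sweep
#' @export
tidy.hap_sweep <- function(x, ...) {
  x$by_threshold
}
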