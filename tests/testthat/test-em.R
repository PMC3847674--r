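mgll <- hap_example("mgll25")

make_pooled <- function(rows, k) {
  m <- matrix(as.integer(unlist(strsplit(rows, ","))), nrow = length(rows),
              byrow = TRUE)
  d <- hap_freq(anc_of(ncol(m)), 1)
  p <- simulate_pools(d, length(rows), k, seed = 1)
  p[paste0("locus_", seq_len(ncol(m)))] <- as.data.frame(m)
  p
}

test_that("configuration enumeration handles the canonical small cases", {
  # all-zero total: the ancestral haplotype taken K times
  cfg <- enumerate_configurations(c(0, 0), c("00", "10", "01", "11"), k = 2)
  expect_identical(nrow(cfg), 1L)
  expect_identical(unname(cfg[1, ]), c(4L, 0L, 0L, 0L))
  # total (1,1) with K=2: either 00+11 or 10+01
  cfg2 <- enumerate_configurations(c(1, 1), c("00", "10", "01", "11"), k = 1)
  expect_identical(nrow(cfg2), 2L)
  expect_true(all(rowSums(cfg2) == 2))
  keys <- apply(cfg2, 1, paste, collapse = "")
  expect_setequal(keys, c("1001", "0110"))
  # infeasible: no member carries a '1' at locus 2
  cfg3 <- enumerate_configurations(c(0, 1), c("00", "10"), k = 1)
  expect_identical(nrow(cfg3), 0L)
})

test_that("enumeration is complete and exact against ordered-tuple search", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      L <- sample(2:5, 1)
      r <- sample(2:8, 1)
      K <- sample(2:4, 1)
      haps <- sort(unique(c(anc_of(L), replicate(r, paste(sample(0:1, L, TRUE),
                                                          collapse = "")))))
      total <- colSums(matrix(as.integer(unlist(strsplit(
        sample(haps, K, TRUE), ""))), nrow = K, byrow = TRUE))
    })
    if (K %% 2 == 1) K <- K + 1
    got <- enumerate_configurations(total, haps, k = K / 2)
    want <- oracle_configs(total, haps, K)
    expect_identical(nrow(got), nrow(want))
    gk <- sort(apply(got, 1, paste, collapse = ","))
    wk <- sort(apply(want, 1, paste, collapse = ","))
    expect_identical(gk, wk)
  }
})

test_that("pool likelihoods reduce to known closed forms and sum to one", {
  expect_equal(pool_likelihood(1, c("0", "1"), c(0.8, 0.2), k = 1),
               2 * 0.8 * 0.2)
  f <- c(`00` = 0.5, `10` = 0.2, `01` = 0.2, `11` = 0.1)
  expect_equal(pool_likelihood(c(1, 1), names(f), f, k = 1),
               2 * 0.5 * 0.1 + 2 * 0.2 * 0.2)
  # total probability over all achievable totals
  for (k in 1:2) {
    K <- 2 * k
    totals <- expand.grid(rep(list(0:K), 2))
    tot_p <- sum(apply(totals, 1, function(t)
      pool_likelihood(t, names(f), f, k = k)))
    expect_equal(tot_p, 1, tolerance = 1e-10)
  }
})

test_that("E and M steps match hand calculations and conserve counts", {
  # forced heterozygote: single pool, total 1 at the only locus
  p1 <- make_pooled("1", k = 1)
  m1 <- e_step(p1, c("0", "1"), c(0.7, 0.3))
  expect_equal(unname(m1), c(1, 1))
  # all-zero pool: everything on the ancestral haplotype
  p0 <- make_pooled("0,0", k = 2)
  m0 <- e_step(p0, c("00", "10"), c(0.6, 0.4))
  expect_equal(unname(m0), c(4, 0))
  # two equally weighted phase configurations
  p11 <- make_pooled("1,1", k = 1)
  m11 <- e_step(p11, c("00", "10", "01", "11"), rep(0.25, 4))
  expect_equal(unname(m11), rep(0.5, 4))
  expect_equal(unname(m_step(m11, n = 1, k = 1)), rep(0.25, 4))
  expect_equal(unname(m_step(c(a = 6, b = 0), n = 3, k = 1)), c(1, 0))
  # count conservation on random instances
  for (seed in 1:6) {
    d <- rand_dist(4, 5, seed = seed)
    p <- simulate_pools(d, n = 25, k = 2, seed = seed)
    f0 <- withr::with_seed(seed, {
      x <- stats::runif(nrow(d)); x / sum(x)
    })
    m <- e_step(p, d$haplotype, stats::setNames(f0, d$haplotype))
    expect_equal(sum(m), 25 * 4, tolerance = 1e-8 * 100)
    expect_true(all(m >= 0))
  }
})

test_that("EM recovers exact answers in identifiable toy problems", {
  # pools (2,0) and (0,0) at K=2 with members 00,10: phase unambiguous
  p <- make_pooled(c("2,0", "0,0"), k = 1)
  fit <- run_em(p, c("00", "10"))
  expect_equal(est_of(fit, "10"), 0.5, tolerance = 1e-6)
  expect_equal(est_of(fit, "00"), 0.5, tolerance = 1e-6)
  # singleton ancestral list, all-zero data: immediate convergence
  p0 <- make_pooled(c("0,0", "0,0"), k = 2)
  fit0 <- run_em(p0, "00")
  expect_equal(fit0$estimates$estimate, 1)
  expect_true(fit0$converged)
})

test_that("the log-likelihood never decreases and estimates stay normalized", {
  for (seed in c(2, 9, 17)) {
    d <- rand_dist(4, 5, seed = seed)
    p <- simulate_pools(d, n = 30, k = 2, seed = seed + 50)
    fit <- suppressWarnings(run_em(p, hap_list(d$haplotype),
                                   on_infeasible = "drop"))
    expect_true(all(diff(fit$loglik) >= -1e-8))
    expect_equal(sum(fit$estimates$estimate), 1, tolerance = 1e-8)
  }
})

test_that("pooled EM at k=1 agrees with a direct genotype-data EM", {
  d <- rand_dist(3, 4, seed = 4)
  p <- simulate_pools(d, n = 40, k = 1, seed = 14)
  haps <- apply(expand.grid(rep(list(0:1), 3)), 1, paste0, collapse = "")
  fit <- run_em(p, haps, em_control(tol = 1e-10, max_iter = 500))
  ref <- oracle_genotype_em(pooled_totals(p), haps, iter = 500)
  expect_equal(stats::setNames(fit$estimates$estimate,
                               fit$estimates$haplotype)[names(ref)],
               ref, tolerance = 1e-6)
})

test_that("EM results match a naive per-pool reference implementation", {
  # grouping identical totals and sharing enumerations must be contract-
  # identical to an ungrouped direct evaluation of one E-step
  d <- rand_dist(3, 4, seed = 21)
  p <- simulate_pools(d, n = 12, k = 2, seed = 22)
  haps <- d$haplotype
  f <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  m_pkg <- e_step(p, haps, f)
  m_ref <- stats::setNames(rep(0, length(haps)), haps)
  for (i in seq_len(nrow(p))) {
    t_i <- pooled_totals(p)[i, ]
    cfg <- enumerate_configurations(t_i, haps, k = 2)
    w <- apply(cfg, 1, function(cc)
      factorial(4) / prod(factorial(cc)) * prod(f^cc))
    w <- w / sum(w)
    m_ref <- m_ref + as.vector(t(cfg) %*% w)
  }
  expect_equal(m_pkg, m_ref, tolerance = 1e-10)
})

test_that("infeasible pools error by default and can be dropped", {
  p <- make_pooled(c("0,2", "0,0"), k = 1)
  expect_error(run_em(p, c("00", "10")), "infeasible.*1")
  expect_warning(fit <- run_em(p, c("00", "10"), on_infeasible = "drop"),
                 "excluded")
  expect_identical(fit$dropped_pools, 1L)
  expect_equal(est_of(fit, "00"), 1, tolerance = 1e-6)
})

test_that("trimming removes rare members but respects protections", {
  d <- rand_dist(4, 5, seed = 33)
  p <- simulate_pools(d, n = 60, k = 2, seed = 34)
  base <- suppressWarnings(run_em(p, hap_list(d$haplotype),
                                  on_infeasible = "drop"))
  # threshold below every converged frequency: identical fit
  eps <- min(base$estimates$estimate[base$estimates$estimate > 0]) / 10
  if (eps > 0) {
    trm <- suppressWarnings(run_em_trimmed(p, hap_list(d$haplotype), eps,
                                           on_infeasible = "drop"))
    expect_equal(trm$estimates$estimate, base$estimates$estimate,
                 tolerance = 1e-6)
  }
  # 50/50 toy: neither member can be trimmed at threshold 0.5 because each
  # is needed for feasibility
  p2 <- make_pooled(c("2,0", "0,0"), k = 1)
  fit2 <- run_em_trimmed(p2, c("00", "10"), 0.5)
  expect_identical(fit2$final_list_size, 2L)
  expect_equal(sort(fit2$estimates$estimate), c(0.5, 0.5), tolerance = 1e-6)
  # ancestral haplotype survives even when its frequency is tiny
  d3 <- hap_freq(c("00", "10"), c(0.05, 0.95))
  p3 <- simulate_pools(d3, n = 60, k = 1, seed = 35)
  fit3 <- suppressWarnings(run_em_trimmed(p3, c("00", "10", "01"), 0.2,
                                          on_infeasible = "drop"))
  expect_true("00" %in% fit3$estimates$haplotype)
  expect_false("01" %in% fit3$estimates$haplotype)
})

test_that("adaptive threshold selection follows the benchmark and tie rule", {
  d <- rand_dist(4, 4, seed = 41)
  p <- simulate_pools(d, n = 50, k = 2, seed = 42)
  acd <- augment_singletons(cd_list(collapse_pools(p)))
  # singleton grid returns that threshold
  one <- suppressWarnings(em_adaptive(p, acd, em_control(grid = 5e-4),
                                      on_infeasible = "drop"))
  expect_equal(one$threshold, 5e-4)
  # all-zero data: every threshold gives f0 = 1; smallest wins by tie rule
  p0 <- make_pooled(c("0,0", "0,0", "0,0"), k = 2)
  fit0 <- em_adaptive(p0, hap_list(c("00", "10")),
                      em_control(grid = c(1e-4, 1e-3)))
  expect_equal(fit0$threshold, 1e-4)
  expect_equal(est_of(fit0, "00"), 1)
  # grid diagnostics expose the selection
  expect_true(is.data.frame(one$grid) && sum(one$grid$selected) == 1)
})

test_that("the estimator front-end dispatches onto the documented lists", {
  p <- simulate_pools(mgll, n = 80, k = 1, seed = 51)
  cdl <- cd_list(collapse_pools(p))
  via_front <- suppressWarnings(estimate_haplotypes(p, "em_cdl"))
  via_manual <- suppressWarnings(run_em(p, cdl, on_infeasible = "drop",
                                        method = "em_cdl"))
  expect_equal(via_front$estimates, via_manual$estimates)
  # em_pl needs truth; degenerate singleton list gives a degenerate estimate
  expect_error(estimate_haplotypes(p, "em_pl"), "truth")
  d1 <- hap_freq(anc_of(25), 1)
  p1 <- simulate_pools(d1, 10, 2, seed = 3)
  plfit <- estimate_haplotypes(p1, "em_pl", truth = d1)
  expect_equal(plfit$estimates$estimate, 1)
  # tidy/glance accessors
  expect_s3_class(tidy(via_front), "tbl_df")
  expect_identical(glance(via_front)$method, "em_cdl")
})

test_that("EM on the perfect list recovers the truth at large n", {
  p <- simulate_pools(mgll, n = 20000, k = 2, seed = 61)
  fit <- suppressWarnings(estimate_haplotypes(p, "em_pl", truth = mgll))
  joined <- merge(fit$estimates, as.data.frame(mgll), by = "haplotype",
                  all = TRUE)
  joined$estimate[is.na(joined$estimate)] <- 0
  expect_true(all(abs(joined$estimate - joined$freq) < 0.005))
})
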