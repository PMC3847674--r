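mgll <- hap_example("mgll25")

test_that("error metrics follow their defining arithmetic", {
  truth <- hap_freq(c("000", "100"), c(0.9, 0.1))
  exact <- tibble::tibble(haplotype = truth$haplotype, estimate = truth$freq)
  expect_equal(sum_squared_errors(exact, truth), 0)
  expect_equal(missed_mass(exact, truth), 0)
  expect_equal(remaining_mass(exact, truth), 0)
  # half the mass misplaced onto a false haplotype
  t0 <- hap_freq("000", 1)
  half <- tibble::tibble(haplotype = c("000", "100"), estimate = c(0.5, 0.5))
  expect_equal(sum_squared_errors(half, t0), 0.5)
  expect_equal(remaining_mass(half, t0), 0.5)
  # a missed haplotype contributes its true mass
  only_anc <- tibble::tibble(haplotype = "000", estimate = 1)
  expect_equal(missed_mass(only_anc, truth), 0.1)
  # partition identity: remaining + mass on true support = 1 when normalized
  for (seed in 1:5) {
    d <- rand_dist(4, 5, seed = seed)
    est <- withr::with_seed(seed, {
      haps <- c(d$haplotype[1:3], "1111")
      w <- stats::runif(4); tibble::tibble(haplotype = haps,
                                           estimate = w / sum(w))
    })
    on_support <- sum(est$estimate[est$haplotype %in% d$haplotype])
    expect_equal(remaining_mass(est, d) + on_support, 1)
  }
  # the five-variant haplotype's mass when only it is missed
  pl <- perfect_list(mgll)
  miss1 <- pl$haplotype[hap_positions(pl$haplotype) == "1, 6, 7, 24"]
  est <- tibble::tibble(haplotype = setdiff(pl$haplotype, miss1),
                        estimate = 0)
  expect_equal(missed_mass(est, mgll), 0.0034)
})

test_that("study runs are deterministic and exact on degenerate truths", {
  t0 <- hap_freq(anc_of(6), 1)
  st <- suppressWarnings(run_study(t0, n = 10, k = 2, replicates = 1,
                                   estimators = c("cdmle", "em_cdl", "em_pl"),
                                   seed = 3))
  expect_true(all(st$metrics$sse == 0))
  expect_true(all(st$metrics$f0_hat == 1))
  st2 <- suppressWarnings(run_study(t0, n = 10, k = 2, replicates = 1,
                                    estimators = c("cdmle", "em_cdl", "em_pl"),
                                    seed = 3))
  expect_identical(st$metrics, st2$metrics)
})

test_that("study reports carry per-haplotype means and summary rows", {
  st <- suppressWarnings(run_study(mgll, n = 50, k = 2, replicates = 3,
                                   estimators = c("cdmle", "em_atcdl"),
                                   seed = 7))
  s <- summary(st)
  expect_setequal(unique(s$haplotypes$estimator), c("cdmle", "em_atcdl"))
  expect_identical(nrow(dplyr::filter(s$haplotypes, estimator == "em_atcdl")),
                   22L)
  expect_true(all(is.finite(s$summary$mean_sse)))
  expect_identical(tidy(st), st$metrics)
  expect_identical(glance(st), s$summary)
  # replicate seeds are recorded for exact re-runs
  expect_identical(unique(st$metrics$seed), 7L + 1:3)
})

test_that("the gold-standard error shrinks as the number of pools doubles", {
  reps <- 12
  st100 <- suppressWarnings(run_study(mgll, n = 100, k = 2, replicates = reps,
                                      estimators = "em_pl", seed = 90))
  st200 <- suppressWarnings(run_study(mgll, n = 200, k = 2, replicates = reps,
                                      estimators = "em_pl", seed = 90))
  expect_lt(mean(st200$metrics$sse), mean(st100$metrics$sse))
})

test_that("the collapsed-data benchmark tracks the gold standard f(0)", {
  reps <- 12
  st <- suppressWarnings(run_study(mgll, n = 200, k = 2, replicates = reps,
                                   estimators = c("cdmle", "em_pl"),
                                   seed = 120))
  m <- dplyr::summarise(dplyr::group_by(st$metrics, estimator),
                        f0 = mean(f0_hat))
  expect_lt(abs(diff(m$f0)), 0.01)
})

test_that("threshold sweeps are deterministic and expose both thresholds", {
  sw1 <- suppressWarnings(threshold_sweep(mgll, n = 60, k = 2, replicates = 2,
                                          grid = 5e-4, seed = 13))
  expect_identical(nrow(sw1$by_threshold), 1L)
  expect_equal(sw1$mean_adaptive, 5e-4)
  sw2 <- suppressWarnings(threshold_sweep(mgll, n = 60, k = 2, replicates = 3,
                                          grid = c(2e-4, 1e-3), seed = 14))
  sw3 <- suppressWarnings(threshold_sweep(mgll, n = 60, k = 2, replicates = 3,
                                          grid = c(2e-4, 1e-3), seed = 14))
  expect_identical(sw2$by_threshold, sw3$by_threshold)
  expect_true(sw2$optimal %in% c(2e-4, 1e-3))
  expect_s3_class(autoplot(sw2), "ggplot")
})

test_that("plot methods return ggplot objects", {
  p <- simulate_pools(mgll, n = 40, k = 2, seed = 15)
  fit <- suppressWarnings(estimate_haplotypes(p, "em_atcdl"))
  expect_s3_class(autoplot(fit, truth = mgll), "ggplot")
  st <- suppressWarnings(run_study(mgll, n = 40, k = 2, replicates = 2,
                                   estimators = "em_cdl", seed = 16))
  expect_s3_class(autoplot(st), "ggplot")
})
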