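test_that("RMSD is zero for identical IRFs and exact for constant shifts", {
  g <- quad_grid()
  p <- plogis(g$z)
  expect_equal(rmsd_irf(p, p, g$w), 0)
  # constant deviation of 0.1 inside (0, 1) integrates to exactly 0.1
  p0 <- rep(0.45, length(g$z))
  expect_equal(rmsd_irf(p0 + 0.1, p0, g$w), 0.1, tolerance = 1e-12)
})

test_that("RMSD matches brute-force dense-grid integration", {
  th <- seq(-8, 8, length.out = 10001)
  w <- dnorm(th); w <- w / sum(w)
  p_joint <- plogis(th - 0)        # a = 1, pooled d = 0
  p_time <- plogis(th - 0.5)       # d shifted by 0.5
  got <- rmsd_irf(p_time, p_joint, w)
  f <- function(t) (plogis(t - 0.5) - plogis(t))^2 * dnorm(t)
  oracle <- sqrt(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  expect_lt(abs(got - oracle), 1e-6)
})

test_that("robust z-scores follow the MAD recipe", {
  v <- c(0.01, 0.02, 0.03, 0.04, 0.15)
  z <- robust_zscores(v)
  expect_equal(z[5], 0.12 / (1.4826 * 0.01), tolerance = 1e-12)
  expect_equal(round(z[5], 3), 8.094)
  # ties: MAD floor makes every score 0
  expect_equal(robust_zscores(rep(0.05, 6)), rep(0, 6))
  # shift invariance
  expect_equal(robust_zscores(v + 0.2), z)
  expect_error(robust_zscores(c(0.1, 0.2)), "3")
})

test_that("flagging respects cutoff, min-anchor truncation and ties", {
  expect_equal(flag_items(c(0.1, 0.2, 0.3), 0.5, n_common = 20), rep(FALSE, 3))
  # 19 of 20 exceed: exactly 17 flagged, 3 anchors kept
  v <- c(0.01, seq(0.1, 2, length.out = 19))
  fl <- flag_items(v, 0.05, n_common = 20)
  expect_equal(sum(fl), 17)
  expect_false(fl[1])
  expect_false(fl[2]); expect_false(fl[3])  # the two smallest exceeders kept
  # ties break toward the lower index
  v <- c(1, 1, 1, 1)
  fl <- flag_items(v, 0.5, n_common = 4, min_anchor = 3)
  expect_equal(fl, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("RMSD statistics from a fit separate drifted items", {
  cond <- cond_row(2500, 20, 1, 10, "unbalanced")
  sim <- sim_responses(cond, 9)
  fit <- calibrate_concurrent(sim$data)
  rs <- rmsd_statistic(fit)
  expect_true(all(rs$rmsd >= 0 & rs$rmsd <= 1))
  wide <- tidyr::pivot_wider(rs, names_from = "time", values_from = "rmsd")
  stat <- pmax(wide$`1`, wide$`2`)
  drifted <- sim$drift$item[sim$drift$delta != 0]
  expect_true(all(stat[wide$item %in% drifted] >
                    max(stat[!wide$item %in% drifted])))
})

test_that("one-step detection flags an injected drifting item", {
  hits <- 0
  for (s in 1:10) {
    cond <- cond_row(2500, 20, 1, 10, "unbalanced")
    sim <- sim_responses(cond, 100 + s)
    part <- detect_drift(sim$data,
                         detection_config("rmsd_fixed", cutoff = 0.05))
    hits <- hits + all(c("I10", "I20") %in% part$biased)
  }
  expect_gte(hits, 9)
})

test_that("lower fixed cutoffs never shrink the flagged set", {
  cond <- cond_row(1000, 20, 1, 30, "unbalanced")
  sim <- sim_responses(cond, 41)
  fit <- calibrate_concurrent(sim$data)
  p05 <- detect_drift(sim$data, detection_config("rmsd_fixed", cutoff = 0.05),
                      baseline = fit)
  p08 <- detect_drift(sim$data, detection_config("rmsd_fixed", cutoff = 0.08),
                      baseline = fit)
  expect_true(all(p08$biased %in% p05$biased))
})

test_that("iterative purification grows monotonically and respects the caps", {
  cond <- cond_row(500, 20, 1, 30, "unbalanced")
  for (s in 1:3) {
    sim <- sim_responses(cond, 200 + s)
    part <- detect_drift(sim$data,
                         detection_config("rmsd_dd", cutoff = 1.7,
                                          approach = "it"))
    expect_lte(part$iterations, 7)
    expect_gte(length(part$anchor), 3)
    # forward-only: flags never reverse across iterations
    st <- part$stats
    for (it in seq_len(part$iterations)[-1]) {
      flagged_before <- st$item[st$flagged & st$iteration < it]
      expect_true(!any(flagged_before %in% st$item[st$iteration == it]))
    }
  }
})

test_that("no-drift data terminates iterative detection quickly", {
  cond <- cond_row(1000, 20)
  sim <- sim_responses(cond, 77)
  part <- detect_drift(sim$data,
                       detection_config("rmsd_fixed", cutoff = 0.05,
                                        approach = "it"))
  expect_equal(part$iterations, 1)
  expect_equal(part$biased, character(0))
})

test_that("likelihood-ratio statistics are nonnegative and nested", {
  cond <- cond_row(500, 20, 1, 30, "unbalanced")
  sim <- sim_responses(cond, 55)
  fit <- calibrate_concurrent(sim$data)
  lr <- lrt_statistics(sim$data, items = c("I01", "I08", "I10"),
                       baseline = fit)
  expect_true(all(lr$G2 > -1e-6))
  expect_equal(lr$df, rep(2, 3))
  # drifted item carries far more evidence than a clean one
  expect_gt(lr$G2[lr$item == "I10"], lr$G2[lr$item == "I01"])
})

test_that("LRT type-I error stays near the nominal level without drift", {
  cond <- cond_row(1000, 20)
  rejections <- 0; tests <- 0
  crit <- qchisq(0.95, 2)
  for (s in 1:10) {
    sim <- sim_responses(cond, 300 + s)
    lr <- lrt_statistics(sim$data)
    rejections <- rejections + sum(lr$G2 > crit, na.rm = TRUE)
    tests <- tests + sum(!is.na(lr$G2))
  }
  rate <- rejections / tests
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("Bonferroni flags are a subset of the alpha = 0.05 flags", {
  cond <- cond_row(1000, 20, 1, 30, "unbalanced")
  sim <- sim_responses(cond, 61)
  fit <- calibrate_concurrent(sim$data)
  lr <- lrt_statistics(sim$data, baseline = fit)
  crit05 <- qchisq(1 - 0.05, 2)
  critb <- qchisq(1 - 0.05 / nrow(lr), 2)
  expect_gt(critb, crit05)
  expect_true(all(lr$item[lr$G2 > critb] %in% lr$item[lr$G2 > crit05]))
})

test_that("an empty biased set reproduces the plain concurrent fit", {
  cond <- cond_row(400, 20)
  sim <- sim_responses(cond, 71)
  part <- detect_drift(sim$data, detection_config("rmsd_fixed", cutoff = 0.3))
  expect_equal(part$biased, character(0))
  re <- reestimate_partial_invariance(sim$data, part, "CC")
  cc <- calibrate_concurrent(sim$data)
  expect_identical(re$mu2, cc$mu2)
  expect_identical(re$sigma2, cc$sigma2)
})

test_that("the oracle partition removes the drift bias", {
  cond <- cond_row(2500, 20, 1, 30, "unbalanced")
  biased_true <- drift_pattern(20, 1, 30, "unbalanced")
  biased_true <- biased_true$item[biased_true$delta != 0]
  part <- list(anchor = setdiff(sprintf("I%02d", 1:20), biased_true),
               biased = biased_true, config = list(reestimator = "CC"))
  est <- numeric(30)
  for (s in 1:30) {
    sim <- sim_responses(cond, 400 + s)
    est[s] <- reestimate_partial_invariance(sim$data, part, "CC")$mu2
  }
  bias <- mean(est) - 1
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(bias), 0.015 + 3 * mc_se)
})

test_that("reestimation guards the minimum anchor count", {
  part <- list(anchor = c("I01", "I02"), biased = sprintf("I%02d", 3:20),
               config = list(reestimator = "CC"))
  expect_error(reestimate_partial_invariance(tibble::tibble(), part, "CC"),
               "3")
})
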