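test_that("the smooth counter matches its closed form and limits", {
  expect_equal(smooth_count(0, 0.001), 0)
  expect_equal(smooth_count(0.1, 0.001), 0.01 / 0.011)
  expect_equal(round(smooth_count(0.1, 0.001), 4), 0.9091)
  expect_equal(smooth_count(1e8, 0.001), 1, tolerance = 1e-12)
  xs <- seq(0, 3, by = 0.05)
  expect_true(all(diff(smooth_count(xs, 0.01)) > 0))
  # smaller eps counts any fixed nonzero effect more fully
  for (x in c(0.05, 0.3, 1)) {
    v <- vapply(c(0.01, 0.001, 0.0001), function(e) smooth_count(x, e),
                numeric(1))
    expect_true(all(diff(v) > 0))
  }
  # penalty term is bounded by the item count
  expect_lte(sum(smooth_count(rnorm(20, 0, 5), 0.001)), 20)
  expect_error(smooth_count(1, -1), "eps")
})

test_that("the smooth BIC decomposes into deviance plus penalty exactly", {
  cond <- cond_row(300, 20)
  sim <- sim_responses(cond, 8)
  cc <- calibrate_concurrent(sim$data)
  model0 <- list(a = cc$bank1$a, d = cc$bank1$d, delta = rep(0, 20),
                 mu2 = cc$mu2, sigma2 = cc$sigma2, eps = 0.001)
  nstar <- sum(cc$n)
  H <- 2 * 20 + 2
  # all effects zero: smooth BIC equals the deviance plus log(N*) H
  expect_equal(sbic_value(model0, sim$data), cc$deviance + log(nstar) * H,
               tolerance = 1e-6)
  # moving one effect to 1 adds log(N*) / (1 + eps) to the penalty
  model1 <- model0
  model1$delta[4] <- 1
  bank1 <- item_bank(cc$items, model1$a, model1$d)
  bank2 <- item_bank(cc$items, model1$a, model1$d + model1$delta)
  sp <- sim$data
  ll1 <- marginal_loglik(bank1, list(mu = 0, sigma = 1),
                         sp[sp$time == 1, -1]) +
    marginal_loglik(bank2, list(mu = model1$mu2, sigma = model1$sigma2),
                    sp[sp$time == 2, -1])
  expect_equal(sbic_value(model1, sim$data),
               -2 * ll1 + log(nstar) * (H + 1 / (1 + 0.001)),
               tolerance = 1e-6)
})

test_that("the fitted smooth BIC never exceeds the concurrent solution's", {
  for (seed in c(3, 14)) {
    cond <- cond_row(400, 20, 1, 30, "unbalanced")
    sim <- sim_responses(cond, seed)
    cc <- calibrate_concurrent(sim$data)
    fit <- fit_regularized(sim$data, cc_fit = cc)
    sbic_cc <- sbic_value(list(a = cc$bank1$a, d = cc$bank1$d,
                               delta = rep(0, 20), mu2 = cc$mu2,
                               sigma2 = cc$sigma2, eps = 0.001), sim$data)
    expect_lte(fit$sbic, sbic_cc + 1e-6)
  }
})

test_that("no-drift data leaves every drift effect near zero", {
  cond <- cond_row(2500, 20)
  sim <- sim_responses(cond, 23)
  fit <- fit_regularized(sim$data)
  expect_lt(max(abs(fit$delta)), 0.05)
  expect_lt(abs(fit$mu2 - 1), 0.05)
  expect_lt(abs(fit$sigma2 - 1.3), 0.05)
})

test_that("the fitted drift effect is profile-optimal on a small toy", {
  # four items, one with large drift, big N: the drift coordinate of the
  # optimum must match a grid search of the smooth BIC profile
  bank <- base_item_bank(10)[c(1, 4, 8, 10), ]
  bank$item <- sprintf("I%02d", 1:4)
  set.seed(99)
  n <- 10000
  gen <- function(mu, sg, dshift) {
    th <- rnorm(n, mu, sg)
    P <- plogis(outer(th, bank$a) - matrix(bank$d + dshift, n, 4, byrow = TRUE))
    X <- matrix(rbinom(length(P), 1, P), n); colnames(X) <- bank$item
    tibble::as_tibble(X)
  }
  data <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(time = 1L), gen(0, 1, 0)),
    dplyr::bind_cols(tibble::tibble(time = 2L), gen(0.5, 1.2, c(0, 0, 0, -1)))
  )
  fit <- fit_regularized(data, eps = 0.001)
  expect_lt(fit$delta[4], 0)  # sign recovered
  expect_equal(unname(fit$delta[4]), -1, tolerance = 0.15)
  # profile grid search over the drifted item's effect
  model <- list(a = fit$bank1$a, d = fit$bank1$d, delta = unname(fit$delta),
                mu2 = fit$mu2, sigma2 = fit$sigma2, eps = 0.001)
  grid <- seq(fit$delta[4] - 0.25, fit$delta[4] + 0.25, by = 0.01)
  prof <- vapply(grid, function(dl) {
    m <- model; m$delta[4] <- dl
    sbic_value(m, data)
  }, numeric(1))
  expect_equal(unname(fit$delta[4]), grid[which.min(prof)], tolerance = 0.011)
})

test_that("drifted items carry the largest estimated effects", {
  cond <- cond_row(2500, 20, 1, 30, "unbalanced")
  truth <- drift_pattern(20, 1, 30, "unbalanced")
  drifted <- truth$item[truth$delta != 0]
  hits <- 0
  for (s in 1:8) {
    sim <- sim_responses(cond, 500 + s)
    fit <- fit_regularized(sim$data)
    top <- names(sort(abs(fit$delta), decreasing = TRUE))[seq_along(drifted)]
    hits <- hits + setequal(top, drifted)
  }
  expect_gte(hits, 7)
})

test_that("regularized fits expose drift tables and selection flags", {
  cond <- cond_row(300, 20, 1, 30, "unbalanced")
  sim <- sim_responses(cond, 77)
  fit <- fit_regularized(sim$data)
  td <- tidy(fit)
  expect_setequal(names(td), c("item", "a", "d", "delta", "selected"))
  expect_identical(td$selected, abs(td$delta) > fit$zero_tol)
  gl <- glance(fit)
  expect_true(all(c("sbic", "eps", "n_selected") %in% names(gl)))
})
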