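test_that("loss functions reproduce their defining values", {
  expect_equal(loss_value(2, loss_spec(2)), 4)
  expect_equal(loss_value(0, loss_spec(0, 0.01)), 0)
  expect_equal(loss_value(1, loss_spec(0, 0.01)), 1 / 1.01)
  expect_equal(round(loss_value(1, loss_spec(0, 0.01)), 4), 0.9901)
  expect_equal(loss_value(0.1, loss_spec(0, 0.001)), 0.01 / 0.011)
  # smooth forms are zero at zero and symmetric
  for (p in c(0, 0.25, 0.5, 1, 2)) {
    sp <- loss_spec(p)
    expect_equal(loss_value(0, sp), 0)
    expect_equal(loss_value(-1.3, sp), loss_value(1.3, sp))
  }
})

test_that("losses are nondecreasing in |x| and L0 has its limits", {
  xs <- seq(0, 5, by = 0.01)
  for (p in c(0, 0.25, 0.5, 1, 2)) {
    expect_true(all(diff(loss_value(xs, loss_spec(p))) >= 0))
  }
  # smooth L0 tends to 1 for large |x| and to the indicator as eps -> 0
  expect_equal(loss_value(1e6, loss_spec(0, 0.01)), 1, tolerance = 1e-9)
  vals <- vapply(c(1e-2, 1e-4, 1e-6),
                 function(e) loss_value(0.5, loss_spec(0, e)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[3], 1, tolerance = 1e-5)
})

test_that("Haberman SD recovers noiseless transformations under every loss", {
  for (p in c(0, 0.25, 0.5, 1, 2)) {
    cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3)
    expect_equal(haberman_sd(cal, loss_spec(p))$sigma2, 1.3, tolerance = 1e-6)
    ident <- noiseless_calibs(mu2 = 0, sigma2 = 1)
    expect_equal(haberman_sd(ident, loss_spec(p))$sigma2, 1, tolerance = 1e-6)
  }
})

test_that("L0 Haberman SD ignores a single discrimination outlier", {
  cal <- noiseless_calibs(mu2 = 0, sigma2 = 1)
  cal$bank2$a[3] <- cal$bank2$a[3] * 2
  got <- haberman_sd(cal, loss_spec(0))
  expect_equal(got$sigma2, 1, tolerance = 1e-3)
  # independent grid-search oracle over s2 at resolution 1e-4
  c_ <- log(cal$bank2$a) - log(cal$bank1$a)
  oracle <- grid_search_link(c_, rep(-1, 10), loss_spec(0),
                             seq(-0.3, 1, by = 1e-4))
  expect_equal(log(got$sigma2), oracle, tolerance = 2e-4)
})

test_that("Haberman SD is exactly invariant to intercept drift", {
  cal <- noiseless_calibs(mu2 = 0.4, sigma2 = 1.2)
  ref <- haberman_sd(cal, loss_spec(0.5))
  cal$bank2$d <- cal$bank2$d + rnorm(10, 0, 5)  # arbitrary intercept change
  expect_identical(haberman_sd(cal, loss_spec(0.5))$sigma2, ref$sigma2)
})

test_that("Haberman intercept mean step recovers noiseless trends", {
  for (p in c(0, 0.25, 0.5, 1, 2)) {
    cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3)
    got <- haberman_mean_intercepts(cal, 1.3, loss_spec(p))
    expect_equal(got$mu2, 1, tolerance = 1e-6)
  }
  ident <- noiseless_calibs(mu2 = 0, sigma2 = 1)
  expect_equal(haberman_mean_intercepts(ident, 1, loss_spec(1))$mu2, 0,
               tolerance = 1e-6)
})

test_that("L0 mean step resists minority contamination; L2 absorbs it", {
  cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3, delta = 0)
  cal$bank2$d[10] <- cal$bank2$d[10] - 1  # one drifted intercept
  l0 <- haberman_mean_intercepts(cal, 1.3, loss_spec(0))
  expect_lt(abs(l0$mu2 - 1), 0.01)
  # grid-search oracle
  e <- cal$bank2$d - cal$bank1$d
  w <- cal$bank2$a / 1.3
  oracle <- grid_search_link(e, w, loss_spec(0), seq(0.5, 2, by = 1e-4))
  expect_equal(l0$mu2, oracle, tolerance = 2e-4)
  # closed-form least-squares oracle for the exact squared loss
  l2 <- haberman_mean_intercepts(cal, 1.3, loss_spec(2))
  expect_equal(l2$mu2, -sum(w * e) / sum(w^2), tolerance = 1e-10)
  expect_gt(abs(l2$mu2 - 1), 0.05)  # pulled toward the contaminated item
})

test_that("the L2 intercept mean step is exactly shift-equivariant", {
  cal <- noiseless_calibs(mu2 = 0.8, sigma2 = 1.1)
  cal$bank2$d <- cal$bank2$d + rnorm(10, 0, 0.1)
  base <- haberman_mean_intercepts(cal, 1.1, loss_spec(2))$mu2
  cshift <- 0.37
  cal$bank2$d <- cal$bank2$d - cshift * cal$bank2$a / 1.1
  shifted <- haberman_mean_intercepts(cal, 1.1, loss_spec(2))$mu2
  expect_equal(shifted, base + cshift, tolerance = 1e-10)
})

test_that("difficulty-based mean step recovers noiseless trends", {
  cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3)
  got <- haberman_mean_difficulties(cal, 1.3, loss_spec(2))
  expect_equal(got$mu2, 1, tolerance = 1e-6)
  ident <- noiseless_calibs(mu2 = 0, sigma2 = 1)
  expect_equal(haberman_mean_difficulties(ident, 1, loss_spec(2))$mu2, 0,
               tolerance = 1e-6)
})

test_that("intercept linking is less variable than difficulty linking", {
  # parametric estimation noise on (a, d); b = d / a inherits both sources
  set.seed(31)
  mu_int <- mu_dif <- numeric(200)
  base <- noiseless_calibs(mu2 = 1, sigma2 = 1.3)
  for (r in 1:200) {
    cal <- base
    cal$bank1$a <- cal$bank1$a * exp(rnorm(10, 0, 0.05))
    cal$bank2$a <- cal$bank2$a * exp(rnorm(10, 0, 0.05))
    cal$bank1$d <- cal$bank1$d + rnorm(10, 0, 0.05)
    cal$bank2$d <- cal$bank2$d + rnorm(10, 0, 0.05)
    cal$bank1$b <- cal$bank1$d / cal$bank1$a
    cal$bank2$b <- cal$bank2$d / cal$bank2$a
    s2 <- haberman_sd(cal, loss_spec(2))$sigma2
    mu_int[r] <- haberman_mean_intercepts(cal, s2, loss_spec(2))$mu2
    mu_dif[r] <- haberman_mean_difficulties(cal, s2, loss_spec(2))$mu2
  }
  expect_gte(stats::var(mu_dif), stats::var(mu_int))
})

test_that("Haebara linking recovers noiseless trends for any weighting", {
  for (wt in list(weight_spec("uniform"), weight_spec("normal", 0.5),
                  weight_spec("normal", 2))) {
    cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3)
    got <- haebara_link(cal, loss_spec(2), wt)
    expect_equal(got$mu2, 1, tolerance = 1e-4)
    expect_equal(got$sigma2, 1.3, tolerance = 1e-4)
  }
  ident <- noiseless_calibs(mu2 = 0, sigma2 = 1)
  got <- haebara_link(ident, loss_spec(2), weight_spec("normal", 1))
  expect_equal(got$mu2, 0, tolerance = 1e-4)
  expect_equal(got$sigma2, 1, tolerance = 1e-4)
})

test_that("Haebara optimum matches a 2-D grid-search oracle", {
  cal <- noiseless_calibs(mu2 = 1, sigma2 = 1.3, n_items = 10)
  cal$bank2$d[9:10] <- cal$bank2$d[9:10] - 0.8  # contamination
  cal$bank2$b <- cal$bank2$d / cal$bank2$a
  wt <- weight_spec("normal", 1)
  got <- haebara_link(cal, loss_spec(2), wt)
  grid_mu <- seq(0.8, 1.4, by = 0.005)
  grid_sg <- seq(1.1, 1.5, by = 0.005)
  obj <- function(mu, sg) {
    v <- 0
    for (i in 1:10) {
      p1 <- plogis(cal$bank1$a[i] * (sg * wt$theta + mu - cal$bank1$b[i]))
      p2 <- plogis(cal$bank2$a[i] * (wt$theta - cal$bank2$b[i]))
      v <- v + sum(wt$w * (p1 - p2)^2)
    }
    v
  }
  vals <- outer(grid_mu, grid_sg, Vectorize(obj))
  k <- arrayInd(which.min(vals), dim(vals))
  expect_equal(got$mu2, grid_mu[k[1]], tolerance = 0.005)
  expect_equal(got$sigma2, grid_sg[k[2]], tolerance = 0.005)
})
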