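# shared fixtures built in code

# condition row builder without the full grid
cond_row <- function(n, n_items = 20, delta = 0, pct_ipd = 0,
                     ipd_type = "none", mu2 = 1, sigma2 = 1.3) {
  tibble::tibble(condition = sprintf("N%d_I%d_d%g_p%d_%s", n, n_items, delta,
                                     pct_ipd, substr(ipd_type, 1, 3)),
                 n = n, n_items = n_items, delta = delta, pct_ipd = pct_ipd,
                 ipd_type = ipd_type, mu2 = mu2, sigma2 = sigma2)
}

# noiseless separate-calibration pair implied by the scale transform
# theta* = sigma2 * theta + mu2 with intercept drift delta on the t1 scale
noiseless_calibs <- function(mu2 = 1, sigma2 = 1.3, delta = 0,
                             n_items = 10) {
  b1 <- base_item_bank(n_items)[seq_len(n_items), ]
  dshift <- rep_len(delta, n_items)
  a2 <- b1$a * sigma2
  d2 <- (b1$d + dshift) - b1$a * mu2
  as_calibs(b1, item_bank(b1$item, a2, d2))
}

# dense-grid brute-force marginal log-likelihood (independent oracle)
brute_loglik <- function(bank, mu, sigma, X, n_nodes = 10001,
                         range = c(-8, 8)) {
  th <- seq(range[1], range[2], length.out = n_nodes)
  h <- diff(th[1:2])
  dens <- dnorm(th, mu, sigma)
  idx <- match(colnames(X), bank$item)
  ll <- 0
  for (p in seq_len(nrow(X))) {
    f <- dens
    for (j in seq_len(ncol(X))) {
      x <- X[p, j]
      if (is.na(x)) next
      P <- plogis(bank$a[idx[j]] * th - bank$d[idx[j]])
      f <- f * if (x == 1) P else 1 - P
    }
    # trapezoid rule
    ll <- ll + log(sum(f * h) - h * (f[1] + f[n_nodes]) / 2)
  }
  ll
}

# grid-search minimizer of the Haberman profile objective (independent
# oracle for the linking optimizers)
grid_search_link <- function(e, w, spec, grid) {
  pair_obj <- function(ci) {
    f <- function(u) loss_value(u, spec) + loss_value(ci - u, spec)
    optimize(f, range(c(0, ci)) + c(-1e-9, 1e-9), tol = 1e-10)$objective
  }
  prof <- vapply(grid, function(l) sum(vapply(e + w * l, pair_obj, numeric(1))),
                 numeric(1))
  grid[which.min(prof)]
}
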