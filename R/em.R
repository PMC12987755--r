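#' EM control settings
#'
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_iter maximum number of EM iterations.
#' @param criterion `"param"` stops on the parameter-change rule; `"deviance"`
#'   stops when the deviance decrease falls below `dev_tol` (used for the
#'   likelihood-ratio-test fits, where only the deviance is consumed).
#' @param dev_tol deviance-change tolerance for `criterion = "deviance"`.
#' @param n_quad,quad_range quadrature nodes and standardized range; the grid
#'   is rescaled per group by its latent mean and SD.
#' @return A list of settings.
#' @export
em_control <- function(tol = 1e-5, max_iter = 1000,
                       criterion = c("param", "deviance"), dev_tol = 1e-4,
                       n_quad = 61, quad_range = c(-6, 6)) {
  list(tol = tol, max_iter = max_iter, criterion = match.arg(criterion),
       dev_tol = dev_tol, n_quad = n_quad, quad_range = quad_range)
}

# stable log(1 + exp(eta))
.log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))

# weighted Bernoulli log-likelihood with logit eta
.bern_obj <- function(eta, r, n) sum(r * eta - n * .log1pexp(eta))

# safeguarded Newton ascent for one item's (a, d) on expected counts
.newton_item2 <- function(a, d, th, r, n, steps = 4) {
  f0 <- .bern_obj(a * th - d, r, n)
  for (s in seq_len(steps)) {
    P <- plogis(a * th - d)
    res <- r - n * P
    W <- n * P * (1 - P)
    g <- c(sum(res * th), -sum(res))
    H <- matrix(c(sum(W * th^2), -sum(W * th), -sum(W * th), sum(W)), 2)
    step <- tryCatch(solve(H, g), error = function(e) g / (max(diag(H)) + 1e-8))
    ok <- FALSE
    for (h in 0:10) {
      a1 <- a + step[1] / 2^h
      d1 <- d + step[2] / 2^h
      if (a1 <= 1e-3) next
      f1 <- .bern_obj(a1 * th - d1, r, n)
      if (f1 >= f0) { a <- a1; d <- d1; f0 <- f1; ok <- TRUE; break }
    }
    if (!ok || max(abs(step)) < 1e-9) break
  }
  c(a = a, d = d)
}

# Newton ascent for (mu2, log sigma2) on the expected complete-data loglik
# of group 2; all items enter, with their group-2 parameters.
.newton_dist <- function(mu2, sigma2, z, a2, d2, r2, n2, steps = 4) {
  obj <- function(mu, sig) {
    eta <- outer(a2, mu + sig * z) - d2
    .bern_obj(eta, r2, n2)
  }
  ls <- log(sigma2)
  f0 <- obj(mu2, sigma2)
  for (s in seq_len(steps)) {
    sig <- exp(ls)
    eta <- outer(a2, mu2 + sig * z) - d2
    P <- plogis(eta)
    res <- r2 - n2 * P
    W <- n2 * P * (1 - P)
    g_mu <- sum(a2 * rowSums(res))
    g_ls <- sig * sum(a2 * (res %*% z))
    H_mm <- -sum(a2^2 * rowSums(W))
    H_ms <- -sig * sum(a2^2 * (W %*% z))
    H_ss <- -sig^2 * sum(a2^2 * (W %*% z^2)) + g_ls
    H <- matrix(c(H_mm, H_ms, H_ms, H_ss), 2)
    step <- tryCatch(solve(H, -c(g_mu, g_ls)),
                     error = function(e) c(g_mu, g_ls) / (abs(H_mm) + 1e-8))
    ok <- FALSE
    for (h in 0:10) {
      mu_n <- mu2 + step[1] / 2^h
      ls_n <- ls + step[2] / 2^h
      f1 <- obj(mu_n, exp(ls_n))
      if (f1 >= f0) { mu2 <- mu_n; ls <- ls_n; f0 <- f1; ok <- TRUE; break }
    }
    if (!ok || max(abs(step)) < 1e-9) break
  }
  c(mu2, exp(ls))
}

# smooth counter of a nonzero drift effect and its derivatives
.neps <- function(x, eps) x^2 / (x^2 + eps)
.neps_d1 <- function(x, eps) 2 * x * eps / (x^2 + eps)^2
.neps_d2 <- function(x, eps) 2 * eps * (eps - 3 * x^2) / (x^2 + eps)^3

# penalized Newton ascent for one item's (a, d, delta) under the smooth-BIC
# penalty; candidate set includes the delta = 0 profile so estimates can
# land exactly in the zero basin.
.newton_item3 <- function(a, d, delta, th1, r1, n1, th2, r2, n2,
                          pen_c, eps, steps = 4) {
  pobj <- function(a, d, delta)
    .bern_obj(a * th1 - d, r1, n1) + .bern_obj(a * th2 - d - delta, r2, n2) -
      pen_c * .neps(delta, eps)
  f0 <- pobj(a, d, delta)
  for (s in seq_len(steps)) {
    e1 <- a * th1 - d; e2 <- a * th2 - d - delta
    P1 <- plogis(e1); P2 <- plogis(e2)
    z1 <- r1 - n1 * P1; z2 <- r2 - n2 * P2
    W1 <- n1 * P1 * (1 - P1); W2 <- n2 * P2 * (1 - P2)
    g <- c(sum(z1 * th1) + sum(z2 * th2), -sum(z1) - sum(z2),
           -sum(z2) - pen_c * .neps_d1(delta, eps))
    H <- matrix(0, 3, 3)
    H[1, 1] <- -sum(W1 * th1^2) - sum(W2 * th2^2)
    H[1, 2] <- H[2, 1] <- sum(W1 * th1) + sum(W2 * th2)
    H[1, 3] <- H[3, 1] <- sum(W2 * th2)
    H[2, 2] <- -sum(W1) - sum(W2)
    H[2, 3] <- H[3, 2] <- -sum(W2)
    H[3, 3] <- -sum(W2) - pen_c * .neps_d2(delta, eps)
    step <- tryCatch(solve(H, -g), error = function(e) g / (sum(abs(diag(H))) + 1e-8))
    ok <- FALSE
    for (h in 0:12) {
      cand <- c(a, d, delta) + step / 2^h
      if (cand[1] <= 1e-3) next
      f1 <- pobj(cand[1], cand[2], cand[3])
      if (f1 >= f0) { a <- cand[1]; d <- cand[2]; delta <- cand[3]; f0 <- f1; ok <- TRUE; break }
    }
    if (!ok || max(abs(step)) < 1e-9) break
  }
  # profile with delta pinned at zero; keep whichever is better penalized
  z0 <- .newton_item2(a, d + delta / 2, c(th1, th2), c(r1, r2), c(n1, n2))
  if (pobj(z0[1], z0[2], 0) > f0) return(c(z0[1], z0[2], 0))
  c(a, d, delta)
}

# crude data-driven starting values
.start_values <- function(X1, X2) {
  clip <- function(p) pmin(pmax(p, 0.02), 0.98)
  p1 <- clip(colMeans(X1, na.rm = TRUE))
  if (is.null(X2)) {
    list(a = rep(1, ncol(X1)), d = -qlogis(p1) * 1.16, mu2 = 0, sigma2 = 1)
  } else {
    p2 <- clip(colMeans(X2, na.rm = TRUE))
    pp <- clip((colSums(X1, na.rm = TRUE) + colSums(X2, na.rm = TRUE)) /
                 (colSums(!is.na(X1)) + colSums(!is.na(X2))))
    mu2 <- mean(qlogis(p2) - qlogis(p1)) * 1.16
    list(a = rep(1, ncol(X1)), d = -qlogis(pp) * 1.16, mu2 = mu2, sigma2 = 1)
  }
}

# Core fitting engine for one- and two-group 2PL marginal ML.
#
# X1, X2     integer response matrices (same columns); X2 NULL for one group.
# free       column indices with time-specific (a, d) (partial invariance).
# fixed      list(a, d): freeze all item parameters (fixed calibration).
# reg        list(eps): regularized fit with per-item drift delta at t2.
# start      optional list(a1, d1, a2, d2, delta, mu2, sigma2).
.fit_2pl <- function(X1, X2 = NULL, free = integer(0), fixed = NULL,
                     reg = NULL, start = NULL, control = em_control()) {
  I <- ncol(X1)
  two <- !is.null(X2)
  gq <- quad_grid(control$n_quad, control$quad_range)
  z <- gq$z; w <- gq$w
  sv <- if (nrow(X1) > 0) .start_values(X1, X2)
        else list(a = NULL, d = NULL, mu2 = 0, sigma2 = 1)
  a1 <- start$a1 %||% fixed$a %||% sv$a
  d1 <- start$d1 %||% fixed$d %||% sv$d
  a2 <- start$a2 %||% a1
  d2 <- start$d2 %||% d1
  delta <- start$delta %||% rep(0, I)
  if (!is.null(reg)) d2 <- d1 + delta
  mu2 <- start$mu2 %||% sv$mu2
  sigma2 <- start$sigma2 %||% sv$sigma2
  if (!two) { mu2 <- 0; sigma2 <- 1 }
  update_items <- is.null(fixed)
  shared <- setdiff(seq_len(I), free)
  pen_c <- if (!is.null(reg)) log(nrow(X1) + nrow(X2)) / 2 else 0

  par_vec <- function() c(a1, d1, a2[free], d2[free], delta, mu2, log(sigma2))
  dev_hist <- numeric(0)
  converged <- FALSE
  it <- 0
  e1 <- e2 <- NULL
  repeat {
    it <- it + 1
    th2 <- mu2 + sigma2 * z
    e1 <- .estep(X1, z, w, a1, d1)
    ll <- e1$loglik
    if (two) { e2 <- .estep(X2, th2, w, a2, d2); ll <- ll + e2$loglik }
    dev_hist <- c(dev_hist, -2 * ll)
    ndev <- length(dev_hist)
    if (control$criterion == "deviance" && ndev > 1 &&
        abs(dev_hist[ndev - 1] - dev_hist[ndev]) < control$dev_tol) {
      converged <- TRUE; break
    }
    if (it > control$max_iter) break
    p_old <- par_vec()
    if (update_items) {
      if (!is.null(reg)) {
        for (i in seq_len(I)) {
          upd <- .newton_item3(a1[i], d1[i], delta[i], z, e1$r[i, ], .item_n(e1, i),
                               th2, e2$r[i, ], .item_n(e2, i), pen_c, reg$eps)
          a1[i] <- a2[i] <- upd[1]; d1[i] <- upd[2]; delta[i] <- upd[3]
          d2[i] <- d1[i] + delta[i]
        }
      } else if (two) {
        for (i in shared) {
          upd <- .newton_item2(a1[i], d1[i], c(z, th2),
                               c(e1$r[i, ], e2$r[i, ]),
                               c(.item_n(e1, i), .item_n(e2, i)))
          a1[i] <- a2[i] <- upd[1]; d1[i] <- d2[i] <- upd[2]
        }
        for (i in free) {
          u1 <- .newton_item2(a1[i], d1[i], z, e1$r[i, ], .item_n(e1, i))
          u2 <- .newton_item2(a2[i], d2[i], th2, e2$r[i, ], .item_n(e2, i))
          a1[i] <- u1[1]; d1[i] <- u1[2]; a2[i] <- u2[1]; d2[i] <- u2[2]
        }
      } else {
        for (i in seq_len(I)) {
          upd <- .newton_item2(a1[i], d1[i], z, e1$r[i, ], .item_n(e1, i))
          a1[i] <- upd[1]; d1[i] <- upd[2]
        }
      }
    }
    if (two) {
      n2m <- if (isTRUE(e2$n_from_nq)) matrix(e2$nq, I, length(z), byrow = TRUE) else e2$n
      du <- .newton_dist(mu2, sigma2, z, a2, d2, e2$r, n2m)
      mu2 <- du[1]; sigma2 <- du[2]
    }
    chg <- max(abs(par_vec() - p_old))
    if (control$criterion == "param" && chg < control$tol) {
      # one closing E-step so reported loglik/stats match the final parameters
      th2 <- mu2 + sigma2 * z
      e1 <- .estep(X1, z, w, a1, d1)
      ll <- e1$loglik
      if (two) { e2 <- .estep(X2, th2, w, a2, d2); ll <- ll + e2$loglik }
      dev_hist <- c(dev_hist, -2 * ll)
      converged <- TRUE
      break
    }
  }
  out <- list(a1 = a1, d1 = d1, a2 = a2, d2 = d2, delta = delta,
              mu2 = mu2, sigma2 = sigma2, loglik = ll,
              deviance = dev_hist[length(dev_hist)], dev_history = dev_hist,
              iterations = it, converged = converged, free = free,
              e1 = e1, e2 = e2, z = z, w = w,
              n1 = nrow(X1), n2 = if (two) nrow(X2) else 0L)
  if (!is.null(reg)) {
    H <- 2 * I + 2
    out$sbic <- out$deviance + log(out$n1 + out$n2) * (H + sum(.neps(delta, reg$eps)))
    out$H <- H
    out$eps <- reg$eps
  }
  out
}
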