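# Two noisy observations of one joint parameter t: rho(x1 - t) + rho(x2 - t).
# By translation invariance only the gap c = x2 - x1 matters; returns the
# minimized pair loss and the offset u = t - x1 at the minimum.
.pair_min <- function(c_, spec) {
  if (spec$p == 2) return(list(val = c_^2 / 2, u = c_ / 2))
  f <- function(u) loss_value(u, spec) + loss_value(c_ - u, spec)
  cand <- c(0, c_, c_ / 2)
  lo <- min(0, c_); hi <- max(0, c_)
  if (hi - lo > 1e-12) cand <- c(cand, optimize(f, c(lo, hi), tol = 1e-9)$minimum)
  vals <- vapply(cand, f, numeric(1))
  k <- which.min(vals)
  list(val = vals[k], u = cand[k])
}

# Minimize prof(lambda) = sum_i g(e_i + w_i * lambda) where g is the profiled
# pair loss. Nonconvex for p < 1, so the per-item exact-match values
# -e_i / w_i seed a candidate scan that local refinement then polishes.
.profile_link <- function(e, w, spec, extra = numeric()) {
  if (spec$p == 2) {
    lam <- -sum(w * e) / sum(w^2)
    return(list(lambda = lam, objective = sum((e + w * lam)^2) / 2))
  }
  prof <- function(l) sum(vapply(e + w * l, function(ci) .pair_min(ci, spec)$val,
                                 numeric(1)))
  ls <- -sum(w * e) / sum(w^2)
  cand <- unique(c(-e / w, ls, 0, extra))
  cand <- cand[is.finite(cand)]
  vals <- vapply(cand, prof, numeric(1))
  ord <- order(vals, abs(cand))
  best <- list(lambda = cand[ord[1]], objective = vals[ord[1]])
  for (k in head(ord, 4)) {
    o <- optimize(prof, c(cand[k] - 0.25, cand[k] + 0.25), tol = 1e-8)
    better <- o$objective < best$objective - 1e-12 ||
      (abs(o$objective - best$objective) <= 1e-12 && abs(o$minimum) < abs(best$lambda))
    if (better) best <- list(lambda = o$minimum, objective = o$objective)
  }
  best
}

.calib_items <- function(calibs, items = NULL) {
  if (!inherits(calibs, "ipd_calibs")) abort("`calibs` must be an `ipd_calibs` object")
  use <- items %||% calibs$items
  use <- intersect(use, calibs$items)
  if (!length(use)) abort("no common items selected for linking")
  i1 <- match(use, calibs$bank1$item); i2 <- match(use, calibs$bank2$item)
  list(item = use,
       a1 = calibs$bank1$a[i1], d1 = calibs$bank1$d[i1], b1 = calibs$bank1$b[i1],
       a2 = calibs$bank2$a[i2], d2 = calibs$bank2$d[i2], b2 = calibs$bank2$b[i2])
}

#' Haberman linking: SD step
#'
#' Estimates the time-2 SD from the log-discriminations of two separate
#' calibrations, jointly with the common log-discriminations `kappa`. Because
#' only discriminations enter, the estimate is untouched by intercept drift.
#'
#' @param calibs an [separate_calibrations()] / [as_calibs()] object.
#' @param loss a [loss_spec()].
#' @param items optional subset of common items (anchor set).
#' @return List with `sigma2`, the joint `kappa` per item, and the objective.
#' @export
haberman_sd <- function(calibs, loss = loss_spec(2), items = NULL) {
  cp <- .calib_items(calibs, items)
  c_ <- log(cp$a2) - log(cp$a1)
  # residual gap at items is c_i - s2: e = c_, w = -1
  opt <- .profile_link(c_, rep(-1, length(c_)), loss)
  s2 <- opt$lambda
  kappa <- log(cp$a1) +
    vapply(c_ - s2, function(ci) .pair_min(ci, loss)$u, numeric(1))
  list(sigma2 = exp(s2), kappa = setNames(kappa, cp$item),
       objective = opt$objective)
}

#' Haberman linking: mean step from item intercepts
#'
#' Given the SD from [haberman_sd()], estimates the time-2 mean jointly with
#' the common intercepts `d`. The time-2 residual uses
#' `d2 + (a2 / sigma2) * mu2 - d`, the intercept image of the scale transform
#' `theta* = sigma2 * theta + mu2`.
#'
#' @inheritParams haberman_sd
#' @param sigma2 the linked time-2 SD.
#' @return List with `mu2`, the joint intercepts `joint_d`, and the objective.
#' @export
haberman_mean_intercepts <- function(calibs, sigma2, loss = loss_spec(2),
                                     items = NULL) {
  cp <- .calib_items(calibs, items)
  e <- cp$d2 - cp$d1
  w <- cp$a2 / sigma2
  opt <- .profile_link(e, w, loss)
  mu2 <- opt$lambda
  joint <- cp$d1 + vapply(e + w * mu2, function(ci) .pair_min(ci, loss)$u,
                          numeric(1))
  list(mu2 = mu2, joint_d = setNames(joint, cp$item), objective = opt$objective)
}

#' Haberman linking: mean step from item difficulties
#'
#' The original difficulty-based variant: the time-2 residual uses
#' `sigma2 * b2 + mu2 - b`.
#'
#' @inheritParams haberman_mean_intercepts
#' @return List with `mu2`, the joint difficulties `joint_b`, and the
#'   objective.
#' @export
haberman_mean_difficulties <- function(calibs, sigma2, loss = loss_spec(2),
                                       items = NULL) {
  cp <- .calib_items(calibs, items)
  e <- sigma2 * cp$b2 - cp$b1
  w <- rep(1, length(e))
  opt <- .profile_link(e, w, loss)
  mu2 <- opt$lambda
  joint <- cp$b1 + vapply(e + mu2, function(ci) .pair_min(ci, loss)$u,
                          numeric(1))
  list(mu2 = mu2, joint_b = setNames(joint, cp$item), objective = opt$objective)
}

#' Haberman linking trend estimate
#'
#' Two-step Haberman linking: SD from log-discriminations, then mean from
#' intercepts (default, the more precise variant) or difficulties.
#'
#' @inheritParams haberman_sd
#' @param parameterization `"intercepts"` or `"difficulties"` for the mean
#'   step.
#' @return One-row trend tibble (`method`, `mu2`, `sigma2`, `converged`).
#' @export
haberman_link <- function(calibs, loss = loss_spec(2),
                          parameterization = c("intercepts", "difficulties"),
                          items = NULL) {
  parameterization <- match.arg(parameterization)
  sd_step <- haberman_sd(calibs, loss, items)
  mean_step <- if (parameterization == "intercepts")
    haberman_mean_intercepts(calibs, sd_step$sigma2, loss, items)
  else haberman_mean_difficulties(calibs, sd_step$sigma2, loss, items)
  lab <- sprintf("HAB-%s(p=%g)",
                 if (parameterization == "intercepts") "int" else "dif", loss$p)
  new_trend(lab, mean_step$mu2, sd_step$sigma2, TRUE,
            settings = list(loss = loss, parameterization = parameterization,
                            items = items))
}

#' Weighting function for Haebara linking
#'
#' @param kind `"normal"` for normal-density weights centred at 0 or
#'   `"uniform"`.
#' @param sigma width of the normal-density weights (0.5, 1 or 2 in the study
#'   grid).
#' @param n,range evaluation grid on the time-2 ability scale.
#' @return A `weight_spec` with grid `theta` and normalized weights `w`.
#' @export
weight_spec <- function(kind = c("normal", "uniform"), sigma = 1,
                        n = 61, range = c(-6, 6)) {
  kind <- match.arg(kind)
  theta <- seq(range[1], range[2], length.out = n)
  w <- if (kind == "normal") dnorm(theta, 0, sigma) else rep(1, n)
  structure(list(kind = kind, sigma = if (kind == "normal") sigma else NA_real_,
                 theta = theta, w = w / sum(w)),
            class = "weight_spec")
}

#' Haebara linking trend estimate
#'
#' Minimizes the weighted discrepancy between the time-1 IRFs transformed to
#' the time-2 scale and the time-2 IRFs, jointly over the time-2 mean and SD.
#' Asymmetric, as originally proposed: the time-1 curves are transformed.
#'
#' @inheritParams haberman_sd
#' @param weight a [weight_spec()].
#' @param start optional `c(mu2, sigma2)` starting values.
#' @return One-row trend tibble; `converged` is `FALSE` when no optimizer
#'   start converged.
#' @export
haebara_link <- function(calibs, loss = loss_spec(2),
                         weight = weight_spec("normal", 1),
                         items = NULL, start = NULL) {
  cp <- .calib_items(calibs, items)
  th <- weight$theta; w <- weight$w
  P2 <- plogis(outer(cp$a2, th) - cp$a2 * cp$b2)
  obj <- function(par) {
    mu2 <- par[1]; sig2 <- exp(par[2])
    P1 <- plogis(cp$a1 * (outer(rep(sig2, length(cp$a1)), th) + mu2 - cp$b1))
    sum(loss_value(P1 - P2, loss) %*% w)
  }
  starts <- list(c(0, 0))
  hb <- tryCatch({
    s <- haberman_sd(calibs, loss_spec(2), items)
    m <- haberman_mean_intercepts(calibs, s$sigma2, loss_spec(2), items)
    c(m$mu2, log(s$sigma2))
  }, error = function(e) NULL)
  if (!is.null(hb)) starts <- c(starts, list(hb))
  if (loss$p < 1) {
    hb0 <- tryCatch({
      s <- haberman_sd(calibs, loss_spec(0), items)
      m <- haberman_mean_intercepts(calibs, s$sigma2, loss_spec(0), items)
      c(m$mu2, log(s$sigma2))
    }, error = function(e) NULL)
    if (!is.null(hb0)) starts <- c(starts, list(hb0))
  }
  if (!is.null(start)) starts <- c(list(c(start[1], log(start[2]))), starts)
  best <- NULL; any_conv <- FALSE
  for (s0 in starts) {
    o <- tryCatch(optim(s0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    any_conv <- any_conv || o$convergence == 0
    better <- is.null(best) || o$value < best$value - 1e-12 ||
      (abs(o$value - best$value) <= 1e-12 && abs(o$par[1]) < abs(best$par[1]))
    if (better) best <- o
  }
  if (is.null(best)) abort("Haebara optimization failed from all starts")
  lab <- sprintf("HAE(%s,p=%g)",
                 if (weight$kind == "normal") paste0("normal", weight$sigma)
                 else "uniform", loss$p)
  new_trend(lab, best$par[1], exp(best$par[2]), any_conv,
            settings = list(loss = loss, weight = weight$kind,
                            weight_sigma = weight$sigma, items = items))
}
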