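new_ipd_fit <- function(raw, items, type, time_labels = c(1, 2)) {
  structure(
    list(items = items, type = type,
         bank1 = item_bank(items, raw$a1, raw$d1),
         bank2 = item_bank(items, raw$a2, raw$d2),
         dist = tibble(time = time_labels,
                       mu = c(0, raw$mu2), sigma = c(1, raw$sigma2)),
         mu2 = raw$mu2, sigma2 = raw$sigma2,
         loglik = raw$loglik, deviance = raw$deviance,
         dev_history = raw$dev_history, iterations = raw$iterations,
         converged = raw$converged,
         free_items = items[raw$free],
         n = c(raw$n1, raw$n2),
         raw = raw),
    class = "ipd_fit")
}

# drop items without both response categories (their logits diverge)
.drop_degenerate <- function(X, context = "calibration") {
  p <- colMeans(X, na.rm = TRUE)
  bad <- !is.finite(p) | p == 0 | p == 1
  if (any(bad)) {
    warn(sprintf("excluding %d degenerate item(s) from %s: %s",
                 sum(bad), context, paste(colnames(X)[bad], collapse = ", ")))
    X <- X[, !bad, drop = FALSE]
  }
  if (ncol(X) == 0) abort("no estimable items remain")
  X
}

#' Calibrate a single time point
#'
#' Marginal maximum-likelihood (EM) estimation of 2PL item parameters for one
#' group, with the latent distribution fixed at mean 0 and SD 1 for
#' identification. Items observed in only one response category are excluded
#' with a warning.
#'
#' @param data person x item responses for one time point (matrix or data
#'   frame of 0/1/NA; no time column).
#' @param control see [em_control()].
#' @param start optional list of starting values (`a1`, `d1`).
#' @return An `ipd_fit` object; `tidy()` extracts item parameters,
#'   `glance()` the fit summary.
#' @export
calibrate_single <- function(data, control = em_control(), start = NULL) {
  X <- .drop_degenerate(.resp_matrix(data), "single-group calibration")
  raw <- .fit_2pl(X, control = control, start = start)
  new_ipd_fit(raw, colnames(X), "single")
}

#' Concurrent (multiple-group) calibration
#'
#' Joint 2PL estimation for both time points. Items listed in `free_items`
#' receive time-specific discriminations and intercepts (partial invariance);
#' all other common items are constrained equal across time points. The
#' time-1 latent distribution is fixed at (0, 1); the time-2 mean and SD are
#' estimated, so at least one item must stay constrained.
#'
#' @param data wide response tibble: one row per person, a time column with
#'   two values, remaining columns the items.
#' @param free_items character vector of item ids freed across time points.
#' @param time_col name of the time column.
#' @inheritParams calibrate_single
#' @return An `ipd_fit` with the estimated time-2 mean `mu2` and SD `sigma2`.
#' @export
calibrate_concurrent <- function(data, free_items = character(),
                                 time_col = "time",
                                 control = em_control(), start = NULL) {
  sp <- .split_times(data, time_col)
  keep <- colnames(.drop_degenerate(rbind(sp$X1, sp$X2), "concurrent calibration"))
  X1 <- sp$X1[, keep, drop = FALSE]; X2 <- sp$X2[, keep, drop = FALSE]
  free <- match(intersect(free_items, keep), keep)
  if (length(free) >= length(keep))
    abort("all items freed: the time-2 distribution is not identified")
  raw <- .fit_2pl(X1, X2, free = free, control = control, start = start)
  new_ipd_fit(raw, keep, "concurrent", sp$times)
}

#' Fixed calibration of the second time point
#'
#' Freezes all item parameters at supplied (time-1) estimates and estimates
#' only the time-2 latent mean and SD.
#'
#' @param data person x item responses at time 2 (no time column).
#' @param bank item bank with the fixed parameters; must cover every response
#'   column.
#' @inheritParams calibrate_single
#' @return An `ipd_fit`; item parameters are bit-identical to `bank`.
#' @export
calibrate_fixed <- function(data, bank, control = em_control(), start = NULL) {
  bank <- .check_bank(bank)
  X <- .resp_matrix(data)
  idx <- match(colnames(X), bank$item)
  if (anyNA(idx))
    abort(sprintf("fixed parameters missing for item(s): %s",
                  paste(colnames(X)[is.na(idx)], collapse = ", ")))
  a <- bank$a[idx]; d <- bank$d[idx]
  raw <- .fit_2pl(matrix(integer(0), 0, ncol(X), dimnames = list(NULL, colnames(X))),
                  X, fixed = list(a = a, d = d), control = control, start = start)
  new_ipd_fit(raw, colnames(X), "fixed")
}

#' Separate per-time-point calibrations
#'
#' Calibrates each time point independently, both identified at (0, 1); the
#' common items carry the information used by the linking estimators.
#'
#' @inheritParams calibrate_concurrent
#' @return An object of class `ipd_calibs`: item banks `bank1`, `bank2`
#'   (common items only) and the underlying fits.
#' @export
separate_calibrations <- function(data, time_col = "time",
                                  control = em_control()) {
  sp <- .split_times(data, time_col)
  f1 <- calibrate_single(sp$X1, control)
  f2 <- calibrate_single(sp$X2, control)
  common <- intersect(f1$items, f2$items)
  if (!length(common)) abort("no common items across time points")
  structure(list(bank1 = f1$bank1[match(common, f1$bank1$item), ],
                 bank2 = f2$bank1[match(common, f2$bank1$item), ],
                 items = common, fits = list(f1, f2)),
            class = "ipd_calibs")
}

# build an ipd_calibs directly from two banks (used in tests / noiseless cases)
#' @rdname separate_calibrations
#' @param bank1,bank2 item banks from independent calibrations of each time
#'   point (each identified at mean 0, SD 1).
#' @export
as_calibs <- function(bank1, bank2) {
  bank1 <- .check_bank(bank1); bank2 <- .check_bank(bank2)
  common <- intersect(bank1$item, bank2$item)
  if (!length(common)) abort("no common items across banks")
  structure(list(bank1 = bank1[match(common, bank1$item), ],
                 bank2 = bank2[match(common, bank2$item), ],
                 items = common, fits = NULL),
            class = "ipd_calibs")
}

# one-row trend-estimate tibble shared by every estimator
new_trend <- function(method, mu2, sigma2, converged = TRUE,
                      settings = list()) {
  tibble(method = method, mu2 = as.numeric(mu2), sigma2 = as.numeric(sigma2),
         converged = isTRUE(converged), settings = list(settings))
}

#' Extract the trend estimate from a fit
#'
#' @param fit an `ipd_fit` (concurrent, fixed or regularized).
#' @param method label recorded in the output row.
#' @return One-row tibble with `method`, `mu2`, `sigma2`, `converged`.
#' @export
trend_estimate <- function(fit, method = fit$type) {
  new_trend(method, fit$mu2, fit$sigma2, fit$converged,
            settings = list(type = fit$type, free_items = fit$free_items))
}

#' @export
tidy.ipd_fit <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$bank1, time = x$dist$time[1], .before = 1),
    if (x$type != "single") mutate(x$bank2, time = x$dist$time[2], .before = 1)
  )
}

#' @export
glance.ipd_fit <- function(x, ...) {
  tibble(logLik = x$loglik, deviance = x$deviance,
         iterations = x$iterations, converged = x$converged,
         n1 = x$n[1], n2 = x$n[2],
         mu2 = if (x$type == "single") NA_real_ else x$mu2,
         sigma2 = if (x$type == "single") NA_real_ else x$sigma2)
}

#' @export
print.ipd_fit <- function(x, ...) {
  cat(sprintf("<ipd_fit: %s> %d items, n = (%d, %d)\n",
              x$type, length(x$items), x$n[1], x$n[2]))
  if (x$type != "single")
    cat(sprintf("  mu2 = %.4f, sigma2 = %.4f\n", x$mu2, x$sigma2))
  cat(sprintf("  logLik = %.2f, %d EM iterations, converged: %s\n",
              x$loglik, x$iterations, x$converged))
  if (length(x$free_items))
    cat("  freed items:", paste(x$free_items, collapse = ", "), "\n")
  invisible(x)
}
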