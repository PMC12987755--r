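#' MAD-to-SD scaling constant
#'
#' The constant 1.4826 that rescales a median absolute deviation to estimate
#' a standard deviation under normality (the reciprocal of the 0.75 standard
#' normal quantile).
#'
#' @export
mad_scale <- 1.4826

#' Root mean square deviation between two IRFs
#'
#' Density-weighted root-mean-square distance between an item's
#' time-point-specific IRF and its invariance-constrained IRF, both evaluated
#' on a common grid.
#'
#' @param p_time,p_joint IRF values on the grid (vectors, or item x node
#'   matrices).
#' @param w normalized density weights over the grid.
#' @return RMSD value(s) in probability units, one per item.
#' @export
rmsd_irf <- function(p_time, p_joint, w) {
  if (is.matrix(p_time)) return(sqrt(as.vector((p_time - p_joint)^2 %*% w)))
  sqrt(sum(w * (p_time - p_joint)^2))
}

#' RMSD drift statistics from a constrained fit
#'
#' For each common item and time point, compares the pseudo-observed IRF
#' (expected correct over expected exposure from the fit's E-step, the
#' operational large-scale-assessment estimator) with the model-implied IRF
#' under the fit's constraints, weighted by the model-implied normal ability
#' density of that time point.
#'
#' @param fit a concurrent `ipd_fit`.
#' @param items optional subset of items.
#' @return Tibble with `item`, `time`, `rmsd`.
#' @export
rmsd_statistic <- function(fit, items = NULL) {
  if (!inherits(fit, "ipd_fit") || fit$type == "single")
    abort("`fit` must be a two-group calibration")
  use <- items %||% fit$items
  idx <- match(use, fit$items)
  raw <- fit$raw
  out <- vector("list", 2)
  for (t in 1:2) {
    e <- if (t == 1) raw$e1 else raw$e2
    theta <- if (t == 1) raw$z else raw$mu2 + raw$sigma2 * raw$z
    a <- if (t == 1) raw$a1 else raw$a2
    d <- if (t == 1) raw$d1 else raw$d2
    pm <- plogis(outer(a[idx], theta) - d[idx])
    nmat <- if (isTRUE(e$n_from_nq))
      matrix(e$nq, length(idx), length(theta), byrow = TRUE) else e$n[idx, , drop = FALSE]
    po <- e$r[idx, , drop = FALSE] / pmax(nmat, 1e-12)
    out[[t]] <- tibble(item = use, time = fit$dist$time[t],
                       rmsd = rmsd_irf(po, pm, raw$w))
  }
  bind_rows(out)
}

#' Robust z-scores of RMSD values
#'
#' Centers at the median and scales by 1.4826 times the median absolute
#' deviation. A degenerate MAD is floored at 1e-8, so ties give z = 0 and a
#' value strictly above the median maps to a large capped score.
#'
#' @param values RMSD values for the common items at one time point.
#' @return Signed z-scores (positive side is the flagging side).
#' @export
robust_zscores <- function(values) {
  if (length(values) < 3) abort("need at least 3 common items")
  med <- median(values)
  scale <- mad_scale * max(median(abs(values - med)), 1e-8)
  pmax(pmin((values - med) / scale, 1e6), -1e6)
}

#' Likelihood-ratio drift tests
#'
#' All-other anchor LRT: the baseline model constrains every common item to
#' be invariant; each tested item is freed (both parameters, at both time
#' points) in turn, and G2 = -2 (logL0 - logL1) is referred to chi-square
#' with 2 degrees of freedom. Alternative fits warm-start from the baseline
#' and stop on a deviance-change rule, which is what G2 consumes.
#'
#' @inheritParams calibrate_concurrent
#' @param items items to test (default: all).
#' @param baseline optional precomputed constrained fit.
#' @param dev_tol deviance-change tolerance for the alternative fits; the
#'   default resolves G2 far below the chi-square critical values in use.
#' @return Tibble with `item`, `G2`, `df`, `p_value`; items whose alternative
#'   fit fails are returned as `NA` with a warning.
#' @export
lrt_statistics <- function(data, items = NULL, time_col = "time",
                           control = em_control(), baseline = NULL,
                           dev_tol = 1e-3) {
  fit0 <- baseline %||% calibrate_concurrent(data, time_col = time_col,
                                             control = control)
  use <- items %||% fit0$items
  ctl <- control; ctl$criterion <- "deviance"; ctl$dev_tol <- dev_tol
  warm <- list(a1 = fit0$raw$a1, d1 = fit0$raw$d1, a2 = fit0$raw$a2,
               d2 = fit0$raw$d2, mu2 = fit0$raw$mu2, sigma2 = fit0$raw$sigma2)
  g2 <- vapply(use, function(it) {
    alt <- tryCatch(
      calibrate_concurrent(data, free_items = it, time_col = time_col,
                           control = ctl, start = warm),
      error = function(e) NULL)
    if (is.null(alt) || !alt$converged) {
      warn(sprintf("alternative fit for item %s did not converge; skipped", it))
      return(NA_real_)
    }
    fit0$deviance - alt$deviance
  }, numeric(1))
  tibble(item = use, G2 = g2, df = 2, p_value = pchisq(g2, 2, lower.tail = FALSE))
}

#' Detection configuration
#'
#' @param statistic `"rmsd_fixed"`, `"rmsd_dd"` (data-driven MAD cutoff) or
#'   `"lrt"`.
#' @param cutoff fixed RMSD cutoff (0.03 / 0.05 / 0.08) or robust-z threshold
#'   tau (1.7 / 2.7); ignored for `"lrt"`.
#' @param alpha LRT significance level, or `"bonferroni"` for 0.05 divided by
#'   the number of items tested.
#' @param approach `"os"` (one-step) or `"it"` (forward-only iterative;
#'   RMSD only).
#' @param max_iter iteration cap for the iterative approach.
#' @param min_anchor minimum number of items that must remain anchors.
#' @param reestimator re-estimation method applied to the final partition:
#'   `"CC"`, `"HAB-int"`, `"HAB-dif"`, `"HAE-uniform"`, `"HAE-normal0.5"`,
#'   `"HAE-normal1"` or `"HAE-normal2"` (linking variants use squared loss).
#' @return A `detection_config` list.
#' @export
detection_config <- function(statistic = c("rmsd_fixed", "rmsd_dd", "lrt"),
                             cutoff = 0.05, alpha = 0.05,
                             approach = c("os", "it"),
                             max_iter = 7, min_anchor = 3,
                             reestimator = "CC") {
  statistic <- match.arg(statistic)
  approach <- match.arg(approach)
  if (statistic == "lrt" && approach == "it")
    abort("the likelihood-ratio test is evaluated with the one-step approach only")
  if (min_anchor < 3) abort("at least three anchor items are required")
  structure(list(statistic = statistic, cutoff = cutoff, alpha = alpha,
                 approach = approach, max_iter = max_iter,
                 min_anchor = min_anchor, reestimator = reestimator),
            class = "detection_config")
}

#' Apply flagging rules to per-item statistics
#'
#' Flags statistics exceeding the threshold, truncated so that at least
#' `min_anchor` of the `n_common` common items stay anchors; when truncating,
#' the largest statistics win, ties broken by lower item position.
#'
#' @param values per-item statistic values (`NA` = not tested).
#' @param threshold flagging threshold.
#' @param n_common total number of common items.
#' @param n_already items already removed from the anchor set.
#' @param min_anchor minimum anchor count.
#' @return Logical flag vector.
#' @export
flag_items <- function(values, threshold, n_common = length(values),
                       n_already = 0, min_anchor = 3) {
  flagged <- !is.na(values) & values > threshold
  max_new <- max(n_common - min_anchor - n_already, 0)
  if (sum(flagged) > max_new) {
    ord <- order(-values, seq_along(values), na.last = TRUE)
    flagged <- rep(FALSE, length(values))
    if (max_new > 0) flagged[ord[seq_len(max_new)]] <- TRUE
  }
  flagged
}

# per-item flagging statistic and threshold for one round
.round_stats <- function(fit, data, config, anchor_items, time_col, control) {
  if (config$statistic == "lrt") {
    k <- length(anchor_items)
    alpha <- if (identical(config$alpha, "bonferroni")) 0.05 / k else config$alpha
    st <- lrt_statistics(data, items = anchor_items, time_col = time_col,
                         control = control, baseline = fit)
    list(value = setNames(st$G2, st$item), threshold = qchisq(1 - alpha, 2),
         detail = st)
  } else {
    rs <- rmsd_statistic(fit, items = anchor_items)
    wide <- tidyr::pivot_wider(rs, names_from = "time", values_from = "rmsd")
    m <- as.matrix(wide[, -1])
    if (config$statistic == "rmsd_fixed") {
      list(value = setNames(pmax(m[, 1], m[, 2]), wide$item),
           threshold = config$cutoff, detail = rs)
    } else {
      z <- apply(m, 2, robust_zscores)
      list(value = setNames(pmax(z[, 1], z[, 2]), wide$item),
           threshold = config$cutoff, detail = rs)
    }
  }
}

#' Detect drifting items and partition the common-item set
#'
#' One-step: statistics are computed once under the full-invariance fit and
#' exceeders move to the biased set. Iterative (RMSD only): each round
#' re-fits the partial-invariance model with the current biased set freed,
#' recomputes statistics for the remaining anchors only, and stops when no
#' new item is flagged or after `max_iter` rounds; flagged items are never
#' retested. At least `min_anchor` anchors always remain.
#'
#' @inheritParams calibrate_concurrent
#' @param config a [detection_config()].
#' @param baseline optional precomputed full-invariance fit.
#' @return An `ipd_partition`: `anchor`, `biased`, per-round `stats`, the
#'   final constrained `fit`, `iterations`, and the `config`.
#' @export
detect_drift <- function(data, config, time_col = "time",
                         control = em_control(), baseline = NULL) {
  fit <- baseline %||% calibrate_concurrent(data, time_col = time_col,
                                            control = control)
  all_items <- fit$items
  biased <- character(0)
  history <- list()
  n_iter <- if (config$approach == "os") 1L else config$max_iter
  it <- 0
  repeat {
    it <- it + 1
    anchor <- setdiff(all_items, biased)
    rs <- .round_stats(fit, data, config, anchor, time_col, control)
    fl <- flag_items(rs$value, rs$threshold, n_common = length(all_items),
                     n_already = length(biased),
                     min_anchor = config$min_anchor)
    history[[it]] <- tibble(item = names(rs$value), statistic = config$statistic,
                            value = unname(rs$value), threshold = rs$threshold,
                            iteration = it, flagged = fl)
    new_flags <- names(rs$value)[fl]
    biased <- c(biased, new_flags)
    if (it >= n_iter || !length(new_flags)) break
    fit <- calibrate_concurrent(data, free_items = biased, time_col = time_col,
                                control = control)
  }
  structure(list(anchor = setdiff(all_items, biased), biased = biased,
                 stats = bind_rows(history), fit = fit, iterations = it,
                 config = config),
            class = "ipd_partition")
}

#' @export
print.ipd_partition <- function(x, ...) {
  cat(sprintf("<ipd_partition> %d anchors, %d biased (%s, %s), %d iteration(s)\n",
              length(x$anchor), length(x$biased), x$config$statistic,
              x$config$approach, x$iterations))
  if (length(x$biased)) cat("  biased:", paste(x$biased, collapse = ", "), "\n")
  invisible(x)
}

#' Re-estimate the trend under partial invariance
#'
#' Given an anchor/biased partition, re-estimates the time-2 mean and SD
#' either by concurrent calibration with the biased items freed, or by
#' linking the separate calibrations on the anchor items with squared loss.
#'
#' @inheritParams calibrate_concurrent
#' @param partition an `ipd_partition` (or list with `anchor` and `biased`).
#' @param reestimator see [detection_config()].
#' @param calibs optional precomputed [separate_calibrations()] (linking
#'   re-estimators only).
#' @return One-row trend tibble.
#' @export
reestimate_partial_invariance <- function(data, partition,
                                          reestimator = partition$config$reestimator,
                                          time_col = "time",
                                          control = em_control(),
                                          calibs = NULL) {
  if (length(partition$anchor) < 3)
    abort(sprintf("partition leaves %d anchors; at least 3 are required",
                  length(partition$anchor)))
  if (reestimator == "CC") {
    fit <- if (!length(partition$biased) && !is.null(partition$fit) &&
               !length(partition$fit$free_items)) partition$fit
      else calibrate_concurrent(data, free_items = partition$biased,
                                time_col = time_col, control = control)
    est <- trend_estimate(fit, "CC-partial")
  } else {
    calibs <- calibs %||% separate_calibrations(data, time_col, control)
    l2 <- loss_spec(2)
    est <- switch(reestimator,
      "HAB-int" = haberman_link(calibs, l2, "intercepts", items = partition$anchor),
      "HAB-dif" = haberman_link(calibs, l2, "difficulties", items = partition$anchor),
      "HAE-uniform" = haebara_link(calibs, l2, weight_spec("uniform"),
                                   items = partition$anchor),
      "HAE-normal0.5" = haebara_link(calibs, l2, weight_spec("normal", 0.5),
                                     items = partition$anchor),
      "HAE-normal1" = haebara_link(calibs, l2, weight_spec("normal", 1),
                                   items = partition$anchor),
      "HAE-normal2" = haebara_link(calibs, l2, weight_spec("normal", 2),
                                   items = partition$anchor),
      abort(sprintf("unknown reestimator `%s`", reestimator)))
  }
  est$settings[[1]]$anchor <- partition$anchor
  est$settings[[1]]$biased <- partition$biased
  est
}
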