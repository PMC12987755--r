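#' Enumerate the trend-estimator grid
#'
#' The full study grid of 126 estimator configurations: concurrent and fixed
#' calibration; Haberman linking (intercepts and difficulties) and Haebara
#' linking (uniform and normal-density weights of width 0.5, 1, 2), each with
#' loss powers 0, 0.25, 0.5, 1, 2; the likelihood-ratio test at alpha 0.05,
#' 0.01 and Bonferroni; RMSD detection with fixed cutoffs 0.03/0.05/0.08 and
#' data-driven cutoffs 1.7/2.7, one-step and iterative, each feeding seven
#' re-estimators; and regularized estimation with eps 0.01/0.001/0.0001.
#'
#' @return Tibble with `label`, `family` and a `settings` list-column.
#' @export
enumerate_estimators <- function() {
  ps <- c(0, 0.25, 0.5, 1, 2)
  re7 <- c("CC", "HAB-int", "HAB-dif", "HAE-uniform",
           "HAE-normal0.5", "HAE-normal1", "HAE-normal2")
  rows <- list(
    tibble(label = "CC", family = "CC", settings = list(list())),
    tibble(label = "FC", family = "FC", settings = list(list()))
  )
  for (par in c("int", "dif")) for (p in ps)
    rows <- c(rows, list(tibble(
      label = sprintf("HAB-%s(p=%g)", par, p), family = "HAB",
      settings = list(list(parameterization =
                             if (par == "int") "intercepts" else "difficulties",
                           p = p)))))
  for (wt in c("uniform", "normal0.5", "normal1", "normal2")) for (p in ps)
    rows <- c(rows, list(tibble(
      label = sprintf("HAE(%s,p=%g)", wt, p), family = "HAE",
      settings = list(list(weight = wt, p = p)))))
  for (al in list("0.05", "0.01", "bonf")) for (re in re7)
    rows <- c(rows, list(tibble(
      label = sprintf("LRT-%s+%s", if (al == "bonf") "bonf" else paste0("a", al),
                      re), family = "LRT",
      settings = list(list(alpha = if (al == "bonf") "bonferroni"
                           else as.numeric(al), reestimator = re)))))
  for (cu in c("FIX0.03", "FIX0.05", "FIX0.08", "DD1.7", "DD2.7"))
    for (ap in c("OS", "IT")) for (re in re7)
      rows <- c(rows, list(tibble(
        label = sprintf("RMSD-%s-%s+%s", cu, ap, re), family = "RMSD",
        settings = list(list(
          statistic = if (startsWith(cu, "FIX")) "rmsd_fixed" else "rmsd_dd",
          cutoff = as.numeric(sub("FIX|DD", "", cu)),
          approach = tolower(ap), reestimator = re)))))
  for (eps in c(0.01, 0.001, 0.0001))
    rows <- c(rows, list(tibble(
      label = sprintf("REG(eps=%s)", format(eps, scientific = FALSE)),
      family = "REG", settings = list(list(eps = eps)))))
  bind_rows(rows)
}

# memoized per-dataset computations shared across estimators
.make_cache <- function(data, time_col, control) {
  env <- new.env(parent = emptyenv())
  env$data <- data; env$time_col <- time_col; env$control <- control
  env$sp <- .split_times(data, time_col)
  env$store <- list()
  env
}

.memo <- function(cache, key, fun) {
  if (is.null(cache$store[[key]])) cache$store[[key]] <- fun()
  cache$store[[key]]
}

.cc_fit <- function(cache) .memo(cache, "cc", function()
  calibrate_concurrent(cache$data, time_col = cache$time_col,
                       control = cache$control))

.calib1 <- function(cache) .memo(cache, "calib1", function()
  calibrate_single(cache$sp$X1, cache$control))

.calibs <- function(cache) .memo(cache, "calibs", function() {
  f1 <- .calib1(cache)
  f2 <- calibrate_single(cache$sp$X2, cache$control)
  common <- intersect(f1$items, f2$items)
  structure(list(bank1 = f1$bank1[match(common, f1$bank1$item), ],
                 bank2 = f2$bank1[match(common, f2$bank1$item), ],
                 items = common, fits = list(f1, f2)),
            class = "ipd_calibs")
})

# concurrent fit with a given biased set freed, warm-started from the
# full-invariance fit and shared across detection variants
.partial_cc <- function(cache, biased) {
  key <- paste0("ccp_", paste(sort(biased), collapse = ","))
  .memo(cache, key, function() {
    cc <- .cc_fit(cache)
    warm <- list(a1 = cc$raw$a1, d1 = cc$raw$d1, a2 = cc$raw$a2,
                 d2 = cc$raw$d2, mu2 = cc$raw$mu2, sigma2 = cc$raw$sigma2)
    calibrate_concurrent(cache$data, free_items = biased,
                         time_col = cache$time_col, control = cache$control,
                         start = warm)
  })
}

.lrt_stats <- function(cache) .memo(cache, "lrt", function()
  lrt_statistics(cache$data, time_col = cache$time_col,
                 control = cache$control, baseline = .cc_fit(cache)))

.loss_for <- function(p) loss_spec(p)

.weight_for <- function(wt) switch(wt,
  uniform = weight_spec("uniform"),
  normal0.5 = weight_spec("normal", 0.5),
  normal1 = weight_spec("normal", 1),
  normal2 = weight_spec("normal", 2),
  abort(sprintf("unknown weight `%s`", wt)))

# build an ipd_partition without re-running detection, from cached one-step
# statistics
.partition_from <- function(values, threshold, statistic, fit, config) {
  fl <- flag_items(values, threshold, n_common = length(values),
                   min_anchor = config$min_anchor)
  structure(list(anchor = names(values)[!fl], biased = names(values)[fl],
                 stats = tibble(item = names(values), statistic = statistic,
                                value = unname(values), threshold = threshold,
                                iteration = 1L, flagged = fl),
                 fit = fit, iterations = 1L, config = config),
            class = "ipd_partition")
}

.detect_cached <- function(cache, st) {
  config <- detection_config(statistic = st$statistic %||% "lrt",
                             cutoff = st$cutoff %||% 0.05,
                             alpha = st$alpha %||% 0.05,
                             approach = st$approach %||% "os",
                             reestimator = st$reestimator)
  if (config$statistic == "lrt") {
    stats <- .lrt_stats(cache)
    k <- nrow(stats)
    alpha <- if (identical(config$alpha, "bonferroni")) 0.05 / k else config$alpha
    return(.partition_from(setNames(stats$G2, stats$item), qchisq(1 - alpha, 2),
                           "lrt", .cc_fit(cache), config))
  }
  if (config$approach == "os") {
    rs <- .memo(cache, "rmsd_os", function() rmsd_statistic(.cc_fit(cache)))
    wide <- tidyr::pivot_wider(rs, names_from = "time", values_from = "rmsd")
    m <- as.matrix(wide[, -1])
    vals <- if (config$statistic == "rmsd_fixed") pmax(m[, 1], m[, 2])
    else pmax(robust_zscores(m[, 1]), robust_zscores(m[, 2]))
    return(.partition_from(setNames(vals, wide$item), config$cutoff,
                           config$statistic, .cc_fit(cache), config))
  }
  key <- paste("det", config$statistic, config$cutoff, sep = "_")
  .memo(cache, key, function()
    detect_drift(cache$data, config, time_col = cache$time_col,
                 control = cache$control, baseline = .cc_fit(cache)))
}

.estimate_one <- function(cache, family, label, st) {
  ctl <- cache$control
  est <- switch(family,
    CC = trend_estimate(.cc_fit(cache), "CC"),
    FC = {
      bank1 <- .calib1(cache)$bank1
      trend_estimate(calibrate_fixed(cache$sp$X2, bank1, control = ctl), "FC")
    },
    HAB = haberman_link(.calibs(cache), .loss_for(st$p), st$parameterization),
    HAE = haebara_link(.calibs(cache), .loss_for(st$p), .weight_for(st$weight)),
    REG = {
      fit <- fit_regularized(cache$data, eps = st$eps,
                             time_col = cache$time_col, control = ctl,
                             cc_fit = .cc_fit(cache),
                             calibs = tryCatch(.calibs(cache),
                                               error = function(e) NULL))
      trend_estimate(fit, label)
    },
    LRT = ,
    RMSD = {
      part <- .detect_cached(cache, st)
      if (st$reestimator == "CC") {
        fit <- .partial_cc(cache, part$biased)
        est <- trend_estimate(fit, label)
        est$settings[[1]]$biased <- part$biased
        est
      } else {
        reestimate_partial_invariance(cache$data, part, st$reestimator,
                                      time_col = cache$time_col, control = ctl,
                                      calibs = .calibs(cache))
      }
    },
    abort(sprintf("unknown estimator family `%s`", family)))
  est$method <- label
  est
}

#' Compute trend estimates for a set of estimators
#'
#' Runs each requested estimator on one two-time-point dataset, sharing the
#' expensive building blocks (concurrent fit, separate calibrations,
#' detection statistics) across estimators. Failed estimators return `NA`
#' estimates with a warning rather than aborting the table.
#'
#' @inheritParams calibrate_concurrent
#' @param estimators tibble from [enumerate_estimators()] (any subset), or a
#'   character vector of labels from that grid.
#' @return Tibble with one row per estimator: `method`, `mu2`, `sigma2`,
#'   `converged`, `settings`.
#' @export
trend_estimates <- function(data, estimators = c("CC", "FC", "REG(eps=0.001)"),
                            time_col = "time", control = em_control()) {
  if (is.character(estimators)) {
    grid <- enumerate_estimators()
    idx <- match(estimators, grid$label)
    if (anyNA(idx))
      abort(sprintf("unknown estimator label(s): %s",
                    paste(estimators[is.na(idx)], collapse = ", ")))
    estimators <- grid[idx, ]
  }
  if (!nrow(estimators)) {
    warn("empty estimator list; returning an empty table")
    return(new_trend(character(0), numeric(0), numeric(0))[0, ])
  }
  cache <- .make_cache(data, time_col, control)
  purrr::pmap(estimators, function(label, family, settings) {
    tryCatch(.estimate_one(cache, family, label, settings),
             error = function(e) {
               warn(sprintf("estimator %s failed: %s", label, conditionMessage(e)))
               new_trend(label, NA_real_, NA_real_, FALSE)
             })
  }) %>% bind_rows()
}
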