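#' Run Monte-Carlo replications for one condition
#'
#' Generates `R` datasets under a simulation condition and applies each
#' requested estimator, with per-replication child seeds drawn
#' deterministically from the master seed.
#'
#' @param condition one row of [sim_design()].
#' @param estimators estimator tibble or labels (see [trend_estimates()]).
#' @param R number of replications.
#' @param master_seed integer master seed.
#' @param control EM settings.
#' @return Tibble of raw estimates: one row per replication x estimator with
#'   the condition id, truth, child seed and convergence flag.
#' @export
run_replications <- function(condition, estimators, R = 100, master_seed = 1,
                             control = em_control()) {
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1, R)
  cond_id <- condition$condition
  true_mu2 <- condition$mu2
  true_sigma2 <- condition$sigma2
  purrr::map(seq_len(R), function(r) {
    sim <- sim_responses(condition, seeds[r])
    est <- trend_estimates(sim$data, estimators, control = control)
    est$settings <- NULL
    mutate(est, condition = cond_id, rep = r, seed = seeds[r],
           true_mu2 = true_mu2, true_sigma2 = true_sigma2, .before = 1)
  }) %>% bind_rows()
}

#' Summarise raw estimates into bias, RMSE and relative RMSE
#'
#' Bias is the mean error, RMSE the root mean squared error over
#' replications; relative RMSE rescales each estimator's RMSE so the
#' reference estimator is 100 within every condition. Failed replications
#' (non-converged or `NA`) are excluded and counted.
#'
#' @param raw output of [run_replications()] (possibly row-bound over
#'   conditions).
#' @param reference reference estimator label for relative RMSE; set `NULL`
#'   to skip the normalization.
#' @param bias_ok,rel_rmse_ok satisfactory-performance thresholds for the
#'   flags.
#' @return An `ipd_evaluation` tibble: one row per condition x estimator x
#'   parameter with `bias`, `rmse`, `rel_rmse`, satisfactory flags, the
#'   replication count `R` used and `n_failed`.
#' @export
evaluate_estimates <- function(raw, reference = "REG(eps=0.001)",
                               bias_ok = 0.015, rel_rmse_ok = 125) {
  long <- raw %>%
    tidyr::pivot_longer(c("mu2", "sigma2"), names_to = "parameter",
                        values_to = "estimate") %>%
    mutate(truth = ifelse(.data$parameter == "mu2", .data$true_mu2,
                          .data$true_sigma2),
           ok = .data$converged & is.finite(.data$estimate))
  out <- long %>%
    group_by(.data$condition, .data$method, .data$parameter) %>%
    summarise(bias = mean(.data$estimate[.data$ok] - .data$truth[.data$ok]),
              rmse = sqrt(mean((.data$estimate[.data$ok] - .data$truth[.data$ok])^2)),
              R = sum(.data$ok), n_failed = sum(!.data$ok),
              .groups = "drop")
  if (!is.null(reference)) {
    if (!reference %in% out$method)
      abort(sprintf("reference estimator `%s` absent from the results", reference))
    ref <- out %>% filter(.data$method == reference) %>%
      select("condition", "parameter", ref_rmse = "rmse")
    out <- out %>% left_join(ref, by = c("condition", "parameter")) %>%
      mutate(rel_rmse = 100 * .data$rmse / .data$ref_rmse) %>%
      select(-"ref_rmse")
  } else {
    out$rel_rmse <- NA_real_
  }
  out <- out %>%
    mutate(bias_satisfactory = abs(.data$bias) < bias_ok,
           rmse_satisfactory = !is.na(.data$rel_rmse) &
             .data$rel_rmse <= rel_rmse_ok)
  class(out) <- c("ipd_evaluation", class(out))
  out
}

#' @importFrom rlang .data
NULL
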