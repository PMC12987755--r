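.read_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or the path to a YAML file")
  config
}

.write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(package = "ipdtrend",
                     version = as.character(utils::packageVersion("ipdtrend")),
                     config_hash = rlang::hash(config),
                     config = config), extra)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

#' Analyze a two-time-point dataset
#'
#' Applies a set of trend estimators to a wide response table: one row per
#' requested estimator with the estimated time-2 mean and SD; detection-based
#' estimators also report their flagged items.
#'
#' @param config list (or YAML path) with fields `data` (path to a delimited
#'   response file) or `dataset` (an in-memory tibble), `estimators`
#'   (character labels), optional `time_col`, `out` (output directory) and
#'   EM `control` overrides.
#' @return Tibble of trend estimates (invisibly written to
#'   `<out>/estimates.tsv` with a manifest when `out` is set).
#' @export
run_analyze <- function(config) {
  config <- .read_config(config)
  data <- config$dataset %||% read_responses(config$data,
                                             config$time_col %||% "time")
  ctl <- do.call(em_control, config$control %||% list())
  est <- trend_estimates(data, config$estimators %||% c("CC", "FC", "REG(eps=0.001)"),
                         time_col = config$time_col %||% "time", control = ctl)
  flagged <- purrr::map_chr(est$settings, function(s)
    paste(s$biased %||% character(0), collapse = ","))
  out <- mutate(select(est, -"settings"), flagged_items = flagged)
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(config$out, "estimates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    cfg <- config; cfg$dataset <- NULL
    .write_manifest(file.path(config$out, "manifest.yaml"), cfg)
  }
  out
}

#' Run a simulation study
#'
#' Wraps [sim_design()], [run_replications()] and [evaluate_estimates()]:
#' simulates every requested condition, applies the requested estimators and
#' writes long-format results plus a self-describing manifest.
#'
#' @param config list (or YAML path) with fields `seed` (mandatory), `reps`,
#'   `estimators`, optional condition filters (`n`, `n_items`, `delta`,
#'   `pct_ipd`, `ipd_type`), `reference` for relative RMSE, `out` directory
#'   and EM `control` overrides.
#' @return List with `raw` estimates, the `evaluation` table and the
#'   manifest.
#' @export
run_simulate <- function(config) {
  config <- .read_config(config)
  if (is.null(config$seed)) abort("`seed` is mandatory for simulation runs")
  known <- c("seed", "reps", "estimators", "reference", "out", "control",
             "n", "n_items", "delta", "pct_ipd", "ipd_type")
  bad <- setdiff(names(config), known)
  if (length(bad))
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  design <- sim_design()
  for (f in c("n", "n_items", "delta", "pct_ipd", "ipd_type"))
    if (!is.null(config[[f]])) design <- design[design[[f]] %in% config[[f]], ]
  if (!nrow(design)) abort("condition filters match no design rows")
  ctl <- do.call(em_control, config$control %||% list())
  estimators <- config$estimators %||% c("CC", "FC", "REG(eps=0.001)")
  R <- config$reps %||% 100
  raw <- purrr::map(seq_len(nrow(design)), function(i)
    run_replications(design[i, ], estimators, R = R,
                     master_seed = config$seed + i - 1, control = ctl)) %>%
    bind_rows()
  reference <- config$reference %||%
    (if ("REG(eps=0.001)" %in% estimators) "REG(eps=0.001)" else NULL)
  evaluation <- evaluate_estimates(raw, reference = reference)
  manifest <- NULL
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write.table(raw, file.path(config$out, "raw_estimates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(evaluation),
                file.path(config$out, "evaluation.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest <- .write_manifest(file.path(config$out, "manifest.yaml"), config,
                                list(conditions = design$condition,
                                     reps = R))
  }
  list(raw = raw, evaluation = evaluation, manifest = manifest)
}
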