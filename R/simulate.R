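#' The simulation condition grid
#'
#' Crosses sample size (500, 1000, 2500 per time point), item count (20, 40),
#' drift effect size (0.5, 1.0), percentage of drifting items (10, 30) and
#' drift type (balanced, unbalanced), plus one no-drift condition per
#' (N, I) cell: 54 unique conditions. The true time-2 distribution is
#' mean 1.0, SD 1.3 throughout.
#'
#' @param n,n_items,delta,pct_ipd,ipd_type factor levels; defaults are the
#'   study grid.
#' @param mu2,sigma2 true time-2 latent mean and SD.
#' @return Tibble of conditions with a `condition` id column.
#' @export
sim_design <- function(n = c(500, 1000, 2500), n_items = c(20, 40),
                       delta = c(0.5, 1), pct_ipd = c(10, 30),
                       ipd_type = c("balanced", "unbalanced"),
                       mu2 = 1, sigma2 = 1.3) {
  drift <- tidyr::expand_grid(delta = delta, pct_ipd = pct_ipd,
                              ipd_type = ipd_type)
  drift <- bind_rows(tibble(delta = 0, pct_ipd = 0, ipd_type = "none"), drift)
  out <- tidyr::expand_grid(n = n, n_items = n_items, drift) %>%
    mutate(mu2 = mu2, sigma2 = sigma2,
           condition = sprintf("N%d_I%d_d%g_p%d_%s", n, n_items, delta,
                               pct_ipd, substr(ipd_type, 1, 3)),
           .before = 1) %>%
    select("condition", dplyr::everything())
  out
}

#' Per-item drift effects for a condition
#'
#' Drift lands on the designated positions of each 10-item block: item 10
#' for 10% drift, items 8-10 for 30%. Unbalanced drift sets every affected
#' effect to `-delta`; balanced drift alternates `+delta`, `-delta` over the
#' affected items in index order, so the effects sum to zero exactly.
#'
#' @param n_items number of items (multiple of 10).
#' @param delta absolute drift effect size.
#' @param pct_ipd percentage of drifting items: 0, 10 or 30.
#' @param ipd_type `"balanced"`, `"unbalanced"` or `"none"`.
#' @return Tibble with `item` and `delta` (the time-2 intercept shift).
#' @export
drift_pattern <- function(n_items, delta, pct_ipd = 30,
                          ipd_type = c("unbalanced", "balanced", "none")) {
  ipd_type <- match.arg(ipd_type)
  bank <- base_item_bank(n_items)
  d <- rep(0, n_items)
  if (ipd_type != "none" && delta != 0 && pct_ipd > 0) {
    pos <- if (pct_ipd == 10) 10 else if (pct_ipd == 30) 8:10
    else abort("`pct_ipd` must be 0, 10 or 30")
    aff <- sort(as.vector(outer(pos, seq(0, n_items - 10, by = 10), `+`)))
    d[aff] <- if (ipd_type == "unbalanced") -abs(delta)
    else abs(delta) * rep_len(c(1, -1), length(aff))
  }
  tibble(item = bank$item, delta = d)
}

#' Simulate two-time-point 2PL responses with intercept drift
#'
#' Time-1 abilities are standard normal; time-2 abilities are normal with the
#' condition's mean and SD. Responses are Bernoulli draws from the 2PL IRF of
#' the base item bank, with the drift effects added to the time-2 intercepts.
#'
#' @param condition one row of [sim_design()] (or a list with fields `n`,
#'   `n_items`, `delta`, `pct_ipd`, `ipd_type`, `mu2`, `sigma2`).
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @return List with `data` (wide tibble: `time` plus item columns), `drift`
#'   (the [drift_pattern()] used) and `bank` (the generating bank).
#' @export
sim_responses <- function(condition, seed) {
  cn <- as.list(condition)
  bank <- base_item_bank(cn$n_items)
  drift <- drift_pattern(cn$n_items, cn$delta, cn$pct_ipd, cn$ipd_type)
  set.seed(as.integer(seed %% .Machine$integer.max))
  draw <- function(mu, sigma, dshift) {
    theta <- rnorm(cn$n, mu, sigma)
    P <- plogis(outer(theta, bank$a) -
                  matrix(bank$d + dshift, cn$n, cn$n_items, byrow = TRUE))
    X <- matrix(rbinom(length(P), 1, P), cn$n, cn$n_items)
    colnames(X) <- bank$item
    X
  }
  X1 <- draw(0, 1, 0)
  X2 <- draw(cn$mu2, cn$sigma2, drift$delta)
  data <- bind_rows(
    bind_cols(tibble(time = 1L), as_tibble(X1)),
    bind_cols(tibble(time = 2L), as_tibble(X2))
  )
  list(data = data, drift = drift, bank = bank)
}

#' Read or write a wide response table
#'
#' Delimited text with a header row: a time column (default `time`, values
#' 1/2) and one 0/1 column per item; missing responses as empty cells or
#' `NA`.
#'
#' @param file path; `.csv` is comma-separated, anything else tab-separated.
#' @param time_col name of the time column.
#' @return `read_responses()` returns a wide tibble.
#' @export
read_responses <- function(file, time_col = "time") {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- as_tibble(read.delim(file, sep = sep, na.strings = c("", "NA"),
                             check.names = FALSE))
  if (!time_col %in% names(df))
    abort(sprintf("response file must contain a `%s` column", time_col))
  df
}

#' @rdname read_responses
#' @param data wide response tibble.
#' @export
write_responses <- function(data, file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  write.table(data, file, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(file)
}
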