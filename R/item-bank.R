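#' Construct an item bank
#'
#' An item bank is a tibble with one row per item holding the 2PL item
#' parameters: the discrimination `a` and the (negative) intercept `d` of the
#' item-response function \eqn{P(\theta) = \Psi(a\theta - d)}. The difficulty
#' `b = d / a` is derived, never stored independently.
#'
#' @param item character vector of unique item identifiers.
#' @param a strictly positive discriminations.
#' @param d intercepts, in logit units.
#'
#' @return A tibble with columns `item`, `a`, `d` and derived `b`.
#' @export
#' @examples
#' item_bank(c("i1", "i2"), a = c(1, 0.8), d = c(0, -0.5))
item_bank <- function(item, a, d) {
  item <- as.character(item)
  if (anyDuplicated(item)) abort("item ids must be unique")
  if (length(a) != length(item) || length(d) != length(item))
    abort("`item`, `a` and `d` must have equal length")
  if (!all(is.finite(a)) || any(a <= 0))
    abort("discriminations `a` must be finite and strictly positive")
  if (!all(is.finite(d))) abort("intercepts `d` must be finite")
  tibble(item = item, a = as.numeric(a), d = as.numeric(d), b = d / a)
}

#' The ten-item base bank used by the simulation design
#'
#' Returns the fixed set of 10 base items replicated into blocks of 10 to
#' reach `n_items` (20 or 40 in the study design; any multiple of 10 works).
#' Items 8-10 of each block have `a = 1` and are the drift-designated
#' positions.
#'
#' @param n_items total number of items; a multiple of 10.
#' @return An item bank tibble (see [item_bank()]).
#' @export
#' @examples
#' base_item_bank(20)
base_item_bank <- function(n_items = 20) {
  if (n_items %% 10 != 0 || n_items < 10)
    abort("`n_items` must be a positive multiple of 10")
  a0 <- c(1.06, 0.78, 0.91, 1.14, 1.19, 0.89, 0.82, 1.00, 1.00, 1.00)
  d0 <- c(-0.17, -0.77, 0.36, 1.37, 2.08, -1.56, 0.72, -0.46, -0.46, -0.46)
  k <- n_items / 10
  item_bank(sprintf("I%02d", seq_len(n_items)), rep(a0, k), rep(d0, k))
}

.check_bank <- function(bank) {
  need <- c("item", "a", "d")
  if (!all(need %in% names(bank)))
    abort("item bank needs columns `item`, `a`, `d`")
  item_bank(bank$item, bank$a, bank$d)
}

#' Read or write an item-parameter table
#'
#' Delimited text with a header row and columns `item`, `a`, `d`. The
#' delimiter is inferred from the extension (`.csv` comma, otherwise tab).
#'
#' @param file path to a delimited text file.
#' @return `read_item_bank()` returns an item bank tibble.
#' @export
read_item_bank <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  .check_bank(df)
}

#' @rdname read_item_bank
#' @param bank an item bank tibble.
#' @export
write_item_bank <- function(bank, file) {
  bank <- .check_bank(bank)
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  write.table(bank[c("item", "a", "d")], file, sep = sep,
              row.names = FALSE, quote = FALSE)
  invisible(file)
}
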