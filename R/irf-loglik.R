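#' 2PL item-response function
#'
#' Probability of a correct response under the two-parameter logistic model,
#' \eqn{P(\theta) = \Psi(a\theta - d)} with \eqn{\Psi} the logistic CDF.
#'
#' @param theta latent-trait value(s).
#' @param a discrimination, strictly positive.
#' @param d intercept (logit units); the difficulty is `d / a`.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' irf_2pl(0, a = 1, d = 0)        # 0.5
#' irf_2pl(0, a = 1.06, d = -0.17) # ~0.542
irf_2pl <- function(theta, a, d) {
  if (any(!is.finite(a)) || any(a <= 0))
    abort("discrimination `a` must be finite and strictly positive")
  plogis(a * theta - d)
}

#' Quadrature grid for marginal likelihood integration
#'
#' Equally spaced nodes in the standardized latent metric with weights
#' proportional to the standard normal density, renormalized to sum to one.
#' Group-specific grids are obtained by the affine rescaling
#' \eqn{\theta = \mu + \sigma z}.
#'
#' @param n number of nodes.
#' @param range endpoints of the node range in standardized units.
#' @return A list with strictly increasing `z` and normalized weights `w`.
#' @export
quad_grid <- function(n = 61, range = c(-6, 6)) {
  if (length(n) != 1 || n < 2) abort("quadrature grid needs at least 2 nodes")
  z <- seq(range[1], range[2], length.out = n)
  w <- dnorm(z)
  list(z = z, w = w / sum(w))
}

# coerce a person x item response object to an integer matrix with NAs
.resp_matrix <- function(data, items = NULL) {
  if (is.data.frame(data)) {
    if (!is.null(items)) data <- data[items] else items <- names(data)
    X <- as.matrix(data)
  } else {
    X <- as.matrix(data)
    if (is.null(items)) items <- colnames(X) %||% sprintf("I%02d", seq_len(ncol(X)))
  }
  storage.mode(X) <- "integer"
  bad <- !(is.na(X) | X == 0L | X == 1L)
  if (any(bad)) abort("responses must be 0, 1 or missing")
  colnames(X) <- items
  X
}

# split a wide response tibble into per-time-point matrices
.split_times <- function(data, time_col = "time") {
  if (!time_col %in% names(data))
    abort(sprintf("response data must contain a `%s` column", time_col))
  tvals <- sort(unique(data[[time_col]]))
  if (length(tvals) != 2)
    abort("response data must contain exactly two time points")
  items <- setdiff(names(data), c(time_col, "person"))
  X1 <- .resp_matrix(data[data[[time_col]] == tvals[1], , drop = FALSE], items)
  X2 <- .resp_matrix(data[data[[time_col]] == tvals[2], , drop = FALSE], items)
  list(X1 = X1, X2 = X2, items = items, times = tvals)
}

.estep <- function(X, theta, w, a, d) {
  e <- .estep_cpp(X, theta, log(w), a, d)
  if (is.null(e$n)) e$n_from_nq <- TRUE
  e
}

# expected exposure counts for item i (row vector over nodes)
.item_n <- function(e, i) if (isTRUE(e$n_from_nq)) e$nq else e$n[i, ]

#' Marginal log-likelihood of a 2PL model for one group
#'
#' Evaluates the marginal (observed-data) log-likelihood, integrating the
#' latent trait over a normal distribution by quadrature. Missing responses
#' contribute a factor of one.
#'
#' @param bank item bank covering the response columns (see [item_bank()]).
#' @param dist list with elements `mu` and `sigma` (latent mean and SD).
#' @param data person x item responses (matrix or data frame of 0/1/NA).
#' @param grid quadrature grid from [quad_grid()].
#' @return A single finite number (0 for zero persons).
#' @export
marginal_loglik <- function(bank, dist, data, grid = quad_grid()) {
  bank <- .check_bank(bank)
  if (!is.list(grid) || is.null(grid$z) || is.null(grid$w) || !length(grid$z))
    abort("`grid` must be a quadrature grid with nodes and weights")
  if (is.null(dist$sigma) || dist$sigma <= 0) abort("`dist$sigma` must be > 0")
  X <- .resp_matrix(data)
  if (nrow(X) == 0) return(0)
  idx <- match(colnames(X), bank$item)
  if (anyNA(idx)) abort("all response columns must map to item bank ids")
  theta <- dist$mu + dist$sigma * grid$z
  .estep(X, theta, grid$w, bank$a[idx], bank$d[idx])$loglik
}
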