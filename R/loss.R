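#' Loss specification for robust linking
#'
#' The `Lp` family \eqn{\rho(x) = |x|^p} and the `L0` counting loss, in the
#' smooth differentiable approximations used for estimation:
#' \eqn{(x^2+\epsilon)^{p/2}} for `p > 0` (centred so the loss is 0 at 0) and
#' \eqn{x^2/(x^2+\epsilon)} for `p = 0`. For `p = 2` the smoothing is a
#' constant shift, so the exact squared loss is used.
#'
#' @param p loss power, `>= 0`; the study grid is 0, 0.25, 0.5, 1, 2.
#' @param epsilon smoothing parameter; defaults to 0.01 for `p = 0` and
#'   0.001 otherwise.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(p = 2, epsilon = NULL) {
  if (length(p) != 1 || !is.finite(p) || p < 0) abort("`p` must be a single number >= 0")
  epsilon <- epsilon %||% if (p == 0) 0.01 else 0.001
  if (epsilon <= 0) abort("`epsilon` must be > 0")
  structure(list(p = p, epsilon = epsilon), class = "loss_spec")
}

#' Evaluate a robust loss
#'
#' @param x residual value(s).
#' @param spec a [loss_spec()].
#' @return Nonnegative loss values; 0 at `x = 0`, symmetric in `x`.
#' @export
#' @examples
#' loss_value(2, loss_spec(2))               # 4
#' loss_value(1, loss_spec(0, 0.01))         # 1/1.01
loss_value <- function(x, spec) {
  if (!inherits(spec, "loss_spec")) spec <- do.call(loss_spec, as.list(spec))
  p <- spec$p; eps <- spec$epsilon
  if (p == 0) return(x^2 / (x^2 + eps))
  if (p == 2) return(x^2)
  (x^2 + eps)^(p / 2) - eps^(p / 2)
}
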