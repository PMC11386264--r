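#' Minimum-norm least-squares fit of the Fourier-series model
#'
#' Solves \eqn{\hat\delta = \arg\min \|y - X\delta\|^2}. Because the stacked
#' design carries `p` identical half-constant columns, the minimizer is not
#' unique for `p >= 2`; among all minimizers the minimum-Euclidean-norm
#' solution is returned, computed through the Moore-Penrose pseudoinverse of
#' `X'X`. On full-rank designs this is the ordinary OLS solution. The
#' minimum-norm choice splits the shared intercept equally across the
#' collinear half-columns, which is why all `p` constant-term estimates
#' coincide.
#'
#' @param design a [`fourier_design`][assemble_design].
#' @param y numeric response vector of length `design$n`, all finite.
#' @return An object of class `"fourier_fit"`: list with
#'   \describe{
#'     \item{delta_hat}{named length-L coefficient vector.}
#'     \item{fitted, residuals}{length-n vectors; `fitted + residuals == y`.}
#'     \item{rss}{residual sum of squares Q.}
#'     \item{df_model}{`rank(X)`.}
#'     \item{df_resid}{`r = n - rank(X)`.}
#'     \item{sigma2_mle}{Q / n (the MLE scale).}
#'     \item{sigma2_resid}{Q / r (the inferential scale).}
#'     \item{metrics}{fit metrics, see [fit_metrics()].}
#'     \item{gram_pinv}{the pseudoinverse of X'X reused by all inference.}
#'   }
#' @seealso [hat_matrix()], [simultaneous_test()], [partial_test()]
#' @export
fit_ols <- function(design, y) {
  stopifnot(inherits(design, "fourier_design"))
  y <- as.numeric(y)
  if (length(y) != design$n)
    stop("length(y) = ", length(y), " does not match n = ", design$n)
  if (any(!is.finite(y)))
    stop("non-finite response at row(s): ",
         paste(which(!is.finite(y)), collapse = ", "))
  if (design$n <= design$rank)
    stop("saturated model: no residual degrees of freedom")
  G <- gram_pinv(design)
  delta_hat <- drop(G %*% crossprod(design$x, y))
  names(delta_hat) <- design$labels
  fitted <- drop(design$x %*% delta_hat)
  res <- y - fitted
  rss <- sum(res^2)
  r <- design$n - design$rank
  fit <- structure(list(delta_hat = delta_hat, fitted = fitted,
                        residuals = res, rss = rss,
                        df_model = design$rank, df_resid = r,
                        sigma2_mle = rss / design$n,
                        sigma2_resid = rss / r,
                        gram_pinv = G, y = y),
                   class = "fourier_fit")
  fit$metrics <- fit_metrics(fit, y)
  fit
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat("Fourier-series fit: df_model =", x$df_model,
      " df_resid =", x$df_resid,
      " RSS =", format(x$rss, digits = 6), "\n")
  cat("R2 =", format(x$metrics$r_squared, digits = 4),
      " MSE =", format(x$metrics$mse, digits = 4),
      " RMSE =", format(x$metrics$rmse, digits = 4), "\n")
  invisible(x)
}

#' Hat matrix of a Fourier-series design
#'
#' The projector `U = X (X'X)^+ X'` onto the column space of `X`, so that
#' `U %*% y` gives the fitted values for any response. `U` is symmetric and
#' idempotent with `trace(U) = rank(X)`.
#'
#' @param design a [`fourier_design`][assemble_design].
#' @return an `n x n` numeric matrix. Note this is dense; it is exposed for
#'   diagnostics and testing, not written to disk by the pipeline.
#' @export
hat_matrix <- function(design) {
  stopifnot(inherits(design, "fourier_design"))
  sv <- design$svd
  keep <- sv$d > design$svd_tol
  u <- sv$u[, keep, drop = FALSE]
  tcrossprod(u)
}

#' Fit metrics
#'
#' Computes the summary metrics reported alongside GCV in the selection
#' tables: `MSE = Q/n` (MLE denominator), `RMSE = sqrt(MSE)`,
#' `MAE = mean |e_i|`, `MAPE = mean |e_i / y_i|` (a proportion; undefined when
#' any `y_i = 0`), and `R2 = 1 - Q / sum((y - mean(y))^2)`.
#'
#' @param fit a [`fourier_fit`][fit_ols].
#' @param y the response the model was fitted on.
#' @return list with elements `mse`, `rmse`, `mae`, `mape`, `r_squared`.
#' @export
fit_metrics <- function(fit, y) {
  stopifnot(inherits(fit, "fourier_fit"))
  e <- fit$residuals
  n <- length(e)
  mse <- fit$rss / n
  mape <- if (any(y == 0)) {
    warning("MAPE undefined: response contains zeros")
    NA_real_
  } else mean(abs(e / y))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - fit$rss / tss else if (fit$rss == 0) 1 else NA_real_
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(e)), mape = mape,
       r_squared = r2)
}
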