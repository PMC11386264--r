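#' Simultaneous significance test (LRT-derived F ratio)
#'
#' Tests the null that every coefficient in the Fourier-series model is zero,
#' with the statistic
#' \deqn{\Lambda = \frac{(X\hat\delta)'y / d_1}{Q / d_2},}
#' where \eqn{d_1 = \mathrm{rank}(X)} and \eqn{d_2 = n - \mathrm{rank}(X)}.
#' Under the null \eqn{\Lambda} is referred to the `F(d1, d2)` distribution,
#' rejecting in the upper tail. Note the numerator is the explained quadratic
#' form including the intercept contribution, exactly as the statistic is
#' defined; with a nonzero response mean the central-F reference is therefore
#' conservative only for mean-zero nulls.
#'
#' @param fit a [`fourier_fit`][fit_ols].
#' @param design the design the model was fitted on.
#' @param y the response.
#' @param alpha significance level in (0, 1).
#' @return An object of class `"fourier_test"`: list with `statistic`, `dist`
#'   (`"F"`), `df` (`c(df1, df2)`), `critical_value`, `p_value`, `alpha`,
#'   `decision` (`"reject"` or `"fail-to-reject"`).
#' @export
simultaneous_test <- function(fit, design, y, alpha = 0.05) {
  stopifnot(inherits(fit, "fourier_fit"), inherits(design, "fourier_design"))
  check_alpha(alpha)
  df1 <- design$rank
  df2 <- design$n - design$rank
  if (df2 < 1) stop("no residual degrees of freedom")
  lambda <- (sum(fit$fitted * y) / df1) / (fit$rss / df2)
  crit <- stats::qf(1 - alpha, df1, df2)
  pval <- stats::pf(lambda, df1, df2, lower.tail = FALSE)
  new_test(lambda, "F", c(df1 = df1, df2 = df2), crit, pval, alpha,
           reject = lambda > crit)
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
}

new_test <- function(stat, dist, df, crit, pval, alpha, reject) {
  structure(list(statistic = stat, dist = dist, df = df,
                 critical_value = crit, p_value = pval, alpha = alpha,
                 decision = if (reject) "reject" else "fail-to-reject"),
            class = "fourier_test")
}

#' @export
print.fourier_test <- function(x, ...) {
  cat(x$dist, "test: statistic =", format(x$statistic, digits = 6),
      " df = (", paste(x$df, collapse = ", "), ")\n")
  cat("critical value =", format(x$critical_value, digits = 6),
      " p-value =", format(x$p_value, digits = 4),
      " ->", x$decision, "at alpha =", x$alpha, "\n")
  invisible(x)
}

## selector row vector a_l: 1 at position l, 0 elsewhere
check_constraint <- function(design, l) {
  L <- ncol(design$x)
  if (length(l) != 1L || !is.finite(l) || l < 1 || l > L || l != round(l))
    stop("constraint index 'l' must be a single integer in 1..", L)
  as.integer(l)
}

#' Constrained least squares under a single zero-coefficient constraint
#'
#' Minimizes \eqn{\|y - X\delta\|^2} subject to \eqn{a_l \delta = 0}, where
#' `a_l` selects the `l`-th coefficient, via the Lagrange-multiplier solution
#' \deqn{\hat\delta_\omega = \hat\delta - (X'X)^+ a_l'\,
#'   (a_l (X'X)^+ a_l')^{-1}\, a_l \hat\delta,}
#' with the multiplier estimate
#' \eqn{\hat\theta = (a_l (X'X)^+ a_l')^{-1} a_l (X'X)^+ X'y}. The generalized
#' inverse is the same pseudoinverse used by [fit_ols()], so on the collinear
#' half-constant columns the constraint acts on the minimum-norm coefficient.
#'
#' @param design a [`fourier_design`][assemble_design].
#' @param y response vector.
#' @param l coefficient index in `1..L` to constrain to zero.
#' @return An object of class `"constrained_fit"`: list with `delta_omega`
#'   (the constrained coefficients; entry `l` is zero), `theta_hat`,
#'   `rss_omega`, `sigma2_omega` (`rss_omega / n`), `l`.
#' @export
constrained_fit <- function(design, y, l) {
  l <- check_constraint(design, l)
  fit <- fit_ols(design, y)
  G <- fit$gram_pinv
  g_ll <- G[l, l]
  if (g_ll <= ncol(G) * .Machine$double.eps * max(abs(diag(G))))
    stop("constraint direction not estimable (a_l (X'X)^+ a_l' ~ 0)")
  theta_hat <- fit$delta_hat[l] / g_ll
  delta_omega <- fit$delta_hat - G[, l] * theta_hat
  names(delta_omega) <- design$labels
  res <- y - drop(design$x %*% delta_omega)
  rss_omega <- sum(res^2)
  structure(list(delta_omega = delta_omega, theta_hat = unname(theta_hat),
                 rss_omega = rss_omega, sigma2_omega = rss_omega / design$n,
                 l = l),
            class = "constrained_fit")
}

#' Partial t test for a single coefficient
#'
#' The LRT-derived statistic for \eqn{H_0: \delta_l = 0} against a two-sided
#' alternative:
#' \deqn{Z = \frac{a_l\hat\delta}{\sqrt{(Q/r)\; a_l (X'X)^+ a_l'}},}
#' with `Q` the residual sum of squares and `r = n - rank(X)`. Under the null
#' `Z` follows a Student t distribution with `r` degrees of freedom; the null
#' is rejected at level `alpha` iff `|Z| >= t(alpha/2, r)`, equivalently iff
#' the two-sided p-value is below `alpha`.
#'
#' @inheritParams constrained_fit
#' @param fit a [`fourier_fit`][fit_ols] for this design and response.
#' @param alpha significance level.
#' @return a `"fourier_test"` object with `dist = "t"` and `df = r`, plus an
#'   `estimate` element (the tested coefficient).
#' @export
partial_test <- function(fit, design, y, l, alpha = 0.05) {
  stopifnot(inherits(fit, "fourier_fit"), inherits(design, "fourier_design"))
  check_alpha(alpha)
  l <- check_constraint(design, l)
  r <- fit$df_resid
  if (r < 1) stop("no residual degrees of freedom")
  G <- fit$gram_pinv
  g_ll <- G[l, l]
  if (g_ll <= ncol(G) * .Machine$double.eps * max(abs(diag(G))))
    stop("constraint direction not estimable (a_l (X'X)^+ a_l' ~ 0)")
  z <- fit$delta_hat[[l]] / sqrt(fit$rss / r * g_ll)
  crit <- stats::qt(1 - alpha / 2, r)
  pval <- 2 * stats::pt(abs(z), r, lower.tail = FALSE)
  out <- new_test(z, "t", c(r = r), crit, pval, alpha,
                  reject = abs(z) >= crit)
  out$estimate <- unname(fit$delta_hat[l])
  out$parameter <- design$labels[l]
  out
}

#' Partial t tests for every coefficient
#'
#' Runs [partial_test()] for `l = 1..L` and returns one row per coefficient
#' with the estimate, `|Z|`, p-value and decision. No multiplicity adjustment
#' is applied by default; `adjust` switches the decision column to adjusted
#' p-values (`stats::p.adjust` methods, e.g. `"bonferroni"`, `"BH"`).
#' Coefficients whose constraint direction is not estimable are reported as
#' `NA` rows rather than failing the whole table.
#'
#' @inheritParams partial_test
#' @param adjust multiplicity adjustment method, default `"none"`.
#' @return a data frame of class `"fourier_test_table"` with columns
#'   `parameter`, `estimate`, `abs_z`, `p_value`, `decision`.
#' @export
partial_test_all <- function(fit, design, y, alpha = 0.05, adjust = "none") {
  L <- ncol(design$x)
  rows <- lapply(seq_len(L), function(l) {
    tst <- tryCatch(partial_test(fit, design, y, l, alpha),
                    error = function(e)
                      list(parameter = design$labels[l], estimate = NA_real_,
                           statistic = NA_real_, p_value = NA_real_,
                           decision = paste0("not estimable: ",
                                             conditionMessage(e))))
    data.frame(parameter = tst$parameter, estimate = tst$estimate,
               abs_z = abs(tst$statistic), p_value = tst$p_value,
               decision = tst$decision)
  })
  tab <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    ok <- !is.na(tab$p_value)
    tab$p_adjusted <- NA_real_
    tab$p_adjusted[ok] <- stats::p.adjust(tab$p_value[ok], method = adjust)
    tab$decision[ok] <- ifelse(tab$p_adjusted[ok] < alpha,
                               "reject", "fail-to-reject")
  }
  rownames(tab) <- NULL
  class(tab) <- c("fourier_test_table", "data.frame")
  tab
}

#' Quadratic-form diagnostics for the partial test
#'
#' Forms `M = X (X'X)^+ a_l' (a_l (X'X)^+ a_l')^{-1} a_l (X'X)^+ X'` and
#' verifies the algebra underlying the partial test's t reference
#' distribution: `M` is symmetric and idempotent with `trace(M) = 1`,
#' `M (I - U) = 0` (so numerator and denominator quadratic forms are
#' independent), and `Z^2 = y'My / (y'(I-U)y / r)`.
#'
#' @inheritParams constrained_fit
#' @return list of residual magnitudes: `sym`, `idem`, `trace_err`,
#'   `orth` (each a max-abs deviation), plus `z2_direct` (from
#'   [partial_test()]) and `z2_quadform` (the quadratic-form ratio).
#' @export
quadratic_form_check <- function(design, y, l) {
  l <- check_constraint(design, l)
  fit <- fit_ols(design, y)
  G <- fit$gram_pinv
  g_ll <- G[l, l]
  xg <- drop(design$x %*% G[, l])     # X (X'X)^+ a_l'
  M <- tcrossprod(xg) / g_ll
  U <- hat_matrix(design)
  IU <- diag(design$n) - U
  r <- fit$df_resid
  z <- partial_test(fit, design, y, l)$statistic
  list(sym = max(abs(M - t(M))),
       idem = max(abs(M %*% M - M)),
       trace_err = abs(sum(diag(M)) - 1),
       orth = max(abs(M %*% IU)),
       z2_direct = z^2,
       z2_quadform = drop(crossprod(y, M %*% y)) /
         (drop(crossprod(y, IU %*% y)) / r))
}

#' Likelihood ratio for a single-coefficient null
#'
#' The likelihood ratio
#' \eqn{w = (1 + (a_l\hat\delta)^2 / ((a_l (X'X)^+ a_l')\, Q))^{-n/2}}
#' comparing the constrained and unconstrained maxima; exposed for testing
#' the monotone relationship between `w` and `|Z|`.
#'
#' @inheritParams constrained_fit
#' @return a single value in (0, 1]; equals 1 iff the tested coefficient
#'   estimate is exactly zero.
#' @export
likelihood_ratio <- function(design, y, l) {
  l <- check_constraint(design, l)
  fit <- fit_ols(design, y)
  g_ll <- fit$gram_pinv[l, l]
  (1 + fit$delta_hat[[l]]^2 / (g_ll * fit$rss))^(-design$n / 2)
}
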