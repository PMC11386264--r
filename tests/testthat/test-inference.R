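test_that("simultaneous statistic matches the dense-matrix oracle", {
  skip_if_not_installed("MASS")
  rd <- rand_design(30, 2, 2, seed = 2)
  set.seed(3); y <- rnorm(30, 2)
  fit <- fit_ols(rd$design, y)
  tst <- simultaneous_test(fit, rd$design, y)
  # oracle: explicit pseudoinverse, explicit quadratic forms
  X <- rd$design$x
  G <- MASS::ginv(crossprod(X))
  dh <- drop(G %*% crossprod(X, y))
  df1 <- qr(X)$rank
  df2 <- 30 - df1
  lam <- (sum((X %*% dh) * y) / df1) /
    (sum((y - X %*% dh)^2) / df2)
  expect_equal(tst$statistic, lam, tolerance = 1e-8)
  expect_equal(unname(tst$df), c(df1, df2))
  expect_equal(tst$p_value, pf(lam, df1, df2, lower.tail = FALSE))
  expect_equal(tst$decision, if (lam > qf(0.95, df1, df2)) "reject"
                             else "fail-to-reject")
})

test_that("response orthogonal to the column space gives Lambda = 0", {
  rd <- rand_design(20, 1, 2, seed = 5)
  U <- hat_matrix(rd$design)
  set.seed(6)
  y <- drop((diag(20) - U) %*% rnorm(20))
  fit <- fit_ols(rd$design, y)
  tst <- simultaneous_test(fit, rd$design, y)
  expect_equal(tst$statistic, 0, tolerance = 1e-12)
  expect_equal(tst$decision, "fail-to-reject")
})

test_that("constrained fit enforces the constraint and increases rss", {
  for (seed in c(8, 9)) {
    inst <- rand_instance(n = 25, T = 3, seed = seed)
    L <- ncol(inst$design$x)
    for (l in c(1L, L)) {
      cf <- constrained_fit(inst$design, inst$y, l)
      expect_lt(abs(cf$delta_omega[l]), 1e-10)
      fit <- fit_ols(inst$design, inst$y)
      expect_gte(cf$rss_omega, fit$rss - 1e-10)
      expect_equal(cf$sigma2_omega, cf$rss_omega / 25)
    }
  }
})

test_that("constrained fit collapses when the coefficient is already zero", {
  rd <- rand_design(30, 1, 2, seed = 11)
  delta <- c(0.9, -0.5, 0.7, 0)                 # last cosine truly zero
  y <- drop(rd$design$x %*% delta)              # noiseless -> delta_hat exact
  cf <- constrained_fit(rd$design, y, 4L)
  fit <- fit_ols(rd$design, y)
  expect_equal(cf$delta_omega, fit$delta_hat, tolerance = 1e-8)
  expect_lt(abs(cf$theta_hat), 1e-6)
  expect_equal(cf$rss_omega, fit$rss, tolerance = 1e-10)
})

test_that("constrained fit matches the column-deletion oracle on full rank", {
  inst <- rand_instance(n = 15, T = 2, seed = 13)   # 15 x 4 full rank
  for (l in 1:4) {
    cf <- constrained_fit(inst$design, inst$y, l)
    Xm <- inst$design$x[, -l, drop = FALSE]
    oracle <- drop(solve(crossprod(Xm), crossprod(Xm, inst$y)))
    expect_equal(unname(cf$delta_omega[-l]), unname(oracle), tolerance = 1e-8)
    expect_equal(unname(cf$delta_omega[l]), 0, tolerance = 1e-12)
  }
})

test_that("partial t statistic matches the reference implementation", {
  skip_if_not_installed("MASS")
  inst <- rand_instance(n = 28, T = 3, seed = 17)
  fit <- fit_ols(inst$design, inst$y)
  ref <- lm_oracle(inst$design, inst$y)$table
  for (l in seq_len(ncol(inst$design$x))) {
    tst <- partial_test(fit, inst$design, inst$y, l)
    expect_equal(tst$statistic, unname(ref[l, "t value"]), tolerance = 1e-8)
    expect_equal(tst$p_value, unname(ref[l, "Pr(>|t|)"]), tolerance = 1e-8)
    expect_equal(tst$estimate, unname(ref[l, "Estimate"]), tolerance = 1e-8)
  }
})

test_that("zero coefficient estimate gives Z = 0 and p = 1", {
  # build a noisy response whose OLS estimate of coefficient 4 is exactly 0:
  # constrained fitted values plus the (column-space-orthogonal) residuals
  inst <- rand_instance(n = 30, T = 2, seed = 19)
  fit0 <- fit_ols(inst$design, inst$y)
  cf <- constrained_fit(inst$design, inst$y, 4L)
  y2 <- drop(inst$design$x %*% cf$delta_omega) + fit0$residuals
  fit2 <- fit_ols(inst$design, y2)
  expect_lt(abs(fit2$delta_hat[4]), 1e-10)
  tst <- partial_test(fit2, inst$design, y2, 4L)
  expect_equal(tst$statistic, 0, tolerance = 1e-8)
  expect_equal(tst$p_value, 1, tolerance = 1e-8)
  expect_equal(tst$decision, "fail-to-reject")
})

test_that("partial_test_all is one consistent row per coefficient", {
  rd <- rand_design(40, 2, 2, seed = 21)
  set.seed(22); y <- drop(rd$design$x %*% runif(8, -1, 1)) + rnorm(40, 0, 0.5)
  fit <- fit_ols(rd$design, y)
  tab <- partial_test_all(fit, rd$design, y)
  L <- ncol(rd$design$x)
  expect_equal(nrow(tab), L)
  expect_equal(tab$parameter, rd$design$labels)
  for (l in c(1L, 3L, L)) {
    tst <- partial_test(fit, rd$design, y, l)
    expect_equal(tab$abs_z[l], abs(tst$statistic), tolerance = 1e-12)
    expect_equal(tab$p_value[l], tst$p_value, tolerance = 1e-12)
    expect_equal(tab$decision[l], tst$decision)
  }
  # the two mu/2 rows are identical under the minimum-norm interpretation
  mu_idx <- c(rd$design$blocks[[1]][1], rd$design$blocks[[2]][1])
  expect_equal(tab$abs_z[mu_idx[1]], tab$abs_z[mu_idx[2]], tolerance = 1e-8)

  # multiplicity adjustment only ever weakens decisions
  tb <- partial_test_all(fit, rd$design, y, adjust = "bonferroni")
  expect_true(all(tb$p_adjusted >= tb$p_value - 1e-15))
  expect_true(all(tb$p_adjusted[tb$decision == "reject"] < 0.05))
})

test_that("quadratic form M has the stated algebraic structure", {
  for (seed in c(24, 25)) {
    inst <- rand_instance(n = 20, T = 2, seed = seed)
    q <- quadratic_form_check(inst$design, inst$y, 2L)
    expect_lt(q$sym, 1e-10)
    expect_lt(q$idem, 1e-10)
    expect_lt(q$trace_err, 1e-10)
    expect_lt(q$orth, 1e-10)
    expect_equal(q$z2_direct, q$z2_quadform, tolerance = 1e-8)
  }
})

test_that("likelihood ratio identity and monotonicity in |Z|", {
  inst <- rand_instance(n = 30, T = 3, seed = 28)
  fit <- fit_ols(inst$design, inst$y)
  L <- ncol(inst$design$x)
  w <- vapply(seq_len(L), function(l) likelihood_ratio(inst$design, inst$y, l),
              numeric(1))
  z <- vapply(seq_len(L), function(l)
    partial_test(fit, inst$design, inst$y, l)$statistic, numeric(1))
  expect_true(all(w > 0 & w <= 1))
  # closed-form link: w = (1 + Z^2 / r)^(-n/2)
  r <- fit$df_resid
  expect_equal(w, (1 + z^2 / r)^(-30 / 2), tolerance = 1e-10)
  # monotone decreasing in |Z|
  ord <- order(abs(z))
  expect_true(all(diff(w[ord]) <= 1e-12))
  # w = 1 iff the estimate is zero (zero-estimate response built as above)
  cf <- constrained_fit(inst$design, inst$y, 4L)
  y2 <- drop(inst$design$x %*% cf$delta_omega) + fit$residuals
  expect_equal(likelihood_ratio(inst$design, y2, 4L), 1, tolerance = 1e-10)
})

test_that("power is nondecreasing in the true coefficient magnitude", {
  spec <- fourier_spec(1, 2)
  mags <- c(0, 0.3, 0.9)
  rates <- vapply(mags, function(m) {
    rej <- 0L
    for (k in 1:60) {
      delta <- c(1, 0.5, 0.8, m)
      ds <- generate_dataset(40, spec, delta, sigma2 = 1, seed = 300 + k)
      design <- assemble_design(ds$predictors, spec)
      fit <- fit_ols(design, ds$y)
      if (partial_test(fit, design, ds$y, 4L)$decision == "reject")
        rej <- rej + 1L
    }
    rej / 60
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("alpha validation and decision coherence", {
  inst <- rand_instance(n = 20, T = 2, seed = 31)
  fit <- fit_ols(inst$design, inst$y)
  expect_error(partial_test(fit, inst$design, inst$y, 1, alpha = 0), "alpha")
  expect_error(simultaneous_test(fit, inst$design, inst$y, alpha = 1.2),
               "alpha")
  tst <- partial_test(fit, inst$design, inst$y, 2, alpha = 0.1)
  expect_equal(tst$decision == "reject", tst$p_value < 0.1)
  expect_equal(tst$decision == "reject",
               abs(tst$statistic) >= tst$critical_value)
})
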