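# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A design on uniform[0, 2pi] predictors. p = 1 gives a full-rank design
# (single half-column); p >= 2 is rank-deficient by p - 1.
rand_design <- function(n, p, T, seed) {
  set.seed(seed)
  d <- matrix(runif(n * p, 0, 2 * pi), n, p)
  list(data = d, design = assemble_design(d, fourier_spec(p, T)))
}

# Full-rank instance with a response: p = 1 so lm() is a usable oracle.
rand_instance <- function(n = 25, T = 2, seed = 1, sigma = 0.5) {
  rd <- rand_design(n, 1, T, seed)
  set.seed(seed + 31L)
  delta <- runif(ncol(rd$design$x), -1.5, 1.5)
  y <- drop(rd$design$x %*% delta) + rnorm(n, 0, sigma)
  list(design = rd$design, y = y, delta = delta, data = rd$data)
}

# Independent oracle: coefficient table from stats::lm on the raw matrix.
lm_oracle <- function(design, y) {
  X <- design$x
  fit <- lm(y ~ 0 + X)
  s <- summary(fit)$coefficients
  rownames(s) <- sub("^X", "", rownames(s))
  list(fit = fit, coef = coef(fit), table = s)
}
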