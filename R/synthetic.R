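#' Generate a synthetic dataset with Fourier-series structure
#'
#' Draws predictors uniformly on per-predictor ranges (default \eqn{[0, 2\pi]},
#' so the cosine harmonics are well excited), builds the additive
#' trend-plus-cosine mean curve from the supplied true coefficient vector, and
#' adds i.i.d. Gaussian noise of variance `sigma2`. Everything is
#' deterministic under `seed`: predictors are drawn under `seed` and noise
#' under a fixed offset of it, so the two streams can be varied independently.
#'
#' @param n number of observations (>= 1).
#' @param spec a [fourier_spec()] giving the true per-predictor oscillation
#'   counts.
#' @param delta_star true coefficient vector, length `spec$L`, ordered as the
#'   design columns (per predictor: constant-column coefficient, trend,
#'   cosine coefficients in increasing harmonic order).
#' @param sigma2 noise variance (>= 0).
#' @param predictor_ranges 2 x p matrix (or length-2 vector, recycled) of
#'   lower/upper bounds for the uniform predictor draws.
#' @param seed integer RNG seed.
#' @return An object of class `"fourier_synth"`: list with `predictors`
#'   (data frame `x1..xp`), `y`, `truth` (list: `spec`, `delta_star`,
#'   `sigma2`), `seed`.
#' @export
generate_dataset <- function(n, spec, delta_star, sigma2 = 1,
                             predictor_ranges = c(0, 2 * pi), seed = 1L) {
  stopifnot(inherits(spec, "fourier_spec"))
  if (n < 1) stop("'n' must be >= 1")
  if (length(delta_star) != spec$L)
    stop("length(delta_star) = ", length(delta_star),
         " does not match spec L = ", spec$L)
  if (sigma2 < 0) stop("'sigma2' must be >= 0")
  rng <- if (is.matrix(predictor_ranges)) predictor_ranges
         else matrix(predictor_ranges, 2, spec$p)
  if (nrow(rng) != 2L || ncol(rng) != spec$p || any(!is.finite(rng)))
    stop("'predictor_ranges' must give finite (lower, upper) per predictor")
  seed <- as.integer(seed)
  set.seed(seed)
  predictors <- vapply(seq_len(spec$p),
                       function(j) stats::runif(n, rng[1, j], rng[2, j]),
                       numeric(n))
  predictors <- matrix(predictors, nrow = n)
  colnames(predictors) <- paste0("x", seq_len(spec$p))
  design <- assemble_design(predictors, spec)
  mu <- drop(design$x %*% delta_star)
  set.seed((seed + 104729L) %% .Machine$integer.max)  # independent noise stream
  eps <- if (sigma2 > 0) stats::rnorm(n, 0, sqrt(sigma2)) else numeric(n)
  structure(list(predictors = as.data.frame(predictors), y = mu + eps,
                 truth = list(spec = spec, delta_star = as.numeric(delta_star),
                              sigma2 = sigma2),
                 seed = seed),
            class = "fourier_synth")
}

#' Generate a null dataset for type-I-error studies
#'
#' As [generate_dataset()], but asserts that the stated coefficients are truly
#' zero, so the partial test of any index in `null_indices` is a genuine null
#' calibration.
#'
#' @inheritParams generate_dataset
#' @param null_indices coefficient positions (1..L) whose true values must be
#'   zero.
#' @return a `"fourier_synth"` object whose `truth` records `null_indices`.
#' @export
generate_null_dataset <- function(n, spec, null_indices, delta_star,
                                  sigma2 = 1, predictor_ranges = c(0, 2 * pi),
                                  seed = 1L) {
  if (any(null_indices < 1) || any(null_indices > spec$L))
    stop("'null_indices' out of range 1..", spec$L)
  if (any(delta_star[null_indices] != 0))
    stop("delta_star must be zero at every null index")
  ds <- generate_dataset(n, spec, delta_star, sigma2, predictor_ranges, seed)
  ds$truth$null_indices <- as.integer(null_indices)
  ds
}

#' Write a synthetic dataset to CSV with a truth sidecar
#'
#' The data file holds `y` and the predictor columns; the sidecar is a JSON
#' record of the generating spec, true coefficients, noise variance and seed,
#' so a run can be reproduced from the files alone.
#'
#' @param ds a [`fourier_synth`][generate_dataset] object.
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".truth.json")` unless `truth_path` is given.
#' @param truth_path optional explicit sidecar path.
#' @return invisibly, the two paths written.
#' @export
write_dataset <- function(ds, path, truth_path = paste0(path, ".truth.json")) {
  stopifnot(inherits(ds, "fourier_synth"))
  utils::write.csv(cbind(y = ds$y, ds$predictors), path, row.names = FALSE)
  truth <- list(p = ds$truth$spec$p, T = ds$truth$spec$T,
                rescale = ds$truth$spec$rescale,
                delta_star = ds$truth$delta_star,
                sigma2 = ds$truth$sigma2, seed = ds$seed)
  if (!is.null(ds$truth$null_indices))
    truth$null_indices <- ds$truth$null_indices
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = path, truth = truth_path))
}
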