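#' Specify a Fourier-series regression basis
#'
#' A Bilodeau-style Fourier basis approximates each additive component
#' \eqn{g(x_j)} by a constant, a linear trend and cosine harmonics:
#' \deqn{g(x_j) = \mu_j/2 + \beta_j x_j + \sum_{t=1}^{T_j} \delta_{tj} \cos(t x_j).}
#' The oscillation parameter \eqn{T_j} is the number of cosine harmonics for
#' predictor \eqn{j} and is the model-complexity knob selected by GCV.
#'
#' @param p number of predictors (integer, >= 1).
#' @param T oscillation parameters: either a single integer (recycled to all
#'   predictors) or a length-`p` integer vector, every entry >= 1.
#' @param rescale if `TRUE`, each predictor is linearly mapped to \eqn{[0, \pi]}
#'   before the cosine basis is evaluated. The default (`FALSE`) applies
#'   `cos(t * x)` to raw predictor values.
#'
#' @return An object of class `"fourier_spec"`: a list with elements `p`, `T`
#'   (length-`p` integer vector), `rescale`, and `L` the total coefficient
#'   count \eqn{\sum_j (T_j + 2)}.
#' @examples
#' fourier_spec(p = 5, T = 2)           # uniform T: L = 5 * 4 = 20
#' fourier_spec(p = 5, T = c(1, 2, 4, 3, 5))  # L = 25
#' @export
fourier_spec <- function(p, T, rescale = FALSE) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != round(p))
    stop("'p' must be a single integer >= 1")
  p <- as.integer(p)
  if (length(T) == 1L) T <- rep(T, p)
  if (length(T) != p)
    stop("'T' must have length 1 or length p = ", p)
  if (any(!is.finite(T)) || any(T < 1) || any(T != round(T)))
    stop("every oscillation parameter T_j must be an integer >= 1")
  structure(list(p = p, T = as.integer(T), rescale = isTRUE(rescale),
                 L = sum(as.integer(T) + 2L)),
            class = "fourier_spec")
}

#' @export
print.fourier_spec <- function(x, ...) {
  cat("Fourier basis spec: p =", x$p,
      " T = (", paste(x$T, collapse = ", "), ")",
      " L =", x$L,
      if (x$rescale) " [predictors rescaled to [0, pi]]" else "", "\n")
  invisible(x)
}

#' Build the basis block for one predictor
#'
#' Returns the `n x (T_j + 2)` block `[1/2, x, cos(1*x), ..., cos(T_j*x)]`.
#' The leading constant column is exactly 1/2: the basis carries the constant
#' as \eqn{\mu_j/2}, so stacking blocks over predictors produces `p` identical
#' half-columns and an intrinsically rank-deficient design (handled downstream
#' by minimum-norm least squares).
#'
#' @param x numeric vector, one predictor's values (finite).
#' @param T_j integer >= 1, number of cosine harmonics.
#' @return numeric matrix with `length(x)` rows and `T_j + 2` columns.
#' @examples
#' build_predictor_block(c(0, pi), 2)
#' @export
build_predictor_block <- function(x, T_j) {
  if (length(T_j) != 1L || !is.finite(T_j) || T_j < 1 || T_j != round(T_j))
    stop("'T_j' must be a single integer >= 1")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite predictor value at row(s): ", paste(bad, collapse = ", "))
  n <- length(x)
  out <- matrix(0, n, T_j + 2L)
  out[, 1L] <- 0.5
  out[, 2L] <- x
  for (t in seq_len(T_j)) out[, t + 2L] <- cos(t * x)
  out
}

#' Assemble the full Fourier-series design matrix
#'
#' Horizontally concatenates the per-predictor blocks of
#' [build_predictor_block()] in predictor order. The numeric rank is computed
#' (via SVD) and stored together with per-predictor column bookkeeping; for
#' `p >= 2` the design is rank-deficient by construction (the `p` half-constant
#' columns are identical), with rank at most `1 + p + sum(T)`.
#'
#' @param data a data frame or matrix of `n` rows and `spec$p` numeric columns.
#' @param spec a [fourier_spec()].
#' @return An object of class `"fourier_design"`: list with `x` (the n x L
#'   matrix), `blocks` (list of column-index vectors per predictor), `labels`
#'   (coefficient names, `mu<j>/2`, `beta<j>`, `delta<t>.<j>`), `rank`, `spec`,
#'   `n`, and the SVD factors used for all pseudoinverse computations.
#' @examples
#' d <- matrix(runif(38 * 5, 0, 2 * pi), 38, 5)
#' X <- assemble_design(d, fourier_spec(5, 2))
#' dim(X$x)   # 38 x 20
#' X$rank     # 16 = 1 + 5 + 5*2
#' @export
assemble_design <- function(data, spec) {
  if (!inherits(spec, "fourier_spec")) stop("'spec' must be a fourier_spec")
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("predictor table must be numeric")
  if (ncol(data) != spec$p)
    stop("predictor column count (", ncol(data),
         ") does not match spec$p (", spec$p, ")")
  n <- nrow(data)
  if (n < 1L) stop("need at least one observation")
  rescaled <- data
  if (spec$rescale) {
    for (j in seq_len(spec$p)) {
      rng <- range(data[, j])
      rescaled[, j] <- if (rng[2] > rng[1])
        (data[, j] - rng[1]) / (rng[2] - rng[1]) * pi else 0
    }
  }
  blocks <- vector("list", spec$p)
  labels <- character(0)
  cols <- vector("list", spec$p)
  at <- 0L
  for (j in seq_len(spec$p)) {
    Tj <- spec$T[j]
    cols[[j]] <- build_predictor_block(rescaled[, j], Tj)
    blocks[[j]] <- seq.int(at + 1L, at + Tj + 2L)
    labels <- c(labels, sprintf("mu%d/2", j), sprintf("beta%d", j),
                sprintf("delta%d.%d", seq_len(Tj), j))
    at <- at + Tj + 2L
  }
  x <- do.call(cbind, cols)
  colnames(x) <- labels
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  structure(list(x = x, blocks = blocks, labels = labels, rank = rank,
                 spec = spec, n = n, svd = sv, svd_tol = tol),
            class = "fourier_design")
}

#' @export
print.fourier_design <- function(x, ...) {
  cat("Fourier design:", x$n, "x", ncol(x$x),
      "(rank", paste0(x$rank, ")"), "\n")
  print(x$spec)
  invisible(x)
}

## Moore-Penrose pseudoinverse of X'X from the stored SVD of X.
## All occurrences of (X'X)^{-1} in estimation and inference go through this,
## so rank-deficient designs get the minimum-norm resolution everywhere.
gram_pinv <- function(design) {
  sv <- design$svd
  keep <- sv$d > design$svd_tol
  v <- sv$v[, keep, drop = FALSE]
  v %*% (t(v) / sv$d[keep]^2)
}

## Evaluate one additive component g(x) = mu/2 + beta x + sum_t delta_t cos(tx)
## directly (scalar form); used to check block-times-coefficients reconstruction.
eval_component <- function(x, coef_block) {
  Tj <- length(coef_block) - 2L
  g <- coef_block[1L] * 0.5 + coef_block[2L] * x
  for (t in seq_len(Tj)) g <- g + coef_block[t + 2L] * cos(t * x)
  g
}
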