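#' Generalized cross-validation score
#'
#' \deqn{GCV = \frac{n^{-1} y'(I-U)'(I-U) y}{(n^{-1}\,\mathrm{trace}(I-U))^2}}
#' Since `I - U` is a projector the numerator reduces to `rss / n` and the
#' trace to `n - rank(X)`; by default the score is computed on that reduced
#' path. `dense = TRUE` forms `I - U` explicitly and evaluates the quotient
#' literally — both paths are exposed so tests can compare them.
#'
#' @param design a [`fourier_design`][assemble_design].
#' @param y numeric response.
#' @param dense evaluate via the explicit `n x n` projector (for testing).
#' @return An object of class `"gcv_result"`: list with `spec`, `gcv`,
#'   `metrics`, `rank`, `rss`.
#' @export
gcv_score <- function(design, y, dense = FALSE) {
  fit <- fit_ols(design, y)   # errors out when saturated
  n <- design$n
  gcv <- if (dense) {
    IU <- diag(n) - hat_matrix(design)
    num <- drop(crossprod(IU %*% y)) / n
    num / (sum(diag(IU)) / n)^2
  } else {
    (fit$rss / n) / ((n - design$rank) / n)^2
  }
  structure(list(spec = design$spec, gcv = gcv, metrics = fit$metrics,
                 rank = design$rank, rss = fit$rss),
            class = "gcv_result")
}

search_report <- function(mode, tab, p, evaluated) {
  ## tab rows arrive in evaluation order; rank by GCV with parsimony tie-breaks
  ## (smaller sum of T, then lexicographic T-vector)
  Tcols <- paste0("T_", seq_len(p))
  ord <- do.call(order, c(list(tab$gcv, rowSums(tab[Tcols])),
                          unname(as.list(tab[Tcols]))))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(mode = mode, candidates_evaluated = evaluated,
                 best = attr(tab, "best") %||% NULL, table = tab, p = p),
            class = "fourier_search")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_candidates <- function(data, y, Tvecs, mode, rescale = FALSE) {
  data <- as.matrix(data)
  p <- ncol(data)
  n <- nrow(data)
  rows <- vector("list", length(Tvecs))
  results <- vector("list", length(Tvecs))
  kept <- logical(length(Tvecs))
  for (k in seq_along(Tvecs)) {
    Tv <- Tvecs[[k]]
    spec <- fourier_spec(p, Tv, rescale = rescale)
    design <- assemble_design(data, spec)
    if (design$rank >= n) {
      warning("skipping T = (", paste(Tv, collapse = ", "),
              "): design rank ", design$rank, " >= n = ", n)
      next
    }
    g <- gcv_score(design, y)
    m <- g$metrics
    rows[[k]] <- data.frame(t(matrix(Tv, dimnames = list(paste0("T_", 1:p)))),
                            gcv = g$gcv, mse = m$mse, mae = m$mae,
                            rmse = m$rmse, mape = m$mape,
                            r_squared = m$r_squared, rank = g$rank)
    results[[k]] <- g
    kept[k] <- TRUE
  }
  if (!any(kept)) stop("no admissible candidate: all designs saturated")
  tab <- do.call(rbind, rows[kept])
  rep <- search_report(mode, tab, p, evaluated = sum(kept))
  ## best = first row after the parsimony ordering
  best_T <- as.integer(rep$table[1, paste0("T_", 1:p)])
  rep$best <- results[kept][[which(vapply(
    Tvecs[kept], function(v) all(v == best_T), logical(1)))]]
  rep
}

#' Search a uniform oscillation parameter by GCV
#'
#' Evaluates the uniform candidates `T = 1, ..., T_max` (the same number of
#' harmonics for every predictor) and returns all scores plus the GCV
#' minimizer; GCV ties are broken toward smaller `T`.
#'
#' @param data n x p predictor table.
#' @param y response vector.
#' @param T_max largest uniform T to consider (>= 1).
#' @param rescale passed to [fourier_spec()].
#' @return An object of class `"fourier_search"`: list with `mode`,
#'   `candidates_evaluated`, `best` (a [`gcv_result`][gcv_score]) and `table`
#'   (one row per candidate, sorted by GCV then parsimony). Candidates whose
#'   design rank reaches `n` are skipped with a warning.
#' @export
search_uniform <- function(data, y, T_max, rescale = FALSE) {
  if (length(T_max) != 1L || T_max < 1 || T_max != round(T_max))
    stop("'T_max' must be a single integer >= 1")
  p <- ncol(as.matrix(data))
  Tvecs <- lapply(seq_len(T_max), function(T) rep(as.integer(T), p))
  eval_candidates(data, y, Tvecs, mode = "uniform", rescale = rescale)
}

#' Exhaustive per-predictor oscillation search by GCV
#'
#' Full Cartesian enumeration of the `T_max^p` oscillation vectors in
#' `{1, ..., T_max}^p`, scoring each by GCV. With `p = 5` this is 243
#' candidates at `T_max = 3` and 3125 at `T_max = 5`. The argmin is returned
#' with ties broken by smaller `sum(T)` then lexicographic order.
#'
#' @inheritParams search_uniform
#' @param budget refuse to enumerate more than this many candidates unless
#'   `override = TRUE`; guards against `T_max^p` blow-up.
#' @param override set `TRUE` to enumerate past the budget anyway.
#' @return a `"fourier_search"` object, as [search_uniform()].
#' @export
search_combinations <- function(data, y, T_max, budget = 5000L,
                                override = FALSE, rescale = FALSE) {
  if (length(T_max) != 1L || T_max < 1 || T_max != round(T_max))
    stop("'T_max' must be a single integer >= 1")
  p <- ncol(as.matrix(data))
  n_cand <- T_max^p
  if (n_cand > budget && !override)
    stop("combination search would evaluate ", n_cand, " candidates ",
         "(budget ", budget, "); use search_uniform(), a smaller T_max, ",
         "or override = TRUE")
  grid <- as.matrix(expand.grid(rep(list(seq_len(T_max)), p)))
  Tvecs <- lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  eval_candidates(data, y, Tvecs, mode = "combinations", rescale = rescale)
}

#' @export
print.fourier_search <- function(x, ...) {
  b <- x$table[1, ]
  cat("GCV search (", x$mode, "): ", x$candidates_evaluated,
      " candidates evaluated\n", sep = "")
  cat("best T = (", paste(b[paste0("T_", 1:x$p)], collapse = ", "),
      ")  GCV = ", format(b$gcv, digits = 6),
      "  R2 = ", format(b$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a search report as CSV
#'
#' Columns mirror the selection-table layout: `T_1..T_p`, GCV, MSE, MAE,
#' RMSE, MAPE, R2.
#'
#' @param report a [`fourier_search`][search_uniform] object.
#' @param path output file path.
#' @export
write_search_report <- function(report, path) {
  stopifnot(inherits(report, "fourier_search"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
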