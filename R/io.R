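#' Read and validate a modelling table from CSV
#'
#' Reads an RFC-4180 CSV with a header row, checks that the requested
#' response and predictor columns exist and are numeric, and rejects rows
#' containing missing values, naming them.
#'
#' @param path CSV file path.
#' @param response response column name.
#' @param predictors character vector of predictor column names; default all
#'   remaining columns.
#' @return list with `y` (numeric vector), `data` (predictor data frame),
#'   `n`, `p`.
#' @export
read_table <- function(path, response, predictors = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) stop("cannot parse CSV '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty table: ", path)
  if (!response %in% names(tab))
    stop("response column '", response, "' not found in ", path)
  if (is.null(predictors)) predictors <- setdiff(names(tab), response)
  missing_cols <- setdiff(predictors, names(tab))
  if (length(missing_cols))
    stop("predictor column(s) not found: ", paste(missing_cols, collapse = ", "))
  cols <- c(response, predictors)
  for (cl in cols)
    if (!is.numeric(tab[[cl]]))
      stop("column '", cl, "' is not numeric")
  na_rows <- which(rowSums(is.na(tab[cols])) > 0)
  if (length(na_rows))
    stop("missing values in row(s): ", paste(na_rows, collapse = ", "))
  list(y = tab[[response]], data = tab[predictors],
       n = nrow(tab), p = length(predictors))
}

#' Pipeline run configuration
#'
#' @param response response column name.
#' @param predictors predictor column names (`NULL` = all others).
#' @param T_max maximum oscillation parameter for the search.
#' @param mode `"uniform"` or `"combinations"`.
#' @param alpha significance level for all tests.
#' @param rescale rescale predictors to `[0, pi]` before the cosine basis.
#' @param adjust multiplicity adjustment for the partial-test table.
#' @param seed seed for simulation subcommands.
#' @param out_dir directory for pipeline outputs.
#' @return a validated `"run_config"` list.
#' @export
run_config <- function(response, predictors = NULL, T_max = 5L,
                       mode = c("combinations", "uniform"), alpha = 0.05,
                       rescale = FALSE, adjust = "none", seed = 1L,
                       out_dir = ".") {
  mode <- match.arg(mode)
  check_alpha(alpha)
  if (T_max < 1) stop("'T_max' must be >= 1")
  structure(list(response = response, predictors = predictors,
                 T_max = as.integer(T_max), mode = mode, alpha = alpha,
                 rescale = isTRUE(rescale), adjust = adjust,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full fit/select/test/diagnose pipeline
#'
#' Searches the oscillation parameters by GCV (uniform or exhaustive
#' combinations per `config$mode`), refits the best model, runs the
#' simultaneous F test, all partial t tests and the Glejser test, and writes
#' the search table, coefficient-test table, diagnostics series, a metrics
#' summary and a plain-text log to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param table a list as returned by [read_table()] (`y`, `data`).
#' @return invisibly, a list with elements `search`, `fit`, `design`,
#'   `simultaneous`, `partial`, `glejser`, `files`.
#' @export
run_pipeline <- function(config, table) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  y <- table$y
  data <- table$data
  search <- switch(config$mode,
    uniform = search_uniform(data, y, config$T_max, rescale = config$rescale),
    combinations = search_combinations(data, y, config$T_max,
                                       override = TRUE,
                                       rescale = config$rescale))
  best_T <- as.integer(search$table[1, paste0("T_", seq_len(ncol(data)))])
  spec <- fourier_spec(ncol(data), best_T, rescale = config$rescale)
  design <- assemble_design(data, spec)
  fit <- fit_ols(design, y)
  sim <- simultaneous_test(fit, design, y, config$alpha)
  partial <- partial_test_all(fit, design, y, config$alpha, config$adjust)
  glej <- glejser_test(fit, design, config$alpha)

  f <- function(name) file.path(config$out_dir, name)
  files <- c(search = f("search.csv"), tests = f("coefficient_tests.csv"),
             diagnostics = f("diagnostics.csv"), metrics = f("metrics.csv"),
             log = f("run_log.txt"))
  write_search_report(search, files[["search"]])
  utils::write.csv(partial, files[["tests"]], row.names = FALSE)
  utils::write.csv(export_diagnostics(fit, y), files[["diagnostics"]],
                   row.names = FALSE)
  m <- fit$metrics
  utils::write.csv(data.frame(gcv = search$best$gcv, r_squared = m$r_squared,
                              mse = m$mse, mae = m$mae, rmse = m$rmse,
                              mape = m$mape, rank = design$rank,
                              df_resid = fit$df_resid),
                   files[["metrics"]], row.names = FALSE)
  log_lines <- c(
    sprintf("mode: %s  T_max: %d  alpha: %g", config$mode, config$T_max,
            config$alpha),
    sprintf("candidates evaluated: %d", search$candidates_evaluated),
    sprintf("selected T: (%s)", paste(best_T, collapse = ", ")),
    sprintf("design rank: %d  df_resid: %d", design$rank, fit$df_resid),
    sprintf("simultaneous F: statistic %.15g  df (%s)  critical %.15g  p %.15g",
            sim$statistic, paste(sim$df, collapse = ", "),
            sim$critical_value, sim$p_value),
    sprintf("partial t critical value (alpha/2, r): %.15g",
            stats::qt(1 - config$alpha / 2, fit$df_resid)),
    sprintf("Glejser simultaneous p: %.15g -> %s", glej$simultaneous_p,
            glej$conclusion))
  writeLines(log_lines, files[["log"]])
  invisible(list(search = search, fit = fit, design = design,
                 simultaneous = sim, partial = partial, glejser = glej,
                 files = files, selected_T = best_T))
}

#' Command-line entry point
#'
#' Subcommands: `fit` (fixed T), `select` (GCV search only), `test` (search +
#' refit + all tests + diagnostics; the full pipeline), `simulate` (write a
#' synthetic dataset + truth sidecar), `calibrate` (Monte-Carlo null rejection
#' rate of the partial test). Invoke via the installed wrapper script
#' `inst/cli/fourierreg.R` or `Rscript -e 'fourierreg::fsr_main()' --args ...`.
#'
#' @param args character vector of command-line arguments; defaults to the
#'   process's trailing arguments.
#' @return invisibly, the subcommand's result object.
#' @export
fsr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: fourierreg <fit|select|test|simulate|calibrate> [options]")
  cmd <- args[[1L]]
  rest <- args[-1L]
  opts <- list(
    optparse::make_option("--data", type = "character", help = "input CSV"),
    optparse::make_option("--response", type = "character", default = "y"),
    optparse::make_option("--T", type = "character", default = NULL,
      help = "comma-separated T vector (fit) or ignored"),
    optparse::make_option("--T-max", type = "integer", default = 5L,
      dest = "T_max"),
    optparse::make_option("--mode", type = "character",
      default = "combinations"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--rescale", action = "store_true", default = FALSE),
    optparse::make_option("--adjust", type = "character", default = "none"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n", type = "integer", default = 100L),
    optparse::make_option("--p", type = "integer", default = 2L),
    optparse::make_option("--sigma2", type = "double", default = 1),
    optparse::make_option("--replicates", type = "integer", default = 500L),
    optparse::make_option("--out", type = "character", default = "fourierreg_out"))
  cfg <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                              args = rest)
  result <- switch(cmd,
    fit = {
      tab <- read_table(cfg$data, cfg$response)
      Tv <- if (is.null(cfg$T)) rep(1L, tab$p)
            else as.integer(strsplit(cfg$T, ",")[[1]])
      design <- assemble_design(tab$data,
                                fourier_spec(tab$p, Tv, cfg$rescale))
      fit <- fit_ols(design, tab$y)
      print(fit)
      fit
    },
    select = {
      tab <- read_table(cfg$data, cfg$response)
      s <- if (cfg$mode == "uniform")
        search_uniform(tab$data, tab$y, cfg$T_max, rescale = cfg$rescale)
      else search_combinations(tab$data, tab$y, cfg$T_max, override = TRUE,
                               rescale = cfg$rescale)
      print(s)
      dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
      write_search_report(s, file.path(cfg$out, "search.csv"))
      s
    },
    test = {
      tab <- read_table(cfg$data, cfg$response)
      conf <- run_config(cfg$response, NULL, cfg$T_max, cfg$mode, cfg$alpha,
                         cfg$rescale, cfg$adjust, cfg$seed, cfg$out)
      rep <- run_pipeline(conf, tab)
      cat("outputs written to", cfg$out, "\n")
      rep
    },
    simulate = {
      spec <- fourier_spec(cfg$p, if (is.null(cfg$T)) 2L
                                  else as.integer(strsplit(cfg$T, ",")[[1]]))
      set.seed(cfg$seed)
      delta <- stats::runif(spec$L, -1.5, 1.5)
      ds <- generate_dataset(cfg$n, spec, delta, cfg$sigma2, seed = cfg$seed)
      dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
      paths <- write_dataset(ds, file.path(cfg$out, "synthetic.csv"))
      cat("dataset written to", paths[["data"]], "\n")
      ds
    },
    calibrate = {
      rate <- null_rejection_rate(n = cfg$n, p = cfg$p,
                                  replicates = cfg$replicates,
                                  alpha = cfg$alpha, seed = cfg$seed)
      cat(sprintf("null rejection rate over %d replicates: %.4f (alpha %g)\n",
                  cfg$replicates, rate, cfg$alpha))
      rate
    },
    stop("unknown subcommand '", cmd, "'"))
  invisible(result)
}

#' Monte-Carlo null rejection rate of the partial test
#'
#' Simulates datasets whose tested coefficient is truly zero, applies
#' [partial_test()] to that coefficient in each replicate, and returns the
#' empirical rejection rate — the observed type-I error, which should match
#' `alpha` when the t reference distribution is exact.
#'
#' @param n observations per replicate.
#' @param p predictors; the tested coefficient is the last cosine term of the
#'   last predictor, with true value zero.
#' @param T_j uniform oscillation parameter of the simulated truth.
#' @param replicates Monte-Carlo replicate count.
#' @param alpha nominal level.
#' @param sigma2 noise variance.
#' @param seed base seed; replicate k uses `seed + k`.
#' @param statistics if `TRUE`, return the vector of Z statistics instead of
#'   the rejection rate (for distributional checks).
#' @return rejection rate (or Z vector).
#' @export
null_rejection_rate <- function(n = 40L, p = 1L, T_j = 2L, replicates = 500L,
                                alpha = 0.05, sigma2 = 1, seed = 1L,
                                statistics = FALSE) {
  spec <- fourier_spec(p, T_j)
  delta <- rep(0.8, spec$L)
  l <- spec$L                       # last cosine coefficient, forced to zero
  delta[l] <- 0
  z <- vapply(seq_len(replicates), function(k) {
    ds <- generate_null_dataset(n, spec, l, delta, sigma2,
                                seed = seed + k)
    design <- assemble_design(ds$predictors, spec)
    fit <- fit_ols(design, ds$y)
    partial_test(fit, design, ds$y, l, alpha)$statistic
  }, numeric(1))
  if (statistics) return(z)
  r <- n - (1L + p + p * T_j)
  mean(abs(z) >= stats::qt(1 - alpha / 2, r))
}
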