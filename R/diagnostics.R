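#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Multi-chain convergence diagnostic for a scalar parameter: with `m`
#' chains of length `n`, `W` is the mean within-chain variance, `B = n *
#' var(chain means)` the between-chain variance, the pooled variance
#' estimate is `V = (n-1)/n * W + B/n`, and the PSRF is `sqrt(V/W)`.
#' Values near 1 indicate the chains have mixed into the same distribution.
#' Because the pooled estimate deflates `W` by `(n-1)/n`, the raw ratio can
#' dip below 1 for well-mixed chains; it is floored at 1 so the statistic
#' reads as "inflation over perfect mixing".
#'
#' @param chains list of (or matrix with columns of) equal-length numeric
#'   traces; at least 2 chains of length at least 2.
#' @return scalar PSRF (`Inf` when the chains are constant but unequal).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2) stop("PSRF requires at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 2) stop("chains must have length >= 2")
  W <- mean(vapply(chains, var, 0))
  B <- n * var(vapply(chains, mean, 0))
  if (W == 0) return(if (B == 0) 1 else Inf)
  V <- (n - 1) / n * W + B / n
  max(1, sqrt(V / W))
}

#' Genomic prediction accuracy
#'
#' Pearson correlation between estimated breeding values
#' `EBV = X_test %*% a_hat` and adjusted phenotypes `y_test - mu_hat`
#' (the general mean is the only fixed effect in the model, so adjustment
#' is its subtraction).
#'
#' @param a_hat posterior-mean marker effects.
#' @param mu_hat posterior-mean general mean.
#' @param X_test test genotype matrix centered with the training means
#'   (a [geno_data] or plain matrix).
#' @param y_test test phenotypes.
#' @return scalar correlation; `NA` with a warning when either side has
#'   zero variance.
#' @export
prediction_accuracy <- function(a_hat, mu_hat, X_test, y_test) {
  ebv <- predict_ebv(X_test, a_hat)
  adj <- y_test - mu_hat
  if (var(ebv) == 0 || var(adj) == 0) {
    warning("zero variance in EBVs or adjusted phenotypes; accuracy undefined")
    return(NA_real_)
  }
  cor(ebv, adj)
}

#' Agreement between two samplers' breeding values
#'
#' Pearson correlation between the test-set EBV vectors implied by the
#' posterior-mean marker effects of two chains run on the same data (the
#' standard check that two samplers target the same posterior).
#'
#' @param trace_a,trace_b `chain_trace` objects over the same marker set.
#' @param X_test centered test genotype matrix.
#' @param burn_in burn-in fraction for both chains (default 0.2).
#' @return scalar correlation.
#' @export
method_agreement <- function(trace_a, trace_b, X_test, burn_in = 0.2) {
  stopifnot(inherits(trace_a, "chain_trace"), inherits(trace_b, "chain_trace"))
  if (!identical(trace_a$marker_names, trace_b$marker_names))
    stop("chains were run on different marker sets")
  ebv_a <- predict_ebv(X_test, posterior_mean_effects(trace_a, burn_in))
  ebv_b <- predict_ebv(X_test, posterior_mean_effects(trace_b, burn_in))
  cor(ebv_a, ebv_b)
}

#' Convergence and prediction report
#'
#' Computes PSRFs across chains for each scalar parameter (convergence is
#' conventionally declared when the PSRF of the marker-effect variance
#' falls below 1.1), and, when test data are supplied, the prediction
#' accuracy of the chain-averaged posterior-mean effects.
#'
#' @param traces list of `chain_trace` objects (>= 2 for PSRFs).
#' @param X_test,y_test optional test set (centered genotypes, phenotypes).
#' @param burn_in burn-in fraction (default 0.2).
#' @return object of class `diagnostics_report`: list with `psrf` (named
#'   vector over `mu`, `pi`, `sigma2_a`, `sigma2_e`), `converged`
#'   (PSRF of `sigma2_a` < 1.1), `accuracy`, `n_iterations_used`, and
#'   `burn_in`.
#' @export
diagnostics_report <- function(traces, X_test = NULL, y_test = NULL,
                               burn_in = 0.2) {
  stopifnot(length(traces) >= 1, all(vapply(traces, inherits, TRUE,
                                            "chain_trace")))
  n_iter <- traces[[1]]$n_iter
  keep <- traces[[1]]$scalars$iter > burn_in * n_iter
  params <- c("mu", "pi", "sigma2_a", "sigma2_e")
  psrfs <- if (length(traces) >= 2) {
    vapply(params, function(pn)
      psrf(lapply(traces, function(tr) tr$scalars[[pn]][keep])), 0)
  } else {
    setNames(rep(NA_real_, length(params)), params)
  }
  accuracy <- NA_real_
  if (!is.null(X_test) && !is.null(y_test)) {
    a_hat <- rowMeans(vapply(traces, posterior_mean_effects,
                             numeric(length(traces[[1]]$a_mean)),
                             burn_in = burn_in))
    mu_hat <- mean(vapply(traces, posterior_mean_mu, 0, burn_in = burn_in))
    accuracy <- prediction_accuracy(a_hat, mu_hat, X_test, y_test)
  }
  structure(list(psrf = psrfs,
                 converged = is.finite(psrfs["sigma2_a"]) &&
                   psrfs["sigma2_a"] < 1.1,
                 accuracy = accuracy,
                 n_iterations_used = sum(keep),
                 burn_in = burn_in),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("diagnostics_report\n")
  for (pn in names(x$psrf))
    cat(sprintf("  psrf.%s = %.6g\n", pn, x$psrf[[pn]]))
  cat(sprintf("  converged = %s (PSRF(sigma2_a) < 1.1)\n", x$converged))
  cat(sprintf("  accuracy = %.6g\n", x$accuracy))
  cat(sprintf("  n_iterations_used = %d\n  burn_in = %g\n",
              x$n_iterations_used, x$burn_in))
  invisible(x)
}

#' Write a diagnostics report as key = value text
#'
#' @param report a `diagnostics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "diagnostics_report"))
  lines <- c(
    sprintf("psrf.%s = %.10g", names(report$psrf), report$psrf),
    sprintf("converged = %s", report$converged),
    sprintf("accuracy = %.10g", report$accuracy),
    sprintf("n_iterations_used = %d", report$n_iterations_used),
    sprintf("burn_in = %g", report$burn_in))
  writeLines(lines, path)
  invisible(path)
}
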