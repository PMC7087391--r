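# ChainTrace container and posterior summaries shared by both samplers.

new_chain_trace <- function(scalars, a_thin, delta_thin, thin_iters, a_mean,
                            n_iter, thin, seed, method, marker_names,
                            op_count = NA_real_) {
  scalars <- as.data.frame(scalars)
  names(scalars) <- c("mu", "pi", "sigma2_a", "sigma2_e", "n_included")
  scalars <- cbind(iter = seq_len(nrow(scalars)) - 1L, scalars)
  colnames(a_thin) <- marker_names
  structure(list(scalars = scalars, a_thin = a_thin,
                 delta_thin = delta_thin, thin_iters = as.integer(thin_iters),
                 a_mean = as.numeric(a_mean), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = seed, method = method,
                 marker_names = marker_names, op_count = op_count,
                 format_version = 1L),
            class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("chain_trace [%s]: %d iterations (thin %d, seed %s), %d markers\n",
              x$method, x$n_iter, x$thin,
              if (is.null(x$seed)) "none" else x$seed,
              length(x$marker_names)))
  invisible(x)
}

#' Posterior-mean marker effects from a chain
#'
#' Averages the thinned marker-effect samples recorded after the burn-in.
#'
#' @param trace a `chain_trace`.
#' @param burn_in fraction of the chain discarded as burn-in (default 0.2).
#' @return named numeric vector of posterior means.
#' @export
posterior_mean_effects <- function(trace, burn_in = 0.2) {
  stopifnot(inherits(trace, "chain_trace"), burn_in >= 0, burn_in < 1)
  keep <- trace$thin_iters > burn_in * trace$n_iter
  if (!any(keep)) keep <- length(trace$thin_iters) == seq_along(trace$thin_iters)
  colMeans(trace$a_thin[keep, , drop = FALSE])
}

#' Posterior-mean general mean from a chain
#'
#' @inheritParams posterior_mean_effects
#' @return scalar posterior mean of `mu`.
#' @export
posterior_mean_mu <- function(trace, burn_in = 0.2) {
  keep <- trace$scalars$iter > burn_in * trace$n_iter
  if (!any(keep)) keep <- seq_len(nrow(trace$scalars)) == nrow(trace$scalars)
  mean(trace$scalars$mu[keep])
}

#' Genomic estimated breeding values
#'
#' `EBV = X %*% a_hat` for a (test) genotype matrix centered with the
#' training means.
#'
#' @param G a [geno_data] or plain matrix.
#' @param a_hat marker-effect estimates (e.g. [posterior_mean_effects()]).
#' @return numeric vector of EBVs.
#' @export
predict_ebv <- function(G, a_hat) {
  X <- if (inherits(G, "geno_data")) G$X else as.matrix(G)
  stopifnot(ncol(X) == length(a_hat))
  as.numeric(X %*% a_hat)
}
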