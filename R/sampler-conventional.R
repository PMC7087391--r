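#' Run a conventional single-site BayesCpi chain
#'
#' Full Gibbs cycle per iteration: general mean, single-site sweep over all
#' marker effects (ascending index order), then variance components and the
#' null-effect probability `pi`.  Two computational variants of the sweep
#' are available with identical output: variant `"I"` maintains the residual
#' vector (time O(n p) per iteration, space O(n p)); variant `"II"` works
#' from precomputed `X'y` and `X'X` (time O(p^2) per iteration, space
#' O(p^2)).  The chain is deterministic given `seed`.
#'
#' @param G a centered [geno_data] (or plain centered matrix with allele
#'   frequencies supplied via `G`).
#' @param y phenotype vector.
#' @param hyper a [bayescpi_hyper]; data-dependent defaults are resolved
#'   against `G` and `y`.
#' @param n_iter chain length (number of Gibbs cycles).
#' @param thin thinning interval for stored marker-effect samples.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param variant `"I"` (residual updating) or `"II"` (crossproducts).
#' @param init optional `model_state` to start from; defaults to
#'   [draw_initial_state()].
#' @param audit_every iterations between internal consistency audits of the
#'   maintained residual/crossproduct state (0 disables).
#' @return a `chain_trace` (see [posterior_mean_effects()]): per-iteration
#'   scalar samples of `mu`, `pi`, `sigma2_a`, `sigma2_e` and the number of
#'   included markers; thinned samples of the marker effects and
#'   indicators; the running mean of the effects; and an elementary
#'   operation count for complexity checks.
#' @export
run_chain <- function(G, y, hyper = bayescpi_hyper(), n_iter = 1000,
                      thin = 10, seed = NULL, variant = c("I", "II"),
                      init = NULL, audit_every = 1000) {
  variant <- match.arg(variant)
  stopifnot(inherits(G, "geno_data"))
  if (!G$centered) stop("genotypes must be centered (see center_genotypes)")
  X <- G$X
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  hyper <- resolve_hyper(hyper, G, y)
  if (!is.null(seed)) set.seed(seed)
  state <- init %||% draw_initial_state(G, y, hyper)
  stopifnot(length(state$a) == ncol(X))

  res <- cpp_bayescpi_chain(
    X, y, match(variant, c("I", "II")), as.integer(n_iter),
    as.integer(thin), hyper$nu_e, hyper$S2_e, hyper$nu_a, hyper$S2_a,
    hyper$estimate_pi, hyper$estimate_variances,
    state$mu, state$a, state$pi, state$sigma2_a, state$sigma2_e,
    as.integer(audit_every))

  new_chain_trace(res$scalars, res$a_thin, res$delta_thin, res$thin_iters,
                  res$a_mean, n_iter, thin, seed,
                  paste0("conventional-", variant), colnames(X),
                  res$op_count)
}

#' Run several chains from dispersed starting values
#'
#' Runs `n_chains` chains whose seeds are `master_seed + 1, ...,
#' master_seed + n_chains`; each chain draws its own starting marker effects
#' from the starting-value distribution, giving the dispersed starts needed
#' for Gelman-Rubin diagnostics.
#'
#' @inheritParams run_chain
#' @param n_chains number of chains.
#' @param master_seed master seed; per-chain seeds are offsets from it.
#' @param method `"conventional"` (with `variant`) or `"xii"`.
#' @param aug augmentation, required for `method = "xii"`.
#' @param workers worker count for the BayesXII marker map.
#' @return list of `chain_trace` objects.
#' @export
run_chains <- function(G, y, hyper = bayescpi_hyper(), n_iter = 1000,
                       thin = 10, n_chains = 5, master_seed = 1,
                       method = c("conventional", "xii"), variant = "I",
                       aug = NULL, workers = 1) {
  method <- match.arg(method)
  lapply(seq_len(n_chains), function(k) {
    s <- as.integer(master_seed + k)
    if (method == "conventional")
      run_chain(G, y, hyper, n_iter, thin, seed = s, variant = variant)
    else
      run_chain_xii(G, y, aug, hyper, n_iter, thin, seed = s,
                    workers = workers)
  })
}
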