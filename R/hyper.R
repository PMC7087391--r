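#' BayesCpi hyperparameters
#'
#' Prior settings for the spike-and-slab whole-genome regression: scaled
#' inverse chi-square priors `nu S^2 inv-chi2(nu)` on the residual and
#' marker-effect variances, and (optionally estimated) probability `pi` that
#' a marker has a *null* effect, with a uniform prior on `pi`.
#'
#' Data-dependent defaults are resolved at run time by the samplers:
#' `S2_a` defaults to the starting-value variance
#' `sigma2_g / ((1 - pi_init) * sum(2 p_i (1 - p_i)))` and `S2_e` to
#' `var(y) * (1 - h2_guess)`.
#'
#' @param nu_e,nu_a prior degrees of freedom (default 4).
#' @param S2_e,S2_a prior scales; `NULL` means resolve from the data.
#' @param pi_init initial value for the null-effect probability.
#' @param estimate_pi draw `pi` from its Beta full conditional each
#'   iteration?  If `FALSE`, `pi` stays fixed at `pi_init`.
#' @param estimate_variances draw the two variance components?  If `FALSE`
#'   they stay fixed at their initial values (used for validation against
#'   closed-form conjugate posteriors).
#' @param genetic_variance assumed total genetic variance feeding the
#'   starting-value formula (default 1).
#' @param h2_guess heritability guess feeding the default residual scale
#'   (default 0.5).
#' @return object of class `bayescpi_hyper`.
#' @export
bayescpi_hyper <- function(nu_e = 4, S2_e = NULL, nu_a = 4, S2_a = NULL,
                           pi_init = 0.5, estimate_pi = TRUE,
                           estimate_variances = TRUE,
                           genetic_variance = 1, h2_guess = 0.5) {
  if (nu_e <= 0 || nu_a <= 0) stop("prior degrees of freedom must be > 0")
  if (!is.null(S2_e) && S2_e <= 0) stop("S2_e must be > 0")
  if (!is.null(S2_a) && S2_a <= 0) stop("S2_a must be > 0")
  if (pi_init < 0 || pi_init > 1) stop("pi_init must lie in [0, 1]")
  if (genetic_variance <= 0) stop("genetic_variance must be > 0")
  if (h2_guess <= 0 || h2_guess >= 1) stop("h2_guess must lie in (0, 1)")
  structure(list(nu_e = nu_e, S2_e = S2_e, nu_a = nu_a, S2_a = S2_a,
                 pi_init = pi_init, estimate_pi = isTRUE(estimate_pi),
                 estimate_variances = isTRUE(estimate_variances),
                 genetic_variance = genetic_variance, h2_guess = h2_guess),
            class = "bayescpi_hyper")
}

#' Starting-value variance for marker effects
#'
#' The marker-effect variance implied by partitioning an assumed genetic
#' variance over the expected number of non-null markers:
#' `sigma2_a = sigma2_g / ((1 - pi) * sum(2 p_i (1 - p_i)))`.
#'
#' @param sigma2_g assumed genetic variance.
#' @param pi null-effect probability (must be < 1).
#' @param sum2pq `sum(2 p_i (1 - p_i))` over loci (must be > 0).
#' @return scalar variance.
#' @export
starting_sigma2_a <- function(sigma2_g, pi, sum2pq) {
  if (sum2pq <= 0) stop("sum(2 p (1 - p)) must be > 0")
  if (pi >= 1) stop("the starting-value formula requires pi < 1")
  sigma2_g / ((1 - pi) * sum2pq)
}

# fill data-dependent hyperparameter defaults; returns hyper with numeric
# S2_e/S2_a and the resolved starting variance attached
resolve_hyper <- function(hyper, G, y) {
  stopifnot(inherits(hyper, "bayescpi_hyper"))
  s2pq <- sum_2pq(G)
  s2a0 <- starting_sigma2_a(hyper$genetic_variance,
                            min(hyper$pi_init, 0.999), s2pq)
  hyper$S2_a <- hyper$S2_a %||% s2a0
  hyper$S2_e <- hyper$S2_e %||% (var(y) * (1 - hyper$h2_guess))
  hyper$sigma2_a_start <- s2a0
  hyper$sigma2_e_start <- var(y) * (1 - hyper$h2_guess)
  hyper
}

#' Draw a starting model state
#'
#' Marker effects start from `N(0, sigma2_a)` with `sigma2_a` given by
#' [starting_sigma2_a()] (dispersed starts for multi-chain convergence
#' diagnostics); all inclusion indicators start at 1, the mean at `mean(y)`,
#' and the residual variance at `var(y) * (1 - h2_guess)`.
#'
#' @param G a [geno_data] (allele frequencies must be available).
#' @param y phenotype vector.
#' @param hyper a [bayescpi_hyper].
#' @return object of class `model_state`: list with `mu`, `a`, `delta`,
#'   `pi`, `sigma2_a`, `sigma2_e`.
#' @export
draw_initial_state <- function(G, y, hyper = bayescpi_hyper()) {
  stopifnot(inherits(G, "geno_data"))
  hyper <- resolve_hyper(hyper, G, y)
  p <- ncol(G$X)
  structure(list(mu = mean(y),
                 a = rnorm(p, 0, sqrt(hyper$sigma2_a_start)),
                 delta = rep(1L, p),
                 pi = hyper$pi_init,
                 sigma2_a = hyper$sigma2_a_start,
                 sigma2_e = hyper$sigma2_e_start),
            class = "model_state")
}
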