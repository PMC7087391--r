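# Reference R implementations of the BayesCpi full conditionals.
#
# These are the single-draw building blocks: the compiled chain runner
# (src/sampler.cpp) replicates them step for step, consuming the R RNG
# stream in exactly the same order, which is asserted by a parity test.
# They are also reused by the BayesXII sampler for the updates that do not
# involve the augmentation (sigma2_a and pi depend only on a and delta).

#' Sample the general mean
#'
#' Flat prior: `mu | ELSE ~ N(1'(y - X a)/n, sigma2_e/n)`.
#'
#' @param state a `model_state`.
#' @param y phenotypes.
#' @param X centered marker matrix.
#' @return updated state (new `mu`).
#' @export
sample_mu <- function(state, y, X) {
  n <- length(y)
  r <- y - as.numeric(X %*% state$a)
  state$mu <- rnorm(1, mean(r), sqrt(state$sigma2_e / n))
  state
}

# log marginal-likelihood ratio of delta_j = 1 vs 0, given the adjusted
# right-hand side rhs_j and the column sum of squares cj (or d for the
# augmented sampler)
marker_log_lr <- function(rhs, cj, sigma2_e, sigma2_a) {
  v <- cj * sigma2_a + sigma2_e
  -0.5 * log(v / sigma2_e) + rhs^2 * sigma2_a / (2 * sigma2_e * v)
}

# inclusion probability from the log likelihood ratio and the null-effect
# prior probability pi; numerically stable via plogis
marker_inclusion_prob <- function(log_lr, pi) {
  if (pi <= 0) return(rep(1, length(log_lr)))
  if (pi >= 1) return(rep(0, length(log_lr)))
  plogis(log_lr + log((1 - pi) / pi))
}

#' Sample one marker effect and its inclusion indicator
#'
#' Spike-and-slab full conditional for marker `j`: the indicator is drawn
#' from its marginal (effect integrated out) via the log likelihood ratio
#' `-0.5 log((cj s2a + s2e)/s2e) + rhs^2 s2a / (2 s2e (cj s2a + s2e))`,
#' and, when included, the effect from
#' `N(rhs / (cj + s2e/s2a), s2e / (cj + s2e/s2a))`.
#'
#' @param rhs adjusted right-hand side
#'   `X_j' (y - 1 mu - sum_{j' != j} X_j' a_j')`.
#' @param cj column sum of squares `X_j' X_j` (must be > 0).
#' @param sigma2_e,sigma2_a current variance components.
#' @param pi null-effect probability.
#' @return list with `a`, `delta`, and the deterministic pieces
#'   `prob_include`, `mean`, `var` (exposed for validation).
#' @export
sample_marker_effect <- function(rhs, cj, sigma2_e, sigma2_a, pi) {
  if (cj <= 0) stop("marker with non-positive sum of squares (monomorphic?)")
  log_lr <- marker_log_lr(rhs, cj, sigma2_e, sigma2_a)
  p1 <- marker_inclusion_prob(log_lr, pi)
  denom <- cj + sigma2_e / sigma2_a
  m <- rhs / denom
  v <- sigma2_e / denom
  u <- runif(1)
  if (u < p1) {
    list(a = rnorm(1, m, sqrt(v)), delta = 1L,
         prob_include = p1, mean = m, var = v)
  } else {
    list(a = 0, delta = 0L, prob_include = p1, mean = m, var = v)
  }
}

#' One single-site sweep over all markers
#'
#' Updates every marker effect in ascending index order from its full
#' conditional.  Variant `"I"` maintains the residual vector
#' `e = y - 1 mu - X a` and computes `rhs_j = X_j' e + cj a_j` (cost O(n)
#' per marker); variant `"II"` works from the precomputed crossproducts
#' `X' y` and `X' X` (cost O(p) per marker).  Both variants consume the RNG
#' stream identically and produce numerically identical chains.
#'
#' @param state a `model_state`.
#' @param y phenotypes.
#' @param X centered marker matrix.
#' @param variant `"I"` or `"II"`.
#' @param XtX,Xty optional precomputations for variant II.
#' @return updated state.
#' @export
marker_sweep <- function(state, y, X, variant = c("I", "II"),
                         XtX = NULL, Xty = NULL) {
  variant <- match.arg(variant)
  p <- ncol(X)
  cj <- colSums(X^2)
  if (variant == "I") {
    e <- y - state$mu - as.numeric(X %*% state$a)
    for (j in seq_len(p)) {
      rhs <- sum(X[, j] * e) + cj[j] * state$a[j]
      dr <- sample_marker_effect(rhs, cj[j], state$sigma2_e,
                                 state$sigma2_a, state$pi)
      if (dr$a != state$a[j]) e <- e - X[, j] * (dr$a - state$a[j])
      state$a[j] <- dr$a
      state$delta[j] <- dr$delta
    }
  } else {
    XtX <- XtX %||% crossprod(X)
    Xty <- Xty %||% as.numeric(crossprod(X, y))
    Xt1 <- colSums(X)
    s <- as.numeric(XtX %*% state$a)
    for (j in seq_len(p)) {
      rhs <- Xty[j] - Xt1[j] * state$mu - s[j] + cj[j] * state$a[j]
      dr <- sample_marker_effect(rhs, cj[j], state$sigma2_e,
                                 state$sigma2_a, state$pi)
      if (dr$a != state$a[j]) s <- s + XtX[, j] * (dr$a - state$a[j])
      state$a[j] <- dr$a
      state$delta[j] <- dr$delta
    }
  }
  state
}

#' Sample the variance components and pi
#'
#' Conjugate updates: with `m = sum(delta)`,
#' `sigma2_a ~ (nu_a S2_a + sum a_j^2) / chisq(nu_a + m)`,
#' `sigma2_e ~ (nu_e S2_e + e'e) / chisq(nu_e + n)`, and with a uniform
#' prior on the null-effect probability,
#' `pi ~ Beta(p - m + 1, m + 1)`.
#'
#' @param state a `model_state`.
#' @param y phenotypes.
#' @param X centered marker matrix.
#' @param hyper resolved [bayescpi_hyper] (numeric scales).
#' @return updated state.
#' @export
sample_variances_and_pi <- function(state, y, X, hyper) {
  p <- length(state$a)
  m <- sum(state$delta)
  if (hyper$estimate_variances) {
    state$sigma2_a <- (hyper$nu_a * hyper$S2_a + sum(state$a^2)) /
      rchisq(1, hyper$nu_a + m)
    e <- y - state$mu - as.numeric(X %*% state$a)
    state$sigma2_e <- (hyper$nu_e * hyper$S2_e + sum(e^2)) /
      rchisq(1, hyper$nu_e + length(y))
  }
  if (hyper$estimate_pi) state$pi <- rbeta(1, p - m + 1, m + 1)
  state
}

# one full Gibbs cycle in pure R (mu -> sweep -> variances/pi); used to
# cross-check the compiled runner
full_iteration_r <- function(state, y, X, hyper, variant = "I",
                             XtX = NULL, Xty = NULL) {
  state <- sample_mu(state, y, X)
  state <- marker_sweep(state, y, X, variant, XtX = XtX, Xty = Xty)
  sample_variances_and_pi(state, y, X, hyper)
}
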